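test_that("a disconnected input has exactly zero sensitivity", {
  coh <- make_mini_cohort(seed = 11)
  ens <- ann_ensemble(coh, features = c("TP", "Na", "K"),
                      n_models = 4, seed = 1)
  # sever potassium from every network's hidden layer
  for (m in seq_along(ens$models))
    ens$models[[m]]$weights$W1[3, ] <- 0
  s <- sensitivity(ens)
  expect_equal(s$mean[s$variable == "K"], 0)
  expect_equal(s$sd[s$variable == "K"], 0)
})

test_that("a zero-variance feature is flagged degenerate", {
  coh <- make_mini_cohort(seed = 12)
  coh$K <- 4.2
  ens <- ann_ensemble(coh, features = c("TP", "Na", "K"),
                      n_models = 4, seed = 1)
  s <- sensitivity(ens)
  expect_true(s$degenerate[s$variable == "K"])
  expect_false(any(s$degenerate[s$variable != "K"]))
})

test_that("forward and central differences give comparable rankings", {
  coh <- make_mini_cohort(seed = 13)
  ens <- ann_ensemble(coh, n_models = 4, seed = 2)
  sf <- sensitivity(ens, method = "forward")
  sc <- sensitivity(ens, method = "central")
  expect_setequal(sf$variable, sc$variable)
  # top variable under one scheme is near the top under the other
  expect_lte(match(sf$variable[1], sc$variable), 3)
  expect_error(sensitivity(ens, delta = 0), "positive")
})

test_that("top-variable selection keeps k analytes plus total length", {
  sens <- structure(
    data.frame(variable = c("TP", "Na", "Ca", "ALB", "GLOB", "K",
                            "total_length", "age"),
               mean = c(0.9, 0.8, 0.7, 0.6, 0.65, 0.1, 0.75, 0.5),
               sd = 0.01, degenerate = FALSE),
    class = c("ann_sensitivity", "data.frame"))
  sel <- select_top_variables(sens, k = 4)
  expect_setequal(sel, c("TP", "Na", "Ca", "ALB", "total_length"))
  expect_false("age" %in% sel)
  # derived globulin is barred by default, included when allowed
  sel2 <- select_top_variables(sens, k = 4, exclusions = character())
  expect_true("GLOB" %in% sel2)
  # lethal mode may keep age
  sel3 <- select_top_variables(sens, k = 4, non_lethal = FALSE)
  expect_true("age" %in% sel3)
  # k covering every analyte returns them all
  sel4 <- select_top_variables(sens, k = 6)
  expect_setequal(setdiff(sel4, "total_length"),
                  c("TP", "Na", "Ca", "ALB", "K"))
})

test_that("an exact tie at the selection boundary warns", {
  sens <- structure(
    data.frame(variable = c("TP", "Na", "Ca", "ALB", "K",
                            "total_length"),
               mean = c(0.9, 0.8, 0.5, 0.5, 0.5, 0.7),
               sd = 0.01, degenerate = FALSE),
    class = c("ann_sensitivity", "data.frame"))
  expect_warning(sel <- select_top_variables(sens, k = 3), "tie")
  # deterministic break: larger mean then lexicographic code
  expect_equal(sel, c("TP", "Na", "ALB", "total_length"))
})

test_that("exact top-4 recovery is sampling-limited at the study's cohort size", {
  # even ranking analytes by their true point-biserial correlation with
  # status (no model at all) often misses the weakest planted analyte at
  # n = 39; tripling the cohort makes the planted set identifiable
  planted <- c("Ca", "Na", "TP", "ALB", "total_length")
  cfg <- plant_effects(default_generator_config(), informative = planted)
  oracle_rate <- function(mult, n_rep = 40) {
    hits <- 0
    for (s in seq_len(n_rep)) {
      coh <- generate_cohort(cfg, n_multiplier = mult, seed = 3000 + s)
      y <- as.numeric(coh$status == "diseased")
      chem <- setdiff(analyte_codes(retained = TRUE), "GLOB")
      r <- vapply(chem, function(v) abs(cor(coh[[v]], y)), numeric(1))
      top4 <- names(sort(r, decreasing = TRUE))[1:4]
      hits <- hits + setequal(top4, c("Ca", "Na", "TP", "ALB"))
    }
    hits / n_rep
  }
  expect_lt(oracle_rate(1), 0.8)
  expect_gte(oracle_rate(3), 0.9)
})

test_that("screening recovers planted signal variables", {
  planted <- c("Ca", "Na", "TP", "ALB", "total_length")
  cfg <- plant_effects(default_generator_config(), informative = planted)
  hits <- 0
  for (s in 1:5) {
    coh <- generate_cohort(cfg, n_multiplier = 3, seed = 500 + s)
    sens <- screen_variables(coh, seed = s)
    sel <- select_top_variables(sens, k = 4)
    hits <- hits + setequal(sel, planted)
  }
  expect_gte(hits, 4)
})
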