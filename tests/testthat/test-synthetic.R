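test_that("generation is deterministic given config and seed", {
  cfg <- default_generator_config()
  c1 <- generate_cohort(cfg, seed = 21)
  c2 <- generate_cohort(cfg, seed = 21)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  c3 <- generate_cohort(cfg, seed = 22)
  expect_false(identical(as.data.frame(c1), as.data.frame(c3)))
})

test_that("globulin equals total protein minus albumin for every fish", {
  coh <- generate_cohort(default_generator_config(), seed = 23)
  expect_equal(coh$GLOB, coh$TP - coh$ALB)
  expect_true(all(coh$GLOB > 0))
})

test_that("zero dispersion collapses each group onto its mean", {
  cfg <- default_generator_config()
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$analyte_sds[] <- 0
    cfg$groups[[g]]$morpho_sds[] <- 0
  }
  coh <- generate_cohort(cfg, seed = 24)
  mh <- coh[coh$sex == "male" & coh$status == "healthy", ]
  expect_equal(unique(mh$TP), cfg$groups$male_healthy$analyte_means[["TP"]])
  expect_equal(unique(mh$total_length),
               cfg$groups$male_healthy$morpho_means[["total_length"]])
  expect_equal(length(unique(mh$Na)), 1)
})

test_that("empirical group means converge to the configured targets", {
  # n x 100 per group; checked within 3 standard errors for analytes whose
  # positivity truncation is negligible (mean > 3 SDs above zero)
  cfg <- default_generator_config()
  coh <- generate_cohort(cfg, n_multiplier = 100, seed = 7)
  for (g in cfg$groups) {
    sub <- coh[coh$sex == g$sex & coh$status == g$status, ]
    for (a in c("TP", "ALB", "Ca", "Na", "K", "GLU", "PHOS")) {
      mu <- g$analyte_means[[a]]; sdev <- g$analyte_sds[[a]]
      if (mu / sdev < 3) next
      se <- sdev / sqrt(nrow(sub))
      expect_lt(abs(mean(sub[[a]]) - mu), 3 * se + 1e-9,
                label = sprintf("%s %s %s", g$sex, g$status, a))
    }
  }
  # healthy-combined total protein sits near its configured 3.9-4.0 g/dL
  expect_equal(mean(coh$TP[coh$status == "healthy"]), 3.95,
               tolerance = 0.02)
})

test_that("vet scores are consistent with group status", {
  coh <- generate_cohort(default_generator_config(), seed = 25)
  expect_true(all(coh$vet_score[coh$status == "healthy"] %in% c(0, 0.5)))
  dis <- coh$vet_score[coh$status == "diseased"]
  expect_true(all(dis >= 1 & dis <= 5))
  expect_true(all(dis * 2 == round(dis * 2)))
})

test_that("study missing-data topology is reproduced", {
  coh <- generate_cohort(default_generator_config(), seed = 26)
  art <- inject_study_artifacts(coh, seed = 26)
  expect_true(all(is.na(art$UA)))
  expect_equal(sum(is.na(art$CK)), 1)
  ba_missing <- sum(is.na(art$BA))
  expect_gt(ba_missing, 0)
  expect_lt(ba_missing, nrow(art) / 2)
  art2 <- inject_study_artifacts(coh, seed = 26)
  expect_identical(is.na(art$BA), is.na(art2$BA))
  expect_identical(which(is.na(art$CK)), which(is.na(art2$CK)))
})

test_that("plant_effects equalizes exactly the non-informative variables", {
  cfg <- default_generator_config()
  expect_identical(plant_effects(cfg, informative = character(),
                                 null_shift = FALSE)$groups, cfg$groups)
  expect_error(plant_effects(cfg, informative = "XYZ"), "unknown")

  planted <- plant_effects(cfg, informative = c("TP", "total_length"))
  g <- planted$groups
  # untouched: TP and length keep their group differences
  expect_false(g$male_healthy$analyte_means[["TP"]] ==
               g$male_diseased$analyte_means[["TP"]])
  expect_false(g$male_healthy$morpho_means[["total_length"]] ==
               g$male_diseased$morpho_means[["total_length"]])
  # flattened: every other variable identical across groups
  for (a in c("Na", "Ca", "ALB", "GLU")) {
    vals <- vapply(g, function(x) x$analyte_means[[a]], numeric(1))
    expect_equal(length(unique(vals)), 1, label = a)
  }
  ages <- vapply(g, function(x) x$morpho_means[["age"]], numeric(1))
  expect_equal(length(unique(ages)), 1)

  nullcfg <- plant_effects(cfg, null_shift = TRUE)
  tps <- vapply(nullcfg$groups, function(x) x$analyte_means[["TP"]],
                numeric(1))
  expect_equal(length(unique(tps)), 1)
})

test_that("the bundled group-statistics file reproduces the default config", {
  cfg_yaml <- generator_config_from_yaml()
  cfg <- default_generator_config()
  for (g in names(cfg$groups)) {
    expect_equal(cfg_yaml$groups[[g]]$analyte_means[names(cfg$groups[[g]]$analyte_means)],
                 cfg$groups[[g]]$analyte_means, info = g)
    expect_equal(cfg_yaml$groups[[g]]$analyte_sds[names(cfg$groups[[g]]$analyte_sds)],
                 cfg$groups[[g]]$analyte_sds, info = g)
    expect_equal(cfg_yaml$groups[[g]]$n, cfg$groups[[g]]$n)
  }
  c1 <- generate_cohort(cfg_yaml, seed = 30)
  c2 <- generate_cohort(cfg, seed = 30)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("instrument-range truncation keeps draws inside detection bounds", {
  cfg <- default_generator_config()
  cfg$truncation <- "instrument_range"
  coh <- generate_cohort(cfg, seed = 27)
  flags <- lapply(seq_len(nrow(coh)), function(i) {
    v <- unlist(as.data.frame(coh)[i, analyte_codes()])
    range_flags(v)
  })
  present <- unlist(flags)
  expect_true(all(present %in% c("in_range", "missing")))
})
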