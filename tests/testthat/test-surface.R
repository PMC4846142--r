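test_that("a 5% step spans each observed range in 21 nodes", {
  coh <- make_mini_cohort(seed = 14)
  ens <- ann_ensemble(coh, n_models = 4, seed = 1)
  g <- clamp_grid(ens, "total_length", "Na")
  expect_length(g$x_values, 21)
  expect_length(g$y_values, 21)
  expect_equal(g$x_values[1], min(ens$x[, "total_length"]))
  expect_equal(g$x_values[21], max(ens$x[, "total_length"]))
  expect_equal(diff(g$x_values), rep(diff(range(ens$x[, "total_length"])) / 20,
                                     20))
  # clamp values are the modelling-cohort column means
  for (v in names(g$clamped))
    expect_equal(g$clamped[[v]], mean(ens$x[, v]), info = v)
  expect_error(clamp_grid(ens, "Na", "Na"), "differ")
  expect_error(clamp_grid(ens, "Na", "UA"), "ensemble features")
})

test_that("grid arithmetic covers a simple known range", {
  coh <- make_mini_cohort(seed = 15)
  coh$GLU <- seq(0, 10, length.out = nrow(coh))
  ens <- ann_ensemble(coh, features = c("GLU", "TP", "total_length"),
                      n_models = 4, seed = 1)
  g <- clamp_grid(ens, "GLU", "TP")
  expect_equal(g$x_values, seq(0, 10, by = 0.5))
})

test_that("an ensemble of identical models yields a zero SD surface", {
  coh <- make_mini_cohort(seed = 16)
  ens <- ann_ensemble(coh, n_models = 4, seed = 2)
  for (m in seq_along(ens$models)) ens$models[[m]] <- ens$models[[1]]
  g <- predict_surface(ens, clamp_grid(ens, "total_length", "Na"))
  expect_equal(max(g$sd_surface), 0)
  adeq <- adequacy_summary(g, threshold = 0)
  expect_equal(adeq$fraction_above, 0)
  expect_equal(nrow(adeq$hotspots), 0)
})

test_that("surfaces are deterministic and invariant to model order", {
  coh <- make_mini_cohort(seed = 17)
  ens <- ann_ensemble(coh, n_models = 5, seed = 3)
  g1 <- predict_surface(ens, clamp_grid(ens, "total_length", "TP"))
  perm <- ens
  perm$models <- perm$models[c(3, 5, 1, 2, 4)]
  g2 <- predict_surface(perm, clamp_grid(perm, "total_length", "TP"))
  expect_equal(g1$mean_surface, g2$mean_surface, tolerance = 1e-12)
  expect_equal(g1$sd_surface, g2$sd_surface, tolerance = 1e-12)
})

test_that("a planted length-only signal gives a monotone mean surface", {
  cfg <- plant_effects(default_generator_config(),
                       informative = "total_length")
  coh <- generate_cohort(cfg, seed = 5)
  ens <- ann_ensemble(coh, seed = 5, lambda = 0.01)
  g <- predict_surface(ens, clamp_grid(ens, "total_length", "Na"))
  # disease prediction never decreases with length at any fixed Na
  for (j in seq_along(g$y_values))
    expect_true(all(diff(g$mean_surface[, j]) >= -1e-8))
})

test_that("refining the grid step re-evaluates shared nodes identically", {
  coh <- make_mini_cohort(seed = 18)
  ens <- ann_ensemble(coh, n_models = 4, seed = 4)
  coarse <- predict_surface(ens, clamp_grid(ens, "total_length", "Na",
                                            step = 0.1))
  fine <- predict_surface(ens, clamp_grid(ens, "total_length", "Na",
                                          step = 0.05))
  shared_i <- seq(1, 21, by = 2)
  expect_equal(fine$mean_surface[shared_i, shared_i],
               coarse$mean_surface, tolerance = 1e-10)
})

test_that("model disagreement is located where it occurs", {
  coh <- make_mini_cohort(seed = 19)
  ens <- ann_ensemble(coh, n_models = 4, seed = 5)
  g <- predict_surface(ens, clamp_grid(ens, "total_length", "Na"))
  g$sd_surface[] <- 0
  g$sd_surface[7, 3] <- 0.5
  adeq <- adequacy_summary(g, threshold = 0.1)
  expect_equal(adeq$fraction_above, 1 / 441)
  expect_equal(nrow(adeq$hotspots), 1)
  expect_equal(adeq$hotspots$total_length, g$x_values[7])
  expect_equal(adeq$hotspots$Na, g$y_values[3])
  expect_equal(adeq$max_sd, 0.5)
})
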