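test_that("assumption gates pass clean normal data and catch violations", {
  set.seed(10)
  a <- rnorm(15); b <- rnorm(15)
  chk <- check_assumptions(a, b)
  expect_true(chk$parametric_ok)
  expect_equal(chk$reason, "")
  # cross-check the gates against direct calls
  expect_equal(chk$shapiro_p[1], shapiro.test(a)$p.value)
  expect_equal(chk$shapiro_p[2], shapiro.test(b)$p.value)

  set.seed(11)
  skewed <- rexp(20)^2
  chk2 <- check_assumptions(skewed, rnorm(20))
  expect_false(chk2$parametric_ok)
  expect_equal(chk2$reason, "normality")

  set.seed(12)
  chk3 <- check_assumptions(rnorm(40, sd = 1), rnorm(40, sd = 10))
  expect_false(chk3$parametric_ok)
  expect_equal(chk3$reason, "variance")

  chk4 <- check_assumptions(c(1, 2), rnorm(10))
  expect_false(chk4$parametric_ok)
  expect_equal(chk4$reason, "insufficient n")
})

test_that("parametric comparisons agree with the reference t-test", {
  set.seed(20)
  for (i in 1:10) {
    a <- rnorm(12, mean = i / 5); b <- rnorm(14)
    chk <- check_assumptions(a, b)
    if (!chk$parametric_ok) next
    cmp <- compare_groups(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(cmp$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(cmp$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(cmp$test_used, "t_test")
  }
})

test_that("identical groups are not significant", {
  set.seed(21)
  v <- rnorm(15)
  cmp <- compare_groups(v, v)
  expect_false(cmp$significant)
  expect_gt(cmp$p_value, 0.9)
})

test_that("tiny-sample Mann-Whitney matches the exhaustive permutation oracle", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  # skewed enough that the pooled gate can't pass: force the rank route
  cmp <- suppressWarnings(compare_groups(c(a, 100), c(b, 2000)))
  expect_equal(cmp$test_used, "mann_whitney")
  # oracle on the canonical tiny fixture: U = 0, exact two-sided p = 0.1
  expect_equal(mw_exact_p(a, b), 0.1)
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(unname(ref$statistic), 0)
  # the normal approximation sits near the exact enumeration
  expect_lt(abs(ref$p.value - 0.1), 0.05)
})

test_that("relabelling the groups flips direction but not the p-value", {
  set.seed(22)
  for (i in 1:5) {
    a <- rnorm(12, 1); b <- rexp(13)
    c1 <- compare_groups(a, b, labels = c("healthy", "diseased"))
    c2 <- compare_groups(b, a, labels = c("diseased", "healthy"))
    expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
    expect_equal(c1$direction, c2$direction)
  }
})

test_that("test selection is deterministic given the data", {
  coh <- make_mini_cohort(seed = 9)
  t1 <- build_comparison_table(coh)
  t2 <- build_comparison_table(coh)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("a planted female shift is flagged dimorphic", {
  # shift of 2 pooled SDs at 20 fish per sex: detected nearly always
  hits <- 0; n_rep <- 100
  cfg <- default_generator_config()
  for (g in names(cfg$groups)) {
    cfg$groups[[g]]$n <- 20L
    if (cfg$groups[[g]]$sex == "female")
      cfg$groups[[g]]$analyte_means[["GLU"]] <-
        cfg$groups[[g]]$analyte_means[["GLU"]] + 2 *
          cfg$groups[[g]]$analyte_sds[["GLU"]]
  }
  for (s in seq_len(n_rep)) {
    coh <- generate_cohort(cfg, seed = 1000 + s)
    dec <- dimorphism_screen(coh, "GLU")
    hits <- hits + dec$dimorphic
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("a variable identical for all fish is not dimorphic", {
  coh <- make_mini_cohort(seed = 5)
  coh$GLU <- 40
  dec <- dimorphism_screen(coh, "GLU")
  expect_false(dec$dimorphic)
})

test_that("comparison table stratifies dimorphic variables and combines others", {
  coh <- make_mini_cohort(seed = 7)
  # UA is excluded from the default battery; when asked for explicitly,
  # its all-missing column is skipped with a reason, never aborting
  full <- build_comparison_table(coh, variables = c(analyte_codes(),
                                                    trait_codes()))
  expect_false("UA" %in% full$variable)
  expect_equal(unname(attr(full, "skipped")["UA"]), "all values missing")
  tab <- build_comparison_table(coh)
  expect_s3_class(tab, "comparison_table")
  expect_false("UA" %in% tab$variable)
  expect_false("BA" %in% tab$variable)
  for (v in unique(tab$variable)) {
    strata <- tab$stratum[tab$variable == v]
    dimo <- unique(tab$dimorphic[tab$variable == v])
    if (dimo) expect_setequal(strata, c("male", "female"))
    else expect_equal(strata, "combined")
  }
  md <- format_comparison_markdown(tab)
  expect_equal(length(md), nrow(tab) + 2)
})

test_that("single-variable cohort with no group difference yields one quiet row", {
  coh <- make_mini_cohort(seed = 8)
  set.seed(1)
  coh$K <- rnorm(nrow(coh), 4.2, 0.4)  # same distribution in all groups
  tab <- build_comparison_table(coh, variables = "K")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$stratum, "combined")
  expect_false(tab$significant)
})
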