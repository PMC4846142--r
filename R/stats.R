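#' Test whether two groups satisfy parametric assumptions
#'
#' Each group is checked for normality with a Shapiro-Wilk test and the
#' pair for equal variances with a Levene test (median-centered is the
#' `car` default; mean-centered classical Levene is used here to match the
#' test named, via `center = mean`). A failure of either gate at `alpha`
#' sends the comparison down the nonparametric route.
#'
#' @param group_a,group_b numeric vectors (NAs dropped).
#' @param alpha gate level, default 0.05.
#' @return List: `parametric_ok` flag, `reason` (`""`, `"normality"`,
#'   `"variance"` or `"insufficient n"`), and the gate p-values.
#' @export
check_assumptions <- function(group_a, group_b, alpha = 0.05) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3)
    return(list(parametric_ok = FALSE, reason = "insufficient n",
                shapiro_p = c(NA_real_, NA_real_), levene_p = NA_real_))
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant: not plausibly normal
    stats::shapiro.test(x)$p.value
  }
  sp <- c(sw(group_a), sw(group_b))
  lev_df <- data.frame(y = c(group_a, group_b),
                       g = factor(rep(c("a", "b"),
                                      c(length(group_a), length(group_b)))))
  lp <- if (stats::sd(lev_df$y) == 0) 1 else
    car::leveneTest(y ~ g, data = lev_df, center = mean)[1, "Pr(>F)"]
  reason <- if (any(sp < alpha)) "normality" else if (lp < alpha) "variance" else ""
  list(parametric_ok = reason == "", reason = reason,
       shapiro_p = sp, levene_p = lp)
}

#' Compare two groups with automatic test selection
#'
#' Runs a classical two-tailed equal-variance t-test when both groups pass
#' the normality and equal-variance gates, otherwise a Mann-Whitney U test
#' (normal approximation with tie and continuity correction). Direction is
#' taken from group means (t) or medians (U).
#'
#' @param group_a,group_b numeric vectors (NAs dropped); by convention a =
#'   healthy, b = diseased.
#' @param alpha significance level, default 0.05.
#' @param labels length-2 character naming the groups for the direction
#'   string.
#' @param welch use Welch's t instead of the pooled-variance t.
#' @return List of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value`, `significant`, `direction`, `n1`, `n2`, `assumptions`.
#' @export
compare_groups <- function(group_a, group_b, alpha = 0.05,
                           labels = c("a", "b"), welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b))
    stop("empty group after missing-value removal")
  chk <- check_assumptions(group_a, group_b, alpha)
  if (chk$parametric_ok) {
    tt <- stats::t.test(group_a, group_b, var.equal = !welch,
                        alternative = "two.sided")
    stat <- unname(tt$statistic); p <- tt$p.value; used <- "t_test"
    ca <- mean(group_a); cb <- mean(group_b)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                              exact = FALSE, correct = TRUE,
                                              alternative = "two.sided"))
    stat <- unname(wt$statistic); p <- wt$p.value; used <- "mann_whitney"
    ca <- stats::median(group_a); cb <- stats::median(group_b)
  }
  direction <- if (ca > cb) paste(labels[1], "higher")
               else if (cb > ca) paste(labels[2], "higher") else "equal"
  structure(list(test_used = used, statistic = stat, p_value = p,
                 significant = p < alpha, direction = direction,
                 n1 = length(group_a), n2 = length(group_b),
                 assumptions = chk),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, p = %.4g%s (%s; n = %d vs %d)\n",
              x$test_used, x$statistic, x$p_value,
              if (x$significant) " *" else "", x$direction, x$n1, x$n2))
  invisible(x)
}

cohort_variable <- function(cohort, variable) {
  if (!variable %in% names(cohort)) stop("unknown variable: ", variable)
  cohort[[variable]]
}

#' Screen a variable for sexual dimorphism
#'
#' Compares males against females separately within the healthy and within
#' the diseased fish; the variable is called dimorphic when either
#' within-status comparison is significant, in which case downstream
#' healthy-vs-diseased comparisons must be stratified by sex.
#'
#' @param cohort a `fish_cohort` with both sexes in both statuses.
#' @param variable analyte or trait column name.
#' @param alpha significance level.
#' @return List: `variable`, `dimorphic`, `p_healthy`, `p_diseased`,
#'   `undetermined` flag.
#' @export
dimorphism_screen <- function(cohort, variable, alpha = 0.05) {
  v <- cohort_variable(cohort, variable)
  p <- c(healthy = NA_real_, diseased = NA_real_)
  und <- FALSE
  for (st in c("healthy", "diseased")) {
    m <- v[cohort$status == st & cohort$sex == "male"]
    f <- v[cohort$status == st & cohort$sex == "female"]
    m <- m[!is.na(m)]; f <- f[!is.na(f)]
    if (!length(m) || !length(f)) { und <- TRUE; next }
    if (stats::sd(c(m, f)) == 0) { p[st] <- 1; next }
    p[st] <- compare_groups(m, f, alpha, labels = c("male", "female"))$p_value
  }
  if (und) warning("missing sex-by-status stratum for ", variable,
                   ": dimorphism undetermined")
  list(variable = variable,
       dimorphic = !und && any(p < alpha, na.rm = TRUE),
       p_healthy = unname(p["healthy"]), p_diseased = unname(p["diseased"]),
       undetermined = und)
}

#' Build the healthy-vs-diseased comparison table
#'
#' For each variable the sexual-dimorphism screen runs first; dimorphic
#' variables are compared healthy-vs-diseased within each sex, the rest
#' with sexes combined (combining increases power when male and female
#' distributions agree). Bile acids and uric acid are excluded by default.
#' Variables that cannot be compared (e.g. all-missing) are skipped with a
#' logged reason, never aborting the table.
#'
#' @param cohort a `fish_cohort`.
#' @param variables columns to compare; default 10 retained analytes plus
#'   the three morphometric traits.
#' @param alpha significance level.
#' @return Data frame of class `comparison_table`: one row per variable x
#'   stratum with test, statistic, p, significance, direction and group
#'   sizes; skipped variables are recorded in attribute `skipped`.
#' @export
build_comparison_table <- function(cohort,
                                   variables = c(analyte_codes(retained = TRUE),
                                                 trait_codes()),
                                   alpha = 0.05) {
  rows <- list(); skipped <- character()
  for (v in variables) {
    vals <- cohort_variable(cohort, v)
    if (all(is.na(vals))) { skipped[v] <- "all values missing"; next }
    dim_dec <- tryCatch(dimorphism_screen(cohort, v, alpha),
                        warning = function(w) suppressWarnings(
                          dimorphism_screen(cohort, v, alpha)))
    strata <- if (dim_dec$dimorphic) c("male", "female") else "combined"
    for (st in strata) {
      sub <- if (st == "combined") cohort else cohort_subset(cohort, sex = st)
      a <- sub[[v]][sub$status == "healthy"]
      b <- sub[[v]][sub$status == "diseased"]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) {
        skipped[paste(v, st)] <- "insufficient group size"; next
      }
      cmp <- compare_groups(a, b, alpha, labels = c("healthy", "diseased"))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, stratum = st, dimorphic = dim_dec$dimorphic,
        test_used = cmp$test_used, statistic = cmp$statistic,
        p_value = cmp$p_value, significant = cmp$significant,
        direction = cmp$direction, n_healthy = cmp$n1, n_diseased = cmp$n2,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(), stratum = character())
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Render a comparison table as markdown
#'
#' @param tab a `comparison_table`.
#' @return Character vector of markdown lines.
#' @export
format_comparison_markdown <- function(tab) {
  hdr <- "| variable | stratum | test | statistic | p | sig | direction |"
  sep <- "|---|---|---|---|---|---|---|"
  body <- sprintf("| %s | %s | %s | %.3g | %.4g | %s | %s |",
                  tab$variable, tab$stratum, tab$test_used, tab$statistic,
                  tab$p_value, ifelse(tab$significant, "*", ""),
                  tab$direction)
  c(hdr, sep, body)
}
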