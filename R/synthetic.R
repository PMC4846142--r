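# Snap derived config numerics to their 15-significant-digit decimal so a
# JSON round trip (replay.json) reproduces them bit for bit.
.canon_num <- function(x) {
  out <- as.numeric(sprintf("%.15g", x))
  names(out) <- names(x)
  out
}

# Printed group statistics (mean, SEM) for the four sex-by-status groups.
# SEMs convert to SDs via SD = SEM * sqrt(n of the printed group).
.table1_cells <- function() {
  # columns: male healthy (n 9), male diseased (n 10),
  #          female healthy (n 9), female diseased (n 11)
  m <- rbind(
    AST  = c(75, 22,  64, 18,  115, 47,  61, 15),
    CK   = c(1258, 500, 2123, 450, 2203, 680, 2079, 420),
    GLU  = c(43, 7,   32, 2,   34, 2,    36, 4),
    Ca   = c(14.5, 0.2, 12.2, 0.3, 15.9, 0.6, 14.8, 0.7),
    PHOS = c(8.0, 0.4, 5.1, 0.3,  7.6, 0.5,  6.4, 0.4),
    TP   = c(3.9, 0.1, 3.1, 0.1,  4.0, 0.2,  3.3, 0.1),
    ALB  = c(2.1, 0.1, 1.6, 0.1,  2.2, 0.1,  2.0, 0.1),
    K    = c(4.3, 0.2, 4.1, 0.2,  4.4, 0.3,  4.1, 0.1),
    Na   = c(172, 2,  162, 3,   170, 2,   166, 3))
  colnames(m) <- c("MH_mean", "MH_sem", "MD_mean", "MD_sem",
                   "FH_mean", "FH_sem", "FD_mean", "FD_sem")
  m
}

#' Default synthetic-cohort configuration
#'
#' Encodes the source study's group structure: four sex-by-status groups
#' of sizes 9 (healthy male), 10 (diseased male), 9 (healthy female) and
#' 11 (diseased female); per-group analyte means with SDs reconstructed
#' from printed standard errors (SD = SEM * sqrt(n)); morphometric means
#' (ages 5.5/7.5 years for healthy/diseased males and 6.4/9.6 for
#' females; total lengths 39.4 cm healthy with diseased males ~10% and
#' females ~6% longer; weights 1.5/2.0 and 1.3/1.5 kg) with SDs
#' defaulting to 10% of the mean. Globulin is never drawn — it is derived
#' as TP - ALB for every fish, and total protein and albumin are drawn
#' with correlation `rho_tp_alb` (default 0.3). Bile acids, which carry
#' no printed group statistics and are excluded from interpretation, are
#' drawn uninformatively within the instrument range. Uric acid is not
#' drawn (undetected in tilapia plasma).
#'
#' Vet scores are assigned consistently with status: healthy fish uniform
#' over \{0, 0.5\}, diseased fish from a truncated geometric over
#' \{1, 1.5, ..., 5\} so low grades dominate.
#'
#' @param seed integer seed stored in the config.
#' @return A `generator_config` list, serializable to JSON/YAML.
#' @export
default_generator_config <- function(seed = 1) {
  t1 <- .table1_cells()
  grp <- function(sex, status, n, mcol, scol, morpho) {
    means <- t1[, mcol]
    sds <- .canon_num(t1[, scol] * sqrt(n))
    # uninformative bile acids within the 35-200 umol/L instrument range
    means <- c(means, BA = 80)
    sds <- c(sds, BA = 25)
    list(sex = sex, status = status, n = n,
         analyte_means = means, analyte_sds = sds,
         morpho_means = morpho, morpho_sds = .canon_num(morpho * 0.10))
  }
  cfg <- list(
    groups = list(
      male_healthy = grp("male", "healthy", 9L, "MH_mean", "MH_sem",
                         c(total_length = 39.4, weight = 1.5, age = 5.5)),
      male_diseased = grp("male", "diseased", 10L, "MD_mean", "MD_sem",
                          c(total_length = 43.3, weight = 2.0, age = 7.5)),
      female_healthy = grp("female", "healthy", 9L, "FH_mean", "FH_sem",
                           c(total_length = 39.4, weight = 1.3, age = 6.4)),
      female_diseased = grp("female", "diseased", 11L, "FD_mean", "FD_sem",
                            c(total_length = 41.8, weight = 1.5, age = 9.6))),
    rho_tp_alb = 0.3,
    vet_score = list(p_geom = 0.4),
    truncation = "none",
    seed = as.integer(seed))
  class(cfg) <- c("generator_config", "list")
  cfg
}

.drawn_analytes <- function() c("AST", "CK", "GLU", "Ca", "PHOS",
                                "TP", "ALB", "K", "Na", "BA")

#' Read a generator configuration from a YAML file
#'
#' The bundled `table1_default.yaml` (under `extdata`) encodes the
#' printed group cells as mean/SEM pairs; SDs are reconstructed as
#' SEM * sqrt(n). Morphometric SDs default to 10% of the mean.
#'
#' @param path YAML file; default the bundled group-statistics file,
#'   which reproduces [default_generator_config()].
#' @param seed integer seed stored in the config.
#' @return A `generator_config`.
#' @export
generator_config_from_yaml <- function(path = system.file(
    "extdata", "table1_default.yaml", package = "tilapiaann"),
    seed = 1) {
  y <- yaml::read_yaml(path)
  groups <- lapply(y$groups, function(g) {
    means <- vapply(g$analytes, `[`, numeric(1), 1)
    sems <- vapply(g$analytes, `[`, numeric(1), 2)
    sds <- .canon_num(sems * sqrt(g$n))
    means <- c(means, BA = y$ba$mean)
    sds <- c(sds, BA = y$ba$sd)
    morpho <- unlist(g$morpho)
    list(sex = g$sex, status = g$status, n = as.integer(g$n),
         analyte_means = means, analyte_sds = sds,
         morpho_means = morpho, morpho_sds = .canon_num(morpho * 0.10))
  })
  cfg <- list(groups = groups, rho_tp_alb = y$rho_tp_alb,
              vet_score = y$vet_score, truncation = y$truncation,
              seed = as.integer(seed))
  class(cfg) <- c("generator_config", "list")
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws each group's analytes from a correlated multivariate normal with
#' the configured means and SDs (rows with a non-positive analyte or with
#' ALB >= TP are redrawn, since analytes are positive and globulin cannot
#' be negative), sets GLOB = TP - ALB exactly, draws morphometrics
#' (ages rounded to whole years, minimum 1), and assigns vet scores
#' consistent with each group's status. With `truncation =
#' "instrument_range"` rows outside the analyzer's detection ranges are
#' also redrawn.
#'
#' @param config a `generator_config`; see [default_generator_config()].
#' @param n_multiplier scale every group size by this factor (used by
#'   convergence checks).
#' @param seed overrides `config$seed` when given.
#' @return A `fish_cohort`. Identical config + seed give identical
#'   cohorts.
#' @export
generate_cohort <- function(config = default_generator_config(),
                            n_multiplier = 1, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  reg <- analyte_registry()
  codes <- .drawn_analytes()
  rows <- list()
  for (g in config$groups) {
    n <- g$n * n_multiplier
    mu <- g$analyte_means[codes]
    sds <- g$analyte_sds[codes]
    Sigma <- diag(sds^2, length(codes))
    dimnames(Sigma) <- list(codes, codes)
    rho <- config$rho_tp_alb
    Sigma["TP", "ALB"] <- Sigma["ALB", "TP"] <- rho * sds["TP"] * sds["ALB"]
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev < -1e-8))
      stop("infeasible correlation between TP and ALB")
    draw <- function(k) {
      x <- MASS::mvrnorm(k, mu, Sigma)
      if (k == 1) x <- matrix(x, 1, dimnames = list(NULL, codes))
      x
    }
    ok_rows <- function(x) {
      ok <- apply(x, 1, function(r) all(r > 0)) & (x[, "TP"] > x[, "ALB"])
      if (config$truncation == "instrument_range") {
        i <- match(codes, reg$code)
        inside <- t(apply(x, 1, function(r)
          r >= reg$range_low[i] & r <= reg$range_high[i]))
        ok <- ok & apply(inside, 1, all)
      }
      ok
    }
    x <- draw(n)
    bad <- which(!ok_rows(x))
    tries <- 0
    while (length(bad) && tries < 1000) {
      x[bad, ] <- draw(length(bad))
      bad <- which(!ok_rows(x))
      tries <- tries + 1
    }
    if (length(bad)) stop("could not draw positive analyte panel")
    morpho <- vapply(names(g$morpho_means), function(v) {
      m <- stats::rnorm(n, g$morpho_means[[v]], g$morpho_sds[[v]])
      while (any(m <= 0)) m[m <= 0] <- stats::rnorm(sum(m <= 0),
                                                    g$morpho_means[[v]],
                                                    g$morpho_sds[[v]])
      m
    }, numeric(n))
    if (n == 1) morpho <- matrix(morpho, 1,
                                 dimnames = list(NULL, names(g$morpho_means)))
    age <- pmax(1, round(morpho[, "age"]))
    score <- if (g$status == "healthy") {
      sample(c(0, 0.5), n, replace = TRUE)
    } else {
      grades <- seq(1, 5, by = 0.5)
      p <- (1 - config$vet_score$p_geom)^(seq_along(grades) - 1)
      grades[sample.int(length(grades), n, replace = TRUE, prob = p)]
    }
    df <- data.frame(sex = g$sex, total_length = morpho[, "total_length"],
                     weight = morpho[, "weight"], age = age,
                     vet_score = score, stringsAsFactors = FALSE)
    for (a in codes) df[[a]] <- x[, a]
    df$GLOB <- df$TP - df$ALB
    df$UA <- NA_real_
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  out$fish_id <- sprintf("SYN%04d", seq_len(nrow(out)))
  fish_cohort(out, provenance = sprintf("synthetic (seed %d)", seed))
}

#' Plant or remove group effects in a generator config
#'
#' Returns a config in which only the named variables differ between the
#' healthy and diseased groups: every other analyte and morphometric
#' trait has its mean (and SD) replaced by the across-group pooled value,
#' weighted by group size. With `null_shift = TRUE` everything is
#' equalized — a global null where no variable carries disease signal —
#' regardless of `informative`. Used by parameter-recovery and type-I
#' calibration simulations.
#'
#' @param config a `generator_config`.
#' @param informative variable codes allowed to keep their between-status
#'   differences.
#' @param null_shift equalize all variables.
#' @return A modified `generator_config`.
#' @export
plant_effects <- function(config, informative = character(),
                          null_shift = FALSE) {
  all_vars <- c(.drawn_analytes(), names(config$groups[[1]]$morpho_means))
  unknown <- setdiff(informative, all_vars)
  if (length(unknown)) stop("unknown code(s): ",
                            paste(unknown, collapse = ", "))
  if (!length(informative) && !null_shift) return(config)  # identity
  flatten <- if (null_shift) all_vars else setdiff(all_vars, informative)
  if (!length(flatten)) return(config)
  w <- vapply(config$groups, `[[`, integer(1), "n")
  pool <- function(field, v)
    sum(w * vapply(config$groups, function(g) g[[field]][[v]],
                   numeric(1))) / sum(w)
  for (v in flatten) {
    is_morpho <- v %in% names(config$groups[[1]]$morpho_means)
    mf <- if (is_morpho) "morpho_means" else "analyte_means"
    sf <- if (is_morpho) "morpho_sds" else "analyte_sds"
    pm <- .canon_num(pool(mf, v)); ps <- .canon_num(pool(sf, v))
    for (gname in names(config$groups)) {
      config$groups[[gname]][[mf]][[v]] <- pm
      config$groups[[gname]][[sf]][[v]] <- ps
    }
  }
  config
}

#' Inject the study's missing-data topology
#'
#' Reproduces the pattern seen in the field data: uric acid entirely
#' unmeasured, bile acids failing to register for a random subset of
#' fish, and exactly one fish lacking a creatine-kinase value (that fish
#' is excluded from ensemble modelling by listwise deletion).
#'
#' @param cohort a `fish_cohort` with at least 2 fish.
#' @param seed integer seed for the random masks.
#' @param ba_rate probability a fish's BA fails to register.
#' @return The cohort with missingness applied.
#' @export
inject_study_artifacts <- function(cohort, seed = 1, ba_rate = 0.2) {
  if (nrow(cohort) < 2) stop("cohort too small")
  set.seed(seed)
  cohort$UA <- NA_real_
  mask <- stats::runif(nrow(cohort)) < ba_rate
  cohort$BA[mask] <- NA_real_
  cohort$CK[sample.int(nrow(cohort), 1)] <- NA_real_
  cohort
}
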