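#' Assemble a pipeline run configuration
#'
#' @param generator a `generator_config` used to synthesize the cohort,
#'   or `NULL` when `cohort_csv` points at field data.
#' @param cohort_csv path to a normalized cohort CSV (overrides
#'   `generator`).
#' @param mode `"full_model"` (all retained analytes + age + total
#'   length), `"top4_nonlethal"` (full model first, then refit on the four
#'   most sensitive analytes + total length, age dropped), `"stats_only"`
#'   (comparison table only) or `"qc_only"`.
#' @param seed base seed for generation, missingness and the ensemble.
#' @param alpha significance level for the comparison battery.
#' @param n_models,train_frac,hidden,maxit,lambda ensemble settings.
#' @param screening_lambda ridge penalty for the variable-selection stage
#'   (see [screen_variables()]).
#' @param delta sensitivity perturbation fraction.
#' @param surface_step grid increment for response surfaces.
#' @param inject_artifacts apply the study's missing-data topology to a
#'   generated cohort.
#' @param qc_replicates optional data frame (`analyte`, `value`) of QC
#'   replicate measurements for the QC stage.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = default_generator_config(),
                       cohort_csv = NULL,
                       mode = c("full_model", "top4_nonlethal",
                                "stats_only", "qc_only"),
                       seed = 1, alpha = 0.05, n_models = 20,
                       train_frac = 0.7, hidden = 5, maxit = 500,
                       lambda = 1e-4, screening_lambda = 0.01,
                       delta = 0.05, surface_step = 0.05,
                       inject_artifacts = TRUE, qc_replicates = NULL) {
  mode <- match.arg(mode)
  structure(list(generator = generator, cohort_csv = cohort_csv,
                 mode = mode, seed = as.integer(seed), alpha = alpha,
                 n_models = n_models, train_frac = train_frac,
                 hidden = hidden, maxit = maxit, lambda = lambda,
                 screening_lambda = screening_lambda,
                 delta = delta, surface_step = surface_step,
                 inject_artifacts = inject_artifacts,
                 qc_replicates = qc_replicates),
            class = c("run_config", "list"))
}

#' Run the analysis pipeline end to end
#'
#' Sequences the stages: cohort acquisition (generation or CSV load),
#' optional QC report, the univariate comparison table, the ensemble fit
#' with sensitivities and ROC, optional top-variable refit, and clamped
#' response/adequacy surfaces for the selected variables against total
#' length. Every stage writes its artifact to `out_dir` as CSV/JSON, and
#' the full configuration is serialized to `replay.json` so the run can
#' be reproduced exactly with [replay_run()].
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) {
      load_cohort(config$cohort_csv)
    } else {
      ch <- generate_cohort(config$generator, seed = config$seed)
      if (config$inject_artifacts)
        ch <- inject_study_artifacts(ch, seed = config$seed)
      ch
    }
  })
  say("cohort: n = %d (%d healthy / %d diseased)", nrow(cohort),
      sum(cohort$status == "healthy"), sum(cohort$status == "diseased"))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))

  results <- list(cohort = cohort)

  if (!is.null(config$qc_replicates)) {
    qc <- stage("qc", qc_report(config$qc_replicates))
    utils::write.csv(qc, file.path(out_dir, "qc_report.csv"),
                     row.names = FALSE)
    results$qc <- qc
  }
  if (config$mode == "qc_only") {
    .finish_run(config, out_dir, log_lines)
    return(invisible(results))
  }

  tab <- stage("comparisons", build_comparison_table(cohort,
                                                     alpha = config$alpha))
  utils::write.csv(as.data.frame(tab),
                   file.path(out_dir, "comparison_table.csv"),
                   row.names = FALSE)
  results$comparisons <- tab
  say("comparisons: %d rows, %d significant", nrow(tab),
      sum(tab$significant))
  if (config$mode == "stats_only") {
    .finish_run(config, out_dir, log_lines)
    return(invisible(results))
  }

  ens <- stage("ensemble", ann_ensemble(
    cohort, features = default_features(), target = "status",
    n_models = config$n_models, train_frac = config$train_frac,
    seed = config$seed, hidden = config$hidden, maxit = config$maxit,
    lambda = config$lambda))
  say("ensemble: n = %d modelled, excluded: %s", ens$n,
      if (length(ens$excluded)) paste(ens$excluded, collapse = ", ")
      else "none")
  sens <- stage("sensitivity", sensitivity(ens, delta = config$delta))
  roc <- stage("roc", roc_curve(ens))

  if (config$mode == "top4_nonlethal") {
    scr <- stage("screening", screen_variables(
      cohort, n_models = config$n_models, seed = config$seed,
      lambda = config$screening_lambda, delta = config$delta,
      train_frac = config$train_frac, hidden = config$hidden,
      maxit = config$maxit))
    feats <- select_top_variables(scr, k = 4, non_lethal = TRUE)
    say("top-4 non-lethal refit on: %s", paste(feats, collapse = ", "))
    ens <- stage("ensemble_top4", ann_ensemble(
      cohort, features = feats, target = "status",
      n_models = config$n_models, train_frac = config$train_frac,
      seed = config$seed, hidden = config$hidden, maxit = config$maxit,
      lambda = config$lambda))
    sens_final <- stage("sensitivity_top4",
                        sensitivity(ens, delta = config$delta))
    roc <- stage("roc_top4", roc_curve(ens))
  } else {
    sens_final <- sens
  }

  utils::write.csv(as.data.frame(sens_final),
                   file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(roc), file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  ens_json <- list(
    n_models = ens$n_models, n = ens$n, features = ens$features,
    excluded = as.list(ens$excluded),
    fit_r2 = ens$fit_r2, cv_r2 = ens$cv_r2,
    fit_r2_mean = mean(ens$fit_r2, na.rm = TRUE),
    fit_r2_sd = stats::sd(ens$fit_r2),
    cv_r2_mean = mean(ens$cv_r2, na.rm = TRUE),
    cv_r2_sd = stats::sd(ens$cv_r2),
    auc = roc$auc, auc_se = roc$auc_se, seed = config$seed)
  jsonlite::write_json(ens_json, file.path(out_dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pooled <- data.frame(fish_id = ens$fish_id, observed = ens$y,
                       pooled_cv_prediction = ens$pooled_cv)
  utils::write.csv(pooled, file.path(out_dir, "cv_predictions.csv"),
                   row.names = FALSE)
  results$ensemble <- ens
  results$sensitivity <- sens_final
  results$roc <- roc

  surf_vars <- setdiff(ens$features, c("total_length", "age"))
  ranked <- sens_final$variable[sens_final$variable %in% surf_vars]
  surf_vars <- utils::head(ranked, 4)
  results$surfaces <- list()
  for (v in surf_vars) {
    g <- stage(paste0("surface_", v), {
      grid <- clamp_grid(ens, "total_length", v, step = config$surface_step)
      predict_surface(ens, grid)
    })
    utils::write.csv(as.data.frame(g),
                     file.path(out_dir, sprintf("surface_total_length_%s.csv",
                                                v)),
                     row.names = FALSE)
    results$surfaces[[v]] <- g
  }
  say("surfaces: total_length x {%s}", paste(surf_vars, collapse = ", "))

  .finish_run(config, out_dir, log_lines)
  invisible(results)
}

.finish_run <- function(config, out_dir, log_lines) {
  writeLines(log_lines, file.path(out_dir, "run.log"))
  cfg <- unclass(config)
  cfg$qc_replicates <- NULL  # data, not configuration
  if (!is.null(cfg$generator)) {
    gen <- unclass(cfg$generator)
    # named atomic vectors serialize as arrays; as.list keeps the names
    gen$groups <- lapply(gen$groups, function(g) {
      for (f in c("analyte_means", "analyte_sds",
                  "morpho_means", "morpho_sds"))
        g[[f]] <- as.list(g[[f]])
      g
    })
    cfg$generator <- gen
  }
  jsonlite::write_json(cfg, file.path(out_dir, "replay.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Rebuild a run configuration from an emitted replay file
#'
#' @param path a `replay.json` written by [run_pipeline()].
#' @return A `run_config`.
#' @export
read_replay <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw$cohort_csv) == 0) raw$cohort_csv <- NULL
  gen <- raw$generator
  if (!is.null(gen)) {
    gen$groups <- lapply(gen$groups, function(g) {
      g$analyte_means <- unlist(g$analyte_means)
      g$analyte_sds <- unlist(g$analyte_sds)
      g$morpho_means <- unlist(g$morpho_means)
      g$morpho_sds <- unlist(g$morpho_sds)
      g$n <- as.integer(g$n)
      g
    })
    gen$seed <- as.integer(gen$seed)
    class(gen) <- c("generator_config", "list")
  }
  run_config(generator = gen, cohort_csv = raw$cohort_csv,
             mode = raw$mode, seed = raw$seed, alpha = raw$alpha,
             n_models = raw$n_models, train_frac = raw$train_frac,
             hidden = raw$hidden, maxit = raw$maxit, lambda = raw$lambda,
             screening_lambda = raw$screening_lambda,
             delta = raw$delta, surface_step = raw$surface_step,
             inject_artifacts = raw$inject_artifacts)
}

#' Replay a pipeline run from its emitted configuration
#'
#' @param run_dir directory holding a `replay.json`.
#' @param out_dir where to write the replayed artifacts.
#' @return Invisibly, the stage results (as [run_pipeline()]).
#' @export
replay_run <- function(run_dir, out_dir) {
  run_pipeline(read_replay(file.path(run_dir, "replay.json")), out_dir)
}

#' Render a human-readable summary of a pipeline run
#'
#' @param run_dir directory of artifacts written by [run_pipeline()].
#' @param file optional path to also write the markdown lines to.
#' @return Character vector of markdown lines.
#' @export
render_reports <- function(run_dir, file = NULL) {
  need <- function(name) {
    p <- file.path(run_dir, name)
    if (!file.exists(p)) stop("missing artifact: ", name)
    p
  }
  lines <- c("# Pipeline run summary", "")
  cmp_path <- file.path(run_dir, "comparison_table.csv")
  if (file.exists(cmp_path)) {
    tab <- utils::read.csv(cmp_path, stringsAsFactors = FALSE)
    class(tab) <- c("comparison_table", "data.frame")
    lines <- c(lines, "## Healthy vs diseased comparisons", "",
               format_comparison_markdown(tab), "")
  }
  ens_path <- file.path(run_dir, "ensemble.json")
  if (file.exists(ens_path)) {
    ens <- jsonlite::read_json(ens_path, simplifyVector = TRUE)
    need("roc.csv")
    sens <- utils::read.csv(need("sensitivity.csv"),
                            stringsAsFactors = FALSE)
    lines <- c(lines, "## Ensemble", "",
               sprintf("- %d networks on %d records (features: %s)",
                       ens$n_models, ens$n,
                       paste(ens$features, collapse = ", ")),
               sprintf("- fit R^2 %.2f +/- %.2f; CV R^2 %.2f +/- %.2f",
                       ens$fit_r2_mean, ens$fit_r2_sd,
                       ens$cv_r2_mean, ens$cv_r2_sd),
               sprintf("- pooled CV AUC %.2f (ensemble SD %.2f)",
                       ens$auc, ens$auc_se), "",
               "## Sensitivity ranking", "",
               sprintf("%d. %s (%.4f +/- %.4f)", seq_len(nrow(sens)),
                       sens$variable, sens$mean, sens$sd), "")
  }
  if (!is.null(file)) writeLines(lines, file)
  lines
}
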