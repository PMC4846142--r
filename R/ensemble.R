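#' Default diagnostic feature set
#'
#' The ten retained analytes (bile acids and uric acid excluded) plus
#' otolith age and total length; the non-lethal variant drops age, whose
#' measurement requires sacrificing the fish.
#'
#' @param non_lethal drop `age`.
#' @return Character vector of feature column names.
#' @export
default_features <- function(non_lethal = FALSE) {
  f <- c(analyte_codes(retained = TRUE), "age", "total_length")
  if (non_lethal) f <- setdiff(f, "age")
  f
}

#' Fit a feed-forward neural-network ensemble to a cohort
#'
#' The core disease-classification procedure: `n_models` small feed-forward
#' networks are each trained on an independent random 70% of the records,
#' and each network predicts the disease status of its held-out 30% as a
#' cross-validation set. Records with any missing selected feature are
#' excluded listwise before resampling. Per-model fit and CV R-squared are
#' the squared Pearson correlations between predicted and observed target
#' on the training and held-out records respectively; per-record CV
#' predictions are pooled by averaging over the models that held the
#' record out.
#'
#' A resample whose training half contains only one class is redrawn (at
#' most 100 attempts per model).
#'
#' @param cohort a `fish_cohort`.
#' @param features feature column names; default [default_features()].
#' @param target `"status"` (healthy/diseased coded 0/1; default) or
#'   `"vet_score"` (0-5 lesion-score regression).
#' @param n_models ensemble size (default 20).
#' @param train_frac training fraction per model (default 0.70).
#' @param seed base seed; model m uses `seed + m` for both its resample
#'   and its weight initialization.
#' @param hidden,maxit,lambda network hyperparameters, passed to
#'   [train_ann()].
#' @return Object of class `ann_ensemble`.
#' @seealso [sensitivity()], [roc_curve()], [select_top_variables()],
#'   [predict_surface()]
#' @export
ann_ensemble <- function(cohort, features = default_features(),
                         target = c("status", "vet_score"),
                         n_models = 20, train_frac = 0.7, seed = 1,
                         hidden = 5, maxit = 500, lambda = 1e-4) {
  target <- match.arg(target)
  if (n_models < 2) stop("n_models must be >= 2")
  if (anyDuplicated(features)) stop("duplicate feature in spec")
  miss_col <- setdiff(features, names(cohort))
  if (length(miss_col)) stop("feature(s) not in cohort: ",
                             paste(miss_col, collapse = ", "))
  y_all <- if (target == "status") as.numeric(cohort$status == "diseased")
           else cohort$vet_score
  X_all <- as.matrix(as.data.frame(cohort)[, features, drop = FALSE])
  complete <- stats::complete.cases(X_all) & !is.na(y_all)
  excluded <- cohort$fish_id[!complete]
  X <- X_all[complete, , drop = FALSE]
  y <- y_all[complete]
  n <- nrow(X)
  if (length(unique(y)) < 2) stop("target has a single class after exclusion")
  n_train <- round(train_frac * n)
  if (n_train < 10 || n_train >= n)
    stop("train fraction leaves too few training or held-out records")
  target_range <- if (target == "status") c(0, 1) else c(0, 5)

  models <- vector("list", n_models)
  train_idx <- vector("list", n_models)
  fit_r2 <- cv_r2 <- numeric(n_models)
  cv_pred <- matrix(NA_real_, n, n_models)
  redraws <- 0L
  safe_r2 <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)^2
  }
  for (m in seq_len(n_models)) {
    sm <- seed + m
    set.seed(sm)
    for (attempt in seq_len(100)) {
      idx <- sort(sample.int(n, n_train))
      if (length(unique(y[idx])) > 1 && length(unique(y[-idx])) > 1) break
      redraws <- redraws + 1L
      if (attempt == 100) stop("could not draw a two-class resample")
    }
    fit <- train_ann(X[idx, , drop = FALSE], y[idx], hidden = hidden,
                     seed = sm, maxit = maxit, lambda = lambda,
                     target_range = target_range)
    models[[m]] <- fit
    train_idx[[m]] <- idx
    fit_r2[m] <- safe_r2(predict(fit, X[idx, , drop = FALSE]), y[idx])
    held <- setdiff(seq_len(n), idx)
    ph <- predict(fit, X[held, , drop = FALSE])
    cv_pred[held, m] <- ph
    cv_r2[m] <- safe_r2(ph, y[held])
  }
  pooled <- rowMeans(cv_pred, na.rm = TRUE)
  pooled[is.nan(pooled)] <- NA_real_
  structure(list(models = models, train_idx = train_idx,
                 fit_r2 = fit_r2, cv_r2 = cv_r2,
                 cv_pred = cv_pred, pooled_cv = pooled,
                 x = X, y = y, features = features, target = target,
                 target_range = target_range,
                 fish_id = cohort$fish_id[complete], excluded = excluded,
                 n = n, n_models = n_models, train_frac = train_frac,
                 seed = seed, redraws = redraws,
                 config = list(hidden = hidden, maxit = maxit,
                               lambda = lambda)),
            class = "ann_ensemble")
}

#' @export
print.ann_ensemble <- function(x, ...) {
  cat(sprintf("<ann_ensemble> %d networks (%d-%d-1), target %s\n",
              x$n_models, length(x$features), x$config$hidden, x$target))
  cat(sprintf("  n = %d records (%d excluded for missing features)\n",
              x$n, length(x$excluded)))
  cat(sprintf("  fit R^2  %.2f +/- %.2f\n",
              mean(x$fit_r2, na.rm = TRUE), stats::sd(x$fit_r2)))
  cat(sprintf("  CV R^2   %.2f +/- %.2f\n",
              mean(x$cv_r2, na.rm = TRUE), stats::sd(x$cv_r2)))
  invisible(x)
}

#' @export
summary.ann_ensemble <- function(object, ...) {
  roc <- if (object$target == "status")
    tryCatch(roc_curve(object), error = function(e) NULL) else NULL
  out <- list(n_models = object$n_models, n = object$n,
              excluded = object$excluded,
              fit_r2_mean = mean(object$fit_r2, na.rm = TRUE),
              fit_r2_sd = stats::sd(object$fit_r2),
              cv_r2_mean = mean(object$cv_r2, na.rm = TRUE),
              cv_r2_sd = stats::sd(object$cv_r2),
              auc = if (!is.null(roc)) roc$auc else NA_real_,
              auc_se = if (!is.null(roc)) roc$auc_se else NA_real_,
              features = object$features)
  class(out) <- "summary.ann_ensemble"
  out
}

#' @export
print.summary.ann_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d networks on %d records\n", x$n_models, x$n))
  cat(sprintf("  features: %s\n", paste(x$features, collapse = ", ")))
  cat(sprintf("  fit R^2 %.2f +/- %.2f | CV R^2 %.2f +/- %.2f\n",
              x$fit_r2_mean, x$fit_r2_sd, x$cv_r2_mean, x$cv_r2_sd))
  if (!is.na(x$auc))
    cat(sprintf("  pooled CV AUC %.2f (ensemble SD %.2f)\n", x$auc, x$auc_se))
  invisible(x)
}

#' Predict disease status for new records
#'
#' @param object an `ann_ensemble`.
#' @param newdata data frame or matrix holding the ensemble's feature
#'   columns.
#' @param type `"mean"` (across-model average), `"sd"` (across-model
#'   standard deviation, the sampling-adequacy signal) or `"all"` (matrix
#'   of per-model predictions).
#' @param ... unused.
#' @return Numeric vector, or matrix for `type = "all"`.
#' @export
predict.ann_ensemble <- function(object, newdata,
                                 type = c("mean", "sd", "all"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  preds <- vapply(object$models, function(m) predict(m, x),
                  numeric(nrow(x)))
  preds <- matrix(preds, nrow = nrow(x))
  switch(type,
         mean = rowMeans(preds),
         sd = apply(preds, 1, stats::sd),
         all = preds)
}
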