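#' Per-variable sensitivity of ensemble predictions
#'
#' Ranks diagnostic variables by how strongly the predicted disease
#' status responds to a perturbation of each input. For every model and
#' variable, the variable is shifted by `delta` times its observed range
#' (over the modelling cohort) for every record, and the mean absolute
#' change in the model's prediction is taken; the ensemble mean and
#' standard deviation across models are reported. The central-difference
#' variant perturbs by +/- delta/2.
#'
#' @param object an `ann_ensemble`.
#' @param ... passed to methods.
#' @export
sensitivity <- function(object, ...) UseMethod("sensitivity")

#' @rdname sensitivity
#' @param delta perturbation as a fraction of each variable's observed
#'   range (default 0.05).
#' @param method `"forward"` (+delta shift) or `"central"` (+/- delta/2).
#' @return Data frame of class `ann_sensitivity`, one row per variable
#'   sorted by decreasing mean sensitivity: `variable`, `mean`, `sd`,
#'   `degenerate` (zero observed range).
#' @export
sensitivity.ann_ensemble <- function(object, delta = 0.05,
                                     method = c("forward", "central"), ...) {
  method <- match.arg(method)
  if (delta <= 0) stop("delta must be positive")
  X <- object$x
  rng <- apply(X, 2, function(v) diff(range(v)))
  k <- length(object$features)
  sens <- matrix(NA_real_, object$n_models, k,
                 dimnames = list(NULL, object$features))
  # raw (unclipped) model response: clipping saturates well-fit records
  # at the target bounds and would mask the strongest drivers
  for (m in seq_len(object$n_models)) {
    fit <- object$models[[m]]
    base <- if (method == "forward") predict(fit, X, clip = FALSE) else NULL
    for (j in seq_len(k)) {
      if (method == "forward") {
        Xp <- X; Xp[, j] <- Xp[, j] + delta * rng[j]
        sens[m, j] <- mean(abs(predict(fit, Xp, clip = FALSE) - base))
      } else {
        Xp <- X; Xp[, j] <- Xp[, j] + delta / 2 * rng[j]
        Xm <- X; Xm[, j] <- Xm[, j] - delta / 2 * rng[j]
        sens[m, j] <- mean(abs(predict(fit, Xp, clip = FALSE) -
                               predict(fit, Xm, clip = FALSE)))
      }
    }
  }
  out <- data.frame(variable = object$features,
                    mean = colMeans(sens),
                    sd = apply(sens, 2, stats::sd),
                    degenerate = rng == 0,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean, out$variable), ]
  rownames(out) <- NULL
  attr(out, "delta") <- delta
  attr(out, "method") <- method
  class(out) <- c("ann_sensitivity", "data.frame")
  out
}

#' Plot the sensitivity ranking
#'
#' Bar chart of mean per-variable sensitivity with across-model standard
#' deviations as error bars.
#'
#' @param x an `ann_ensemble`.
#' @param delta,method passed to [sensitivity()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ann_ensemble <- function(x, delta = 0.05, method = "forward", ...) {
  s <- sensitivity(x, delta = delta, method = method)
  mid <- graphics::barplot(s$mean, names.arg = s$variable, las = 2,
                           ylab = "mean |prediction change|",
                           ylim = c(0, max(s$mean + s$sd) * 1.1), ...)
  graphics::arrows(mid, pmax(s$mean - s$sd, 0), mid, s$mean + s$sd,
                   angle = 90, code = 3, length = 0.04)
  invisible(s)
}

#' Select the most sensitive blood-chemistry variables
#'
#' Returns the `k` blood-chemistry analytes with the highest mean
#' sensitivity, together with total length; in non-lethal mode otolith age
#' is excluded even if ranked highly, since measuring it requires
#' sacrificing the fish. Ties at the selection boundary are broken by
#' larger mean sensitivity then lexicographic code (deterministic), with a
#' warning when an exact tie straddles the boundary.
#'
#' @param sens an `ann_sensitivity` table.
#' @param k number of chemistry variables to retain (default 4).
#' @param non_lethal exclude age (default `TRUE`).
#' @param exclusions variable codes barred from selection. Globulin is
#'   excluded by default: the analyzer derives it as TP - ALB, so it
#'   duplicates its parents' signal and selecting it alongside them adds
#'   no measurement.
#' @return Character vector of feature names (k analytes +
#'   `total_length`), usable as the `features` argument of
#'   [ann_ensemble()].
#' @export
select_top_variables <- function(sens, k = 4, non_lethal = TRUE,
                                 exclusions = "GLOB") {
  if (k < 1) stop("k must be >= 1")
  chem <- sens[sens$variable %in% analyte_codes() &
               !sens$variable %in% exclusions, ]
  chem <- chem[order(-chem$mean, chem$variable), ]
  k <- min(k, nrow(chem))
  if (k < nrow(chem) && chem$mean[k] == chem$mean[k + 1])
    warning("tie in mean sensitivity at the selection boundary")
  picked <- chem$variable[seq_len(k)]
  out <- c(picked, "total_length")
  if (!non_lethal && "age" %in% sens$variable) out <- c(out, "age")
  out
}

#' Rank diagnostic variables with a screening-configured ensemble
#'
#' Variable ranking and prediction want different regularization. The
#' prediction default (`lambda = 1e-4`) lets networks fit the training
#' records nearly exactly, but near-interpolating networks lean on
#' whichever of several correlated informative inputs they happen to
#' pick, and also respond to noise inputs, which destabilizes the
#' sensitivity ranking. A much stronger ridge penalty (default
#' `lambda = 0.01`) spreads weight across correlated informative inputs
#' and shrinks noise inputs toward zero, giving a far more reproducible
#' ranking at the cost of training fit — irrelevant when the question is
#' which variables matter. This wrapper fits an ensemble with the
#' screening penalty and returns its sensitivity table.
#'
#' @param cohort a `fish_cohort`.
#' @param features,n_models,seed as in [ann_ensemble()].
#' @param lambda screening ridge penalty (default 0.01).
#' @param delta sensitivity perturbation fraction.
#' @param ... further arguments to [ann_ensemble()].
#' @return An `ann_sensitivity` table (see [sensitivity()]).
#' @export
screen_variables <- function(cohort, features = default_features(),
                             n_models = 20, seed = 1, lambda = 0.01,
                             delta = 0.05, ...) {
  ens <- ann_ensemble(cohort, features = features, n_models = n_models,
                      seed = seed, lambda = lambda, ...)
  sensitivity(ens, delta = delta)
}
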