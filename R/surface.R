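#' Build a clamped two-variable prediction grid
#'
#' Constructs the artificial data set for a response surface: two chosen
#' variables sweep their observed ranges (over the ensemble's modelling
#' cohort) in increments of `step` times the range — 5% steps give a
#' 21 x 21 grid inclusive of both endpoints — while every other feature is
#' clamped to its cohort mean.
#'
#' @param ensemble an `ann_ensemble` (supplies the modelling cohort and
#'   feature set).
#' @param var_x,var_y distinct feature names to vary.
#' @param step grid increment as a fraction of each variable's range
#'   (default 0.05).
#' @return Object of class `surface_grid` with coordinates and clamp
#'   values; `mean_surface`/`sd_surface` are filled by
#'   [predict_surface()].
#' @export
clamp_grid <- function(ensemble, var_x, var_y, step = 0.05) {
  if (var_x == var_y) stop("var_x and var_y must differ")
  feats <- ensemble$features
  if (!all(c(var_x, var_y) %in% feats))
    stop("both variables must be ensemble features")
  X <- ensemble$x
  grid_axis <- function(v) {
    r <- range(X[, v])
    if (diff(r) == 0) stop("zero observed range for ", v)
    seq(r[1], r[2], length.out = round(1 / step) + 1)
  }
  clamped <- colMeans(X)[setdiff(feats, c(var_x, var_y))]
  structure(list(var_x = var_x, var_y = var_y,
                 x_values = grid_axis(var_x), y_values = grid_axis(var_y),
                 clamped = clamped, features = feats, step = step,
                 mean_surface = NULL, sd_surface = NULL),
            class = "surface_grid")
}

#' Predict over a clamped grid with an ensemble
#'
#' Fills the grid with the across-model mean prediction and the
#' across-model standard deviation at each node. The SD surface is the
#' sampling-adequacy diagnostic: where independently trained models agree,
#' the SD approaches zero and further field sampling in that region of
#' covariate space adds little.
#'
#' @param ensemble the `ann_ensemble` used to build the grid.
#' @param grid a `surface_grid` from [clamp_grid()].
#' @return The grid with `mean_surface` and `sd_surface` matrices filled
#'   (rows index `x_values`, columns `y_values`).
#' @export
predict_surface <- function(ensemble, grid) {
  if (!identical(grid$features, ensemble$features))
    stop("grid and ensemble feature specs differ")
  nx <- length(grid$x_values); ny <- length(grid$y_values)
  nodes <- expand.grid(x = grid$x_values, y = grid$y_values,
                       KEEP.OUT.ATTRS = FALSE)
  newdata <- matrix(rep(NA_real_, nrow(nodes) * length(grid$features)),
                    nrow(nodes), length(grid$features),
                    dimnames = list(NULL, grid$features))
  for (v in names(grid$clamped)) newdata[, v] <- grid$clamped[[v]]
  newdata[, grid$var_x] <- nodes$x
  newdata[, grid$var_y] <- nodes$y
  preds <- predict(ensemble, newdata, type = "all")
  grid$mean_surface <- matrix(rowMeans(preds), nx, ny)
  grid$sd_surface <- matrix(apply(preds, 1, stats::sd), nx, ny)
  grid
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %s x %s, %d x %d nodes%s\n",
              x$var_x, x$var_y, length(x$x_values), length(x$y_values),
              if (is.null(x$mean_surface)) " (not yet predicted)" else ""))
  invisible(x)
}

#' Export a filled surface grid in long format
#'
#' @param x a filled `surface_grid`.
#' @param row.names,optional,... standard [as.data.frame()] arguments,
#'   ignored.
#' @return Data frame: `var_x` value, `var_y` value, `mean_prediction`,
#'   `sd_prediction`.
#' @export
as.data.frame.surface_grid <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  if (is.null(x$mean_surface)) stop("surface not yet predicted")
  nodes <- expand.grid(x = x$x_values, y = x$y_values,
                       KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(nodes$x, nodes$y,
                    mean_prediction = as.vector(x$mean_surface),
                    sd_prediction = as.vector(x$sd_surface))
  names(out)[1:2] <- c(x$var_x, x$var_y)
  out
}

#' Summarize model disagreement over a surface
#'
#' Reports the fraction of grid nodes whose across-model SD exceeds a
#' threshold and the coordinates where disagreement concentrates —
#' regions of covariate space the cohort under-samples.
#'
#' @param grid a filled `surface_grid`.
#' @param threshold SD threshold (same scale as predictions).
#' @return List: `fraction_above`, `hotspots` (data frame of node
#'   coordinates and SDs above threshold, sorted by SD), `max_sd`.
#' @export
adequacy_summary <- function(grid, threshold = 0.15) {
  if (is.null(grid$sd_surface)) stop("surface not yet predicted")
  long <- as.data.frame(grid)
  above <- long[long$sd_prediction > threshold, , drop = FALSE]
  above <- above[order(-above$sd_prediction), , drop = FALSE]
  rownames(above) <- NULL
  list(fraction_above = nrow(above) / nrow(long),
       hotspots = above,
       max_sd = max(long$sd_prediction))
}

#' Plot a filled surface grid
#'
#' Image map of the mean prediction (or the across-model SD) over the
#' two swept variables.
#'
#' @param x a filled `surface_grid`.
#' @param what `"mean"` or `"sd"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.surface_grid <- function(x, what = c("mean", "sd"), ...) {
  what <- match.arg(what)
  z <- if (what == "mean") x$mean_surface else x$sd_surface
  if (is.null(z)) stop("surface not yet predicted")
  graphics::image(x$x_values, x$y_values, z,
                  xlab = x$var_x, ylab = x$var_y, ...)
  invisible(x)
}
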