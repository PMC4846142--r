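#' Train a single feed-forward neural network
#'
#' A small fully connected network with one hidden layer of logistic
#' units and a linear output, trained by full-batch BFGS on mean squared
#' error with a mild ridge penalty on the weights. Inputs are min-max
#' scaled to \[0, 1\] with scaling parameters learned from the training
#' data only; the target is likewise rescaled to \[0, 1\] and predictions
#' are mapped back and clipped to the target range. Training is
#' deterministic given `seed`: weight initialization draws from a seeded
#' uniform, and the optimizer is deterministic. The loss is recorded at
#' segment boundaries, giving a non-increasing trace.
#'
#' @param x numeric matrix of predictors (rows = records); no missing
#'   cells.
#' @param y numeric target vector: binary status coded 0/1, or a bounded
#'   score (rescaled internally).
#' @param hidden number of hidden units.
#' @param seed integer seed for weight initialization.
#' @param maxit total BFGS iterations, split across `segments` restarts to
#'   record the loss trace.
#' @param lambda ridge penalty on weights (not biases).
#' @param segments number of loss checkpoints.
#' @param target_range numeric length-2; defaults to `range(y)` when `y`
#'   spans more than a point, and `c(0, 1)` for 0/1 targets.
#' @return Object of class `ann_fit`: weight matrices, scaling, loss
#'   trace, and training metadata.
#' @export
train_ann <- function(x, y, hidden = 5, seed = 1, maxit = 500,
                      lambda = 1e-4, segments = 5, target_range = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(y)) stop("missing cells not allowed in training data")
  if (nrow(x) < 10) stop("need >= 10 training records")
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)")
  if (stats::sd(y) == 0) stop("degenerate constant target")
  if (is.null(target_range)) {
    target_range <- if (all(y %in% c(0, 1))) c(0, 1) else range(y)
  }
  p <- ncol(x)
  xmin <- apply(x, 2, min)
  xrange <- apply(x, 2, max) - xmin
  xrange[xrange == 0] <- 1  # constant column maps to 0
  xs <- sweep(sweep(x, 2, xmin), 2, xrange, "/")
  yr <- target_range[2] - target_range[1]
  ys <- (y - target_range[1]) / yr

  n <- nrow(xs)
  n_par <- p * hidden + hidden + hidden + 1
  unpack <- function(w) {
    list(W1 = matrix(w[seq_len(p * hidden)], p, hidden),
         b1 = w[p * hidden + seq_len(hidden)],
         w2 = w[p * hidden + hidden + seq_len(hidden)],
         b2 = w[n_par])
  }
  fwd <- function(par, X) {
    a1 <- stats::plogis(sweep(X %*% par$W1, 2, par$b1, "+"))
    list(a1 = a1, yhat = drop(a1 %*% par$w2) + par$b2)
  }
  loss <- function(w) {
    par <- unpack(w)
    f <- fwd(par, xs)
    mean((f$yhat - ys)^2) + lambda * (sum(par$W1^2) + sum(par$w2^2))
  }
  grad <- function(w) {
    par <- unpack(w)
    f <- fwd(par, xs)
    d <- 2 * (f$yhat - ys) / n
    gw2 <- drop(crossprod(f$a1, d)) + 2 * lambda * par$w2
    gb2 <- sum(d)
    d1 <- (d %*% t(par$w2)) * f$a1 * (1 - f$a1)
    gW1 <- crossprod(xs, d1) + 2 * lambda * par$W1
    gb1 <- colSums(d1)
    c(as.vector(gW1), gb1, gw2, gb2)
  }

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  w <- stats::runif(n_par, -0.5, 0.5)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv()))
    rm(".Random.seed", envir = globalenv())

  per_seg <- max(1L, ceiling(maxit / segments))
  trace <- numeric(segments + 1)
  trace[1] <- loss(w)
  converged <- FALSE
  for (s in seq_len(segments)) {
    opt <- stats::optim(w, loss, grad, method = "BFGS",
                        control = list(maxit = per_seg, reltol = 1e-10))
    w <- opt$par
    trace[s + 1] <- opt$value
    if (opt$convergence == 0) { converged <- TRUE }
  }
  structure(list(weights = unpack(w), hidden = hidden,
                 xmin = xmin, xrange = xrange,
                 target_range = target_range,
                 loss_trace = trace, final_loss = trace[length(trace)],
                 converged = converged, seed = seed, lambda = lambda,
                 maxit = maxit, features = colnames(x)),
            class = "ann_fit")
}

#' Predict from a fitted network
#'
#' @param object an `ann_fit`.
#' @param newdata numeric matrix (or data frame) with the training
#'   feature columns.
#' @param clip clip predictions to the target range (default `TRUE`).
#' @param ... unused.
#' @return Numeric vector of predictions on the original target scale.
#' @export
predict.ann_fit <- function(object, newdata, clip = TRUE, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x)))
    x <- x[, object$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$xmin), 2, object$xrange, "/")
  par <- object$weights
  a1 <- stats::plogis(sweep(xs %*% par$W1, 2, par$b1, "+"))
  ys <- drop(a1 %*% par$w2) + par$b2
  tr <- object$target_range
  out <- tr[1] + ys * (tr[2] - tr[1])
  if (clip) out <- pmin(pmax(out, tr[1]), tr[2])
  out
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf("<ann_fit> %d-%d-1 network, final loss %.4g (seed %d%s)\n",
              length(x$xmin), x$hidden, x$final_loss, x$seed,
              if (x$converged) "" else "; not converged"))
  invisible(x)
}
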