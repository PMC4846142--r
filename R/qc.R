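#' Relative standard deviation of a replicate set
#'
#' Replicate precision as 100 * sample SD / mean, the convention for
#' benchtop-analyzer QC panels run at small n (here typically n = 7).
#' The sample (n - 1 denominator) standard deviation is used.
#'
#' @param values numeric vector of replicate measurements, length >= 2.
#' @return RSD in percent (non-negative scalar).
#' @examples
#' rsd(c(9, 10, 11))  # 10
#' @export
rsd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 replicates")
  m <- mean(values)
  if (m == 0) stop("RSD undefined: replicate mean is zero")
  100 * stats::sd(values) / m
}

#' Symmetric percent difference between two values
#'
#' 100 * |a - b| / mean(a, b). The symmetric (mean-denominator) form is the
#' one used for method-comparison checks against reference materials.
#'
#' @param a,b numeric scalars with a + b != 0.
#' @return Percent difference (non-negative).
#' @examples
#' percent_difference(2.10, 2.31)  # ~9.5
#' @export
percent_difference <- function(a, b) {
  if (a + b == 0) stop("percent difference undefined: a + b = 0")
  100 * abs(a - b) / ((a + b) / 2)
}

#' Derive globulin from total protein and albumin
#'
#' The analyzer does not measure globulin; it reports TP - ALB.
#'
#' @param tp total protein (g/dL).
#' @param alb albumin (g/dL), with 0 <= alb <= tp.
#' @return Globulin (g/dL).
#' @export
derive_glob <- function(tp, alb) {
  if (any(alb < 0, na.rm = TRUE)) stop("albumin must be non-negative")
  if (any(alb > tp, na.rm = TRUE)) stop("negative globulin: ALB exceeds TP")
  tp - alb
}

#' Compare a measured mean against a reference value
#'
#' Classifies the measurement against the reference confidence interval
#' (when bounds are supplied) and reports the signed percent difference
#' relative to the reference center, so a measurement under the certified
#' value is negative.
#'
#' @param measured_mean measured mean value.
#' @param center reference (certified/reference/comparison) value.
#' @param ci_low,ci_high optional confidence bounds with
#'   `ci_low <= center <= ci_high`.
#' @return List with `classification` (`within`/`below`/`above`, or `NA`
#'   when no CI given) and `percent_difference` (signed, relative to
#'   center).
#' @export
compare_to_reference <- function(measured_mean, center,
                                 ci_low = NA, ci_high = NA) {
  if (center == 0) stop("reference center must be nonzero")
  pd <- 100 * (measured_mean - center) / center
  cls <- NA_character_
  if (!is.na(ci_low) && !is.na(ci_high)) {
    if (!(ci_low <= center && center <= ci_high))
      stop("confidence bounds must bracket the center")
    cls <- if (measured_mean < ci_low) "below"
           else if (measured_mean > ci_high) "above" else "within"
  }
  list(classification = cls, percent_difference = pd)
}

#' QC report for a table of replicate panels
#'
#' @param replicates data frame with columns `analyte` and `value` (one row
#'   per replicate measurement); a `label` column is carried through if
#'   present.
#' @return Data frame per analyte: n, mean, sd, rsd_percent.
#' @export
qc_report <- function(replicates) {
  stopifnot(all(c("analyte", "value") %in% names(replicates)))
  sp <- split(replicates$value, replicates$analyte)
  out <- do.call(rbind, lapply(names(sp), function(a) {
    v <- sp[[a]][!is.na(sp[[a]])]
    data.frame(analyte = a, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) >= 2) stats::sd(v) else NA_real_,
               rsd_percent = if (length(v) >= 2 && mean(v) != 0)
                 rsd(v) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
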