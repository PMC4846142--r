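#' Blood-chemistry analyte registry
#'
#' The 12-analyte panel reported by the benchtop analyzer's avian/reptile
#' rotor, with reporting units and instrument detection ranges. GLOB
#' (globulin) is the only derived analyte: the analyzer computes it as
#' total protein minus albumin rather than measuring it.
#'
#' Range bounds are inclusive at both ends.
#'
#' @return A data frame with one row per analyte and columns `code`,
#'   `name`, `units`, `range_low`, `range_high`, `derived`.
#' @examples
#' analyte_registry()
#' @export
analyte_registry <- function() {
  reg <- data.frame(
    code = c("AST", "BA", "CK", "UA", "GLU", "PHOS",
             "Ca", "TP", "ALB", "GLOB", "K", "Na"),
    name = c("aspartate aminotransferase", "bile acids", "creatine kinase",
             "uric acid", "glucose", "inorganic phosphorus",
             "calcium", "total protein", "albumin", "globulin",
             "potassium", "sodium"),
    units = c("U/L", "umol/L", "U/L", "mg/dL", "mg/dL", "mg/dL",
              "mg/dL", "g/dL", "g/dL", "g/dL", "mmol/L", "mmol/L"),
    range_low = c(5, 35, 5, 0.3, 10, 0.2, 4, 2, 1, 0, 1.5, 110),
    range_high = c(2000, 200, 14000, 25, 700, 20, 16, 14, 13, 6.5, 8.5, 170),
    derived = FALSE,
    stringsAsFactors = FALSE
  )
  # ALB tops at 6.5, GLOB at 13: fix the two rows that share g/dL bounds
  reg$range_high[reg$code == "ALB"] <- 6.5
  reg$range_high[reg$code == "GLOB"] <- 13
  reg$derived[reg$code == "GLOB"] <- TRUE
  stopifnot(all(reg$range_low < reg$range_high), nrow(reg) == 12L)
  reg
}

#' Analyte codes of the panel
#'
#' @param retained if `TRUE`, drop BA and UA (excluded from interpretation:
#'   BA is sporadically unmeasured and UA undetected in tilapia plasma).
#' @return Character vector of analyte codes.
#' @export
analyte_codes <- function(retained = FALSE) {
  codes <- analyte_registry()$code
  if (retained) codes <- setdiff(codes, c("BA", "UA"))
  codes
}

#' Morphometric trait codes
#'
#' @return Character vector: total length (cm), weight (kg), otolith age
#'   (years).
#' @export
trait_codes <- function() c("total_length", "weight", "age")

#' Classify disease status from a veterinary score
#'
#' Necropsy lesion scores run 0-5 in 0.5 steps (the average of multiple
#' independent veterinarians' grades). A score below 1 is healthy --
#' fish scored 0.5 carry only subtle lesions and are classified healthy;
#' a score of 1 or more is diseased.
#'
#' @param vet_score numeric vector of scores in \[0, 5\] on a 0.5 grid.
#' @param strict error (rather than warn) on scores off the 0.5 grid.
#' @return Factor with levels `healthy`, `diseased` (NA stays NA).
#' @examples
#' classify_status(c(0, 0.5, 1, 3.5))
#' @export
classify_status <- function(vet_score, strict = FALSE) {
  ok <- is.na(vet_score) | (vet_score >= 0 & vet_score <= 5)
  if (!all(ok)) stop("vet_score outside [0, 5]: ",
                     paste(vet_score[!ok], collapse = ", "))
  off <- !is.na(vet_score) & abs(vet_score * 2 - round(vet_score * 2)) > 1e-8
  if (any(off)) {
    msg <- paste("vet_score off the 0.5 grid:",
                 paste(vet_score[off], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  factor(ifelse(vet_score < 1, "healthy", "diseased"),
         levels = c("healthy", "diseased"))
}

#' Flag analyte values against instrument detection ranges
#'
#' @param values named numeric vector or one-row data frame of analyte
#'   values; names must be registry codes. `NA` means not measured.
#' @return Character vector (same names) with entries `below`, `in_range`,
#'   `above` or `missing`. Bounds are inclusive.
#' @examples
#' range_flags(c(Na = 171, AST = 5, GLU = 9, BA = NA))
#' @export
range_flags <- function(values) {
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  reg <- analyte_registry()
  codes <- names(values)
  unknown <- setdiff(codes, reg$code)
  if (length(unknown)) stop("unknown analyte code(s): ",
                            paste(unknown, collapse = ", "))
  i <- match(codes, reg$code)
  out <- ifelse(is.na(values), "missing",
         ifelse(values < reg$range_low[i], "below",
         ifelse(values > reg$range_high[i], "above", "in_range")))
  names(out) <- codes
  out
}
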