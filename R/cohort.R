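#' Construct a cohort of sampled fish
#'
#' A cohort is a data frame with one row per fish: identifier, sex,
#' morphometrics, veterinary lesion score, the 12-analyte panel, and the
#' derived health status. Missing analyte values are `NA`, never 0 or a
#' sentinel: bile acids fail to register for some fish, uric acid is
#' typically undetected, and the occasional creatine-kinase value is absent.
#'
#' @param records data frame holding at least `fish_id`, `sex`,
#'   `total_length`, `weight`, `vet_score`; analyte columns optional
#'   (absent panels are filled with `NA`); `age` optional.
#' @param provenance free-text source label stored as an attribute.
#' @return An object of class `fish_cohort` (a data frame).
#' @export
fish_cohort <- function(records, provenance = "unspecified") {
  req <- c("fish_id", "sex", "total_length", "weight", "vet_score")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  records$fish_id <- as.character(records$fish_id)
  if (anyDuplicated(records$fish_id))
    stop("duplicate fish_id: ",
         paste(unique(records$fish_id[duplicated(records$fish_id)]),
               collapse = ", "))
  bad_sex <- !records$sex %in% c("male", "female")
  if (any(bad_sex)) stop("sex must be 'male' or 'female'")
  if (any(records$total_length <= 0, na.rm = TRUE) ||
      any(records$weight <= 0, na.rm = TRUE))
    stop("total_length and weight must be positive")
  if (!"age" %in% names(records)) records$age <- NA_real_
  for (a in analyte_codes())
    if (!a %in% names(records)) records[[a]] <- NA_real_
  records$status <- classify_status(records$vet_score)
  cols <- c("fish_id", "sex", "total_length", "weight", "age",
            "vet_score", "status", analyte_codes())
  records <- records[, cols]
  structure(records, provenance = provenance,
            class = c("fish_cohort", "data.frame"))
}

#' @export
print.fish_cohort <- function(x, ...) {
  cat(sprintf("<fish_cohort> %d fish (%d healthy / %d diseased; %d M / %d F)\n",
              nrow(x), sum(x$status == "healthy"), sum(x$status == "diseased"),
              sum(x$sex == "male"), sum(x$sex == "female")))
  cat("provenance:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Read a cohort from a normalized CSV/TSV file
#'
#' Expects one row per fish with a header. Canonical column names are the
#' constructor's; `col_map` renames non-canonical headers (a named character
#' vector `c(canonical = "file_header")`). Blank or "NA" analyte cells
#' become explicit missing values.
#'
#' @param path CSV (or TSV, with `sep = "\t"`) file path.
#' @param col_map optional named character vector mapping canonical column
#'   names to the file's headers.
#' @param sep field separator.
#' @return A `fish_cohort`; attribute `n_read`/`n_rejected` carry row
#'   accounting.
#' @export
load_cohort <- function(path, col_map = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw))
        stop("mapped column not in file: ", col_map[[canon]])
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  req <- c("fish_id", "sex", "total_length", "weight", "vet_score")
  miss <- setdiff(req, names(raw))
  if (length(miss)) stop("missing required header(s): ",
                         paste(miss, collapse = ", "))
  known <- c(req, "age", "status", analyte_codes())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown column(s): ",
                            paste(unknown, collapse = ", "))
  num_cols <- intersect(c("total_length", "weight", "age", "vet_score",
                          analyte_codes()), names(raw))
  n_read <- nrow(raw)
  for (cc in num_cols) {
    v <- raw[[cc]]
    if (is.logical(v) && all(is.na(v))) raw[[cc]] <- as.numeric(v)
    if (is.character(v)) {
      v[trimws(v) == ""] <- NA
      vn <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(vn)))
        stop("non-numeric value in column ", cc, ": ",
             paste(unique(v[!is.na(v) & is.na(vn)]), collapse = ", "))
      raw[[cc]] <- vn
    }
  }
  raw$status <- NULL
  coh <- fish_cohort(raw, provenance = path)
  attr(coh, "n_read") <- n_read
  attr(coh, "n_rejected") <- n_read - nrow(coh)
  coh
}

#' Write a cohort to a normalized CSV
#'
#' Emits canonical column order; missing values are empty cells so the
#' round trip through [load_cohort()] is lossless including missingness.
#'
#' @param cohort a `fish_cohort`.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$status <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Subset a cohort, preserving class and provenance
#'
#' @param cohort a `fish_cohort`.
#' @param sex,status optional filters.
#' @return A `fish_cohort`.
#' @export
cohort_subset <- function(cohort, sex = NULL, status = NULL) {
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(sex)) keep <- keep & cohort$sex %in% sex
  if (!is.null(status)) keep <- keep & cohort$status %in% status
  out <- cohort[keep, , drop = FALSE]
  structure(out, provenance = attr(cohort, "provenance"),
            class = class(cohort))
}
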