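# CSV readers/writers for the long-format dose-response table and the
# fit-record table (an S1-Table-style 8-column layout plus status).

#' Read a long-format dose-response CSV
#'
#' Expected columns: `receptor_id`, `odorant_id`, `concentration_M`,
#' `response`, optional `replicate`. Schema problems are reported naming
#' the offending column or row.
#'
#' @param path CSV path.
#' @return Data frame with validated columns.
#' @export
read_dose_response <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("receptor_id", "odorant_id", "concentration_M", "response")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("read_dose_response: '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (!is.numeric(df$concentration_M) || !is.numeric(df$response)) {
    stop("read_dose_response: concentration_M and response must be numeric")
  }
  bad <- which(!is.finite(df$concentration_M) | df$concentration_M <= 0)
  if (length(bad)) {
    stop("read_dose_response: non-positive or missing concentration_M at ",
         "row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}

#' Write a dose-response table to CSV
#'
#' @param data Dose-response data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dose_response <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write fit records to CSV
#'
#' Columns mirror the per-pair parameter-table layout: receptor and
#' odorant ids, basal activity, response amplitude, efficacy, EC50, Hill
#' coefficient, fit correlation — plus the classification status. Floats
#' are written at full precision.
#'
#' @param records Fit-record data frame from [fit_panel()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_records <- function(records, path) {
  cols <- c("receptor_id", "odorant_id", "B", "dS_max", "E", "EC50", "H",
            "corr", "status")
  out <- records[, intersect(cols, names(records)), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a fit-record CSV
#'
#' @param path CSV path written by [write_fit_records()].
#' @return Fit-record data frame.
#' @export
read_fit_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("receptor_id", "odorant_id", "B", "dS_max", "E", "EC50", "H",
           "corr")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("read_fit_records: '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}
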