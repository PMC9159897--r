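#' Read a long-format measurement series CSV
#'
#' Expects a UTF-8 CSV with a header row and columns `patient_id`, `session`
#' and `score`. Rows whose `session` or `score` fail to parse as numbers are
#' reported by CSV line number.
#'
#' @param path Path to the CSV file.
#' @return A tibble with `patient_id` (character), `session` and `score`
#'   (numeric), ordered by patient and session.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("patient_id", "session", "score")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    abort(paste0(path, ": missing column(s) ", paste(miss, collapse = ", ")),
          class = "rehabspc_error_csv")
  }
  session <- suppressWarnings(as.numeric(raw$session))
  score <- suppressWarnings(as.numeric(raw$score))
  bad <- which(is.na(session) | is.na(score))
  if (length(bad) > 0L) {
    abort(
      sprintf("%s: unparseable numeric value at line %d (and %d more).",
              path, bad[1] + 1L, length(bad) - 1L),
      class = "rehabspc_error_csv"
    )
  }
  check_series_frame(tibble(patient_id = raw$patient_id,
                            session = session, score = score))
}

#' Read a per-patient covariate CSV
#'
#' @param path Path to a CSV with a `patient_id` column and one row per
#'   patient.
#' @return A tibble; `patient_id` coerced to character. Duplicate ids are an
#'   error.
#' @export
read_covariates_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  cov <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!"patient_id" %in% names(cov)) {
    abort(paste0(path, ": missing column patient_id"),
          class = "rehabspc_error_csv")
  }
  cov$patient_id <- as.character(cov$patient_id)
  dup <- unique(cov$patient_id[duplicated(cov$patient_id)])
  if (length(dup) > 0L) {
    abort(paste0(path, ": duplicate patient ids: ",
                 paste(utils::head(dup, 5L), collapse = ", ")),
          class = "rehabspc_error_duplicate_id")
  }
  cov
}

#' Read a bare counts CSV as a contingency table
#'
#' For direct table analysis: rows are exposure levels, columns outcome
#' levels; the first column holds row labels.
#'
#' @param path Path to the CSV.
#' @return A numeric matrix with dimnames.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw[[1]]
  storage.mode(m) <- "numeric"
  check_counts(m)
}
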