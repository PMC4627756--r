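#' Validate a study-level correlation table
#'
#' The package's common input is a plain data frame with one row per
#' study: an `id` column (unique labels), a Pearson correlation `r` in
#' (-1, 1), a sample size `n >= 4`, optionally an `se` column overriding
#' the analytic standard error, and any number of additional columns
#' holding categorical moderators (e.g. `frame_of_reference`, `source`).
#'
#' `validate_meta_data()` checks every invariant and reports all
#' violations at once, naming the offending rows; it returns the data
#' (as a tibble) invisibly so it can sit inside a pipe.
#'
#' @param data A data frame with at least columns `id`, `r`, `n`.
#' @return `data` as a tibble, invisibly.
#' @export
validate_meta_data <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing_cols <- setdiff(c("id", "r", "n"), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing_cols, collapse = ", "), "."))
  }
  problems <- character()
  r <- suppressWarnings(as.numeric(data$r))
  n <- suppressWarnings(as.numeric(data$n))
  bad_r <- which(is.na(r) | abs(r) >= 1)
  if (length(bad_r) > 0) {
    problems <- c(problems, paste0(
      "`r` must be in (-1, 1); violated on row(s) ", paste(bad_r, collapse = ", "), "."))
  }
  bad_n <- which(is.na(n) | n < 4)
  if (length(bad_n) > 0) {
    problems <- c(problems, paste0(
      "`n` must be >= 4; violated on row(s) ", paste(bad_n, collapse = ", "), "."))
  }
  dup <- unique(as.character(data$id[duplicated(data$id)]))
  if (length(dup) > 0) {
    problems <- c(problems, paste0("duplicate study id(s): ", paste(dup, collapse = ", "), "."))
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid study table:\n", paste0("- ", problems, collapse = "\n")))
  }
  invisible(tibble::as_tibble(data))
}

# Cheap re-check used by analysis entry points.
check_meta_data <- function(data) {
  if (!is.data.frame(data) || !all(c("id", "r", "n") %in% names(data))) {
    abort("`data` must be a data frame with columns `id`, `r`, `n`.")
  }
  if (nrow(data) < 1) abort("`data` must contain at least one study.")
  invisible(data)
}

#' Read a study-level CSV
#'
#' Reads a UTF-8, header-first CSV with columns `id`, `r`, `n` and any
#' additional moderator columns, and validates it with
#' [validate_meta_data()].
#'
#' @param path Path to the CSV file.
#' @return A validated tibble of studies.
#' @export
read_meta_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_meta_data(data)
  tibble::as_tibble(data)
}

#' Write a study-level CSV
#'
#' Writes the schema that [read_meta_csv()] reads.
#'
#' @param data A study table.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_meta_csv <- function(data, path) {
  validate_meta_data(data)
  readr::write_csv(data, path)
  invisible(data)
}

#' Moderator columns of a study table
#'
#' @param data A study table.
#' @return Character vector of column names other than the reserved
#'   `id`, `r`, `n`, `se`.
#' @export
moderator_columns <- function(data) {
  setdiff(names(data), c("id", "r", "n", "se"))
}
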