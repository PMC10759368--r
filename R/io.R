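#' Canonical column order for population files
#'
#' @param n_subscores Number of clock subscore columns.
#' @return Character vector of column names in file order.
#' @export
population_columns <- function(n_subscores = 22) {
  c(
    "participant_id", "age", "sex", "education_years", "race", "ethnicity",
    "ravlt_long_delay", "tmtb_seconds", "faq", "mmse", "dct_summary",
    sprintf("dct_sub_%02d", seq_len(n_subscores)),
    "delayed_recall", "true_state"
  )
}

#' Write / read a participant population as CSV
#'
#' The on-disk format is UTF-8, comma-separated, one header row, `.` as
#' the decimal mark, with the column order of [population_columns()]
#' (`true_state` is optional: real study exports do not carry it).
#' `read_population()` validates presence of the required columns and the
#' admissible range of every score, reporting the offending column and
#' rows; an absent `dct_summary` (unanalyzable clock) may be empty/NA.
#'
#' `read_population(write_population(x))` is field-for-field identical
#' for generated populations (numeric values are written in full
#' precision).
#'
#' @param records Population tibble as from [generate_population()].
#' @param path File path.
#' @return `read_population()` returns a validated tibble;
#'   `write_population()` returns `path` invisibly.
#' @export
write_population <- function(records, path) {
  k <- sum(grepl("^dct_sub_", names(records)))
  cols <- population_columns(k)
  cols <- cols[cols %in% names(records)]
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- setdiff(population_columns(0), "true_state")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  check_range <- function(col, lo, hi, integer = FALSE, allow_na = FALSE) {
    v <- x[[col]]
    if (!is.numeric(v)) stop(sprintf("column `%s`: unparseable non-numeric values", col), call. = FALSE)
    bad <- if (allow_na) {
      !is.na(v) & (v < lo | v > hi)
    } else {
      is.na(v) | v < lo | v > hi
    }
    if (integer) bad <- bad | (!is.na(v) & v != round(v))
    if (any(bad)) {
      stop(sprintf(
        "column `%s`: value out of range [%s, %s] at row(s) %s",
        col, lo, hi, paste(utils::head(which(bad), 5), collapse = ", ")
      ), call. = FALSE)
    }
  }
  check_range("age", 0, 120)
  check_range("education_years", 0, 30, integer = TRUE)
  check_range("ravlt_long_delay", 0, 15, integer = TRUE)
  check_range("tmtb_seconds", 1e-9, Inf)
  check_range("faq", 0, 30, integer = TRUE)
  check_range("mmse", 0, 30, integer = TRUE)
  check_range("dct_summary", 0, 100, allow_na = TRUE)
  check_range("delayed_recall", 0, 3, integer = TRUE)
  if (anyDuplicated(x$participant_id)) {
    stop("column `participant_id`: duplicated identifiers", call. = FALSE)
  }
  for (col in c("education_years", "ravlt_long_delay", "faq", "mmse", "delayed_recall")) {
    x[[col]] <- as.integer(x[[col]])
  }
  tibble::as_tibble(x)
}
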