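#' Clock and recall points of the DCR composite
#'
#' `clock_points()` maps the clock summary score (0-100) to 0-2 points by
#' the interval rule: below 60 scores 0, 60 up to (but excluding) 75
#' scores 1, 75 and above scores 2. The rule applies to real-valued
#' summaries (74.5 scores 1). A missing summary (unanalyzable clock)
#' propagates as `NA` so such records can be excluded explicitly, never
#' imputed. `recall_points()` is the identity on the number of delayed
#' recall words (0-3); immediate recall never contributes.
#'
#' @param dct_summary Clock summary score in \[0, 100\], `NA` allowed.
#' @param words_recalled Integer delayed-recall word count in \[0, 3\].
#' @return Integer points vector (`NA` where the summary is `NA`).
#' @export
#' @examples
#' clock_points(c(59.9, 60, 74, 75))
clock_points <- function(dct_summary) {
  ok <- is.na(dct_summary) | (dct_summary >= 0 & dct_summary <= 100)
  if (!all(ok)) stop_field("dct_summary", "must lie in [0, 100]")
  as.integer(findInterval(dct_summary, c(60, 75)))
}

#' @rdname clock_points
#' @export
recall_points <- function(words_recalled) {
  ok <- is.na(words_recalled) |
    (words_recalled >= 0 & words_recalled <= 3 & words_recalled == round(words_recalled))
  if (!all(ok)) stop_field("words_recalled", "must be an integer in [0, 3]")
  as.integer(words_recalled)
}

#' Total DCR score and colour band
#'
#' Combines clock points (0-2) and recall points (0-3) into the 0-5
#' composite and its band: Green for totals 4-5 (no indication of
#' impairment), Yellow for 2-3 (borderline), Red for 0-1 (likely
#' impaired).
#'
#' @param clock_points Integer 0-2 (or `NA` for unanalyzable clocks).
#' @param recall_points Integer 0-3.
#' @return Tibble with `clock_points`, `recall_points`, `dcr_total`,
#'   `dcr_band` (factor Red < Yellow < Green).
#' @export
#' @examples
#' dcr_score(2, 3)
dcr_score <- function(clock_points, recall_points) {
  if (any(!is.na(clock_points) & !(clock_points %in% 0:2))) {
    stop_field("clock_points", "must be an integer in [0, 2]")
  }
  if (any(!is.na(recall_points) & !(recall_points %in% 0:3))) {
    stop_field("recall_points", "must be an integer in [0, 3]")
  }
  total <- as.integer(clock_points + recall_points)
  tibble::tibble(
    clock_points = as.integer(clock_points),
    recall_points = as.integer(recall_points),
    dcr_total = total,
    dcr_band = dcr_band(total)
  )
}

#' @rdname dcr_score
#' @param dcr_total Integer composite total in \[0, 5\].
#' @export
dcr_band <- function(dcr_total) {
  if (any(!is.na(dcr_total) & !(dcr_total %in% 0:5))) {
    stop_field("dcr_total", "must be an integer in [0, 5]")
  }
  band <- cut(dcr_total, breaks = c(-0.5, 1.5, 3.5, 5.5),
              labels = c("Red", "Yellow", "Green"), ordered_result = TRUE)
  band
}

#' Screening labels from the DCR total and the MMSE
#'
#' `dcr_screen_positive()` flags a participant as screen-positive
#' (possible impairment) when the composite total is at or below the
#' cutoff (default 3, i.e. the Yellow and Red bands).
#' `mmse_screen_negative()` returns `TRUE` when the MMSE labels the
#' participant unimpaired, i.e. the total is at or above the cutoff
#' (default 28, the conservative rule-out threshold used in clinical
#' practice).
#'
#' @param dcr_total Integer DCR total in \[0, 5\].
#' @param mmse Integer MMSE total in \[0, 30\].
#' @param cutoff Screening cutoff (defaults 3 and 28 respectively).
#' @return Logical vector.
#' @export
dcr_screen_positive <- function(dcr_total, cutoff = 3) {
  if (any(!is.na(dcr_total) & !(dcr_total %in% 0:5))) {
    stop_field("dcr_total", "must be an integer in [0, 5]")
  }
  dcr_total <= cutoff
}

#' @rdname dcr_screen_positive
#' @export
mmse_screen_negative <- function(mmse, cutoff = 28) {
  ok <- is.na(mmse) | (mmse >= 0 & mmse <= 30 & mmse == round(mmse))
  if (!all(ok)) stop_field("mmse", "must be an integer in [0, 30]")
  mmse >= cutoff
}

#' Score a population tibble
#'
#' Appends `clock_points`, `recall_points`, `dcr_total`, `dcr_band`,
#' `dcr_positive` and `mmse_negative` columns to a population carrying
#' `dct_summary`, `delayed_recall` and `mmse`.
#'
#' @param records Population tibble.
#' @param dcr_cutoff,mmse_cutoff Screening cutoffs (defaults 3 and 28).
#' @return The input tibble with appended columns.
#' @export
score_records <- function(records, dcr_cutoff = 3, mmse_cutoff = 28) {
  sc <- dcr_score(clock_points(records$dct_summary),
                  recall_points(records$delayed_recall))
  out <- cbind(records, sc)
  out$dcr_positive <- dcr_screen_positive(sc$dcr_total, dcr_cutoff)
  out$mmse_negative <- mmse_screen_negative(records$mmse, mmse_cutoff)
  tibble::as_tibble(out)
}
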