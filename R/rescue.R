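#' RAVLT-confirmed memory impairment mask
#'
#' Flags records whose RAVLT long-delay z-score is at or more than
#' `sd_cut` SDs below the age-normed mean (inclusive boundary).
#'
#' @param records Tibble with `ravlt_long_delay` and `age`.
#' @param norms A [norm_table()].
#' @param sd_cut Cut in SD units (default 1).
#' @return Logical vector.
#' @export
memory_impairment_mask <- function(records, norms, sd_cut = 1) {
  ravlt_zscore(records$ravlt_long_delay, records$age, norms) <= -sd_cut
}

#' Missed / rescued cross-tabulation of the two screens
#'
#' Among participants with RAVLT-confirmed memory impairment,
#' cross-tabulates the MMSE rule-out label (unimpaired when the total is
#' at or above `mmse_cutoff`) against the DCR screen (impaired when the
#' composite is at or below `dcr_cutoff`):
#'
#' * `mmse_missed` — impaired participants the MMSE labels unimpaired;
#' * `dcr_rescued` — those of the MMSE-missed the DCR flags;
#' * `dcr_missed` — impaired participants the DCR labels unimpaired
#'   (composite above the cutoff);
#' * `mmse_rescued` — those of the DCR-missed the MMSE flags.
#'
#' Records without an analyzable clock (missing `dct_summary`/
#' `dcr_total`) are excluded from the DCR-side denominators and counted
#' in `n_dcr_unanalyzable`; rates are percent of their stated
#' denominators, `NA` when a denominator is zero.
#'
#' @param records Tibble carrying `mmse`, `age`, `ravlt_long_delay`, and
#'   either `dcr_total` or both `dct_summary` and `delayed_recall` (the
#'   composite is computed on the fly in the latter case).
#' @param norms A [norm_table()].
#' @param thresholds An [impairment_thresholds()] (its `ravlt_sd_cut`
#'   defines confirmed memory impairment).
#' @param mmse_cutoff,dcr_cutoff Screening cutoffs (defaults 28 and 3).
#' @return List of class `rescue_table` with counts, denominators and
#'   rates (raw percentages; the print method shows one decimal).
#' @export
build_rescue_table <- function(records, norms,
                               thresholds = impairment_thresholds(),
                               mmse_cutoff = 28, dcr_cutoff = 3) {
  if (!"dcr_total" %in% names(records)) {
    records$dcr_total <- dcr_score(clock_points(records$dct_summary),
                                   recall_points(records$delayed_recall))$dcr_total
  }
  impaired <- memory_impairment_mask(records, norms, thresholds$ravlt_sd_cut)
  mmse_neg <- mmse_screen_negative(records$mmse, mmse_cutoff)
  analyzable <- !is.na(records$dcr_total)
  dcr_pos <- dcr_screen_positive(records$dcr_total, dcr_cutoff)

  n_mem <- sum(impaired)
  mmse_missed <- sum(impaired & mmse_neg)
  dcr_rescued <- sum(impaired & mmse_neg & analyzable & dcr_pos)
  n_mem_dcr <- sum(impaired & analyzable)
  dcr_missed <- sum(impaired & analyzable & !dcr_pos)
  mmse_rescued <- sum(impaired & analyzable & !dcr_pos & !mmse_neg)

  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(
    list(
      n_memory_impaired = n_mem,
      n_memory_impaired_dcr_analyzable = n_mem_dcr,
      n_dcr_unanalyzable = sum(impaired & !analyzable),
      mmse_missed = mmse_missed,
      dcr_rescued = dcr_rescued,
      dcr_missed = dcr_missed,
      mmse_rescued = mmse_rescued,
      mmse_missed_rate = rate(mmse_missed, n_mem),
      dcr_rescued_rate = rate(dcr_rescued, sum(impaired & mmse_neg & analyzable)),
      dcr_missed_rate = rate(dcr_missed, n_mem_dcr),
      mmse_rescued_rate = rate(mmse_rescued, dcr_missed),
      mmse_cutoff = mmse_cutoff, dcr_cutoff = dcr_cutoff,
      ravlt_sd_cut = thresholds$ravlt_sd_cut
    ),
    class = "rescue_table"
  )
}

# display rounding: half-up to one decimal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.rescue_table <- function(x, ...) {
  fmt <- function(r) if (is.na(r)) "undefined" else sprintf("%.1f%%", round_half_up(r))
  cat(sprintf("RAVLT-confirmed memory impairment (z <= -%g): n = %d\n",
              x$ravlt_sd_cut, x$n_memory_impaired))
  if (x$n_dcr_unanalyzable > 0) {
    cat(sprintf("  (of whom %d without an analyzable clock, excluded from DCR-side counts)\n",
                x$n_dcr_unanalyzable))
  }
  cat(sprintf("  missed by MMSE (>= %d): %d (%s)\n",
              x$mmse_cutoff, x$mmse_missed, fmt(x$mmse_missed_rate)))
  cat(sprintf("    of those, rescued by DCR (<= %d): %d (%s)\n",
              x$dcr_cutoff, x$dcr_rescued, fmt(x$dcr_rescued_rate)))
  cat(sprintf("  missed by DCR (> %d): %d (%s)\n",
              x$dcr_cutoff, x$dcr_missed, fmt(x$dcr_missed_rate)))
  cat(sprintf("    of those, rescued by MMSE (< %d): %d (%s)\n",
              x$mmse_cutoff, x$mmse_rescued, fmt(x$mmse_rescued_rate)))
  invisible(x)
}
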