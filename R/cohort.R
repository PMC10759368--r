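cohort_levels <- c("healthy", "aMCI", "mdMCI", "naMCI", "probable_mild_ADRD", "excluded")

#' Impairment thresholds for the rules-based cohort classifier
#'
#' @param ravlt_sd_cut Memory impairment cut in SD units: RAVLT long-delay
#'   z-score at or below `-ravlt_sd_cut` flags memory impairment
#'   (default 1; a more stringent sensitivity setting is 1.5).
#' @param tmtb_sd_cut Executive impairment cut in SD units: TMT-B z-score
#'   at or above `+tmtb_sd_cut` flags executive impairment (default 1).
#' @param faq_functional_cut FAQ score at or above which a participant is
#'   functionally impaired (default 6).
#' @param faq_exclusion_cut FAQ score strictly above which a participant
#'   is excluded as too far progressed for an early-detection analysis
#'   (default 9).
#'
#' @return A list of class `impairment_thresholds`.
#' @export
impairment_thresholds <- function(ravlt_sd_cut = 1, tmtb_sd_cut = 1,
                                  faq_functional_cut = 6, faq_exclusion_cut = 9) {
  check_scalar_number(ravlt_sd_cut, "ravlt_sd_cut", lo = 1e-12)
  check_scalar_number(tmtb_sd_cut, "tmtb_sd_cut", lo = 1e-12)
  check_scalar_number(faq_functional_cut, "faq_functional_cut", 0, 30)
  check_scalar_number(faq_exclusion_cut, "faq_exclusion_cut", faq_functional_cut, 30)
  structure(
    list(
      ravlt_sd_cut = ravlt_sd_cut, tmtb_sd_cut = tmtb_sd_cut,
      faq_functional_cut = faq_functional_cut,
      faq_exclusion_cut = faq_exclusion_cut
    ),
    class = "impairment_thresholds"
  )
}

#' Norm-referenced z-scores for RAVLT recall and TMT-B time
#'
#' `ravlt_zscore()` returns `(raw - age_mean) / age_sd` so that negative
#' values are worse (fewer words recalled than the age norm).
#' `tmtb_zscore()` returns `(seconds - age_mean) / age_sd` so that
#' positive values are worse (slower than the age norm). Each record is
#' scored against its own age bin only, with no interpolation.
#'
#' @param ravlt_long_delay RAVLT long-delay recall (words, 0-15).
#' @param tmtb_seconds TMT-B completion time (seconds, > 0).
#' @param age Age in years; must fall inside the norm table coverage.
#' @param norms A [norm_table()].
#' @return Numeric vector of z-scores in SD units.
#' @export
ravlt_zscore <- function(ravlt_long_delay, age, norms) {
  p <- norm_lookup(norms, age)
  (ravlt_long_delay - p$ravlt_mean) / p$ravlt_sd
}

#' @rdname ravlt_zscore
#' @export
tmtb_zscore <- function(tmtb_seconds, age, norms) {
  if (any(tmtb_seconds <= 0)) stop_field("tmtb_seconds", "must be > 0")
  p <- norm_lookup(norms, age)
  (tmtb_seconds - p$tmtb_mean) / p$tmtb_sd
}

#' Impairment flags from raw scores
#'
#' Computes, per record, the four boolean flags feeding the cohort
#' decision tree. All cut comparisons on z-scores are inclusive
#' ("at least 1 SD in the direction of worse performance"); the FAQ
#' functional cut is inclusive (`faq >= cut`) while the severe-exclusion
#' cut is strict (`faq > cut`).
#'
#' @param records Tibble with `ravlt_long_delay`, `tmtb_seconds`, `faq`,
#'   `age`.
#' @param norms A [norm_table()].
#' @param thresholds An [impairment_thresholds()].
#' @return Tibble with `ravlt_z`, `tmtb_z`, `memory_impaired`,
#'   `executive_impaired`, `functionally_impaired`, `excluded_severe`.
#' @export
flag_impairments <- function(records, norms, thresholds = impairment_thresholds()) {
  stopifnot(inherits(thresholds, "impairment_thresholds"))
  rz <- ravlt_zscore(records$ravlt_long_delay, records$age, norms)
  tz <- tmtb_zscore(records$tmtb_seconds, records$age, norms)
  tibble::tibble(
    ravlt_z = rz,
    tmtb_z = tz,
    memory_impaired = rz <= -thresholds$ravlt_sd_cut,
    executive_impaired = tz >= thresholds$tmtb_sd_cut,
    functionally_impaired = records$faq >= thresholds$faq_functional_cut,
    excluded_severe = records$faq > thresholds$faq_exclusion_cut
  )
}

#' Rules-based cohort label from impairment flags
#'
#' Applies the decision tree: severe functional impairment (FAQ above the
#' exclusion cut) excludes the record first; otherwise functional
#' impairment together with any cognitive deficit gives probable mild
#' ADRD; without functional impairment, memory-only gives aMCI,
#' memory-plus-executive mdMCI, executive-only naMCI, and neither gives
#' healthy. Functional impairment with no cognitive deficit is not a
#' branch of the published tree; by default such records are excluded
#' (a dementia label without a cognitive deficit is not defensible), and
#' `functional_without_cognitive = "probable_mild_ADRD"` switches them
#' into the dementia cohort instead.
#'
#' @param flags Tibble from [flag_impairments()].
#' @param functional_without_cognitive Label for the undefined branch,
#'   `"excluded"` (default) or `"probable_mild_ADRD"`.
#' @return Factor with levels
#'   `healthy, aMCI, mdMCI, naMCI, probable_mild_ADRD, excluded`.
#' @export
classify_cohort <- function(flags,
                            functional_without_cognitive = c("excluded", "probable_mild_ADRD")) {
  functional_without_cognitive <- match.arg(functional_without_cognitive)
  mem <- flags$memory_impaired
  exe <- flags$executive_impaired
  fun <- flags$functionally_impaired
  lab <- rep("healthy", length(mem))
  lab[mem & !exe] <- "aMCI"
  lab[mem & exe] <- "mdMCI"
  lab[!mem & exe] <- "naMCI"
  lab[fun & (mem | exe)] <- "probable_mild_ADRD"
  lab[fun & !mem & !exe] <- functional_without_cognitive
  lab[flags$excluded_severe] <- "excluded"
  factor(lab, levels = cohort_levels)
}

#' Collapse cohort labels to impaired / unimpaired / excluded
#'
#' The four impaired cohorts (aMCI, mdMCI, naMCI, probable mild ADRD)
#' are combined into a single cognitively impaired class; healthy maps
#' to unimpaired; excluded records stay excluded and are dropped from
#' classification analyses.
#'
#' @param label Factor from [classify_cohort()].
#' @return Factor with levels `unimpaired, impaired, excluded`.
#' @export
binarize_cohort <- function(label) {
  out <- ifelse(label == "healthy", "unimpaired",
                ifelse(label == "excluded", "excluded", "impaired"))
  factor(out, levels = c("unimpaired", "impaired", "excluded"))
}

#' Classify a population tibble
#'
#' Convenience wrapper appending z-scores, impairment flags, the cohort
#' label (`cohort`) and the binary label (`impairment_status`) to a
#' population.
#'
#' @inheritParams flag_impairments
#' @inheritParams classify_cohort
#' @return The input tibble with appended columns.
#' @export
#' @examples
#' pop <- generate_population(simulation_config(n_participants = 100, seed = 1))
#' table(classify_records(pop, default_norm_table())$cohort)
classify_records <- function(records, norms, thresholds = impairment_thresholds(),
                             functional_without_cognitive = c("excluded", "probable_mild_ADRD")) {
  flags <- flag_impairments(records, norms, thresholds)
  out <- cbind(records, flags)
  out$cohort <- classify_cohort(flags, functional_without_cognitive)
  out$impairment_status <- binarize_cohort(out$cohort)
  tibble::as_tibble(out)
}
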