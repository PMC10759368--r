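#' Age-binned normative table for RAVLT long-delay recall and TMT-B
#'
#' Builds a lookup table of age-binned normative means and standard
#' deviations used for z-scoring the RAVLT long-delay recall (words) and
#' the TMT-B completion time (seconds). Bins are half-open intervals
#' `[age_min, age_max)`: a query age equal to a bin boundary resolves to
#' the bin that starts there. Bins must be contiguous and non-overlapping.
#'
#' @param age_min,age_max Numeric vectors of bin edges (years);
#'   `age_max[i]` must equal `age_min[i + 1]`.
#' @param ravlt_mean,ravlt_sd Normative mean and SD of RAVLT long-delay
#'   recall per bin (words; SD > 0).
#' @param tmtb_mean,tmtb_sd Normative mean and SD of TMT-B completion time
#'   per bin (seconds; SD > 0).
#'
#' @return A tibble of class `norm_table` with one row per age bin.
#' @seealso [norm_lookup()], [default_norm_table()]
#' @export
#' @examples
#' norm_table(c(60, 70), c(70, 80), c(8, 7), c(2.5, 2.5), c(100, 120), c(35, 35))
norm_table <- function(age_min, age_max, ravlt_mean, ravlt_sd, tmtb_mean, tmtb_sd) {
  n <- length(age_min)
  lens <- lengths(list(age_max, ravlt_mean, ravlt_sd, tmtb_mean, tmtb_sd))
  if (any(lens != n) || n == 0L) {
    stop("all norm table columns must have the same positive length", call. = FALSE)
  }
  if (any(age_max <= age_min)) stop_field("age_max", "each bin must satisfy age_min < age_max")
  if (n > 1L && any(abs(age_min[-1L] - age_max[-n]) > 1e-12)) {
    stop_field("age_min", "bins must be contiguous and non-overlapping")
  }
  if (any(ravlt_sd <= 0)) stop_field("ravlt_sd", "SDs must be > 0")
  if (any(tmtb_sd <= 0)) stop_field("tmtb_sd", "SDs must be > 0")
  out <- tibble::tibble(
    age_min = as.numeric(age_min), age_max = as.numeric(age_max),
    ravlt_mean = as.numeric(ravlt_mean), ravlt_sd = as.numeric(ravlt_sd),
    tmtb_mean = as.numeric(tmtb_mean), tmtb_sd = as.numeric(tmtb_sd)
  )
  class(out) <- c("norm_table", class(out))
  out
}

#' Look up normative parameters for given ages
#'
#' @param norms A [norm_table()].
#' @param age Numeric vector of ages (years).
#'
#' @return A tibble with one row per query age carrying the containing
#'   bin's `ravlt_mean`, `ravlt_sd`, `tmtb_mean`, `tmtb_sd`.
#'   Ages outside the covered range raise an error.
#' @export
norm_lookup <- function(norms, age) {
  stopifnot(inherits(norms, "norm_table"))
  breaks <- c(norms$age_min, norms$age_max[nrow(norms)])
  idx <- findInterval(age, breaks)
  bad <- idx < 1L | idx > nrow(norms) | age >= breaks[length(breaks)]
  if (any(bad)) {
    stop(sprintf(
      "age out of normative range [%g, %g): %s",
      breaks[1L], breaks[length(breaks)],
      paste(unique(age[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  norms[idx, c("ravlt_mean", "ravlt_sd", "tmtb_mean", "tmtb_sd")]
}

#' Synthetic normative table shipped with the package
#'
#' A small synthetic stand-in for published age-adjusted norms (the real
#' tables are not redistributable); it exists so that the z-scoring and
#' classification logic can be exercised end to end. Covers ages
#' \[55, 90).
#'
#' @return A [norm_table()].
#' @export
default_norm_table <- function() {
  path <- system.file("extdata", "synthetic_norms.csv", package = "dcreval")
  x <- utils::read.csv(path)
  norm_table(x$age_min, x$age_max, x$ravlt_mean, x$ravlt_sd, x$tmtb_mean, x$tmtb_sd)
}
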