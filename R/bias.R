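#' Configuration for the bootstrapped bias comparison
#'
#' @param factor Demographic factor of interest: `"ethnicity"`
#'   (Hispanic vs Non-Hispanic), `"race"` (White vs Non-White) or
#'   `"education_group"` (high, >= `education_split` years, vs low).
#' @param n_iterations Bootstrap iterations (default 5000).
#' @param per_group_n Records drawn with replacement from each subgroup
#'   per iteration (default 100).
#' @param ci_level Two-sided percentile confidence level (default 0.95).
#' @param education_split Years of education splitting high from low
#'   (default 15; high means >= 15).
#' @param seed RNG seed.
#' @return A list of class `bias_config`.
#' @export
bias_config <- function(factor = c("ethnicity", "race", "education_group"),
                        n_iterations = 5000, per_group_n = 100,
                        ci_level = 0.95, education_split = 15, seed = 1L) {
  factor <- match.arg(factor)
  check_scalar_number(n_iterations, "n_iterations", lo = 1)
  check_scalar_number(per_group_n, "per_group_n", lo = 2)
  check_scalar_number(ci_level, "ci_level", 1e-9, 1 - 1e-9)
  check_scalar_number(education_split, "education_split", 0, 30)
  structure(
    list(factor = factor, n_iterations = as.integer(n_iterations),
         per_group_n = as.integer(per_group_n), ci_level = ci_level,
         education_split = education_split, seed = as.integer(seed)),
    class = "bias_config"
  )
}

#' Z-standardize a score over the analyzable sample
#'
#' @param x Numeric score vector (no missing values).
#' @return `(x - mean(x)) / sd(x)`; errors on zero variance.
#' @export
scale_scores <- function(x) {
  if (anyNA(x)) stop("scores contain missing values", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("scores have zero variance", call. = FALSE)
  (x - mean(x)) / s
}

bias_subgroups <- function(records, factor, education_split = 15) {
  switch(factor,
    ethnicity = list(level = "Hispanic",
                     member = records$ethnicity == "Hispanic"),
    race = list(level = "Non-White",
                member = records$race == "Non-White"),
    education_group = list(level = sprintf("low (< %g yrs)", education_split),
                           member = records$education_years < education_split)
  )
}

#' Two-sample Wilcoxon rank-sum subgroup comparison
#'
#' Compares a test's scores between the two subgroups of a demographic
#' factor with a two-sided two-sample Wilcoxon rank-sum test (exact for
#' small tie-free samples, tie-corrected normal approximation
#' otherwise).
#'
#' @param records Population tibble.
#' @param factor One of `"ethnicity"`, `"race"`, `"education_group"`.
#' @param test Name of the score column to compare (e.g. `"dcr_total"`,
#'   `"mmse"`).
#' @param education_split Split in years for the education factor.
#' @return List with `statistic` (rank-sum W of the first subgroup),
#'   `p_value`, and subgroup sizes.
#' @export
subgroup_wilcoxon <- function(records, factor = c("ethnicity", "race", "education_group"),
                              test, education_split = 15) {
  factor <- match.arg(factor)
  grp <- bias_subgroups(records, factor, education_split)
  a <- records[[test]][grp$member]
  b <- records[[test]][!grp$member]
  if (length(a) == 0L || length(b) == 0L) {
    stop(sprintf("empty subgroup for factor `%s`", factor), call. = FALSE)
  }
  # exact null only when tie-free and small; ties use the tie-corrected
  # normal approximation without warning chatter
  ties <- anyDuplicated(c(a, b)) > 0L
  wt <- wilcox.test(a, b, alternative = "two.sided",
                    exact = if (ties) FALSE else NULL)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(a), length(b)), method = wt$method)
}

bias_design <- function(records) {
  cols <- c("race", "ethnicity", "education_years", "sex", "age", "impairment_status")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop(sprintf("missing column(s) for the bias model: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cbind(
    intercept = 1,
    race_nonwhite = as.numeric(records$race == "Non-White"),
    ethnicity_hispanic = as.numeric(records$ethnicity == "Hispanic"),
    education_years = as.numeric(records$education_years),
    sex_male = as.numeric(records$sex == "Male"),
    age = as.numeric(records$age),
    impaired = as.numeric(records$impairment_status == "impaired")
  )
}

#' Poisson regression of a screen score on demographics and cohort
#'
#' Fits a log-link Poisson count model predicting an integer-valued
#' score from race, ethnicity, years of education, sex, age and binary
#' cohort status, via iteratively reweighted least squares (convergence
#' tolerance 1e-8). Collinear designs raise an error naming the aliased
#' columns.
#'
#' @param records Population tibble carrying the demographic columns and
#'   an `impairment_status` factor (see [classify_records()]).
#' @param test Name of the integer score column (e.g. `"dcr_total"`,
#'   `"mmse"`).
#' @return Tibble with `term`, `estimate`, `std_error`, `z`, `p_value`.
#' @export
count_model_regression <- function(records, test) {
  y <- records[[test]]
  if (is.null(y)) stop(sprintf("no column `%s`", test), call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop_field(test, "count model requires non-negative integer scores")
  }
  X <- bias_design(records)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop(sprintf("collinear design: aliased column(s) %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  df <- data.frame(y = y, X[, -1, drop = FALSE])
  fit <- glm(y ~ ., data = df, family = poisson(),
             control = list(epsilon = 1e-8, maxit = 100))
  s <- summary(fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    z = s[, 3], p_value = s[, 4]
  )
}

#' Bootstrapped comparison of demographic bias between the two screens
#'
#' Operationalizes each screen's "bias" for a demographic factor as the
#' magnitude of that factor's coefficient in a linear model predicting
#' the screen's z-scaled score from race, ethnicity, years of education,
#' sex, age and binary cohort status. On each iteration, `per_group_n`
#' records are drawn with replacement from each factor subgroup, the two
#' models are fitted on the pooled resample, and the difference of bias
#' magnitudes (DCR minus MMSE) is recorded. The scaled scores are
#' computed once on the full analyzable sample before resampling.
#' Iterations with a singular design are skipped and counted. The
#' percentile confidence interval at `ci_level` is taken from the
#' empirical quantiles of the difference vector; the interval excluding
#' zero indicates that one screen is significantly less biased
#' (negative differences mean a smaller DCR bias).
#'
#' @param records Population tibble carrying `dcr_total`, `mmse`,
#'   demographics and `impairment_status`.
#' @param config A [bias_config()].
#' @return Object of class `bias_result`: per-iteration signed
#'   coefficients (`coef_dcr`, `coef_mmse`), bias differences `diffs`,
#'   `median_diff`, `ci`, `n_skipped`, and the configuration.
#' @export
bootstrap_bias_difference <- function(records, config = bias_config()) {
  stopifnot(inherits(config, "bias_config"))
  grp <- bias_subgroups(records, config$factor, config$education_split)
  i1 <- which(grp$member)
  i2 <- which(!grp$member)
  if (length(i1) < 2L || length(i2) < 2L) {
    stop(sprintf("factor `%s`: both subgroups need at least 2 records", config$factor),
         call. = FALSE)
  }
  y_dcr <- scale_scores(records$dcr_total)
  y_mmse <- scale_scores(records$mmse)
  X <- bias_design(records)
  coef_col <- switch(config$factor,
    ethnicity = "ethnicity_hispanic", race = "race_nonwhite",
    education_group = "education_years"
  )
  jc <- match(coef_col, colnames(X))

  set.seed(config$seed)
  n_it <- config$n_iterations
  coef_dcr <- coef_mmse <- rep(NA_real_, n_it)
  skipped <- 0L
  for (it in seq_len(n_it)) {
    idx <- c(sample(i1, config$per_group_n, replace = TRUE),
             sample(i2, config$per_group_n, replace = TRUE))
    Xi <- X[idx, , drop = FALSE]
    q <- qr(Xi)
    if (q$rank < ncol(Xi)) {
      skipped <- skipped + 1L
      next
    }
    coef_dcr[it] <- qr.coef(q, y_dcr[idx])[jc]
    coef_mmse[it] <- qr.coef(q, y_mmse[idx])[jc]
  }
  ok <- !is.na(coef_dcr)
  diffs <- abs(coef_dcr[ok]) - abs(coef_mmse[ok])
  alpha <- 1 - config$ci_level
  ci <- unname(quantile(diffs, c(alpha / 2, 1 - alpha / 2)))
  structure(
    list(
      factor = config$factor, coef_dcr = coef_dcr[ok], coef_mmse = coef_mmse[ok],
      diffs = diffs, median_diff = median(diffs), ci = ci,
      ci_level = config$ci_level, n_skipped = skipped, config = config
    ),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrapped bias difference (DCR minus MMSE) for %s:\n  median = %.3f, %d%% CI = [%.3f, %.3f] (%d iterations, %d singular fits skipped)\n",
    x$factor, x$median_diff, round(100 * x$ci_level), x$ci[1], x$ci[2],
    length(x$diffs), x$n_skipped
  ))
  dir <- if (x$ci[1] > 0) {
    "the MMSE shows significantly smaller bias"
  } else if (x$ci[2] < 0) {
    "the DCR shows significantly smaller bias"
  } else {
    "no significant difference in bias"
  }
  cat(sprintf("  -> %s\n", dir))
  invisible(x)
}
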