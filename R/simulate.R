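sim_tests <- c("ravlt", "tmtb", "faq", "mmse", "dct_summary", "delayed_recall")

# direction in which the latent severity factor moves each score
# (+1 = higher is worse, -1 = lower is worse)
sim_worse_sign <- c(
  ravlt = -1, tmtb = +1, faq = +1, mmse = -1, dct_summary = -1, delayed_recall = -1
)

sim_classes <- c("healthy", "aMCI", "mdMCI", "naMCI", "probable_mild_ADRD")

#' Default per-class score distributions
#'
#' Mean/SD of each raw score within each true generating class. The
#' values are chosen so that, against [default_norm_table()] and the
#' default impairment thresholds, each class lands predominantly in its
#' nominal cohort while leaving realistic overlap: healthy participants
#' sit near the normative means, amnestic classes 1.5-2 normative SDs
#' below on RAVLT recall, the dysexecutive class 1.5-2 SDs above on
#' TMT-B time, and the mild-dementia class adds functional impairment
#' (FAQ 6-9) and globally lower screen scores.
#'
#' @return Named list (one element per class) of named lists (one per
#'   test) of `c(mean, sd)` vectors.
#' @export
default_class_params <- function() {
  list(
    healthy = list(
      ravlt = c(mean = 9.5, sd = 2.0), tmtb = c(mean = 90, sd = 20),
      faq = c(mean = 1.0, sd = 1.2), mmse = c(mean = 29, sd = 1.2),
      dct_summary = c(mean = 82, sd = 10), delayed_recall = c(mean = 2.6, sd = 0.6)
    ),
    aMCI = list(
      ravlt = c(mean = 3.5, sd = 1.5), tmtb = c(mean = 100, sd = 22),
      faq = c(mean = 2.0, sd = 1.5), mmse = c(mean = 27, sd = 2.0),
      dct_summary = c(mean = 68, sd = 12), delayed_recall = c(mean = 1.2, sd = 0.8)
    ),
    mdMCI = list(
      ravlt = c(mean = 3.2, sd = 1.5), tmtb = c(mean = 195, sd = 25),
      faq = c(mean = 2.5, sd = 1.5), mmse = c(mean = 26, sd = 2.0),
      dct_summary = c(mean = 62, sd = 12), delayed_recall = c(mean = 1.0, sd = 0.8)
    ),
    naMCI = list(
      ravlt = c(mean = 9.0, sd = 2.0), tmtb = c(mean = 195, sd = 25),
      faq = c(mean = 2.0, sd = 1.5), mmse = c(mean = 27.5, sd = 1.8),
      dct_summary = c(mean = 60, sd = 13), delayed_recall = c(mean = 2.0, sd = 0.8)
    ),
    probable_mild_ADRD = list(
      ravlt = c(mean = 2.5, sd = 1.5), tmtb = c(mean = 200, sd = 30),
      faq = c(mean = 7.3, sd = 1.1), mmse = c(mean = 23.5, sd = 2.5),
      dct_summary = c(mean = 45, sd = 13), delayed_recall = c(mean = 0.7, sd = 0.7)
    )
  )
}

#' Configuration for synthetic cohort generation
#'
#' Defines the joint structure of a simulated study population: mixture
#' over five true cognitive states, per-class score distributions,
#' demographic mixtures, and optional planted demographic effects.
#'
#' Scores are generated from per-class normal distributions tied
#' together by a single latent severity factor per participant
#' (`severity_correlation`), so that impairment-sensitive tests agree
#' more than chance. Bounded scores are rounded (integer instruments)
#' and clamped to their ranges.
#'
#' @param n_participants Number of participants to generate (>= 0).
#' @param cohort_mixture Named proportions over the five true-state
#'   classes `healthy, aMCI, mdMCI, naMCI, probable_mild_ADRD`; must sum
#'   to 1. Defaults follow the observed rules-based cohort frequencies
#'   of a large multisite screening sample (roughly 47/25/9/10/9 percent).
#' @param class_params Per-class score means/SDs, see
#'   [default_class_params()].
#' @param prop_female,prop_white,prop_hispanic Demographic mixture
#'   proportions (defaults 0.589, 0.851, 0.093).
#' @param age_mean,age_sd Age distribution in years (default 71.5, 6.7);
#'   ages are clamped to `age_range`.
#' @param age_range Closed-open interval of admissible ages; must be
#'   covered by the norm table used downstream (default `c(55, 90)`).
#' @param education_mean,education_sd Years of education (default 15.4, 2.7),
#'   rounded and clamped to \[6, 22\].
#' @param severity_correlation Correlation strength `rho` in \[0, 1)
#'   between the latent severity factor and each score (default 0.5).
#' @param n_clock_subscores Number of age-scaled clock subscores emitted
#'   (default 22); generated as noisy monotone transforms of the clock
#'   summary score.
#' @param bias_effects Planted additive demographic shifts, in units of
#'   the affected test's marginal population SD (the SD implied by the
#'   class mixture and per-class distributions, see
#'   [config_marginal_sd()]): a named list keyed by test name
#'   (`ravlt`, `tmtb`, `faq`, `mmse`, `dct_summary`, `delayed_recall`),
#'   each element a named numeric vector keyed by subgroup
#'   (`Female`, `Male`, `Hispanic`, `Non-Hispanic`, `White`, `Non-White`).
#'   E.g. `list(mmse = c(Hispanic = -0.5))` lowers Hispanic participants'
#'   MMSE by half a population SD.
#' @param seed RNG seed; identical configurations (including seed)
#'   reproduce identical populations.
#'
#' @return A validated configuration object of class `sim_config`.
#' @export
simulation_config <- function(n_participants = 706,
                              cohort_mixture = c(
                                healthy = 331, aMCI = 176, mdMCI = 61,
                                naMCI = 71, probable_mild_ADRD = 59
                              ) / 698,
                              class_params = default_class_params(),
                              prop_female = 0.589,
                              prop_white = 0.851,
                              prop_hispanic = 0.093,
                              age_mean = 71.5, age_sd = 6.7,
                              age_range = c(55, 90),
                              education_mean = 15.4, education_sd = 2.7,
                              severity_correlation = 0.5,
                              n_clock_subscores = 22,
                              bias_effects = list(),
                              seed = 1L) {
  check_scalar_number(n_participants, "n_participants", lo = 0)
  if (n_participants != round(n_participants)) {
    stop_field("n_participants", "must be a whole number")
  }
  check_proportions(cohort_mixture, "cohort_mixture")
  if (is.null(names(cohort_mixture)) || !setequal(names(cohort_mixture), sim_classes)) {
    stop_field("cohort_mixture", paste(
      "must be named with exactly the classes:",
      paste(sim_classes, collapse = ", ")
    ))
  }
  cohort_mixture <- cohort_mixture[sim_classes]
  for (cl in sim_classes) {
    if (is.null(class_params[[cl]])) stop_field("class_params", paste("missing class", cl))
    for (t in sim_tests) {
      p <- class_params[[cl]][[t]]
      if (is.null(p) || !all(c("mean", "sd") %in% names(p))) {
        stop_field("class_params", sprintf("missing mean/sd for %s in class %s", t, cl))
      }
      if (p[["sd"]] <= 0) {
        stop_field("class_params", sprintf("sd for %s in class %s must be > 0", t, cl))
      }
    }
  }
  for (f in c("prop_female", "prop_white", "prop_hispanic")) {
    check_scalar_number(get(f), f, 0, 1)
  }
  check_scalar_number(age_sd, "age_sd", lo = 1e-12)
  check_scalar_number(education_sd, "education_sd", lo = 1e-12)
  check_scalar_number(severity_correlation, "severity_correlation", 0, 1 - 1e-9)
  check_scalar_number(n_clock_subscores, "n_clock_subscores", lo = 1)
  if (!is.list(bias_effects) ||
      (length(bias_effects) && !all(names(bias_effects) %in% sim_tests))) {
    stop_field("bias_effects", paste(
      "must be a list keyed by test name:", paste(sim_tests, collapse = ", ")
    ))
  }
  subgroups <- c("Female", "Male", "Hispanic", "Non-Hispanic", "White", "Non-White")
  for (t in names(bias_effects)) {
    if (!all(names(bias_effects[[t]]) %in% subgroups)) {
      stop_field("bias_effects", paste(
        "subgroup keys must be among:", paste(subgroups, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      cohort_mixture = cohort_mixture,
      class_params = class_params,
      prop_female = prop_female, prop_white = prop_white,
      prop_hispanic = prop_hispanic,
      age_mean = age_mean, age_sd = age_sd, age_range = age_range,
      education_mean = education_mean, education_sd = education_sd,
      severity_correlation = severity_correlation,
      n_clock_subscores = as.integer(n_clock_subscores),
      bias_effects = bias_effects,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Marginal population SD of a test implied by a configuration
#'
#' The SD of the mixture distribution over classes,
#' `sqrt(sum(p_c (sd_c^2 + mean_c^2)) - (sum(p_c mean_c))^2)`; the unit
#' in which `bias_effects` shifts are expressed.
#'
#' @param config A [simulation_config()].
#' @param test Test name (one of `ravlt`, `tmtb`, `faq`, `mmse`,
#'   `dct_summary`, `delayed_recall`).
#' @return The marginal SD as a single number.
#' @export
config_marginal_sd <- function(config, test) {
  stopifnot(inherits(config, "sim_config"), test %in% sim_tests)
  p <- config$cohort_mixture
  mu <- vapply(names(p), function(cl) config$class_params[[cl]][[test]][["mean"]], 0)
  s <- vapply(names(p), function(cl) config$class_params[[cl]][[test]][["sd"]], 0)
  sqrt(sum(p * (s^2 + mu^2)) - sum(p * mu)^2)
}

score_ranges <- list(
  ravlt = c(0, 15), faq = c(0, 30), mmse = c(0, 30),
  dct_summary = c(0, 100), delayed_recall = c(0, 3)
)

#' Generate a synthetic participant population
#'
#' Draws `n_participants` records from the generative model described in
#' [simulation_config()]: a true-state class per participant, independent
#' demographics, and per-class truncated-normal test scores correlated
#' through one latent severity factor. The hidden `true_state` column is
#' retained for recovery tests and is not used by any downstream
#' analysis.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per participant: `participant_id`,
#'   demographics (`age`, `sex`, `education_years`, `race`, `ethnicity`),
#'   raw scores (`ravlt_long_delay`, `tmtb_seconds`, `faq`, `mmse`,
#'   `dct_summary`, `delayed_recall`), the clock subscores
#'   (`dct_sub_01` ...), and `true_state`.
#' @export
#' @examples
#' pop <- generate_population(simulation_config(n_participants = 50, seed = 7))
#' dim(pop)
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  k <- config$n_clock_subscores
  sub_names <- sprintf("dct_sub_%02d", seq_len(k))
  if (n == 0L) {
    cols <- population_columns(k)
    out <- tibble::as_tibble(setNames(
      lapply(cols, function(x) logical(0)), cols
    ))
    return(out)
  }

  set.seed(config$seed)
  cls <- sample(sim_classes, n, replace = TRUE, prob = config$cohort_mixture)
  sex <- sample(c("Female", "Male"), n, TRUE,
                prob = c(config$prop_female, 1 - config$prop_female))
  race <- sample(c("White", "Non-White"), n, TRUE,
                 prob = c(config$prop_white, 1 - config$prop_white))
  ethnicity <- sample(c("Hispanic", "Non-Hispanic"), n, TRUE,
                      prob = c(config$prop_hispanic, 1 - config$prop_hispanic))
  age <- clamp(rnorm(n, config$age_mean, config$age_sd),
               config$age_range[1], config$age_range[2] - 1e-6)
  education_years <- as_bounded_int(
    rnorm(n, config$education_mean, config$education_sd), 6, 22
  )

  rho <- config$severity_correlation
  u <- rnorm(n) # latent severity factor, higher = more severe
  in_group <- list(
    "Female" = sex == "Female", "Male" = sex == "Male",
    "Hispanic" = ethnicity == "Hispanic", "Non-Hispanic" = ethnicity == "Non-Hispanic",
    "White" = race == "White", "Non-White" = race == "Non-White"
  )

  raw <- list()
  for (t in sim_tests) {
    mu <- vapply(cls, function(cl) config$class_params[[cl]][[t]][["mean"]], 0)
    s <- vapply(cls, function(cl) config$class_params[[cl]][[t]][["sd"]], 0)
    e <- rnorm(n)
    x <- mu + s * (sim_worse_sign[[t]] * rho * u + sqrt(1 - rho^2) * e)
    if (!is.null(config$bias_effects[[t]])) {
      marg_sd <- config_marginal_sd(config, t)
      for (grp in names(config$bias_effects[[t]])) {
        x <- x + in_group[[grp]] * config$bias_effects[[t]][[grp]] * marg_sd
      }
    }
    raw[[t]] <- x
  }

  ravlt <- as_bounded_int(raw$ravlt, score_ranges$ravlt[1], score_ranges$ravlt[2])
  tmtb <- pmax(raw$tmtb, 10) # completion time floor, seconds
  faq <- as_bounded_int(raw$faq, score_ranges$faq[1], score_ranges$faq[2])
  mmse <- as_bounded_int(raw$mmse, score_ranges$mmse[1], score_ranges$mmse[2])
  dct <- clamp(raw$dct_summary, 0, 100)
  recall <- as_bounded_int(raw$delayed_recall, 0, 3)

  # subscores: noisy monotone transforms of the clock summary
  w <- runif(k, 0.6, 1)
  subs <- sapply(seq_len(k), function(j) {
    clamp(w[j] * dct + (1 - w[j]) * 50 + rnorm(n, 0, 6), 0, 100)
  })
  subs <- matrix(subs, nrow = n, dimnames = list(NULL, sub_names))

  out <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, education_years = education_years,
    race = race, ethnicity = ethnicity,
    ravlt_long_delay = ravlt, tmtb_seconds = tmtb, faq = faq, mmse = mmse,
    dct_summary = dct
  )
  out <- cbind(out, tibble::as_tibble(subs))
  out$delayed_recall <- recall
  out$true_state <- cls
  tibble::as_tibble(out)
}
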