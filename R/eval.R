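#' Configuration for repeated-split classifier evaluation
#'
#' @param n_iterations Number of random train/test partitions
#'   (default 200).
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.7).
#' @param n_trees_max Maximum number of trees per forest (default 500).
#' @param oob_error_floor Tolerance on out-of-bag error used during
#'   features-per-split tuning: the smallest `mtry` whose OOB error is
#'   within this amount of the best candidate is selected (default
#'   0.001).
#' @param feature_sets Named list of character vectors of feature column
#'   names; `NULL` (default) lets [evaluate_feature_sets()] build the
#'   standard sets (`dcr`, `mmse`, `demographics`, `all`) from the data.
#' @param n_permutations Permutations for the paired AUC test
#'   (default 5000).
#' @param classifier A fitting function `function(x, y, config, seed)`
#'   returning an object with a `$score(newdata)` member mapping rows to
#'   the probability of the positive (impaired) class; `NULL` (default)
#'   uses the random-forest engine of [fit_classifier()]. Plugging a
#'   deterministic stub here lets the surrounding pipeline be tested
#'   independently of the learner.
#' @param seed Master RNG seed; all per-iteration seeds are derived from
#'   it.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(n_iterations = 200, train_fraction = 0.7,
                        n_trees_max = 500, oob_error_floor = 0.001,
                        feature_sets = NULL, n_permutations = 5000,
                        classifier = NULL, seed = 1L) {
  check_scalar_number(n_iterations, "n_iterations", lo = 1)
  check_scalar_number(train_fraction, "train_fraction", 1e-9, 1 - 1e-9)
  check_scalar_number(n_trees_max, "n_trees_max", lo = 1)
  check_scalar_number(oob_error_floor, "oob_error_floor", lo = 0)
  check_scalar_number(n_permutations, "n_permutations", lo = 1)
  structure(
    list(
      n_iterations = as.integer(n_iterations), train_fraction = train_fraction,
      n_trees_max = as.integer(n_trees_max), oob_error_floor = oob_error_floor,
      feature_sets = feature_sets, n_permutations = as.integer(n_permutations),
      classifier = classifier, seed = as.integer(seed)
    ),
    class = "eval_config"
  )
}

#' Stratified train/test split
#'
#' Partitions indices into disjoint, exhaustive train and test sets so
#' that each class contributes `train_fraction` of its members (within
#' one record) to training, keeping class distributions matched between
#' the two sets.
#'
#' @param labels Class label vector (any type with >= 2 members per
#'   class).
#' @param train_fraction Training fraction in (0, 1).
#' @param seed RNG seed; identical seeds reproduce identical splits.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  tab <- table(labels)
  if (any(tab < 2L)) {
    stop(sprintf("class(es) with fewer than 2 records: %s",
                 paste(names(tab)[tab < 2L], collapse = ", ")), call. = FALSE)
  }
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L) # both sides non-empty
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Upsample a training set to class balance
#'
#' Randomly samples training records with replacement, within each
#' minority class, until every class count equals the majority-class
#' count. All original records are retained; only copies of existing
#' training records are added. Applied to training data only — test sets
#' keep their native class distribution.
#'
#' @param labels Class labels of the training records.
#' @param seed RNG seed.
#' @return Integer vector of positions into the training set (the
#'   original positions followed by the sampled duplicates).
#' @export
upsample_to_balance <- function(labels, seed = 1L) {
  tab <- table(labels)
  if (length(tab) == 0L || any(tab < 1L)) {
    stop("every class must have at least one training record", call. = FALSE)
  }
  set.seed(seed)
  target <- max(tab)
  extra <- integer(0)
  for (cl in names(tab)) {
    need <- target - tab[[cl]]
    idx_cl <- which(labels == cl)
    # index into idx_cl to stay safe when a class has a single record
    if (need > 0L) extra <- c(extra, idx_cl[sample.int(length(idx_cl), need, replace = TRUE)])
  }
  c(seq_along(labels), extra)
}

#' Fit the probability-scoring random-forest classifier
#'
#' Fits a probability forest on a balanced training set and returns a
#' scoring closure. Features-per-split (`mtry`) is tuned over a small
#' grid (1 and the square root of the feature count): the smallest value
#' whose out-of-bag error is within `oob_error_floor` of the best
#' candidate is kept, preferring sparser splits. Trees are capped at
#' `n_trees_max`. Fully deterministic for a given seed (single thread).
#'
#' @param x Data frame / matrix of numeric features.
#' @param y Two-level factor of class labels; the second level is scored
#'   as the positive class.
#' @param config An [eval_config()].
#' @param seed RNG seed.
#' @return List of class `dcr_classifier` with elements `model`, `mtry`,
#'   `oob_error`, and `score(newdata)` returning positive-class
#'   probabilities.
#' @export
fit_classifier <- function(x, y, config = eval_config(), seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class", call. = FALSE)
  if (!is.null(config$classifier)) {
    return(config$classifier(x, y, config, seed))
  }
  x <- as.data.frame(x)
  p <- ncol(x)
  candidates <- sort(unique(pmin(p, c(1L, max(1L, floor(sqrt(p)))))))
  fits <- lapply(candidates, function(m) {
    ranger::ranger(
      x = x, y = y, num.trees = config$n_trees_max, mtry = m,
      probability = TRUE, seed = seed, num.threads = 1
    )
  })
  oob <- vapply(fits, function(f) f$prediction.error, 0)
  keep <- which(oob <= min(oob) + config$oob_error_floor)[1L]
  fit <- fits[[keep]]
  pos <- levels(y)[2L]
  structure(
    list(
      model = fit, mtry = candidates[keep], oob_error = oob[keep],
      positive = pos,
      score = function(newdata) {
        predict(fit, data = as.data.frame(newdata),
                num.threads = 1)$predictions[, pos]
      }
    ),
    class = "dcr_classifier"
  )
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Computes the AUC as the probability that a random positive case
#' scores above a random negative case, with ties counted as one half —
#' the Mann-Whitney U statistic scaled to \[0, 1\], computed via average
#' ranks.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or coercible) vector, `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index optimal threshold and accuracy metrics
#'
#' Scans all observed score values as candidate cutpoints for the rule
#' "positive if score >= threshold" and selects the cutpoint maximizing
#' the Youden index J = sensitivity + specificity - 1. When several
#' cutpoints tie, the lowest is chosen (the most sensitive rule, in
#' keeping with a screening use-case).
#'
#' @inheritParams roc_auc
#' @return List with `threshold` and `metrics`, a tibble with
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `balanced_accuracy`,
#'   `youden` at the selected threshold (predictive values are `NA` when
#'   their denominator is empty).
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("threshold undefined: both classes must be present", call. = FALSE)
  }
  ths <- sort(unique(scores))
  # counts of each class strictly below each candidate threshold
  pos_below <- vapply(ths, function(t) sum(labels & scores < t), 0L)
  neg_below <- vapply(ths, function(t) sum(!labels & scores < t), 0L)
  sens <- (n1 - pos_below) / n1
  spec <- neg_below / n0
  j <- sens + spec - 1
  k <- which(j >= max(j) - 1e-12)[1L] # lowest threshold among ties
  t <- ths[k]
  tp <- n1 - pos_below[k]
  fp <- n0 - neg_below[k]
  fn <- pos_below[k]
  tn <- neg_below[k]
  metrics <- tibble::tibble(
    sensitivity = sens[k], specificity = spec[k],
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    balanced_accuracy = (sens[k] + spec[k]) / 2,
    youden = j[k]
  )
  list(threshold = t, metrics = metrics)
}

# Encode a feature subset as a numeric data frame (two-level categorical
# columns become 0/1 indicators named col_level).
build_features <- function(records, cols) {
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop(sprintf("feature column(s) not found: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- list()
  for (cl in cols) {
    v <- records[[cl]]
    if (is.numeric(v)) {
      out[[cl]] <- v
    } else {
      lev <- sort(unique(as.character(v)))
      for (l in lev[-1L]) {
        out[[paste(cl, l, sep = "_")]] <- as.numeric(v == l)
      }
    }
  }
  as.data.frame(out, optional = TRUE)
}

#' Standard feature sets for screen comparison
#'
#' Builds the four standard predictor sets from a scored population:
#' `dcr` (all age-scaled clock subscores plus the delayed recall count —
#' no composite scores), `mmse` (the MMSE total only), `demographics`
#' (age, sex, years of education), and `all` (their union).
#'
#' @param records Population tibble.
#' @return Named list of character vectors of column names.
#' @export
default_feature_sets <- function(records) {
  subs <- grep("^dct_sub_", names(records), value = TRUE)
  if (length(subs) == 0L) stop("no dct_sub_* columns found", call. = FALSE)
  dcr <- c(subs, "delayed_recall")
  demo <- c("age", "sex", "education_years")
  list(dcr = dcr, mmse = "mmse", demographics = demo, all = c(dcr, "mmse", demo))
}

#' Repeated stratified-split evaluation of feature sets
#'
#' For each of `n_iterations` random stratified 70/30 partitions, every
#' feature set sees the identical partition (paired design); the
#' training side is upsampled to class balance, a probability classifier
#' is fitted, and test-set metrics (AUC, Youden-thresholded sensitivity,
#' specificity, PPV, NPV, balanced accuracy) are recorded. Per-iteration
#' seeds are drawn once from the master seed, so the whole experiment is
#' reproducible from a single integer.
#'
#' @param records Population tibble (excluded records already removed).
#' @param labels Two-class factor (`unimpaired`/`impaired`); the second
#'   level is the positive class.
#' @param config An [eval_config()].
#' @return Object of class `repeated_eval`: list with `metrics` (tibble
#'   of per-iteration metrics by feature set), `summary` (median and SD
#'   of each metric per feature set), `auc` (iterations x feature-set
#'   matrix for paired tests), and `config`.
#' @export
evaluate_feature_sets <- function(records, labels, config = eval_config()) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) {
    stop("labels must contain exactly two classes (drop excluded records first)",
         call. = FALSE)
  }
  if (length(labels) != nrow(records)) stop("labels/records length mismatch", call. = FALSE)
  feature_sets <- config$feature_sets %||% default_feature_sets(records)
  xs <- lapply(feature_sets, function(cols) build_features(records, cols))
  pos <- levels(labels)[2L]

  seeds <- matrix(derive_seeds(config$seed, 3L * config$n_iterations), ncol = 3L)
  rows <- vector("list", config$n_iterations * length(feature_sets))
  auc_mat <- matrix(NA_real_, config$n_iterations, length(feature_sets),
                    dimnames = list(NULL, names(feature_sets)))
  r <- 0L
  for (i in seq_len(config$n_iterations)) {
    sp <- stratified_split(labels, config$train_fraction, seed = seeds[i, 1L])
    bal <- upsample_to_balance(labels[sp$train], seed = seeds[i, 2L])
    tr_idx <- sp$train[bal]
    for (fs in names(feature_sets)) {
      fit <- fit_classifier(xs[[fs]][tr_idx, , drop = FALSE], labels[tr_idx],
                            config, seed = seeds[i, 3L])
      sc <- fit$score(xs[[fs]][sp$test, , drop = FALSE])
      truth <- labels[sp$test] == pos
      auc <- roc_auc(sc, truth)
      yt <- youden_threshold(sc, truth)
      r <- r + 1L
      rows[[r]] <- cbind(
        tibble::tibble(iteration = i, feature_set = fs, auc = auc,
                       youden_threshold = yt$threshold),
        yt$metrics
      )
      auc_mat[i, fs] <- auc
    }
  }
  metrics <- tibble::as_tibble(do.call(rbind, rows))
  num_cols <- c("auc", "sensitivity", "specificity", "ppv", "npv",
                "balanced_accuracy", "youden")
  summ <- do.call(rbind, lapply(names(feature_sets), function(fs) {
    m <- metrics[metrics$feature_set == fs, ]
    tibble::tibble(
      feature_set = fs,
      metric = num_cols,
      median = vapply(num_cols, function(cl) median(m[[cl]], na.rm = TRUE), 0),
      sd = vapply(num_cols, function(cl) sd(m[[cl]], na.rm = TRUE), 0)
    )
  }))
  structure(
    list(metrics = metrics, summary = tibble::as_tibble(summ),
         auc = auc_mat, config = config),
    class = "repeated_eval"
  )
}

#' @export
print.repeated_eval <- function(x, ...) {
  cat(sprintf("Repeated stratified-split evaluation: %d iterations, %d feature set(s)\n",
              x$config$n_iterations, ncol(x$auc)))
  s <- x$summary[x$summary$metric == "auc", ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-14s median AUC = %.3f (SD = %.3f)\n",
                s$feature_set[i], s$median[i], s$sd[i]))
  }
  invisible(x)
}

#' Paired permutation test on a median difference
#'
#' Tests whether the median of paired differences `a - b` (e.g. paired
#' per-iteration AUCs of two models) differs from zero. The null
#' distribution is generated by independent random sign flips of each
#' paired difference; the two-sided p-value is
#' `(1 + #{|perm| >= |observed|}) / (n_permutations + 1)`, so its
#' smallest attainable value is `1 / (n_permutations + 1)`.
#'
#' @param aucs_a,aucs_b Equal-length paired numeric vectors.
#' @param n_permutations Number of random sign-flip permutations.
#' @param seed RNG seed.
#' @return List of class `permutation_result` with
#'   `observed_median_diff`, `p_value`, `n_permutations`.
#' @export
paired_permutation_median_diff <- function(aucs_a, aucs_b,
                                           n_permutations = 5000, seed = 1L) {
  if (length(aucs_a) != length(aucs_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  d <- aucs_a - aucs_b
  obs <- median(d)
  set.seed(seed)
  n <- length(d)
  perm <- vapply(seq_len(n_permutations), function(i) {
    median(d * sample(c(-1, 1), n, replace = TRUE))
  }, 0)
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-15)) / (n_permutations + 1)
  structure(
    list(observed_median_diff = obs, p_value = p,
         n_permutations = as.integer(n_permutations)),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Paired sign-flip permutation test: median diff = %.4f, p = %.4g (%d permutations)\n",
              x$observed_median_diff, x$p_value, x$n_permutations))
  invisible(x)
}
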