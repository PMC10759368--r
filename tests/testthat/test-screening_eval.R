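test_that("stratified splits are balanced, exhaustive and seeded", {
  labels <- rep(c("a", "b"), c(60, 40))
  sp <- stratified_split(labels, 0.7, seed = 1)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sum(labels[sp$train] == "a"), 42, tolerance = 0) # 0.7 * 60
  expect_equal(sum(labels[sp$train] == "b"), 28, tolerance = 0)
  expect_identical(sp, stratified_split(labels, 0.7, seed = 1))
  expect_false(identical(sp, stratified_split(labels, 0.7, seed = 2)))
  expect_error(stratified_split(c("a", "a", "b"), 0.7), "fewer than 2")
})

test_that("upsampling balances classes using only existing training records", {
  labels <- rep(c("A", "B"), c(30, 70))
  idx <- upsample_to_balance(labels, seed = 3)
  expect_equal(as.integer(table(labels[idx])), c(70L, 70L))
  expect_true(all(seq_along(labels) %in% idx))      # superset of original
  expect_true(all(idx %in% seq_along(labels)))      # closure
  balanced <- rep(c("A", "B"), c(50, 50))
  expect_equal(upsample_to_balance(balanced, seed = 3), seq_along(balanced))
  expect_error(upsample_to_balance(character(0)), "at least one")
})

test_that("AUC equals the pairwise Mann-Whitney oracle, ties half-credited", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(7)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), auc_pairwise_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(80)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE, prob = c(0.4, 0.6))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<", levels = c(FALSE, TRUE))))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("the Youden threshold matches exhaustive cutpoint enumeration", {
  sep <- youden_threshold(c(1, 2, 3, 10, 11, 12), c(rep(FALSE, 3), rep(TRUE, 3)))
  expect_equal(sep$metrics$youden, 1)
  expect_equal(sep$metrics$sensitivity, 1)
  expect_equal(sep$metrics$specificity, 1)
  degen <- youden_threshold(rep(0.4, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(degen$metrics$youden, 0)

  set.seed(19)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    got <- youden_threshold(scores, labels)
    ora <- youden_exhaustive_oracle(scores, labels)
    expect_equal(got$metrics$youden, ora$j, tolerance = 1e-12)
    expect_equal(got$threshold, ora$threshold)
    expect_equal(got$metrics$sensitivity, ora$sens)
    expect_equal(got$metrics$specificity, ora$spec)
    expect_equal(got$metrics$balanced_accuracy,
                 (got$metrics$sensitivity + got$metrics$specificity) / 2)
  }
})

test_that("the forest scores a separable toy problem perfectly and is seeded", {
  set.seed(5)
  x <- data.frame(f1 = c(rnorm(30, -3), rnorm(30, 3)), f2 = rnorm(60))
  y <- factor(rep(c("unimpaired", "impaired"), each = 30),
              levels = c("unimpaired", "impaired"))
  fit <- fit_classifier(x, y, eval_config(), seed = 2)
  expect_equal(roc_auc(fit$score(x), y == "impaired"), 1)
  fit2 <- fit_classifier(x, y, eval_config(), seed = 2)
  expect_identical(fit$score(x), fit2$score(x))
  expect_error(fit_classifier(x, factor(rep("impaired", 60))), "single class")
})

test_that("with permuted labels the forest sits at chance on fresh data", {
  set.seed(17)
  x <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  xt <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  yt <- rep(c(TRUE, FALSE), 30)
  aucs <- vapply(1:50, function(s) {
    set.seed(100 + s)
    y <- factor(sample(rep(c("unimpaired", "impaired"), 30)),
                levels = c("unimpaired", "impaired"))
    fit <- fit_classifier(x, y, eval_config(n_trees_max = 150), seed = s)
    roc_auc(fit$score(xt), yt)
  }, 0)
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("repeated evaluation pairs feature sets on identical splits", {
  pop <- generate_population(simulation_config(n_participants = 200, seed = 23))
  labels <- factor(ifelse(pop$true_state == "healthy", "unimpaired", "impaired"),
                   levels = c("unimpaired", "impaired"))
  cfg <- eval_config(
    n_iterations = 4, seed = 6, classifier = stub_classifier,
    feature_sets = list(one = "mmse", two = "mmse", dcr = "delayed_recall")
  )
  ev <- evaluate_feature_sets(pop, labels, cfg)
  expect_equal(nrow(ev$metrics), 4 * 3)
  # identical feature sets on identical splits give identical metric paths
  expect_equal(ev$auc[, "one"], ev$auc[, "two"])
  expect_equal(ev$metrics$sensitivity[ev$metrics$feature_set == "one"],
               ev$metrics$sensitivity[ev$metrics$feature_set == "two"])
  # summaries recompute from the stored per-iteration values
  med <- ev$summary$median[ev$summary$feature_set == "dcr" & ev$summary$metric == "auc"]
  expect_equal(unname(med), median(ev$auc[, "dcr"]))

  one <- evaluate_feature_sets(pop, labels,
                               eval_config(n_iterations = 1, seed = 6,
                                           classifier = stub_classifier,
                                           feature_sets = list(m = "mmse")))
  expect_equal(nrow(one$metrics), 1)
})

test_that("the sign-flip permutation test matches full enumeration at length 10", {
  expect_equal(paired_permutation_median_diff(1:8 / 10, 1:8 / 10, 500, seed = 1)$p_value, 1)

  set.seed(29)
  for (i in 1:5) {
    d <- rnorm(10, mean = 0.4 * (i %% 2), sd = 1)
    ora <- perm_median_enumeration_oracle(d)
    got <- paired_permutation_median_diff(d, rep(0, 10), n_permutations = 20000, seed = i)
    expect_equal(got$observed_median_diff, ora$obs)
    expect_lt(abs(got$p_value - ora$p), 0.02)
  }
  expect_error(paired_permutation_median_diff(1:3, 1:4), "equal length")
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(31)
  ps <- vapply(1:150, function(i) {
    d <- rnorm(30)
    paired_permutation_median_diff(d, rep(0, 30), n_permutations = 199,
                                   seed = 1000 + i)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
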