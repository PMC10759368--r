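# Independent brute-force oracles used across the suite.

# AUC by O(n^2) pairwise comparison, ties credited 0.5
auc_pairwise_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Youden threshold by exhaustive enumeration of observed cutpoints
# (rule: positive if score >= t; ties broken toward the lowest t)
youden_exhaustive_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- list(j = -Inf, threshold = NA_real_, sens = NA_real_, spec = NA_real_)
  for (t in sort(unique(scores))) {
    pred <- scores >= t
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) {
      best <- list(j = j, threshold = t, sens = sens, spec = spec)
    }
  }
  best
}

# Exact sign-flip null of the median-difference statistic (full 2^n grid)
perm_median_enumeration_oracle <- function(d) {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- apply(signs, 1, function(s) median(d * s))
  obs <- median(d)
  list(obs = obs, p = mean(abs(stats) >= abs(obs) - 1e-15))
}

# Hand-enumerated decision-tree truth table over the four flags,
# for the default branch choice (functional-only -> excluded)
cohort_truth_table <- function() {
  g <- expand.grid(mem = c(FALSE, TRUE), exe = c(FALSE, TRUE),
                   fun = c(FALSE, TRUE), excl = c(FALSE, TRUE))
  expected <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    r <- g[i, ]
    expected[i] <- if (r$excl) {
      "excluded"
    } else if (r$fun && (r$mem || r$exe)) {
      "probable_mild_ADRD"
    } else if (r$fun) {
      "excluded"
    } else if (r$mem && r$exe) {
      "mdMCI"
    } else if (r$mem) {
      "aMCI"
    } else if (r$exe) {
      "naMCI"
    } else {
      "healthy"
    }
  }
  cbind(g, expected = expected)
}

# Small single-bin norm table: z-scores reduce to simple arithmetic
flat_norms <- function(ravlt_mean = 8, ravlt_sd = 2, tmtb_mean = 100, tmtb_sd = 40) {
  norm_table(55, 90, ravlt_mean, ravlt_sd, tmtb_mean, tmtb_sd)
}

# Minimal record tibble for rule-level tests (ages inside flat_norms)
make_records <- function(ravlt, tmtb, faq, age = 70) {
  n <- max(lengths(list(ravlt, tmtb, faq)))
  tibble::tibble(
    participant_id = sprintf("R%03d", seq_len(n)),
    age = rep_len(age, n),
    ravlt_long_delay = rep_len(ravlt, n),
    tmtb_seconds = rep_len(tmtb, n),
    faq = rep_len(faq, n)
  )
}

# Deterministic stub classifier: score = mean of feature columns
stub_classifier <- function(x, y, config, seed) {
  list(score = function(newdata) rowMeans(as.data.frame(newdata)))
}
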