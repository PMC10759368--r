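test_that("generation is a pure, seeded function of the configuration", {
  cfg <- simulation_config(n_participants = 500, seed = 7)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 500)
  expect_false(anyDuplicated(a$participant_id) > 0)
  c <- generate_population(simulation_config(n_participants = 500, seed = 8))
  expect_false(identical(a, c))

  empty <- generate_population(simulation_config(n_participants = 0))
  expect_equal(nrow(empty), 0)
  expect_setequal(names(empty), population_columns(22))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(simulation_config(n_participants = -1), "n_participants")
  expect_error(
    simulation_config(cohort_mixture = c(healthy = 0.6, aMCI = 0.2, mdMCI = 0.1,
                                         naMCI = 0.05, probable_mild_ADRD = 0.1)),
    "cohort_mixture"
  )
  bad <- default_class_params()
  bad$healthy$mmse[["sd"]] <- -1
  expect_error(simulation_config(class_params = bad), "class_params")
  expect_error(simulation_config(bias_effects = list(nonsense = c(Hispanic = 1))),
               "bias_effects")
})

test_that("per-class sample means converge to configured values", {
  # class parameters kept well inside score bounds so that rounding and
  # clamping do not shift the means materially
  cp <- default_class_params()
  for (cl in names(cp)) {
    cp[[cl]]$faq <- c(mean = 8, sd = 1.5)
    cp[[cl]]$mmse <- c(mean = 22, sd = 2)
    cp[[cl]]$delayed_recall <- c(mean = 1.5, sd = 0.45)
    cp[[cl]]$ravlt <- c(mean = 8, sd = 1.8)
    cp[[cl]]$dct_summary <- c(mean = 60, sd = 9)
    cp[[cl]]$tmtb <- c(mean = 150, sd = 30)
  }
  pop <- generate_population(simulation_config(
    n_participants = 10000, class_params = cp, seed = 11
  ))
  cols <- c(ravlt = "ravlt_long_delay", tmtb = "tmtb_seconds", faq = "faq",
            mmse = "mmse", dct_summary = "dct_summary", delayed_recall = "delayed_recall")
  for (cl in unique(pop$true_state)) {
    sub <- pop[pop$true_state == cl, ]
    for (t in names(cols)) {
      m <- cp[[cl]][[t]][["mean"]]
      s <- cp[[cl]][[t]][["sd"]]
      se <- s / sqrt(nrow(sub))
      # 3 standard errors, plus a small allowance for integer rounding
      expect_lt(abs(mean(sub[[cols[[t]]]]) - m), 3 * se + 0.06)
    }
  }
})

test_that("planted demographic shifts appear on the targeted test only", {
  cfg <- simulation_config(
    n_participants = 8000, seed = 21,
    prop_hispanic = 0.3,
    bias_effects = list(mmse = c(Hispanic = -0.8))
  )
  # keep the shifted score away from its ceiling so clamping is immaterial
  cfg$class_params <- lapply(cfg$class_params, function(p) {
    p$mmse <- c(mean = 20, sd = 2.5)
    p
  })
  pop <- generate_population(cfg)
  hisp <- pop$ethnicity == "Hispanic"
  # observed shift in units of the (shared) class SD
  d_mmse <- (mean(pop$mmse[hisp]) - mean(pop$mmse[!hisp])) / 2.5
  expect_lt(abs(d_mmse - (-0.8)), 0.1)
  # untouched test: standardized subgroup difference indistinguishable from 0
  d_dct <- (mean(pop$dct_summary[hisp]) - mean(pop$dct_summary[!hisp])) /
    sd(pop$dct_summary)
  expect_lt(abs(d_dct), 0.08)
})

test_that("an all-healthy population classifies almost entirely healthy", {
  cp <- default_class_params()
  # configured distributions >= 2 SD clear of every impairment cutoff
  cp$healthy$ravlt <- c(mean = 9.5, sd = 1.0)
  cp$healthy$tmtb <- c(mean = 90, sd = 15)
  cp$healthy$faq <- c(mean = 0.8, sd = 0.8)
  cfg <- simulation_config(
    n_participants = 2000,
    cohort_mixture = c(healthy = 1, aMCI = 0, mdMCI = 0, naMCI = 0,
                       probable_mild_ADRD = 0),
    class_params = cp, seed = 5
  )
  lab <- classify_records(generate_population(cfg), default_norm_table())
  expect_gte(mean(lab$cohort == "healthy"), 0.95)
})

test_that("norm table lookup follows half-open bins and matches a linear scan", {
  nt <- norm_table(c(60, 70), c(70, 80), c(8, 7), c(2, 2), c(100, 120), c(30, 30))
  expect_equal(norm_lookup(nt, 70)$ravlt_mean, 7) # boundary -> second bin
  expect_equal(norm_lookup(nt, 69.999)$ravlt_mean, 8)
  expect_error(norm_lookup(nt, 80), "out of normative range")
  expect_error(norm_lookup(nt, 59.9), "out of normative range")

  single <- norm_table(50, 95, 8, 2, 100, 30)
  expect_equal(norm_lookup(single, c(50, 72, 94.9))$tmtb_mean, rep(100, 3))

  set.seed(42)
  nt5 <- norm_table(seq(55, 83, 7), seq(62, 90, 7),
                    9:5, rep(2.5, 5), seq(90, 150, 15), rep(35, 5))
  ages <- runif(1000, 55, 90 - 1e-6)
  got <- norm_lookup(nt5, ages)
  for (i in seq_along(ages)) {
    j <- which(nt5$age_min <= ages[i] & ages[i] < nt5$age_max)
    expect_equal(got$ravlt_mean[i], nt5$ravlt_mean[j])
    expect_equal(got$tmtb_sd[i], nt5$tmtb_sd[j])
  }
})

test_that("norm table construction validates bins and SDs", {
  expect_error(norm_table(c(60, 71), c(70, 80), c(8, 7), c(2, 2), c(100, 120), c(30, 30)),
               "contiguous")
  expect_error(norm_table(60, 70, 8, 0, 100, 30), "ravlt_sd")
})

test_that("population files round-trip identically and are validated on read", {
  pop <- generate_population(simulation_config(n_participants = 100, seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, path)
  back <- read_population(path)
  expect_equal(as.data.frame(back), as.data.frame(pop), tolerance = 1e-12)

  # missing required column is named in the error
  broken <- pop
  broken$faq <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(broken, p2, row.names = FALSE)
  expect_error(read_population(p2), "faq")

  # out-of-range score is caught with its column
  broken2 <- pop
  broken2$mmse[3] <- 31L
  p3 <- withr::local_tempfile(fileext = ".csv")
  write_population(broken2, p3)
  expect_error(read_population(p3), "mmse")
})
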