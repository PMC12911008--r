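test_that("cohort generation is deterministic and reproduces the sample flow", {
  spec <- cohort_spec(n_baseline = 256, seed = 7)
  a <- generate_cohort(spec, conn_waves = 1)
  b <- generate_cohort(spec, conn_waves = 1)
  expect_identical(a$table, b$table)
  expect_identical(a$connectivity[[5]][[1]], b$connectivity[[5]][[1]])

  counts <- table(a$table$wave)
  expect_equal(unname(counts[["1"]]), 256)
  expect_equal(unname(counts[["2"]]), 227)   # round(0.887 * 256)
  expect_equal(unname(counts[["3"]]), 202)   # round(0.789 * 256)
  # wave-1 complete for all participants
  cols <- c(attr(a$table, "motor_cols"), attr(a$table, "cognitive_cols"))
  expect_false(anyNA(a$table[a$table$wave == 1, cols]))
})

test_that("attrition respects the rounding rule, monotone dropout and edge cases", {
  spec <- cohort_spec(n_baseline = 100, retention = c(0.5, 0.25),
                      missing_rates = c(0.5, 0.75), seed = 3)
  ch <- generate_cohort(spec, conn_waves = integer(0))
  expect_equal(sum(ch$table$wave == 2), 50)
  expect_equal(sum(ch$table$wave == 3), 25)
  # monotone: every wave-3 completer is a wave-2 completer
  w2 <- ch$table$participant[ch$table$wave == 2]
  w3 <- ch$table$participant[ch$table$wave == 3]
  expect_true(all(w3 %in% w2))

  spec_full <- cohort_spec(n_baseline = 40, retention = c(1, 1),
                           missing_rates = c(0, 0), seed = 3)
  ch_full <- generate_cohort(spec_full, conn_waves = integer(0))
  expect_equal(nrow(ch_full$table), 120)
  cols <- c(attr(ch_full$table, "motor_cols"), attr(ch_full$table, "cognitive_cols"))
  expect_false(anyNA(ch_full$table[, cols]))

  expect_error(cohort_spec(retention = c(0.7, 0.9)), "non-increasing")
  expect_error(cohort_spec(retention = c(1.2, 0.5)), "\\[0, 1\\]")
})

test_that("wave-level missing fractions hit the configured rates", {
  spec <- cohort_spec(n_baseline = 256, seed = 11)
  ch <- generate_cohort(spec, conn_waves = integer(0))
  expect_lt(abs(cohort_missing_fraction(ch$table, 2) - 0.113), 0.01)
  expect_lt(abs(cohort_missing_fraction(ch$table, 3) - 0.211), 0.01)

  # a rate below the dropout floor is a parameter error
  spec_bad <- cohort_spec(n_baseline = 256, seed = 11,
                          missing_rates = c(0.05, 0.211))
  expect_error(generate_cohort(spec_bad), "floor")
})

test_that("item missingness is MAR: driven by auxiliaries, not by values", {
  spec <- cohort_spec(n_baseline = 600, missing_rates = c(0.35, 0.45), seed = 5)
  ch <- generate_cohort(spec, conn_waves = integer(0))
  # same seed, floor rates: identical table pre-masking
  spec0 <- spec
  spec0$missing_rates <- c(0.1134, 0.2115)
  ch0 <- generate_cohort(spec0, conn_waves = integer(0))
  w2 <- ch$table[ch$table$wave == 2, ]
  w2_true <- ch0$table[ch0$table$wave == 2, ]
  expect_identical(w2$participant, w2_true$participant)

  masked <- is.na(w2$fine_motor)
  # mechanism sign: masked records sit at higher motion
  expect_gt(mean(w2$mean_fd[masked]), mean(w2$mean_fd[!masked]))
  # MAR: conditional on auxiliaries the mechanism ignores the values, and
  # values are independent of the auxiliaries in the generator, so the
  # underlying scores of masked cells are unbiased
  expect_lt(abs(mean(w2_true$fine_motor[masked]) -
                mean(w2_true$fine_motor[!masked])), 4)
})

test_that("behavioral scores match configured norms and the signal dial works", {
  # zero effect size: baseline connectivity is uninformative about change
  spec0 <- cohort_spec(n_baseline = 400, effect_size = 0, seed = 21)
  ch0 <- generate_cohort(spec0, conn_waves = integer(0))
  lab0 <- outcome_labels(ch0$table)
  base0 <- ch0$table[ch0$table$wave == 1, ]
  r0 <- cor(base0$eta, lab0$change_motor, use = "complete.obs")
  expect_lt(abs(r0), 3 / sqrt(sum(!is.na(lab0$change_motor))))

  # large-n mean of the age-3 fine-motor subgroup matches the configured
  # norm, allowing for the analytic effect of clamping to [0, 100]
  spec <- cohort_spec(n_baseline = 2000, effect_size = 0.8, seed = 23)
  ch <- generate_cohort(spec, conn_waves = integer(0))
  base <- ch$table[ch$table$wave == 1 & ch$table$age_group == 3, ]
  mu <- 38.2; sg <- 23.7
  clamp_shift <- sg * (dnorm(mu / sg) - (mu / sg) * pnorm(-mu / sg)) -
    sg * (dnorm((100 - mu) / sg) - ((100 - mu) / sg) * pnorm(-(100 - mu) / sg))
  expected <- mu + clamp_shift
  se <- sg / sqrt(nrow(base))
  expect_lt(abs(mean(base$fine_motor) - expected), 2 * se + 0.2)

  # monotone point-biserial correlation between eta and the binary outcome
  pb <- sapply(c(0, 0.5, 1), function(es) {
    sp <- cohort_spec(n_baseline = 500, effect_size = es, seed = 29)
    chx <- generate_cohort(sp, conn_waves = integer(0))
    lab <- outcome_labels(chx$table)
    eta <- chx$table$eta[chx$table$wave == 1]
    cor(eta, lab$motor_class, use = "complete.obs")
  })
  expect_true(all(diff(pb) > 0))
})

test_that("connectivity matrices are symmetric, unit-diagonal and age-calibrated", {
  spec <- cohort_spec(seed = 31)
  st <- list(age_months = 50, scan_state = "sleep", eta = 0.4, months = 0)
  m <- generate_connectivity(st, spec)
  expect_equal(max(abs(m - t(m))), 0)
  expect_true(all(diag(m) == 1))
  expect_true(all(m >= -1 & m <= 1))

  # sensorimotor-subcortical block mean over many draws matches the
  # configured younger-child level (0.12 at the 3-4y group center)
  set.seed(41)
  part <- network_partition(spec$n_regions, spec$n_networks)
  draws <- replicate(300, {
    eta <- rnorm(1)
    mm <- generate_connectivity(list(age_months = 48, scan_state = "sleep",
                                     eta = eta, months = 0), spec, part)
    block_means(mm, part)["SomMot", "Limbic"]
  })
  expect_lt(abs(mean(draws) - 0.12), 3 * sd(draws) / sqrt(length(draws)) + 0.005)

  # awake scan state raises visual-block connectivity (state confound)
  sleep <- generate_connectivity(list(age_months = 59, scan_state = "sleep",
                                      eta = 0, months = 0), spec, part)
  awake <- generate_connectivity(list(age_months = 61, scan_state = "awake",
                                      eta = 0, months = 0), spec, part)
  d <- block_means(awake, part)["Vis", "Vis"] - block_means(sleep, part)["Vis", "Vis"]
  expect_gt(d, 0.01)
})

test_that("sampled time series converge to the target correlation", {
  target <- unvectorize_upper(c(0.5, 0.2, -0.3), diag_value = 1)
  set.seed(9)
  ts <- generate_timeseries(target, n_timepoints = 50000)
  expect_lt(max(abs(fc_matrix(ts) - target)), 0.05)

  # identity target: off-diagonal sample correlations near zero
  set.seed(10)
  ts0 <- generate_timeseries(diag(4), n_timepoints = 20000)
  f0 <- fc_matrix(ts0)
  expect_lt(max(abs(f0[upper.tri(f0)])), 0.05)

  # determinism under a fixed seed
  set.seed(11); a <- generate_timeseries(target, 100)
  set.seed(11); b <- generate_timeseries(target, 100)
  expect_identical(a, b)

  # indefinite target is repaired with a warning
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_warning(generate_timeseries(bad, 10), "positive definite")
})
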