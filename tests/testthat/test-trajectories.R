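test_that("growth slopes reduce to closed forms", {
  tab <- data.frame(
    participant = rep(1:3, each = 3), wave = rep(1:3, 3),
    months = rep(c(0, 6, 12), 3), age_group = 4,
    total_motor = c(40, 45, 50, 20, 20, 20, 38, NA, 52),
    digit_span = c(2, 3, 4, 3, 3, 3, 4, 5, 5),
    visuospatial_span = c(3, 3, 4, 2, 3, 3, 4, 4, 5),
    gonogo_accuracy = c(60, 65, 70, 70, 72, 71, 80, 82, 85),
    ant_score = 60, dccs_switch_cost = 300, fist_score = 10,
    nepsy_attention = 10, nepsy_statue = 10, nepsy_memory_designs = 10,
    gonogo_rt_ms = 600, ant_rt_ms = 800, dccs_accuracy = 80
  )
  gr <- growth_slopes(tab)
  expect_equal(gr$motor_slope[1], 5 / 6, tolerance = 1e-12)   # 0.8333/month
  expect_equal(gr$motor_slope[2], 0)
  expect_equal(gr$motor_slope[3], 14 / 12, tolerance = 1e-12) # two-point slope
  expect_equal(gr$n_waves_motor, c(3L, 3L, 2L))
})

test_that("growth classification follows the dual 1-SD conjunction rule", {
  rec <- data.frame(participant = 1:40,
                    motor_slope = c(rnorm(39, 0, 0.01), 0),
                    ef_slope = c(rnorm(39, 0, 0.01), 0))
  # one participant far above on motor only stays typical
  rec$motor_slope[1] <- 10
  rec$ef_slope[1] <- mean(rec$ef_slope[-1])
  class(rec) <- c("growth_records", "data.frame")
  out <- classify_growth(rec)
  expect_equal(as.character(out$growth_class[1]), "typical")

  # degenerate zero-SD slopes: all typical with a warning
  rec0 <- data.frame(participant = 1:5, motor_slope = 1, ef_slope = 1)
  class(rec0) <- c("growth_records", "data.frame")
  expect_warning(out0 <- classify_growth(rec0), "degenerate")
  expect_true(all(out0$growth_class == "typical"))
})

test_that("accelerated fractions match the bivariate-normal orthant oracle", {
  n <- 60000
  for (rho in c(0, 0.5, 1)) {
    set.seed(100 + round(10 * rho))
    z1 <- rnorm(n)
    z2 <- if (rho >= 1) z1 else rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    rec <- data.frame(participant = seq_len(n), motor_slope = z1, ef_slope = z2)
    class(rec) <- c("growth_records", "data.frame")
    out <- classify_growth(rec)
    frac <- mean(out$growth_class == "accelerated")
    target <- oracle_orthant_upper(rho)
    tol <- 3 * sqrt(target * (1 - target) / n) + 0.002
    expect_lt(abs(frac - target), tol, label = paste("rho =", rho))
  }
  # rho = 1 degenerates to the univariate tail, about 15.87%
  expect_equal(oracle_orthant_upper(1), 1 - pnorm(1), tolerance = 1e-12)
})

test_that("partial correlation equals the residualization oracle", {
  set.seed(31)
  n <- 200
  cov1 <- rnorm(n); cov2 <- factor(sample(c("a", "b", "c"), n, TRUE))
  x <- 0.5 * cov1 + rnorm(n)
  y <- -0.3 * cov1 + rnorm(n)
  res <- partial_correlation(x, y, data.frame(cov1, cov2))
  expect_equal(res$estimate, oracle_partial_cor(x, y, data.frame(cov1, cov2)),
               tolerance = 1e-10)
  expect_lt(res$conf_int[1], res$estimate)
  expect_gt(res$conf_int[2], res$estimate)

  # covariates orthogonal to both variables: partial equals plain Pearson
  x2 <- c(scale(rnorm(n))); y2 <- c(scale(rnorm(n)))
  covo <- resid(lm(rnorm(n) ~ x2 + y2))
  r_part <- partial_correlation(x2, y2, data.frame(covo))
  expect_equal(r_part$estimate, cor(resid(lm(x2 ~ covo)), resid(lm(y2 ~ covo))),
               tolerance = 1e-12)

  # a confound shared by x and y is fully removed
  set.seed(32)
  z <- rnorm(5000)
  xs <- z + rnorm(5000); ys <- z + rnorm(5000)
  raw_r <- cor(xs, ys)
  pc <- partial_correlation(xs, ys, data.frame(z = z))
  expect_gt(raw_r, 0.4)
  expect_lt(abs(pc$estimate), 0.05)
  expect_equal(pc$estimate, oracle_partial_cor(xs, ys, data.frame(z = z)),
               tolerance = 1e-10)

  # y exactly equal to a covariate: zero residual is an error
  expect_error(partial_correlation(rnorm(50), z[1:50],
                                   data.frame(z = z[1:50])),
               "zero-variance residual")
  # collinear covariates warn but still fit
  expect_warning(partial_correlation(xs[1:100], ys[1:100],
                                     data.frame(a = z[1:100], b = 2 * z[1:100])),
                 "collinear")
})

test_that("natural spline basis satisfies the boundary conditions", {
  ages <- seq(36, 84, by = 0.5)
  basis <- splines::ns(ages, knots = c(48, 60), Boundary.knots = range(ages))
  # numerical second derivative vanishes at the boundary knots (natural
  # condition) but not at an interior point of the same column
  h <- 0.01
  for (j in seq_len(ncol(basis))) {
    f <- splines::ns(c(36, 36 + h, 36 + 2 * h, 84 - 2 * h, 84 - h, 84,
                       54, 54 + h, 54 + 2 * h),
                     knots = c(48, 60), Boundary.knots = range(ages))[, j]
    d2_lo <- (f[3] - 2 * f[2] + f[1]) / h^2
    d2_hi <- (f[6] - 2 * f[5] + f[4]) / h^2
    expect_lt(abs(d2_lo), 1e-4)
    expect_lt(abs(d2_hi), 1e-4)
  }
})

sim_lmm_data <- function(n = 120, effect = c("linear", "inverted_u"),
                         amplitude = 0.1, seed = 1) {
  effect <- match.arg(effect)
  set.seed(seed)
  age0 <- runif(n, 36, 72)
  b0 <- rnorm(n, 0, 0.05)
  rows <- lapply(1:n, function(i) {
    ages <- age0[i] + c(0, 6, 12)
    mu <- if (effect == "linear") 0.002 * ages
    else amplitude * (1 - ((ages - 57) / 21)^2)
    data.frame(participant = i, age_months = ages,
               y = 0.15 + b0[i] + mu + rnorm(3, 0, 0.03))
  })
  do.call(rbind, rows)
}

test_that("the dAIC>10 rule selects the right age model", {
  # linear truth: spline is rarely preferred
  prefs <- sapply(1:8, function(s) {
    fit <- fit_spline_lmm(sim_lmm_data(effect = "linear", seed = s))
    fit$preferred
  })
  expect_gte(mean(prefs == "linear"), 0.85)

  # strong inverted-U truth: spline wins decisively
  fit_u <- fit_spline_lmm(sim_lmm_data(effect = "inverted_u", amplitude = 0.15,
                                       seed = 99))
  expect_equal(fit_u$preferred, "spline")
  expect_gt(fit_u$delta_aic, 10)

  expect_error(fit_spline_lmm(sim_lmm_data(seed = 1), knots = c(10, 200)),
               "inside")
})

test_that("spline mixed model recovers simulated fixed effects", {
  dat <- sim_lmm_data(n = 400, effect = "linear", seed = 7)
  fit <- fit_spline_lmm(dat)
  lin <- fit$linear$fit
  est <- lme4::fixef(lin)["age_months"]
  se <- sqrt(diag(as.matrix(vcov(lin))))["age_months"]
  expect_lt(abs(est - 0.002), 2 * se)
  expect_gte(fit$linear$ranef_var, 0)
  # AIC bookkeeping: -2 logLik + 2 * parameter count
  expect_equal(fit$linear$aic,
               -2 * fit$linear$loglik + 2 * fit$linear$df, tolerance = 1e-8)
})

test_that("network change contrasts recover configured deltas and symmetries", {
  spec <- cohort_spec(n_baseline = 40, n_regions = 35, retention = c(1, 1),
                      missing_rates = c(0, 0), seed = 41)
  ch <- generate_cohort(spec)
  # wave3 identical to wave1: all deltas and t statistics vanish
  ch_same <- ch
  for (id in seq_along(ch_same$connectivity)) {
    if (length(ch_same$connectivity[[id]]) >= 3)
      ch_same$connectivity[[id]][[3]] <- ch_same$connectivity[[id]][[1]]
  }
  cc <- network_change_contrasts(ch_same)
  expect_true(all(abs(cc$delta_mean) < 1e-12))
  expect_true(all(cc$t == 0))

  # block means are invariant to permuting regions within blocks
  part <- ch$partition
  m <- ch$connectivity[[1]][[1]]
  perm <- unlist(lapply(levels(part), function(l) {
    idx <- which(part == l); sample(idx)
  }))
  expect_equal(block_means(m[perm, perm], part), block_means(m, part),
               tolerance = 1e-12)
})
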