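test_that("holdout split reproduces the 70/15/15 sizes and partitions", {
  s <- holdout_split(256, seed = 1)
  expect_equal(lengths(s), c(train = 179L, val = 38L, test = 39L))
  expect_setequal(c(s$train, s$val, s$test), 1:256)

  s2 <- holdout_split(20, seed = 2)
  expect_equal(lengths(s2), c(train = 14L, val = 3L, test = 3L))

  # stratified: set proportions track the strata mix
  strata <- rep(c("a", "b"), each = 128)
  s3 <- holdout_split(256, strata = strata, seed = 3)
  expect_lte(abs(sum(strata[s3$train] == "a") - 179 / 2), 1)
  expect_error(holdout_split(5), "small")
  expect_error(holdout_split(100, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("stratified k-fold balances strata and fold sizes deterministically", {
  strata <- rep(c(0, 1), each = 50)
  plan <- stratified_kfold(strata, k = 5, seed = 4)
  for (f in 1:5) {
    expect_equal(sum(unclass(plan) == f & strata == 0), 10)
    expect_equal(sum(unclass(plan) == f & strata == 1), 10)
  }
  expect_identical(unclass(stratified_kfold(strata, 5, seed = 9)),
                   unclass(stratified_kfold(strata, 5, seed = 9)))

  plan2 <- stratified_kfold(rep(1, 52), k = 5, seed = 5)
  expect_equal(sort(as.integer(table(unclass(plan2))), decreasing = TRUE),
               c(11L, 11L, 10L, 10L, 10L))
  expect_error(stratified_kfold(rep(1, 3), k = 5), "exceeds")

  # tiny strata are merged rather than split unstratifiably
  plan3 <- stratified_kfold(c(rep("a", 40), rep("b", 2)), k = 5, seed = 6)
  expect_equal(length(unclass(plan3)), 42L)
})

test_that("fold preprocessing never lets test data into train-fitted parameters", {
  set.seed(7)
  n_tr <- 60; n_te <- 20
  X_tr <- matrix(rnorm(n_tr * 5), n_tr, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
  X_tr[sample(n_tr, 10), 2] <- NA
  X_te <- matrix(rnorm(n_te * 5), n_te, 5,
                 dimnames = list(NULL, paste0("v", 1:5)))
  X_te[c(3, 7), 2] <- NA
  aux_tr <- data.frame(age_months = rnorm(n_tr, 55, 10), sex = sample(c("M", "F"), n_tr, TRUE),
                       mean_fd = runif(n_tr, 0.1, 0.4))
  aux_te <- data.frame(age_months = rnorm(n_te, 55, 10), sex = sample(c("M", "F"), n_te, TRUE),
                       mean_fd = runif(n_te, 0.1, 0.4))
  a <- fold_preprocess(X_tr, X_te, aux_tr, aux_te, m = 3, seed = 8)
  # perturb the test fold by a constant: all train-fitted parameters must be
  # bit-identical, and train completions unchanged
  b <- fold_preprocess(X_tr, X_te + 100, aux_tr, aux_te, m = 3, seed = 8)
  expect_identical(a$params, b$params)
  expect_identical(a$train_sets, b$train_sets)

  # no missing data: the m completed sets are identical and equal the scaled input
  X_c <- X_tr; X_c[is.na(X_c)] <- 0
  cc <- fold_preprocess(X_c, X_te, aux_tr, aux_te, m = 3, seed = 9)
  expect_identical(cc$train_sets[[1]], cc$train_sets[[3]])
  manual <- scale(X_c)
  expect_equal(cc$train_sets[[1]], manual, ignore_attr = TRUE, tolerance = 1e-12)

  # label columns must never be imputable
  X_bad <- X_tr; colnames(X_bad)[5] <- "motor_class"
  expect_error(fold_preprocess(X_bad, X_te, aux_tr, aux_te, m = 2), "label")

  # a column entirely missing in training is dropped with a warning
  X_all_na <- X_tr; X_all_na[, 4] <- NA
  expect_warning(d <- fold_preprocess(X_all_na, X_te, aux_tr, aux_te, m = 2,
                                      seed = 10),
                 "dropping")
  expect_false("v4" %in% colnames(d$train_sets[[1]]))
})

test_that("imputation recovers a linear conditional mean", {
  set.seed(11)
  n <- 600
  x <- rnorm(n)
  y <- 2 * x + rnorm(n, sd = 0.3)
  X <- cbind(x = x, y = y)
  X_te <- X[1:2, , drop = FALSE]
  miss_row <- 5
  X[miss_row, "y"] <- NA
  aux <- data.frame(age_months = rnorm(n, 55, 5), mean_fd = runif(n))
  pr <- fold_preprocess(X, X_te, aux, aux[1:2, ], m = 20, seed = 12)
  # pool the m imputed values on the original scale
  imp <- sapply(seq_len(20), function(c) {
    sc <- pr$params[[c]]
    pr$train_sets[[c]][miss_row, "y"] * sc$scale_sd["y"] + sc$scale_mean["y"]
  })
  pooled <- mean(imp)
  post_sd <- sd(imp) + 0.3      # between-imputation spread plus residual SD
  expect_lt(abs(pooled - 2 * x[miss_row]), 3 * post_sd)
})

test_that("classification metrics match brute-force oracles", {
  expect_equal(evaluate(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)),
               c(accuracy = 1, auc = 1, f1 = 1))
  ev <- evaluate(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(unname(ev["accuracy"]), 0.5)
  expect_equal(unname(ev["auc"]), 0.5)
  expect_equal(unname(evaluate(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.9))["auc"]), 0.75)
  expect_error(evaluate(c(1, 1, 1), c(0.2, 0.3, 0.4)), "single-class")

  # every 4-sample truth/probability combination agrees with pair enumeration
  set.seed(13)
  probs <- matrix(round(runif(40), 2), 10, 4)
  probs[1, ] <- c(0.5, 0.5, 0.2, 0.8)          # include ties
  for (labs in list(c(0,0,0,1), c(0,0,1,1), c(0,1,1,1), c(1,0,1,0))) {
    for (r in seq_len(nrow(probs))) {
      expect_equal(unname(evaluate(labs, probs[r, ])["auc"]),
                   oracle_auc(labs, probs[r, ]), tolerance = 1e-12)
    }
  }

  # metrics invariant to sample ordering
  set.seed(14)
  y <- rep(0:1, 10); p <- runif(20)
  perm <- sample(20)
  expect_equal(evaluate(y, p), evaluate(y[perm], p[perm]))
})

test_that("cross-validation produces a complete, seeded report", {
  sep <- separable_bundle(n = 90, shift = 1, seed = 15)
  aux <- data.frame(age_months = sample(36:83, 90, TRUE),
                    sex = sample(c("M", "F"), 90, TRUE),
                    ses = sample(c("low", "middle", "high"), 90, TRUE),
                    mean_fd = runif(90, 0.1, 0.4),
                    scan_state = sample(c("sleep", "awake"), 90, TRUE))
  aux$age_group <- aux$age_months %/% 12
  plan <- stratified_kfold(make_strata(aux$age_group, sep$y), k = 5, seed = 16)
  cfg <- tiny_model_config("behavioral_only", seed = 17)
  rep1 <- cross_validate(sep$bundle, sep$y, aux, cfg, plan, m = 2, m_train = 1,
                         seed = 18)
  expect_equal(nrow(rep1$folds), 15L)      # 5 folds x 3 strata rows
  expect_setequal(unique(rep1$folds$stratum), c("overall", "3-4y", "5-6y"))
  expect_true(all(rep1$folds$accuracy >= 0 & rep1$folds$accuracy <= 1,
                  na.rm = TRUE))
  rep2 <- cross_validate(sep$bundle, sep$y, aux, cfg, plan, m = 2, m_train = 1,
                         seed = 18)
  expect_identical(rep1$folds, rep2$folds)
})
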