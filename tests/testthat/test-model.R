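test_that("configuration and bundle constructors validate their contracts", {
  expect_error(model_config(conv_filters = 0), "positive")
  expect_error(model_config(max_epochs = 5, early_stop_patience = 10), "patience")
  b <- separable_bundle(n = 20)
  expect_s3_class(b$bundle, "feature_bundle")
  expect_error(feature_bundle(matrix(0, 3, 5), matrix(0, 3, 11),
                              matrix(0, 3, 16), matrix(0, 3, 12), 1:3),
               "12")
})

test_that("the network separates a high-signal bundle and is deterministic", {
  sep <- separable_bundle(n = 200, shift = 1, seed = 31)
  tr <- 1:160; va <- 161:200
  cfg <- tiny_model_config(seed = 32)
  fit <- train_model(bundle_rows(sep$bundle, tr), sep$y[tr],
                     bundle_rows(sep$bundle, va), sep$y[va], cfg)
  p_tr <- predict_proba(fit, bundle_rows(sep$bundle, tr))
  expect_gt(mean((p_tr > 0.5) == sep$y[tr]), 0.95)

  fit2 <- train_model(bundle_rows(sep$bundle, tr), sep$y[tr],
                      bundle_rows(sep$bundle, va), sep$y[va], cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(predict_proba(fit, bundle_rows(sep$bundle, va)),
                   predict_proba(fit2, bundle_rows(sep$bundle, va)))

  # probabilities: valid range, identical for duplicated rows
  p <- predict_proba(fit, bundle_rows(sep$bundle, c(1, 1, 5)))
  expect_true(all(p > 0 & p < 1))
  expect_identical(p[1], p[2])
})

test_that("label-permuted training yields chance-level holdout AUC", {
  aucs <- sapply(1:10, function(s) {
    sep <- separable_bundle(n = 120, shift = 1, seed = 100 + s)
    set.seed(200 + s)
    y_perm <- sample(sep$y)
    tr <- 1:80; va <- 81:100; te <- 101:120
    cfg <- tiny_model_config("behavioral_only", seed = 300 + s)
    fit <- train_model(bundle_rows(sep$bundle, tr), y_perm[tr],
                       bundle_rows(sep$bundle, va), y_perm[va], cfg)
    evaluate(y_perm[te], predict_proba(fit, bundle_rows(sep$bundle, te)))["auc"]
  })
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})

test_that("early stopping halts patience epochs after the best one", {
  sep <- separable_bundle(n = 80, shift = 0.3, seed = 41)
  tr <- 1:60; va <- 61:80
  cfg <- tiny_model_config(seed = 42, max_epochs = 50L,
                           early_stop_patience = 5L)
  fit <- train_model(bundle_rows(sep$bundle, tr), sep$y[tr],
                     bundle_rows(sep$bundle, va), sep$y[va], cfg)
  if (nrow(fit$history) < cfg$max_epochs) {
    expect_equal(nrow(fit$history), fit$best_epoch + cfg$early_stop_patience)
  }
  # best epoch has the minimum validation loss seen
  expect_equal(fit$best_epoch, which.min(fit$history$val_loss))
})

test_that("ablation variants consume only their own channels", {
  sep <- separable_bundle(n = 80, seed = 51)
  tr <- 1:60; va <- 61:80
  for (v in c("connectivity_only", "behavioral_only")) {
    cfg <- tiny_model_config(v, seed = 52)
    fit <- train_model(bundle_rows(sep$bundle, tr), sep$y[tr],
                       bundle_rows(sep$bundle, va), sep$y[va], cfg)
    zeroed <- sep$bundle
    unused <- setdiff(c("conn", "graph", "motor", "cog"), variant_channels(v))
    for (ch in unused) zeroed[[ch]][] <- 0
    expect_identical(predict_proba(fit, bundle_rows(sep$bundle, va)),
                     predict_proba(fit, bundle_rows(zeroed, va)),
                     label = v)
  }
})

test_that("degenerate labels and shape mismatches are hard errors", {
  sep <- separable_bundle(n = 40, seed = 61)
  cfg <- tiny_model_config(seed = 62)
  expect_error(train_model(bundle_rows(sep$bundle, 1:20), rep(1, 20),
                           bundle_rows(sep$bundle, 21:40), sep$y[21:40], cfg),
               "degenerate")
  fit <- train_model(bundle_rows(sep$bundle, 1:30), sep$y[1:30],
                     bundle_rows(sep$bundle, 31:40), sep$y[31:40], cfg)
  bad <- feature_bundle(sep$bundle$conn[, 1:100], sep$bundle$graph,
                        sep$bundle$motor, sep$bundle$cog,
                        sep$bundle$participant)
  expect_error(predict_proba(fit, bad), "mismatch")
})

test_that("label flip trains the complementary classifier on symmetric data", {
  sep <- separable_bundle(n = 160, shift = 1.2, seed = 71)
  tr <- 1:120; va <- 121:160
  cfg <- tiny_model_config(seed = 72)
  fit1 <- train_model(bundle_rows(sep$bundle, tr), sep$y[tr],
                      bundle_rows(sep$bundle, va), sep$y[va], cfg)
  fit2 <- train_model(bundle_rows(sep$bundle, tr), 1 - sep$y[tr],
                      bundle_rows(sep$bundle, va), 1 - sep$y[va], cfg)
  p1 <- predict_proba(fit1, bundle_rows(sep$bundle, va))
  p2 <- predict_proba(fit2, bundle_rows(sep$bundle, va))
  # both runs solve the same separable problem with labels exchanged, so
  # probabilities should be close to complementary on a well-learned problem
  expect_lt(mean(abs(p1 + p2 - 1)), 0.2)
  expect_gt(cor(p1, 1 - p2), 0.8)
})
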