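apportion <- function(weights, total, cap = NULL) {
  # largest-remainder apportionment of `total` units across strata
  if (is.null(cap)) cap <- rep(Inf, length(weights))
  raw <- weights / sum(weights) * total
  base <- pmin(floor(raw), cap)
  left <- total - sum(base)
  frac <- raw - floor(raw)
  ord <- order(-frac, seq_along(frac))
  i <- 1L
  while (left > 0L && i <= 10L * length(weights)) {
    s <- ord[(i - 1L) %% length(ord) + 1L]
    if (base[s] < cap[s]) { base[s] <- base[s] + 1L; left <- left - 1L }
    i <- i + 1L
  }
  if (left > 0L) stop("apportionment infeasible under caps")
  as.integer(base)
}

#' Stratified train/validation/test holdout split
#'
#' Sizes are `floor(f1*n)`, `floor(f2*n)` and the remainder; assignment is
#' stratified so each set preserves the strata mix as closely as integer
#' counts allow. The three sets are disjoint and exhaustive.
#'
#' @param n Number of participants.
#' @param fractions Length-3 fractions summing to 1 (default 0.70/0.15/0.15).
#' @param strata Optional factor of length `n`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
holdout_split <- function(n, fractions = c(0.70, 0.15, 0.15), strata = NULL,
                          seed = 1L) {
  if (n < 10L) stop("n too small for a three-way split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(strata)) strata <- factor(rep(1L, n))
  strata <- droplevels(as.factor(strata))
  set.seed(seed)
  n_tr <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  sizes <- as.integer(table(strata))
  tr_s <- apportion(sizes, n_tr, cap = sizes)
  val_s <- apportion(sizes, n_val, cap = sizes - tr_s)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (s in seq_along(levels(strata))) {
    members <- sample(which(strata == levels(strata)[s]))
    train <- c(train, members[seq_len(tr_s[s])])
    val <- c(val, members[tr_s[s] + seq_len(val_s[s])])
    test <- c(test, members[-seq_len(tr_s[s] + val_s[s])])
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}

#' Stratified k-fold plan
#'
#' Within each stratum, members are shuffled and dealt round-robin over the
#' folds ordered by current fill, so per-fold stratum counts differ by at
#' most 1 and overall fold sizes are balanced. Strata with fewer than `k`
#' members are merged into a pooled remainder stratum (documented fallback).
#'
#' @param strata Factor (or interaction) of length n.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: integer fold assignment per index,
#'   with `k`, `strata` and `seed` attributes.
#' @export
stratified_kfold <- function(strata, k = 5L, seed = 1L) {
  n <- length(strata)
  if (k > n) stop("k exceeds the number of participants")
  strata <- droplevels(as.factor(strata))
  small <- names(which(table(strata) < k))
  if (length(small) > 0) {
    lv <- as.character(strata)
    lv[lv %in% small] <- ".pooled"
    strata <- factor(lv)
  }
  set.seed(seed)
  fold <- integer(n)
  fill <- integer(k)
  for (s in levels(strata)) {
    members <- sample(which(strata == s))
    ord <- order(fill, seq_len(k))
    for (i in seq_along(members)) {
      f <- ord[(i - 1L) %% k + 1L]
      fold[members[i]] <- f
      fill[f] <- fill[f] + 1L
    }
  }
  structure(fold, k = k, strata = strata, seed = seed, class = "fold_plan")
}

numeric_design <- function(aux) {
  # expand an auxiliary data.frame into a complete numeric design matrix
  cols <- lapply(names(aux), function(nm) {
    v <- aux[[nm]]
    if (is.numeric(v)) {
      out <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- as.factor(v)
      if (nlevels(f) < 2L) return(NULL)
      out <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(out) <- paste0(nm, levels(f)[-1])
    }
    out
  })
  do.call(cbind, cols[!vapply(cols, is.null, TRUE)])
}

label_like_cols <- c("motor_class", "ef_class", "change_motor", "change_ef")

bayes_lm_draw <- function(X, y) {
  # posterior draw from the standard noninformative normal linear model
  qrX <- qr(X)
  r <- qrX$rank
  coef <- qr.coef(qrX, y)
  coef[is.na(coef)] <- 0
  res <- y - X %*% coef
  df <- max(length(y) - r, 1L)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrX)[seq_len(r), seq_len(r), drop = FALSE]
  piv <- if (r < ncol(X)) qrX$pivot[seq_len(r)] else seq_len(ncol(X))
  z <- stats::rnorm(r)
  beta <- coef
  pert <- backsolve(R, z) * sqrt(sigma2)
  beta[piv] <- beta[piv] + pert
  list(beta = as.numeric(beta), sigma = sqrt(sigma2))
}

#' Fold-internal multiple imputation and scaling
#'
#' Chained stochastic regression imputation fit strictly on the training
#' fold: each incomplete feature column is modeled on the complete auxiliary
#' design (age, sex, SES, mean FD, scan state) plus the other columns in
#' `predictor_cols`, with Bayesian posterior draws of the coefficients and
#' residual SD per chain (so the `m` completed datasets differ). Test-fold
#' missing values are filled using the train-fitted coefficient draws only,
#' and z-score scaling uses train means/SDs only - no test statistic ever
#' enters a train-fitted parameter.
#'
#' Label columns are never imputable: passing a feature matrix containing a
#' label column is a hard error. A column entirely missing in the training
#' fold is dropped (from train and test) with a warning.
#'
#' @param train_x,test_x Numeric feature matrices with identical columns;
#'   missing values only in imputable (non-label) columns.
#' @param aux_train,aux_test Complete auxiliary data.frames (one row per
#'   participant).
#' @param m Number of imputations (default 20).
#' @param maxit Chained-update sweeps per chain (default 5).
#' @param predictor_cols Columns (names) usable as predictors in imputation
#'   models; defaults to all columns. Restrict to the low-dimensional
#'   channels when `train_x` contains the full connectivity vector.
#' @param seed Integer seed.
#' @return List: `train_sets` and `test_sets` (m scaled matrices each),
#'   `params` (per chain: imputation draws and scaling means/SDs),
#'   `dropped` column names.
#' @export
fold_preprocess <- function(train_x, test_x, aux_train, aux_test, m = 20L,
                            maxit = 5L, predictor_cols = NULL, seed = 1L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (any(colnames(train_x) %in% label_like_cols))
    stop("attempt to impute a label column")
  all_miss <- colnames(train_x)[colSums(!is.na(train_x)) == 0L]
  if (length(all_miss) > 0) {
    warning("dropping column(s) entirely missing in training fold: ",
            paste(all_miss, collapse = ", "))
    keep <- setdiff(colnames(train_x), all_miss)
    train_x <- train_x[, keep, drop = FALSE]
    test_x <- test_x[, keep, drop = FALSE]
  }
  if (is.null(predictor_cols)) predictor_cols <- colnames(train_x)
  predictor_cols <- setdiff(intersect(predictor_cols, colnames(train_x)),
                            label_like_cols)
  D_tr <- numeric_design(aux_train)
  D_te <- numeric_design(aux_test)
  incomplete <- colnames(train_x)[colSums(is.na(train_x)) > 0L]
  col_means <- colMeans(train_x, na.rm = TRUE)

  set.seed(seed)
  params <- vector("list", m)
  train_sets <- vector("list", m)
  for (c in seq_len(m)) {
    filled <- train_x
    for (j in incomplete) {           # mean init
      filled[is.na(filled[, j]), j] <- col_means[j]
    }
    draws <- list()
    if (length(incomplete) > 0) {
      for (it in seq_len(maxit)) {
        for (j in incomplete) {
          obs <- !is.na(train_x[, j])
          preds <- setdiff(predictor_cols, j)
          X <- cbind(1, D_tr, filled[, preds, drop = FALSE])
          dr <- bayes_lm_draw(X[obs, , drop = FALSE], train_x[obs, j])
          mis <- which(!obs)
          if (length(mis) > 0)
            filled[mis, j] <- X[mis, , drop = FALSE] %*% dr$beta +
              stats::rnorm(length(mis), 0, dr$sigma)
          draws[[j]] <- dr
        }
      }
    }
    mu <- colMeans(filled)
    sg <- apply(filled, 2, stats::sd)
    sg[!is.finite(sg) | sg <= 0] <- 1
    params[[c]] <- list(draws = draws, scale_mean = mu, scale_sd = sg,
                        col_means = col_means, predictor_cols = predictor_cols)
    train_sets[[c]] <- sweep(sweep(filled, 2, mu), 2, sg, "/")
  }

  # test phase: only train-fitted parameters are used
  set.seed(seed + 1L)
  test_sets <- vector("list", m)
  for (c in seq_len(m)) {
    pp <- params[[c]]
    filled <- test_x
    for (j in colnames(filled)) {
      filled[is.na(filled[, j]), j] <- pp$col_means[j]
    }
    for (j in names(pp$draws)) {
      mis <- which(is.na(test_x[, j]))
      if (length(mis) == 0) next
      preds <- setdiff(pp$predictor_cols, j)
      X <- cbind(1, D_te, filled[, preds, drop = FALSE])
      dr <- pp$draws[[j]]
      filled[mis, j] <- X[mis, , drop = FALSE] %*% dr$beta +
        stats::rnorm(length(mis), 0, dr$sigma)
    }
    test_sets[[c]] <- sweep(sweep(filled, 2, pp$scale_mean), 2, pp$scale_sd, "/")
  }
  list(train_sets = train_sets, test_sets = test_sets, params = params,
       dropped = all_miss)
}

#' Classification metrics
#'
#' Accuracy at the 0.5 threshold, AUC-ROC via the rank statistic (ties
#' counted one half), and the F1 score for class 1.
#'
#' @param y_true 0/1 labels.
#' @param prob Predicted class-1 probabilities.
#' @return Named numeric vector `c(accuracy=, auc=, f1=)`.
#' @export
evaluate <- function(y_true, prob) {
  if (length(unique(y_true)) < 2L) stop("AUC undefined: single-class truth")
  pred <- as.integer(prob > 0.5)
  acc <- mean(pred == y_true)
  r <- rank(prob)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = acc, auc = auc, f1 = f1)
}

split_channels <- function(X, dims) {
  offs <- cumsum(c(0, dims))
  lapply(seq_along(dims), function(i) X[, (offs[i] + 1):offs[i + 1], drop = FALSE])
}

#' Stratified cross-validation of the fusion classifier
#'
#' For each fold: fold-internal multiple imputation and scaling
#' ([fold_preprocess()]), an inner stratified early-stopping split (15% of
#' the training fold), training on `m_train` of the `m` completed datasets,
#' pooling of the predicted test-fold probabilities by averaging, and
#' metric evaluation overall and within age strata (3-4 vs 5-6 years).
#'
#' @param bundle A [feature_bundle()] for all labeled participants.
#' @param labels 0/1 outcome labels aligned with the bundle.
#' @param aux Auxiliary data.frame (must contain `age_group`; used both for
#'   imputation models and age stratification).
#' @param cfg A [model_config()].
#' @param plan A [stratified_kfold()] plan over the same participants.
#' @param m Imputations per fold (default 20).
#' @param m_train Completed datasets actually used for network training
#'   (default 5; probability pooling is across these).
#' @param inner_val_frac Early-stopping split fraction (default 0.15).
#' @param seed Integer seed for fold-level preprocessing/inner splits.
#' @return Object of class `cv_report`: `folds` data.frame (fold, stratum,
#'   accuracy, auc, f1, n) and `summary` (per stratum: mean and SD over
#'   folds).
#' @export
cross_validate <- function(bundle, labels, aux, cfg, plan, m = 20L,
                           m_train = 5L, inner_val_frac = 0.15, seed = 1L) {
  stopifnot(length(labels) == length(bundle$participant))
  m_train <- min(m_train, m)
  k <- attr(plan, "k")
  dims <- c(conn = ncol(bundle$conn), graph = ncol(bundle$graph),
            motor = ncol(bundle$motor), cog = ncol(bundle$cog))
  X <- cbind(bundle$conn, bundle$graph, bundle$motor, bundle$cog)
  colnames(X) <- c(paste0("conn_", seq_len(dims["conn"])),
                   paste0("graph_", seq_len(dims["graph"])),
                   paste0("motor_", seq_len(dims["motor"])),
                   paste0("cog_", seq_len(dims["cog"])))
  predictor_cols <- colnames(X)[-seq_len(dims["conn"])]
  rows <- list()
  for (f in seq_len(k)) {
    te <- which(unclass(plan) == f)
    tr <- which(unclass(plan) != f)
    prep <- fold_preprocess(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                            aux[tr, , drop = FALSE], aux[te, , drop = FALSE],
                            m = m, predictor_cols = predictor_cols,
                            seed = seed + f)
    inner <- stratified_kfold(factor(labels[tr]),
                              k = max(2L, round(1 / inner_val_frac)),
                              seed = seed + 100L + f)
    iv <- which(unclass(inner) == 1L)
    it <- setdiff(seq_along(tr), iv)
    probs <- matrix(0, length(te), m_train)
    for (c in seq_len(m_train)) {
      Xc <- prep$train_sets[[c]]
      chans_tr <- split_channels(Xc, dims)
      b_tr <- feature_bundle(chans_tr[[1]], chans_tr[[2]], chans_tr[[3]],
                             chans_tr[[4]], bundle$participant[tr])
      chans_te <- split_channels(prep$test_sets[[c]], dims)
      b_te <- feature_bundle(chans_te[[1]], chans_te[[2]], chans_te[[3]],
                             chans_te[[4]], bundle$participant[te])
      cfg_c <- cfg
      cfg_c$seed <- cfg$seed + 1000L * f + c
      fit <- train_model(bundle_rows(b_tr, it), labels[tr][it],
                         bundle_rows(b_tr, iv), labels[tr][iv], cfg_c)
      probs[, c] <- predict_proba(fit, b_te)
    }
    pool <- rowMeans(probs)
    add_row <- function(stratum, idx) {
      met <- tryCatch(evaluate(labels[te][idx], pool[idx]),
                      error = function(e) c(accuracy = NA, auc = NA, f1 = NA))
      data.frame(fold = f, stratum = stratum, accuracy = met["accuracy"],
                 auc = met["auc"], f1 = met["f1"], n = length(idx),
                 row.names = NULL)
    }
    young <- which(aux$age_group[te] <= 4)
    old <- which(aux$age_group[te] >= 5)
    rows[[f]] <- rbind(add_row("overall", seq_along(te)),
                       add_row("3-4y", young), add_row("5-6y", old))
  }
  folds <- do.call(rbind, rows)
  agg <- stats::aggregate(folds[, c("accuracy", "auc", "f1")],
                          by = list(stratum = folds$stratum),
                          function(x) c(mean = mean(x, na.rm = TRUE),
                                        sd = stats::sd(x, na.rm = TRUE)))
  out <- list(folds = folds, summary = agg, variant = cfg$variant)
  class(out) <- "cv_report"
  out
}

#' Mean of a cv_report metric over folds
#' @param report A `cv_report`.
#' @param metric One of "accuracy", "auc", "f1".
#' @param stratum Stratum row (default "overall").
#' @return Scalar mean over folds.
#' @export
cv_mean <- function(report, metric = "accuracy", stratum = "overall") {
  v <- report$folds[report$folds$stratum == stratum, metric]
  mean(v, na.rm = TRUE)
}
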