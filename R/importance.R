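#' Grouped permutation feature importance
#'
#' For each feature group, the group's columns are jointly row-permuted in
#' the evaluation set `n_perm` times while all other features are held
#' fixed; importance is the baseline accuracy minus the mean permuted
#' accuracy, in percentage points. Accuracy is the degraded metric by
#' default (AUC available behind `metric`). Seeded and deterministic.
#'
#' @param model Trained `fusion_model`.
#' @param bundle Evaluation [feature_bundle()] (already fold-preprocessed).
#' @param labels 0/1 labels.
#' @param groups Named list of groups, each `list(channel =, cols =)` (see
#'   [default_feature_groups()]).
#' @param n_perm Permutations per group (default 100, minimum 2).
#' @param seed Integer seed.
#' @param metric `"accuracy"` (default) or `"auc"`.
#' @param threshold Substantive-importance flag threshold in percentage
#'   points (default 5).
#' @return data.frame: `group`, `importance` (mean drop, points),
#'   `sd` (over permutations), `substantive` flag.
#' @export
permutation_importance <- function(model, bundle, labels, groups,
                                   n_perm = 100L, seed = 1L,
                                   metric = c("accuracy", "auc"),
                                   threshold = 5) {
  metric <- match.arg(metric)
  if (n_perm < 2L) stop("n_perm must be at least 2")
  score <- function(prob) {
    if (metric == "accuracy") mean((prob > 0.5) == labels)
    else unname(evaluate(labels, prob)["auc"])
  }
  for (g in groups) {
    if (!g$channel %in% c("conn", "graph", "motor", "cog"))
      stop("unknown channel in group definition")
    if (any(g$cols < 1L) || any(g$cols > ncol(bundle[[g$channel]])))
      stop("group references unknown columns")
  }
  base_score <- score(predict_proba(model, bundle))
  n <- length(labels)
  set.seed(seed)
  out <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    drops <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      perm <- sample.int(n)
      b2 <- bundle
      b2[[g$channel]][, g$cols] <- bundle[[g$channel]][perm, g$cols, drop = FALSE]
      drops[r] <- 100 * (base_score - score(predict_proba(model, b2)))
    }
    data.frame(group = nm, importance = mean(drops), sd = stats::sd(drops),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$substantive <- out$importance > threshold
  attr(out, "baseline") <- base_score
  out
}

#' Aggregate per-fold importance into a cross-fold report
#'
#' Averages group importances across folds and computes Kendall's W of the
#' per-fold group rankings (largest importance = rank 1).
#'
#' @param fold_reports List of per-fold data.frames from
#'   [permutation_importance()] (identical group sets).
#' @param threshold Substantive flag threshold in points (default 5).
#' @return List: `table` (group, mean importance across folds, SD across
#'   folds, substantive flag) and `kendalls_w`.
#' @export
aggregate_importance <- function(fold_reports, threshold = 5) {
  groups <- fold_reports[[1]]$group
  imp <- sapply(fold_reports, function(r) r$importance[match(groups, r$group)])
  imp <- matrix(imp, nrow = length(groups))
  tab <- data.frame(group = groups,
                    importance = rowMeans(imp),
                    sd = apply(imp, 1, stats::sd))
  tab$substantive <- tab$importance > threshold
  ranks <- t(apply(-imp, 2, rank))        # k folds x g groups
  list(table = tab, kendalls_w = kendalls_w(ranks))
}

#' Kendall's coefficient of concordance W
#'
#' `W = 12 S / (k^2 (g^3 - g) - k * sum(T))` with `S` the sum of squared
#' deviations of the rank sums and the standard tie correction
#' `T = sum(t^3 - t)` per rater over tied groups.
#'
#' @param rankings k x g matrix: each row one rater's ranks (ties allowed as
#'   midranks) of the same g items.
#' @return W in \[0, 1\].
#' @export
kendalls_w <- function(rankings) {
  rankings <- as.matrix(rankings)
  k <- nrow(rankings); g <- ncol(rankings)
  if (g < 2L) stop("need at least 2 items to rank")
  rsum <- colSums(rankings)
  s <- sum((rsum - mean(rsum))^2)
  tie_t <- sum(apply(rankings, 1, function(r) {
    t <- table(r); sum(t^3 - t)
  }))
  denom <- k^2 * (g^3 - g) - k * tie_t
  if (denom <= 0) return(0)
  12 * s / denom
}
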