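#' Evaluation-scale model configuration
#'
#' The configuration the package's own simulation experiments run at: 32
#' convolution filters with non-overlapping stride-7 windows and pool 4 over
#' the 90-region upper-triangle vector, dropout 0.2 and learning rate 0.003
#' (the smaller network trains stably at a higher rate), at most 60 epochs
#' with patience 12. All other settings match [model_config()] defaults. The
#' full-scale architecture (128 filters, stride 1, lr 0.001) remains the
#' default of [model_config()].
#'
#' @param variant Model variant.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
model_config_desk <- function(variant = "multimodal", seed = 1L, ...) {
  model_config(variant = variant, conv_filters = 32L, conv_stride = 7L,
               pool_size = 4L, dropout_rate = 0.2, learning_rate = 0.003,
               max_epochs = 60L, early_stop_patience = 12L,
               seed = seed, ...)
}

#' Cross-validated performance of one synthetic cohort
#'
#' Generates a cohort at the given latent effect size, extracts baseline
#' feature bundles, computes 12-month motor outcome labels, and runs
#' stratified 5-fold cross-validation for each requested model variant at
#' the evaluation-scale configuration. This is the unit of the package's
#' calibration experiments (null AUC, signal recovery), run across seeds.
#'
#' @param seed Master seed for this replicate.
#' @param effect_size Latent-factor effect size (scalar or named pair).
#' @param variants Model variants to evaluate.
#' @param n_baseline Cohort size (default 200).
#' @param n_regions Parcellation size (default 90).
#' @param n_null Null-ensemble size for graph features (default 10).
#' @param outcome `"motor"` (default) or `"ef"`.
#' @param m,m_train Imputations per fold / networks trained per fold.
#' @return data.frame: one row per variant with mean CV accuracy and AUC
#'   (overall stratum).
#' @export
run_cv_experiment <- function(seed, effect_size, variants = "multimodal",
                              n_baseline = 200L, n_regions = 90L,
                              n_null = 10L, outcome = "motor",
                              m = 2L, m_train = 1L) {
  spec <- cohort_spec(n_baseline = n_baseline, n_regions = n_regions,
                      effect_size = effect_size, seed = seed)
  cohort <- generate_cohort(spec, conn_waves = 1L)
  feats <- build_feature_bundles(cohort, n_null = n_null, seed = seed + 1L)
  labels <- outcome_labels(cohort$table)
  lab_col <- paste0(outcome, "_class")
  lab <- labels[[lab_col]][match(feats$participant, labels$participant)]
  keep <- which(!is.na(lab))
  bnd <- bundle_rows(feats$bundle, keep)
  aux <- feats$aux[keep, ]
  y <- lab[keep]
  plan <- stratified_kfold(make_strata(aux$age_group, y), k = 5L,
                           seed = seed + 2L)
  out <- lapply(variants, function(v) {
    cfg <- model_config_desk(v, seed = seed + 3L)
    rep <- cross_validate(bnd, y, aux, cfg, plan, m = m, m_train = m_train,
                          seed = seed + 4L)
    data.frame(seed = seed, variant = v,
               accuracy = cv_mean(rep, "accuracy"),
               auc = cv_mean(rep, "auc"),
               n = length(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
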