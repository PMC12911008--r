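#' Run configuration for the end-to-end pipeline
#'
#' Bundles the cohort spec, model/evaluation parameters and the master seed.
#' Every stochastic stage derives its own seed from the master seed via
#' [derive_seed()], so stages are individually reproducible. The `"desk"`
#' profile uses the evaluation-scale settings the package's own analyses
#' run at (90 regions, reduced null ensembles, one trained network per
#' fold); `"full"` keeps the publication-scale architecture and m_train.
#'
#' @param cohort A [cohort_spec()].
#' @param profile `"desk"` (default) or `"full"`.
#' @param seed Master seed.
#' @param out_dir Artifact directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(n_baseline = 160, seed = 11L),
                       profile = c("desk", "full"), seed = 20260101L,
                       out_dir = "results/pipeline") {
  profile <- match.arg(profile)
  small <- profile == "desk"
  cfg <- list(
    cohort = cohort,
    density = 0.15,
    n_null = if (small) 10L else 50L,
    model = list(conv_filters = if (small) 32L else 128L,
                 conv_stride = if (small) 7L else 1L,
                 max_epochs = if (small) 40L else 100L,
                 early_stop_patience = if (small) 8L else 10L),
    cv = list(k = 5L, m = if (small) 5L else 20L,
              m_train = if (small) 1L else 5L),
    importance = list(n_perm = if (small) 20L else 100L),
    profile = profile, seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(config) {
  strip <- config
  strip$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(strip, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

write_provenance <- function(config, stage, out_dir, extra = list()) {
  prov <- c(list(stage = stage, config_hash = config_hash(config),
                 seed = derive_seed(config$seed, stage),
                 package_version = as.character(utils::packageVersion("devfuse"))),
            extra)
  jsonlite::write_json(prov, file.path(out_dir, paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

check_upstream <- function(config, stage, out_dir) {
  f <- file.path(out_dir, paste0(stage, ".provenance.json"))
  if (!file.exists(f))
    stop(sprintf("missing upstream artifact for stage '%s'; run that stage first",
                 stage))
  prov <- jsonlite::read_json(f)
  if (!identical(prov$config_hash, unname(config_hash(config))))
    stop(sprintf("artifact of stage '%s' was produced under a different config; rerun it",
                 stage))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

model_cfg_from <- function(config, variant, seed) {
  do.call(model_config, c(list(variant = variant, seed = seed), config$model))
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in order (simulate, features, composites,
#' cv, importance, trajectories, report), writing each stage's artifact and
#' a provenance record (config hash, derived seed, package version) under
#' `config$out_dir`. Re-running with an identical config reproduces
#' identical artifacts; a stage whose upstream artifact is missing or was
#' produced under a different config fails with an actionable error.
#'
#' @param config A [run_config()].
#' @param stages Subset of [pipeline_stages()] (default: all).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, stages = pipeline_stages()) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  state <- new.env()

  load_cohort <- function() {
    if (is.null(state$cohort)) {
      check_upstream(config, "simulate", out_dir)
      spec <- config$cohort
      spec$seed <- derive_seed(config$seed, "simulate")
      state$cohort <- generate_cohort(spec)
    }
    state$cohort
  }
  load_features <- function() {
    if (is.null(state$features)) {
      check_upstream(config, "features", out_dir)
      state$features <- build_feature_bundles(
        load_cohort(), density = config$density, n_null = config$n_null,
        seed = derive_seed(config$seed, "features"))
    }
    state$features
  }
  load_labels <- function() {
    if (is.null(state$labels)) {
      check_upstream(config, "composites", out_dir)
      state$labels <- outcome_labels(load_cohort()$table)
    }
    state$labels
  }

  for (stage in pipeline_stages()) {
    if (!stage %in% stages) next
    seed <- derive_seed(config$seed, stage)
    if (stage == "simulate") {
      spec <- config$cohort
      spec$seed <- seed
      state$cohort <- generate_cohort(spec)
      tab <- state$cohort$table
      tab$eta <- NULL                       # generator-internal state
      write_tsv(tab, file.path(out_dir, "phenotypes.tsv"))
      conn_dir <- file.path(out_dir, "connectivity")
      dir.create(conn_dir, showWarnings = FALSE)
      manifest <- list()
      for (id in seq_along(state$cohort$connectivity)) {
        cm <- state$cohort$connectivity[[id]]
        if (is.null(cm)) next
        for (w in seq_along(cm)) {
          if (is.null(cm[[w]])) next
          f <- sprintf("sub%03d_wave%d.txt", id, w)
          write_conn_matrix(cm[[w]], file.path(conn_dir, f))
          manifest[[length(manifest) + 1L]] <-
            data.frame(participant = id, wave = w, file = f)
        }
      }
      write_tsv(do.call(rbind, manifest), file.path(out_dir, "conn_manifest.tsv"))
      write_provenance(config, stage, out_dir,
                       list(n_baseline = config$cohort$n_baseline))
      res$simulate <- state$cohort
    } else if (stage == "features") {
      state$features <- build_feature_bundles(load_cohort(),
                                              density = config$density,
                                              n_null = config$n_null,
                                              seed = seed)
      gf <- data.frame(participant = state$features$participant,
                       state$features$bundle$graph)
      write_tsv(gf, file.path(out_dir, "graph_features.tsv"))
      write_provenance(config, stage, out_dir)
      res$features <- state$features
    } else if (stage == "composites") {
      tab <- load_cohort()$table
      comp <- data.frame(participant = tab$participant, wave = tab$wave,
                         ef_composite = as.numeric(ef_composite_scores(tab)))
      write_tsv(comp, file.path(out_dir, "ef_composites.tsv"))
      state$labels <- outcome_labels(tab)
      write_tsv(state$labels, file.path(out_dir, "outcome_labels.tsv"))
      write_provenance(config, stage, out_dir)
      res$composites <- state$labels
    } else if (stage == "cv") {
      feats <- load_features()
      labels <- load_labels()
      rows <- list()
      state$cv_fits <- list()
      for (outc in c("motor", "ef")) {
        lab_col <- paste0(outc, "_class")
        lab <- labels[[lab_col]][match(feats$participant, labels$participant)]
        keep <- which(!is.na(lab))
        bnd <- bundle_rows(feats$bundle, keep)
        aux <- feats$aux[keep, ]
        y <- lab[keep]
        plan <- stratified_kfold(make_strata(aux$age_group, y),
                                 k = config$cv$k, seed = seed)
        for (variant in c("multimodal", "connectivity_only", "behavioral_only")) {
          cfg <- model_cfg_from(config, variant, seed)
          rep <- cross_validate(bnd, y, aux, cfg, plan, m = config$cv$m,
                                m_train = config$cv$m_train, seed = seed)
          r <- rep$folds
          r$variant <- variant
          r$outcome <- outc
          rows[[length(rows) + 1L]] <- r
          if (variant == "multimodal")
            state$cv_fits[[outc]] <- list(bundle = bnd, labels = y, aux = aux,
                                          plan = plan)
        }
      }
      state$cv_report <- do.call(rbind, rows)
      write_tsv(state$cv_report, file.path(out_dir, "cv_report.tsv"))
      write_provenance(config, stage, out_dir)
      res$cv <- state$cv_report
    } else if (stage == "importance") {
      check_upstream(config, "cv", out_dir)
      feats <- load_features()
      ctx <- state$cv_fits[["motor"]]
      if (is.null(ctx)) stop("missing upstream artifact for stage 'cv'; run that stage first")
      imp <- cv_permutation_importance(
        ctx$bundle, ctx$labels, ctx$aux,
        model_cfg_from(config, "multimodal", seed), ctx$plan,
        partition = load_cohort()$partition,
        n_perm = config$importance$n_perm, m = config$cv$m,
        m_train = config$cv$m_train, seed = seed)
      write_tsv(imp$table, file.path(out_dir, "importance.tsv"))
      write_provenance(config, stage, out_dir,
                       list(kendalls_w = imp$kendalls_w))
      state$importance <- imp
      res$importance <- imp
    } else if (stage == "trajectories") {
      cohort <- load_cohort()
      gr <- classify_growth(growth_slopes(cohort$table))
      write_tsv(gr, file.path(out_dir, "growth_records.tsv"))
      contrasts <- network_change_contrasts(cohort)
      write_tsv(contrasts, file.path(out_dir, "network_contrasts.tsv"))
      conn_long <- sensorimotor_block_long(cohort)
      spl <- fit_spline_lmm(conn_long)
      spl_tab <- data.frame(
        model = c("spline", "linear"),
        aic = c(spl$spline$aic, spl$linear$aic),
        bic = c(spl$spline$bic, spl$linear$bic),
        loglik = c(spl$spline$loglik, spl$linear$loglik),
        delta_aic = spl$delta_aic, preferred = spl$preferred)
      write_tsv(spl_tab, file.path(out_dir, "spline_comparison.tsv"))
      write_provenance(config, stage, out_dir)
      state$trajectories <- list(growth = gr, contrasts = contrasts, spline = spl)
      res$trajectories <- state$trajectories
    } else if (stage == "report") {
      for (up in c("cv", "trajectories")) check_upstream(config, up, out_dir)
      cvr <- utils::read.delim(file.path(out_dir, "cv_report.tsv"))
      lines <- c("devfuse pipeline report",
                 sprintf("config hash: %s", config_hash(config)),
                 "",
                 "cross-validated performance (mean over folds, overall stratum):")
      ov <- cvr[cvr$stratum == "overall", ]
      for (outc in unique(ov$outcome)) for (v in unique(ov$variant)) {
        sel <- ov[ov$outcome == outc & ov$variant == v, ]
        lines <- c(lines, sprintf("  %-6s %-18s acc=%.3f auc=%.3f f1=%.3f",
                                  outc, v, mean(sel$accuracy, na.rm = TRUE),
                                  mean(sel$auc, na.rm = TRUE),
                                  mean(sel$f1, na.rm = TRUE)))
      }
      gr <- utils::read.delim(file.path(out_dir, "growth_records.tsv"))
      lines <- c(lines, "",
                 sprintf("accelerated growth: %.1f%% of classified participants",
                         100 * mean(gr$growth_class == "accelerated", na.rm = TRUE)))
      writeLines(lines, file.path(out_dir, "report.txt"))
      write_provenance(config, stage, out_dir)
      res$report <- lines
    }
  }
  invisible(res)
}

#' Combined age-by-outcome strata
#' @param age_group Integer age group (3-6).
#' @param class 0/1 outcome class.
#' @return Interaction factor (3-4 vs 5-6 years crossed with class).
#' @export
make_strata <- function(age_group, class) {
  band <- ifelse(age_group <= 4, "3-4y", "5-6y")
  interaction(band, class, drop = TRUE)
}

#' Long-format sensorimotor block means for trajectory modeling
#'
#' One row per participant-wave with connectivity: the within-sensorimotor
#' block mean plus the covariates of the spline mixed model.
#'
#' @param cohort Output of [generate_cohort()].
#' @return data.frame with columns y, age_months, participant, sex, ses,
#'   mean_fd, scan_state.
#' @export
sensorimotor_block_long <- function(cohort) {
  part <- cohort$partition
  tab <- cohort$table
  y <- rep(NA_real_, nrow(tab))
  for (r in seq_len(nrow(tab))) {
    cm <- cohort$connectivity[[tab$participant[r]]]
    w <- tab$wave[r]
    if (is.null(cm) || length(cm) < w || is.null(cm[[w]])) next
    y[r] <- block_means(cm[[w]], part)["SomMot", "SomMot"]
  }
  out <- data.frame(y = y, age_months = tab$age_months,
                    participant = tab$participant, sex = tab$sex,
                    ses = tab$ses, mean_fd = tab$mean_fd,
                    scan_state = tab$scan_state)
  out[!is.na(out$y), ]
}

#' Cross-fold grouped permutation importance
#'
#' Trains a model per cross-validation fold (one completed dataset per
#' fold), computes grouped permutation importance on each held-out fold and
#' aggregates with [aggregate_importance()].
#'
#' @inheritParams cross_validate
#' @param partition Network partition for connectivity block groups.
#' @param n_perm Permutations per group per fold.
#' @return As [aggregate_importance()], plus `per_fold`.
#' @export
cv_permutation_importance <- function(bundle, labels, aux, cfg, plan,
                                      partition, n_perm = 100L, m = 5L,
                                      m_train = 1L, seed = 1L) {
  k <- attr(plan, "k")
  dims <- c(conn = ncol(bundle$conn), graph = ncol(bundle$graph),
            motor = ncol(bundle$motor), cog = ncol(bundle$cog))
  X <- cbind(bundle$conn, bundle$graph, bundle$motor, bundle$cog)
  colnames(X) <- c(paste0("conn_", seq_len(dims["conn"])),
                   paste0("graph_", seq_len(dims["graph"])),
                   paste0("motor_", seq_len(dims["motor"])),
                   paste0("cog_", seq_len(dims["cog"])))
  predictor_cols <- colnames(X)[-seq_len(dims["conn"])]
  reports <- list()
  for (f in seq_len(k)) {
    te <- which(unclass(plan) == f)
    tr <- which(unclass(plan) != f)
    prep <- fold_preprocess(X[tr, , drop = FALSE], X[te, , drop = FALSE],
                            aux[tr, , drop = FALSE], aux[te, , drop = FALSE],
                            m = m, predictor_cols = predictor_cols,
                            seed = seed + f)
    chans_tr <- split_channels(prep$train_sets[[1]], dims)
    chans_te <- split_channels(prep$test_sets[[1]], dims)
    b_tr <- feature_bundle(chans_tr[[1]], chans_tr[[2]], chans_tr[[3]],
                           chans_tr[[4]], bundle$participant[tr])
    b_te <- feature_bundle(chans_te[[1]], chans_te[[2]], chans_te[[3]],
                           chans_te[[4]], bundle$participant[te])
    inner <- stratified_kfold(factor(labels[tr]), k = 7L, seed = seed + 200L + f)
    iv <- which(unclass(inner) == 1L)
    it <- setdiff(seq_along(tr), iv)
    cfg_f <- cfg
    cfg_f$seed <- cfg$seed + 5000L + f
    fit <- train_model(bundle_rows(b_tr, it), labels[tr][it],
                       bundle_rows(b_tr, iv), labels[tr][iv], cfg_f)
    groups <- default_feature_groups(b_te, partition)
    reports[[f]] <- permutation_importance(fit, b_te, labels[te], groups,
                                           n_perm = n_perm, seed = seed + 300L + f)
  }
  out <- aggregate_importance(reports)
  out$per_fold <- reports
  out
}
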