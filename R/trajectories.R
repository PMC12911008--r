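#' Per-participant growth slopes
#'
#' Ordinary least-squares slope of the total motor percentile and the EF
#' composite on months since baseline, per participant, using the waves at
#' which the score is observed. Participants with fewer than two observed
#' waves for a measure get NA; omissions are recorded with reasons. OLS
#' slopes (rather than mixed-model BLUPs) make the downstream subgroup
#' classification exactly reproducible; with two waves the slope reduces to
#' the two-point difference quotient.
#'
#' @param table Cohort table.
#' @param ef_variant EF composite variant.
#' @return data.frame of class `growth_records`: `participant`,
#'   `motor_slope`, `ef_slope` (points/month), `n_waves_motor`,
#'   `n_waves_ef`; omitted measure-participants in attribute `omitted`.
#' @export
growth_slopes <- function(table, ef_variant = "six_measure") {
  base <- table[table$wave == 1L, ]
  ef <- ef_composite_scores(table, variant = ef_variant,
                            rescale_sample = attr(
                              ef_composite_scores(base, variant = ef_variant),
                              "raw"))
  df <- data.frame(participant = table$participant, months = table$months,
                   motor = table$total_motor, ef = as.numeric(ef))
  slope_of <- function(y, x) {
    ok <- !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    x <- x[ok]; y <- y[ok]
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  ids <- unique(df$participant)
  out <- data.frame(participant = ids, motor_slope = NA_real_,
                    ef_slope = NA_real_, n_waves_motor = 0L, n_waves_ef = 0L)
  for (i in seq_along(ids)) {
    d <- df[df$participant == ids[i], ]
    out$motor_slope[i] <- slope_of(d$motor, d$months)
    out$ef_slope[i] <- slope_of(d$ef, d$months)
    out$n_waves_motor[i] <- sum(!is.na(d$motor))
    out$n_waves_ef[i] <- sum(!is.na(d$ef))
  }
  omitted <- out$participant[is.na(out$motor_slope) | is.na(out$ef_slope)]
  attr(out, "omitted") <- data.frame(
    participant = omitted,
    reason = rep("fewer than 2 observed waves", length(omitted)))
  class(out) <- c("growth_records", "data.frame")
  out
}

#' Classify growth subgroups from slopes
#'
#' Accelerated development: both the motor and the EF slope exceed the
#' sample mean by more than 1 SD simultaneously; slower: both fall more than
#' 1 SD below the mean; otherwise typical. Sample moments are taken over the
#' records with both slopes present; records missing a slope are left
#' unclassified (NA).
#'
#' @param records `growth_records` from [growth_slopes()].
#' @return The records with a `growth_class` factor column
#'   (accelerated/typical/slower).
#' @export
classify_growth <- function(records) {
  both <- !is.na(records$motor_slope) & !is.na(records$ef_slope)
  if (sum(both) < 3L) stop("need at least 3 records with both slopes")
  ms <- records$motor_slope[both]; es <- records$ef_slope[both]
  m_mu <- mean(ms); m_sd <- stats::sd(ms)
  e_mu <- mean(es); e_sd <- stats::sd(es)
  cls <- rep(NA_character_, nrow(records))
  if (m_sd <= 0 || e_sd <= 0) {
    warning("degenerate zero-SD slopes; all records classified typical")
    cls[both] <- "typical"
  } else {
    hi <- records$motor_slope > m_mu + m_sd & records$ef_slope > e_mu + e_sd
    lo <- records$motor_slope < m_mu - m_sd & records$ef_slope < e_mu - e_sd
    cls[both] <- ifelse(hi[both], "accelerated",
                        ifelse(lo[both], "slower", "typical"))
  }
  records$growth_class <- factor(cls, levels = c("accelerated", "typical", "slower"))
  records
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on the
#' covariate design (intercept included; categorical covariates expanded to
#' dummies). The 95% CI uses the Fisher z-transform with standard error
#' `1/sqrt(n - k - 3)` (k = number of covariate columns after expansion);
#' the two-sided p-value uses the t statistic on `n - k - 2` degrees of
#' freedom. Rank-deficient designs are fit with the pseudo-inverse and
#' flagged with a warning; a zero-variance residual (a variable exactly
#' collinear with the covariates) is an error.
#'
#' @param x,y Numeric vectors.
#' @param covariates data.frame (or matrix) of covariates.
#' @return List: `estimate`, `conf_int` (length 2), `p_value`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]; covariates <- covariates[ok, , drop = FALSE]
  design <- stats::model.matrix(~ ., data = covariates)
  n <- length(x); k <- ncol(design) - 1L
  if (n <= k + 3L) stop("need n > number of covariates + 3")
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    warning("collinear covariates; using pseudo-inverse (rank-deficient) fit")
  rx <- stats::residuals(stats::lm.fit(design, x))
  ry <- stats::residuals(stats::lm.fit(design, y))
  if (stats::sd(rx) <= .Machine$double.eps^0.5 ||
      stats::sd(ry) <= .Machine$double.eps^0.5)
    stop("zero-variance residual: variable is collinear with covariates")
  r <- stats::cor(rx, ry)
  z <- atanh(r)
  se <- 1 / sqrt(n - k - 3)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(estimate = r, conf_int = ci, p_value = p, df = df, n = n)
}

extract_lmm_fit <- function(fit) {
  ll <- stats::logLik(fit)
  vc <- lme4::VarCorr(fit)
  list(fixef = lme4::fixef(fit),
       ranef_var = as.numeric(vc[[1]][1]),
       resid_var = attr(vc, "sc")^2,
       loglik = as.numeric(ll), df = attr(ll, "df"),
       aic = stats::AIC(fit), bic = stats::BIC(fit), fit = fit)
}

#' Spline versus linear random-intercept model comparison
#'
#' Fits a Gaussian random-intercept mixed model of a longitudinal outcome on
#' a natural cubic spline of age (df = 3; interior knots at 48 and 60
#' months, boundary knots at the observed age range) plus any of sex, SES,
#' mean FD and scan state present in the data, against the same model with a
#' linear age term. Both models are fit by maximum likelihood (not REML) so
#' the AIC difference across fixed-effect structures is meaningful; the
#' spline model is preferred when `AIC(linear) - AIC(spline) > 10`.
#'
#' @param data data.frame with columns `y` (outcome), `age_months`,
#'   `participant`, and optionally `sex`, `ses`, `mean_fd`, `scan_state`.
#' @param knots Interior knots in months (default c(48, 60)).
#' @param delta_aic_rule Preference threshold (default 10).
#' @return List: `spline` and `linear` fit summaries (fixed effects,
#'   variances, logLik/AIC/BIC), `delta_aic` (linear minus spline),
#'   `preferred` ("spline"/"linear").
#' @export
fit_spline_lmm <- function(data, knots = c(48, 60), delta_aic_rule = 10) {
  if (length(unique(data$age_months)) < 3L) stop("need at least 3 distinct ages")
  rng <- range(data$age_months)
  if (any(knots <= rng[1]) || any(knots >= rng[2]))
    stop("knots must lie inside the observed age range")
  covs <- intersect(c("sex", "ses", "mean_fd", "scan_state"), names(data))
  covs <- covs[vapply(covs, function(cn) length(unique(data[[cn]])) > 1L, TRUE)]
  cov_part <- if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""
  f_spline <- stats::as.formula(paste(
    "y ~ splines::ns(age_months, knots = knots, Boundary.knots = rng)",
    cov_part, "+ (1 | participant)"))
  f_linear <- stats::as.formula(paste("y ~ age_months", cov_part,
                                      "+ (1 | participant)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  fs <- lme4::lmer(f_spline, data = data, REML = FALSE, control = ctrl)
  fl <- lme4::lmer(f_linear, data = data, REML = FALSE, control = ctrl)
  s <- extract_lmm_fit(fs); l <- extract_lmm_fit(fl)
  delta <- l$aic - s$aic
  list(spline = s, linear = l, delta_aic = delta,
       preferred = if (delta > delta_aic_rule) "spline" else "linear")
}

#' Per-block mean connectivity of a matrix
#'
#' Mean off-diagonal edge value within each network block (within-network)
#' and across each pair of networks (between-network).
#'
#' @param m Connectivity matrix.
#' @param partition Network partition factor.
#' @return k x k symmetric matrix of block means.
#' @export
block_means <- function(m, partition) {
  ind <- stats::model.matrix(~ 0 + partition)
  sums <- t(ind) %*% m %*% ind
  sizes <- as.numeric(table(partition))
  counts <- outer(sizes, sizes)
  diag(counts) <- sizes^2 - sizes
  diag(sums) <- diag(sums) - sapply(split(diag(m), partition), sum)
  out <- sums / counts
  dimnames(out) <- list(levels(partition), levels(partition))
  out
}

#' Wave-to-wave network change contrasts
#'
#' For each participant with connectivity at both waves, computes per-block
#' mean connectivity at each wave; then per block the paired differences
#' (later minus earlier), their mean and SD, the paired t statistic with
#' two-sided p, a Benjamini-Hochberg adjusted p over all blocks, and a
#' within/between label.
#'
#' @param cohort Output of [generate_cohort()] (with matrices at both
#'   waves).
#' @param waves Length-2 wave numbers (default c(1, 3)).
#' @return data.frame: block, type, n, delta_mean, delta_sd, t, p, p_bh.
#' @export
network_change_contrasts <- function(cohort, waves = c(1, 3)) {
  part <- cohort$partition
  ids <- names(cohort$connectivity)
  deltas <- list()
  for (id in ids) {
    cm <- cohort$connectivity[[id]]
    if (is.null(cm) || length(cm) < max(waves)) next
    m1 <- cm[[waves[1]]]; m2 <- cm[[waves[2]]]
    if (is.null(m1) || is.null(m2)) next
    deltas[[id]] <- block_means(m2, part) - block_means(m1, part)
  }
  if (length(deltas) == 0L) stop("no participants with both waves observed")
  k <- nlevels(part)
  nets <- levels(part)
  rows <- list()
  for (a in seq_len(k)) for (b in a:k) {
    d <- vapply(deltas, function(x) x[a, b], numeric(1))
    n <- length(d)
    mu <- mean(d); sg <- stats::sd(d)
    tval <- if (sg > 0) mu / (sg / sqrt(n)) else 0
    p <- if (sg > 0) 2 * stats::pt(-abs(tval), n - 1) else 1
    rows[[length(rows) + 1L]] <- data.frame(
      block = paste(nets[a], nets[b], sep = "|"),
      type = if (a == b) "within" else "between",
      n = n, delta_mean = mu, delta_sd = sg, t = tval, p = p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  out
}
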