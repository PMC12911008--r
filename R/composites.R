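#' Age-standardize a raw score against a norm
#'
#' @param raw Raw score(s).
#' @param norm_mean,norm_sd Normative mean and SD for the child's age group
#'   (here taken from the generator configuration, standing in for published
#'   norms).
#' @return z-score(s).
#' @export
age_standardize <- function(raw, norm_mean, norm_sd) {
  if (any(norm_sd <= 0)) stop("norm_sd must be positive")
  (raw - norm_mean) / norm_sd
}

#' Cronbach's alpha from an item matrix
#'
#' Standard item-covariance formula: `alpha = k/(k-1) * (1 - sum(var_i) /
#' var(total))`.
#'
#' @param items n x k numeric matrix of item scores (complete cases used).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2L || nrow(items) < 3L) stop("need at least 2 items and 3 observations")
  vt <- stats::var(rowSums(items))
  if (vt <= 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / vt)
}

#' Default reliability weights for the EF composite domains
#'
#' Mean Cronbach's alpha of the two tasks per domain (working memory: digit
#' span 0.82 and visuospatial span 0.78; inhibitory control: go/no-go 0.85
#' and attention network test 0.81; cognitive flexibility: card sort 0.79
#' and flexible item selection 0.76). Sample-estimated alphas can be
#' supplied instead.
#'
#' @return Named numeric vector `c(wm=, ic=, cf=)`.
#' @export
default_reliability_weights <- function() {
  c(wm = mean(c(0.82, 0.78)), ic = mean(c(0.85, 0.81)), cf = mean(c(0.79, 0.76)))
}

#' Reliability-weighted executive-function composite
#'
#' Raw composite is the reliability-weighted mean of the three domain
#' z-scores, `(a_wm*z_wm + a_ic*z_ic + a_cf*z_cf) / (a_wm + a_ic + a_cf)`,
#' then linearly rescaled so that the supplied rescale sample has mean
#' exactly 100 and SD exactly 15.
#'
#' @param z_wm,z_ic,z_cf Domain z-scores (equal length).
#' @param weights Positive reliability weights, named wm/ic/cf
#'   (default [default_reliability_weights()]).
#' @param rescale_sample Raw-composite sample defining the 100/15 metric;
#'   defaults to the computed raw composites themselves.
#' @return Numeric vector of rescaled composites, with the raw composite and
#'   the linear transform as attributes `raw` and `transform`.
#' @export
ef_composite <- function(z_wm, z_ic, z_cf,
                         weights = default_reliability_weights(),
                         rescale_sample = NULL) {
  if (any(weights <= 0)) stop("reliability weights must be strictly positive")
  raw <- (weights[1] * z_wm + weights[2] * z_ic + weights[3] * z_cf) / sum(weights)
  if (is.null(rescale_sample)) rescale_sample <- raw
  rs <- rescale_sample[!is.na(rescale_sample)]
  if (length(rs) < 2L) stop("rescale sample must contain at least 2 scores")
  sg <- stats::sd(rs)
  if (sg <= 0) stop("rescale sample has zero variance")
  mu <- mean(rs)
  out <- 100 + 15 * (raw - mu) / sg
  attr(out, "raw") <- raw
  attr(out, "transform") <- c(mean = mu, sd = sg)
  out
}

ef_domain_z <- function(table) {
  norms <- default_behavior_norms()
  # standardize against the norms of the participant's baseline age group
  # (the anchor the generator grows scores from), falling back to the
  # current age group for tables without longitudinal anchoring
  grp <- table$age_group_baseline %||% table$age_group
  zcol <- function(measure) {
    nr <- norms[norms$measure == measure, ]
    mu <- unlist(nr[, paste0("m", grp)], use.names = FALSE)
    sd <- unlist(nr[, paste0("s", grp)], use.names = FALSE)
    nr$direction * age_standardize(table[[measure]], mu, sd)
  }
  list(
    wm_six = (zcol("digit_span") + zcol("visuospatial_span")) / 2,
    ic_six = (zcol("gonogo_accuracy") + zcol("ant_score")) / 2,
    cf_six = (zcol("dccs_switch_cost") + zcol("fist_score")) / 2,
    wm_nepsy = zcol("nepsy_memory_designs"),
    ic_nepsy = zcol("nepsy_statue"),
    cf_nepsy = zcol("nepsy_attention")
  )
}

#' EF composite scores for every row of a cohort table
#'
#' Two named variants are exposed: `"six_measure"` (the modeling composite:
#' two tasks per domain - spans for working memory, go/no-go and attention
#' network for inhibitory control, card-sort switch cost and flexible item
#' selection for flexibility) and `"nepsy"` (the narrower composite from the
#' three NEPSY-style scaled scores alone). Cost-type measures enter with
#' their sign flipped so larger z is always better.
#'
#' @param table Cohort table.
#' @param variant `"six_measure"` (default) or `"nepsy"`.
#' @param weights Reliability weights (see [ef_composite()]).
#' @param rescale_sample Optional raw-composite sample fixing the 100/15
#'   metric (e.g. baseline scores when scoring follow-up waves).
#' @return Numeric vector aligned with `table` rows (NA where a contributing
#'   score is missing).
#' @export
ef_composite_scores <- function(table, variant = c("six_measure", "nepsy"),
                                weights = default_reliability_weights(),
                                rescale_sample = NULL) {
  variant <- match.arg(variant)
  z <- ef_domain_z(table)
  if (variant == "six_measure")
    ef_composite(z$wm_six, z$ic_six, z$cf_six, weights, rescale_sample)
  else
    ef_composite(z$wm_nepsy, z$ic_nepsy, z$cf_nepsy, weights, rescale_sample)
}

#' Median-split binary classes from change scores
#'
#' Class 1 iff the change score is strictly greater than the sample median
#' of the non-missing changes; values exactly at the median get class 0 (a
#' fixed, documented tie rule so labeling is deterministic). Missing changes
#' yield NA and are never imputed.
#'
#' @param changes Numeric change scores.
#' @return Integer vector of 0/1/NA.
#' @export
binarize_outcomes <- function(changes) {
  obs <- changes[!is.na(changes)]
  if (length(obs) < 2L) stop("need at least 2 non-missing change scores")
  med <- stats::median(obs)
  ifelse(is.na(changes), NA_integer_, as.integer(changes > med))
}

#' Twelve-month outcome labels from a cohort table
#'
#' Computes per-participant baseline-to-wave-3 change in total motor
#' percentile and in the EF composite (scored on the baseline 100/15
#' metric), then median-splits each. Participants lacking an observed change
#' score for an outcome are absent from that outcome's labels - outcome
#' labels are never imputed.
#'
#' @param table Cohort table.
#' @param ef_variant Composite variant passed to [ef_composite_scores()].
#' @return data.frame: `participant`, `change_motor`, `change_ef`,
#'   `motor_class`, `ef_class` (NA where the change is unobserved).
#' @export
outcome_labels <- function(table, ef_variant = "six_measure") {
  base <- table[table$wave == 1L, ]
  ef_all <- ef_composite_scores(table, variant = ef_variant,
                                rescale_sample = attr(
                                  ef_composite_scores(base, variant = ef_variant),
                                  "raw"))
  tab <- data.frame(participant = table$participant, wave = table$wave,
                    total_motor = table$total_motor, ef = as.numeric(ef_all))
  w1 <- tab[tab$wave == 1L, ]
  w3 <- tab[tab$wave == 3L, ]
  ids <- w1$participant
  m3 <- w3$total_motor[match(ids, w3$participant)]
  e3 <- w3$ef[match(ids, w3$participant)]
  out <- data.frame(
    participant = ids,
    change_motor = m3 - w1$total_motor,
    change_ef = e3 - w1$ef
  )
  out$motor_class <- rep(NA_integer_, nrow(out))
  out$ef_class <- rep(NA_integer_, nrow(out))
  ok_m <- !is.na(out$change_motor)
  ok_e <- !is.na(out$change_ef)
  out$motor_class[ok_m] <- binarize_outcomes(out$change_motor[ok_m])
  out$ef_class[ok_e] <- binarize_outcomes(out$change_ef[ok_e])
  out
}
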