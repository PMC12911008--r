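#' @title Synthetic three-wave cohort generator
#' @description Internal machinery shared by the cohort operations: age
#'   groups, measure bookkeeping and the latent-factor behavioral model.
#' @name synthetic-cohort
#' @keywords internal
NULL

age_group_of <- function(age_months) pmin(6L, pmax(3L, age_months %/% 12L))

#' Names of the motor and cognitive feature columns of a cohort table
#'
#' 16 motor features (fine/gross/balance/total percentiles plus 12
#' item-level synthetic subscores derived from the domain percentiles) and
#' 12 cognitive features.
#'
#' @return A list with `motor` and `cognitive` character vectors.
#' @export
behavior_feature_columns <- function() {
  norms <- default_behavior_norms()
  motor_domains <- norms$measure[norms$domain == "motor"]
  items <- as.vector(t(outer(c("fine", "gross", "balance"),
                             paste0("_item", 1:4), paste0)))
  list(
    motor = c(motor_domains, "total_motor", items),
    cognitive = norms$measure[norms$domain != "motor"]
  )
}

draw_participants <- function(spec) {
  n <- spec$n_baseline
  lo <- spec$age_range[1] * 12
  hi <- (spec$age_range[2] + 1) * 12
  age <- floor(stats::runif(n, lo, hi))
  grp <- age_group_of(age)
  sex <- ifelse(stats::runif(n) < spec$sex_prob_female, "F", "M")
  ses <- sample(names(spec$ses_probs), n, replace = TRUE, prob = spec$ses_probs)
  idx <- grp - 2L
  fd <- pmax(0.02, stats::rnorm(n, spec$fd_by_age[idx], spec$fd_sd_by_age[idx]))
  data.frame(
    participant = seq_len(n), age_months = age, age_group = grp,
    sex = sex, ses = ses,
    scan_state = ifelse(age < 60, "sleep", "awake"),
    mean_fd = fd, eta = stats::rnorm(n),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic cohort
#'
#' Draws participants, samples all three assessment waves from the
#' latent-factor behavioral model, applies attrition and item-level MAR
#' missingness, and generates a connectivity matrix per retained
#' participant-wave. Deterministic for a fixed `spec$seed`.
#'
#' The behavioral model for each measure is, on the z-score scale,
#' `z_w = a*trait + b0*eff*eta + b1*eff*eta*(months/12) + e_w`, where
#' `trait` is a stable participant ability (loading `a`), `eta` the scalar
#' latent factor shared with connectivity, and `b0`/`b1` the baseline and
#' change loadings scaled by `effect_size["outcome"]`. Occasion noise `e_w`
#' is a participant-level random walk (baseline SD `s` with `a^2 + s^2 = 1`,
#' so baseline scores match the configured norms in distribution before
#' clamping; later waves add independent increments). Raw scores grow from
#' the baseline age-group norm anchor at a constant within-person rate
#' (raw-unit growth for motor percentiles, z-unit growth for cognitive
#' measures), and are clamped to each measure's valid range. Because
#' change-score noise consists of increments independent of baseline and the
#' expected change is identical across ages, baseline features predict
#' 12-month change only through `eta` - at `effect_size = 0` the outcome is
#' unpredictable by construction.
#'
#' @param spec A [cohort_spec()].
#' @param conn_waves Integer waves (subset of 1:3) for which connectivity
#'   matrices are generated; restrict to `1` when only baseline features are
#'   needed.
#' @return A list with `table` (the long cohort data.frame, one row per
#'   retained participant-wave, NA for masked cells) and `connectivity`
#'   (nested list: `connectivity[[participant]][[wave]]`, matrices carrying
#'   the network partition as attribute `network`).
#' @export
generate_cohort <- function(spec, conn_waves = 1:3) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  ppl <- draw_participants(spec)
  norms <- spec$behavior_norms
  n <- spec$n_baseline
  waves <- seq_along(spec$wave_months)

  # stable traits: shared general factor + measure-specific component
  general <- stats::rnorm(n)
  traits <- sqrt(0.5) * general +
    sqrt(0.5) * matrix(stats::rnorm(n * nrow(norms)), n, nrow(norms))

  eff_out <- spec$effect_size["outcome"]
  # occasion noise follows a participant-level random walk across waves:
  # increments are independent of the baseline draw, so change scores carry
  # no regression-to-the-mean artifact and, at effect_size 0, are
  # unpredictable from baseline features
  occ <- array(0, c(n, nrow(norms), length(waves)))
  occ[, , 1] <- stats::rnorm(n * nrow(norms), 0, spec$occasion_sd)
  for (w in waves[-1]) {
    occ[, , w] <- occ[, , w - 1] +
      stats::rnorm(n * nrow(norms), 0, spec$occasion_sd / sqrt(2))
  }
  rows <- vector("list", length(waves))
  for (w in waves) {
    months <- spec$wave_months[w]
    age_w <- ppl$age_months + months
    grp_w <- age_group_of(age_w)
    rec <- data.frame(
      participant = ppl$participant, wave = w, months = months,
      age_months = age_w, age_group = grp_w, sex = ppl$sex, ses = ppl$ses,
      scan_state = ifelse(age_w < 60, "sleep", "awake"),
      mean_fd = pmax(0.02, stats::rnorm(
        n, spec$fd_by_age[grp_w - 2L], spec$fd_sd_by_age[grp_w - 2L])),
      eta = ppl$eta, stringsAsFactors = FALSE
    )
    # norms are anchored at the baseline age group with a constant
    # within-person growth rate derived from the age-3 to age-6 norm span:
    # motor percentiles grow in raw units (their change score is taken in
    # raw percentile points) and cognitive measures grow in z units (their
    # change enters through age-standardized composites). Anchoring keeps
    # the expected change identical across ages, so at effect_size = 0 the
    # median-split outcome carries no age signal.
    grp0 <- ppl$age_group
    for (m in seq_len(nrow(norms))) {
      mu0 <- unlist(norms[m, paste0("m", grp0)], use.names = FALSE)
      sd0 <- unlist(norms[m, paste0("s", grp0)], use.names = FALSE)
      span <- norms$m6[m] - norms$m3[m]
      z <- spec$trait_loading * traits[, m] +
        spec$baseline_eta_loading * eff_out * ppl$eta +
        spec$change_eta_loading * eff_out * ppl$eta * (months / 12) +
        occ[, m, w]
      if (norms$domain[m] == "motor") {
        raw <- mu0 + (span / 36) * months + sd0 * norms$direction[m] * z
      } else {
        g_z <- norms$direction[m] * span /
          (36 * mean(unlist(norms[m, c("s3", "s4", "s5", "s6")])))
        raw <- mu0 + sd0 * norms$direction[m] * (z + g_z * months)
      }
      rec[[norms$measure[m]]] <- pmin(norms$hi[m], pmax(norms$lo[m], raw))
    }
    rec$age_group_baseline <- grp0
    rec$total_motor <- (rec$fine_motor + rec$gross_motor + rec$balance) / 3
    dom_col <- c(fine = "fine_motor", gross = "gross_motor", balance = "balance")
    for (dom in names(dom_col)) {
      base <- rec[[dom_col[[dom]]]]
      for (it in 1:4) {
        rec[[paste0(dom, "_item", it)]] <-
          pmin(100, pmax(0, base + stats::rnorm(n, 0, 8)))
      }
    }
    rows[[w]] <- rec
  }
  tab <- do.call(rbind, rows)
  cols <- behavior_feature_columns()
  tab <- tab[, c("participant", "wave", "months", "age_months", "age_group",
                 "age_group_baseline", "sex", "ses", "scan_state", "mean_fd",
                 "eta", cols$motor, cols$cognitive)]
  tab <- tab[order(tab$participant, tab$wave), ]
  rownames(tab) <- NULL
  attr(tab, "spec") <- spec
  attr(tab, "motor_cols") <- cols$motor
  attr(tab, "cognitive_cols") <- cols$cognitive
  class(tab) <- c("cohort_table", "data.frame")

  tab <- apply_attrition(tab, spec)
  tab <- inject_missingness(tab, spec)

  # persistent per-subject block jitter, then one matrix per retained wave
  part <- network_partition(spec$n_regions, spec$n_networks)
  k <- nlevels(part)
  jit <- lapply(seq_len(n), function(i) {
    j <- matrix(stats::rnorm(k * k, 0, spec$conn_profile$subject_block_sd), k, k)
    (j + t(j)) / 2
  })
  conn <- vector("list", n)
  names(conn) <- as.character(seq_len(n))
  for (r in seq_len(nrow(tab))) {
    w <- tab$wave[r]
    if (!(w %in% conn_waves)) next
    p <- tab$participant[r]
    st <- list(age_months = tab$age_months[r], scan_state = tab$scan_state[r],
               eta = tab$eta[r], months = tab$months[r],
               block_jitter = jit[[p]])
    if (is.null(conn[[p]])) conn[[p]] <- list()
    conn[[p]][[w]] <- generate_connectivity(st, spec, partition = part)
  }
  list(table = tab, connectivity = conn, partition = part)
}

block_mean_grid <- function(state, spec) {
  pr <- spec$conn_profile
  nets <- pr$networks
  k <- length(nets)
  # cross-sectional age trends anchor at the participant's baseline age;
  # within-study longitudinal change is carried by the configured wave
  # deltas, so a configured delta is recovered exactly by wave contrasts
  age <- state$age_months - (state$months %||% 0)
  g <- matrix(pr$between_base + pr$between_slope * (age - 36), k, k,
              dimnames = list(nets, nets))
  diag(g) <- pr$within_base + pr$within_slope * (age - 36)
  for (key in names(pr$between_pairs)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    v <- pr$between_pairs[[key]]
    g[ab[1], ab[2]] <- g[ab[2], ab[1]] <- v$base + v$slope * (age - 36)
  }
  iu <- pr$inverted_u
  g[iu$pair[1], iu$pair[2]] <- g[iu$pair[2], iu$pair[1]] <-
    iu$peak_value - iu$curvature * (age - iu$peak_month)^2
  if (identical(state$scan_state, "awake"))
    g["Vis", "Vis"] <- g["Vis", "Vis"] + pr$awake_vis_increment
  for (key in names(pr$wave_deltas)) {
    ab <- strsplit(key, "|", fixed = TRUE)[[1]]
    d <- pr$wave_deltas[[key]] * (state$months %||% 0) / 12
    g[ab[1], ab[2]] <- g[ab[1], ab[2]] + d
    if (ab[1] != ab[2]) g[ab[2], ab[1]] <- g[ab[2], ab[1]] + d
  }
  load <- pr$eta_loading * spec$effect_size["conn"] * (state$eta %||% 0)
  for (ab in pr$eta_blocks) {
    g[ab[1], ab[2]] <- g[ab[1], ab[2]] + load
    if (ab[1] != ab[2]) g[ab[2], ab[1]] <- g[ab[2], ab[1]] + load
  }
  if (!is.null(state$block_jitter)) g <- g + state$block_jitter
  g
}

#' Generate one synthetic connectivity matrix
#'
#' Builds the participant-wave block-mean grid (age trajectories, scan-state
#' increment, wave deltas, latent-factor loading, persistent subject jitter)
#' and samples symmetric edge-level noise around it. Output is symmetric
#' with unit diagonal and entries clamped to (-1, 1).
#'
#' @param state List with `age_months`, `scan_state` ("sleep"/"awake"),
#'   `eta`, optional `months` (since baseline) and optional `block_jitter`
#'   (k x k symmetric matrix).
#' @param spec A [cohort_spec()].
#' @param partition Optional precomputed [network_partition()].
#' @return P x P matrix with attribute `network` (the partition factor).
#' @export
generate_connectivity <- function(state, spec, partition = NULL) {
  if (is.null(partition)) partition <- network_partition(spec$n_regions, spec$n_networks)
  p <- length(partition)
  g <- block_mean_grid(state, spec)
  bm <- g[as.integer(partition), as.integer(partition)]
  noise <- matrix(0, p, p)
  ut <- upper.tri(noise)
  noise[ut] <- stats::rnorm(sum(ut), 0, spec$conn_profile$edge_noise_sd)
  noise <- noise + t(noise)
  m <- bm + noise
  m <- pmin(pmax(m, -0.999), 0.999)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(paste0("R", seq_len(p)), paste0("R", seq_len(p)))
  attr(m, "network") <- partition
  m
}

#' Sample region-by-time series with a target correlation structure
#'
#' Draws multivariate normal time series whose population correlation equals
#' the target connectivity matrix, so [fc_matrix()] of the output converges
#' to the target as the number of timepoints grows. An indefinite target is
#' repaired to the nearest positive-definite correlation matrix with a
#' warning.
#'
#' @param target Target correlation matrix, or a participant state list (in
#'   which case the target is built by [generate_connectivity()], requiring
#'   `spec`).
#' @param n_timepoints Number of time samples (default 170 usable volumes).
#' @param spec Required when `target` is a state list.
#' @return `P x n_timepoints` numeric matrix.
#' @export
generate_timeseries <- function(target, n_timepoints = 170, spec = NULL) {
  if (!is.matrix(target)) {
    if (is.null(spec)) stop("spec required when target is a participant state")
    target <- generate_connectivity(target, spec)
  }
  p <- nrow(target)
  ch <- tryCatch(chol(target), error = function(e) NULL)
  if (is.null(ch)) {
    warning("target not positive definite; applying nearest-PD repair")
    ch <- chol(nearest_pd(target))
  }
  z <- matrix(stats::rnorm(p * n_timepoints), n_timepoints, p)
  t(z %*% ch)
}

#' Apply monotone attrition to a cohort table
#'
#' Removes wave-2 and wave-3 records so that retained counts equal
#' `round(retention * n_baseline)` (half-up). Dropout ranks participants by
#' a logistic score built from observed auxiliaries (SES, baseline motion,
#' scan state) plus independent noise, so dropout is associated with
#' auxiliaries but independent of outcome values given them, and is
#' monotone: a wave-3 completer is always a wave-2 completer.
#'
#' @param table A cohort table with complete waves.
#' @param spec The [cohort_spec()].
#' @return The table with dropped-out wave records removed.
#' @export
apply_attrition <- function(table, spec) {
  if (any(spec$retention <= 0 | spec$retention > 1))
    stop("retention must lie in (0, 1]")
  base <- table[table$wave == 1L, ]
  if (anyNA(base[, attr(table, "motor_cols")])) stop("wave-1 records must be complete")
  n <- nrow(base)
  lp <- 0.3 * as.numeric(scale(base$mean_fd)) +
    0.25 * (base$ses == "low") - 0.25 * (base$ses == "high") +
    0.10 * (base$scan_state == "awake")
  u <- lp + stats::rlogis(n)
  n2 <- round_half_up(spec$retention[1] * n)
  n3 <- round_half_up(spec$retention[2] * n)
  ord <- order(u)                         # lowest dropout propensity first
  keep2 <- base$participant[ord[seq_len(n2)]]
  keep3 <- base$participant[ord[seq_len(n3)]]
  drop <- (table$wave == 2L & !(table$participant %in% keep2)) |
    (table$wave == 3L & !(table$participant %in% keep3))
  out <- table[!drop, ]
  attributes(out)[c("spec", "motor_cols", "cognitive_cols")] <-
    attributes(table)[c("spec", "motor_cols", "cognitive_cols")]
  class(out) <- class(table)
  out
}

#' Inject item-level MAR missingness
#'
#' Masks behavioral cells among retained wave-2/3 records so that the total
#' wave-level missing fraction (dropout plus item missingness) matches the
#' configured rates. Cell masking probability is a logistic function of
#' observed auxiliaries only (mean FD, SES, scan state), with the intercept
#' calibrated so the expected item rate hits the target - missing at random
#' by construction. Wave-1 cells are never masked.
#'
#' @param table Cohort table after [apply_attrition()].
#' @param spec The [cohort_spec()].
#' @return The table with masked cells set to NA.
#' @export
inject_missingness <- function(table, spec) {
  cols <- c(attr(table, "motor_cols"), attr(table, "cognitive_cols"))
  n <- spec$n_baseline
  for (w in 2:3) {
    target <- spec$missing_rates[w - 1]
    rows <- which(table$wave == w)
    dropout <- 1 - length(rows) / n
    # rates are typically quoted to 0.1%, so allow rounding slack at the floor
    if (target < dropout - 5e-3)
      stop(sprintf("wave-%d missing rate %.3f below dropout-implied floor %.3f",
                   w, target, dropout))
    q <- max(0, (target - dropout) / (1 - dropout))
    if (q <= 1e-12) next
    lp <- 0.8 * as.numeric(scale(table$mean_fd[rows])) +
      0.5 * (table$ses[rows] == "low") + 0.4 * (table$scan_state[rows] == "awake")
    alpha <- stats::uniroot(
      function(a) mean(stats::plogis(a + lp)) - q, c(-30, 30))$root
    pr <- stats::plogis(alpha + lp)
    for (cl in cols) {
      mask <- stats::runif(length(rows)) < pr
      table[rows[mask], cl] <- NA_real_
    }
  }
  table
}

#' Total wave-level missing fraction of a cohort table
#'
#' Fraction of expected behavioral cells at a wave that are unobserved,
#' counting both whole-record dropout and item-level masking.
#'
#' @param table Cohort table.
#' @param wave Wave number.
#' @param n_baseline Baseline sample size (defaults to the table's spec).
#' @return A proportion in \[0, 1\].
#' @export
cohort_missing_fraction <- function(table, wave,
                                    n_baseline = attr(table, "spec")$n_baseline) {
  cols <- c(attr(table, "motor_cols"), attr(table, "cognitive_cols"))
  rows <- table[table$wave == wave, cols]
  total <- n_baseline * length(cols)
  (total - sum(!is.na(as.matrix(rows)))) / total
}
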