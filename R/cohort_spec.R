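#' Default per-age-group behavioral norms
#'
#' Mean/SD table for every generated behavioral measure, by age group
#' (3-, 4-, 5-, 6-year-olds). Motor percentiles, executive-function task
#' scores and scan-quality measures use published descriptive values for a
#' preschool cohort; measures the source battery does not enumerate
#' (visuospatial span, ANT, FIST, NEPSY-style scaled scores, RT fillers) are
#' synthetic stand-ins with developmentally plausible values and are labeled
#' as such via the `synthetic` column.
#'
#' `direction` is +1 when larger raw scores indicate better performance and
#' -1 for cost/latency measures (switch cost, reaction times), so the latent
#' ability factor loads with the correct sign. `lo`/`hi` are hard clamps
#' applied after sampling (percentiles and accuracies live in \[0, 100\]).
#'
#' @return A data.frame with one row per measure: `measure`, `domain`
#'   (motor / wm / ic / cf / filler), `direction`, `lo`, `hi`, `synthetic`,
#'   and `m3`,`s3`,...,`m6`,`s6` mean/SD columns per age group.
#' @export
default_behavior_norms <- function() {
  tab <- rbind(
    # measure,            domain, dir, lo,  hi,   syn, m3,   s3,   m4,   s4,   m5,   s5,   m6,   s6
    c("fine_motor",        "motor", 1,  0,   100,  0,   38.2, 23.7, 45.6, 25.8, 52.4, 26.9, 56.3, 27.1),
    c("gross_motor",       "motor", 1,  0,   100,  0,   41.7, 22.4, 48.3, 24.6, 53.1, 26.8, 54.9, 28.2),
    c("balance",           "motor", 1,  0,   100,  0,   40.8, 24.3, 47.2, 26.7, 52.3, 28.4, 54.1, 29.6),
    c("digit_span",        "wm",    1,  0,   9,    0,   2.5,  0.7,  3.2,  0.8,  4.1,  0.9,  4.6,  1.0),
    c("visuospatial_span", "wm",    1,  0,   9,    1,   2.3,  0.7,  3.0,  0.8,  3.8,  0.9,  4.4,  1.0),
    c("gonogo_accuracy",   "ic",    1,  0,   100,  0,   62.4, 18.2, 69.7, 19.1, 76.8, 19.8, 79.3, 20.4),
    c("ant_score",         "ic",    1,  0,   100,  1,   55,   15,   62,   15,   68,   16,   72,   16),
    c("dccs_switch_cost",  "cf",   -1,  50,  1500, 0,   385,  112,  324,  94,   289,  87,   268,  82),
    c("fist_score",        "cf",    1,  0,   30,   1,   8,    3,    10,   3,    12,   3,    13,   3),
    c("nepsy_attention",   "cf",    1,  1,   19,   1,   9,    3,    10,   3,    10,   3,    11,   3),
    c("nepsy_statue",      "ic",    1,  1,   19,   1,   9,    3,    10,   3,    10,   3,    11,   3),
    c("nepsy_memory_designs", "wm", 1,  1,   19,   1,   9,    3,    10,   3,    10,   3,    11,   3),
    c("gonogo_rt_ms",      "filler", -1, 100, 2000, 1,  650,  120,  600,  110,  560,  100,  530,  95),
    c("ant_rt_ms",         "filler", -1, 100, 2500, 1,  900,  150,  840,  140,  780,  130,  740,  120),
    c("dccs_accuracy",     "filler", 1,  0,   100,  1,  70,   15,   78,   14,   84,   12,   88,   10)
  )
  out <- data.frame(
    measure = tab[, 1], domain = tab[, 2],
    direction = as.numeric(tab[, 3]),
    lo = as.numeric(tab[, 4]), hi = as.numeric(tab[, 5]),
    synthetic = as.numeric(tab[, 6]) == 1,
    stringsAsFactors = FALSE
  )
  ms <- matrix(as.numeric(tab[, 7:14]), nrow = nrow(tab))
  colnames(ms) <- c("m3", "s3", "m4", "s4", "m5", "s5", "m6", "s6")
  cbind(out, as.data.frame(ms))
}

#' Canonical network names for the seven-network partition
#' @return Character vector of length 7.
#' @export
network_names <- function() {
  c("SomMot", "Vis", "DorsAttn", "VentAttn", "Default", "Control", "Limbic")
}

#' Default connectivity generation profile
#'
#' Block-level trajectory settings for the seven-network connectivity
#' generator: cross-sectional age trends (per-month slopes anchored at 36
#' months), longitudinal within-study wave deltas (change per 12 months),
#' the awake scan-state increment on the visual block, and the latent-factor
#' loading geometry.
#'
#' Defaults encode the developmental patterns the generator is calibrated
#' to: within-sensorimotor and sensorimotor-ventral-attention connectivity
#' rising 0.15 to 0.22 across ages 3-6, sensorimotor-subcortical/limbic
#' rising 0.12 (younger) to 0.16 (older), control-default falling 0.11 to
#' 0.07, an inverted-U dorsal-ventral attention trajectory peaking near 4.5
#' years, and 12-month wave deltas of +0.07 (sensorimotor), +0.05 (visual),
#' -0.04 (control-default) and +0.01 (limbic).
#'
#' @return A list of profile settings consumed by [generate_connectivity()].
#' @export
default_connectivity_profile <- function() {
  nets <- network_names()
  within_base <- c(SomMot = 0.15, Vis = 0.25, DorsAttn = 0.20, VentAttn = 0.20,
                   Default = 0.22, Control = 0.20, Limbic = 0.18)
  within_slope <- c(SomMot = (0.22 - 0.15) / 36, Vis = 0, DorsAttn = 0,
                    VentAttn = 0, Default = 0, Control = 0, Limbic = 0)
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  between <- list()
  between[[pair_key("SomMot", "VentAttn")]] <- list(base = 0.15, slope = (0.22 - 0.15) / 36)
  between[[pair_key("SomMot", "Limbic")]]   <- list(base = 0.10, slope = 0.04 / 24)
  between[[pair_key("Control", "Default")]] <- list(base = 0.13, slope = -0.04 / 24)
  list(
    networks = nets,
    within_base = within_base,
    within_slope = within_slope,
    between_base = 0.08,
    between_slope = 0,
    between_pairs = between,
    inverted_u = list(pair = c("DorsAttn", "VentAttn"), peak_month = 54,
                      peak_value = 0.18, curvature = 1.2e-4),
    awake_vis_increment = 0.03,
    wave_deltas = list("SomMot|SomMot" = 0.07, "Vis|Vis" = 0.05,
                       "Control|Default" = -0.04, "Limbic|Limbic" = 0.01),
    eta_blocks = list(c("SomMot", "SomMot"), c("SomMot", "VentAttn"),
                      c("SomMot", "Limbic")),
    eta_loading = 0.06,
    subject_block_sd = 0.05,
    edge_noise_sd = 0.05
  )
}

#' Specification of a synthetic longitudinal cohort
#'
#' Bundles every parameter of the three-wave cohort generator: sample size,
#' parcellation, assessment schedule, retention and wave-level missingness,
#' the latent-factor effect sizes coupling baseline connectivity to 12-month
#' behavioral change, behavioral norms, motion by age, and the connectivity
#' profile.
#'
#' @param n_baseline Baseline sample size (default 256).
#' @param n_regions Number of parcellation regions (default 90; 360
#'   supported).
#' @param n_networks Number of networks in the partition (default 7).
#' @param age_range Baseline age range in years, inclusive of the final age
#'   group (default `c(3, 6)`: ages are drawn uniformly over 36-84 months so
#'   the four year-of-age groups are balanced).
#' @param wave_months Assessment offsets in months (default `c(0, 6, 12)`).
#' @param retention Proportion of the baseline sample retained at waves 2
#'   and 3 (default `c(0.887, 0.789)`).
#' @param missing_rates Total wave-level missing fraction (dropout plus item
#'   missingness) at waves 2 and 3 (default `c(0.113, 0.211)`, i.e. at the
#'   default retention all wave-level missingness is attrition).
#' @param effect_size Length-2 numeric (recycled from a scalar): loading of
#'   the scalar latent factor on connectivity (`conn`) and on 12-month
#'   behavioral change (`outcome`), each in \[0, 1\].
#' @param behavior_norms Norm table as returned by
#'   [default_behavior_norms()].
#' @param fd_by_age Mean framewise displacement (mm) per age group 3-6.
#' @param fd_sd_by_age SD of mean FD per age group.
#' @param ses_probs Named probabilities for low/middle/high socioeconomic
#'   status.
#' @param sex_prob_female Probability of female sex.
#' @param conn_profile Connectivity profile list
#'   ([default_connectivity_profile()]).
#' @param trait_loading,occasion_sd Stable-trait loading and occasion noise
#'   SD of the behavioral z-score model (their squares sum to 1 so baseline
#'   scores match the configured norms exactly in distribution).
#' @param baseline_eta_loading Loading of the latent factor on baseline
#'   behavioral z-scores (scaled by `effect_size["outcome"]`).
#' @param change_eta_loading Loading of the latent factor on the 12-month
#'   behavioral z-score change (scaled by `effect_size["outcome"]`).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_baseline = 256, n_regions = 90, n_networks = 7,
                        age_range = c(3, 6), wave_months = c(0, 6, 12),
                        retention = c(0.887, 0.789),
                        missing_rates = c(0.113, 0.211),
                        effect_size = c(conn = 0.5, outcome = 0.5),
                        behavior_norms = default_behavior_norms(),
                        fd_by_age = c(0.32, 0.28, 0.24, 0.21),
                        fd_sd_by_age = c(0.18, 0.15, 0.12, 0.10),
                        ses_probs = c(low = 0.203, middle = 0.551, high = 0.246),
                        sex_prob_female = 0.508,
                        conn_profile = default_connectivity_profile(),
                        trait_loading = 0.8, occasion_sd = 0.6,
                        baseline_eta_loading = 0.25,
                        change_eta_loading = 1.2,
                        seed = 1L) {
  if (length(effect_size) == 1L) effect_size <- c(conn = effect_size, outcome = effect_size)
  if (is.null(names(effect_size)) || !all(c("conn", "outcome") %in% names(effect_size)))
    names(effect_size) <- c("conn", "outcome")
  spec <- list(
    n_baseline = as.integer(n_baseline), n_regions = as.integer(n_regions),
    n_networks = as.integer(n_networks), age_range = age_range,
    wave_months = wave_months, retention = retention,
    missing_rates = missing_rates, effect_size = effect_size,
    behavior_norms = behavior_norms, fd_by_age = fd_by_age,
    fd_sd_by_age = fd_sd_by_age, ses_probs = ses_probs,
    sex_prob_female = sex_prob_female, conn_profile = conn_profile,
    trait_loading = trait_loading, occasion_sd = occasion_sd,
    baseline_eta_loading = baseline_eta_loading,
    change_eta_loading = change_eta_loading,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_baseline < 1L) stop("n_baseline must be positive")
    if (n_networks < 1L || n_regions < n_networks)
      stop("n_regions must divide into a partition with every network nonempty")
    props <- c(retention, missing_rates, effect_size, ses_probs, sex_prob_female)
    if (any(!is.finite(props)) || any(props < 0) || any(props > 1))
      stop("all proportions must lie in [0, 1]")
    if (length(retention) != 2L || diff(retention) > 0)
      stop("retention must be non-increasing across waves")
    if (any(retention <= 0)) stop("retention must lie in (0, 1]")
    if (abs(sum(ses_probs) - 1) > 1e-8) stop("ses_probs must sum to 1")
    if (any(fd_by_age <= 0)) stop("fd_by_age must be positive")
    if (trait_loading^2 + occasion_sd^2 > 1 + 1e-8)
      stop("trait_loading^2 + occasion_sd^2 must not exceed 1")
  })
  invisible(spec)
}

#' Region-to-network partition with contiguous equal blocks
#'
#' @param n_regions Number of regions.
#' @param n_networks Number of networks (default 7).
#' @param names Network labels (default [network_names()]).
#' @return Factor of length `n_regions` assigning each region a network.
#' @export
network_partition <- function(n_regions, n_networks = 7, names = network_names()) {
  if (n_regions < n_networks) stop("every network must be nonempty")
  names <- names[seq_len(n_networks)]
  sizes <- rep(n_regions %/% n_networks, n_networks)
  extra <- n_regions %% n_networks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  factor(rep(names, times = sizes), levels = names)
}
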