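#' Build per-participant feature bundles from a generated cohort
#'
#' Assembles, for every participant with a baseline connectivity matrix, the
#' four model channels: the row-major upper-triangle connectivity vector,
#' the 12 graph metrics of the thresholded baseline graph, and the 16 motor
#' and 12 cognitive baseline scores. Also returns the auxiliary table used
#' for imputation models and stratification.
#'
#' @param cohort Output of [generate_cohort()].
#' @param density Graph threshold density (default 0.15).
#' @param n_null Null-ensemble size per graph (default 50; reduce for large
#'   experiment grids).
#' @param seed Integer seed for community detection / null ensembles.
#' @return List: `bundle` ([feature_bundle()]), `aux` (data.frame with
#'   age_months, age_group, sex, ses, mean_fd, scan_state), `participant`.
#' @export
build_feature_bundles <- function(cohort, density = 0.15, n_null = 50L,
                                  seed = 1L) {
  tab <- cohort$table
  base <- tab[tab$wave == 1L, ]
  have_conn <- vapply(base$participant, function(p) {
    !is.null(cohort$connectivity[[p]]) && length(cohort$connectivity[[p]]) >= 1L &&
      !is.null(cohort$connectivity[[p]][[1L]])
  }, TRUE)
  base <- base[have_conn, ]
  ids <- base$participant
  p_regions <- nrow(cohort$connectivity[[ids[1]]][[1L]])
  conn <- matrix(NA_real_, length(ids), p_regions * (p_regions - 1) / 2)
  graph <- matrix(NA_real_, length(ids), 12L,
                  dimnames = list(NULL, graph_metric_names()))
  for (i in seq_along(ids)) {
    m <- cohort$connectivity[[ids[i]]][[1L]]
    conn[i, ] <- vectorize_upper(m)
    graph[i, ] <- graph_features(m, density = density, n_null = n_null,
                                 seed = seed + i)
  }
  cols <- behavior_feature_columns()
  bundle <- feature_bundle(conn, graph,
                           as.matrix(base[, cols$motor]),
                           as.matrix(base[, cols$cognitive]), ids)
  aux <- base[, c("age_months", "age_group", "sex", "ses", "mean_fd",
                  "scan_state")]
  rownames(aux) <- NULL
  list(bundle = bundle, aux = aux, participant = ids)
}

#' Default feature groups for permutation importance
#'
#' The four channels plus one group per connectivity network block (e.g.
#' `conn:SomMot|SomMot`, `conn:SomMot|VentAttn`), so block-level importance
#' statements are reproducible in kind.
#'
#' @param bundle A [feature_bundle()].
#' @param partition Network partition factor of length P.
#' @return Named list of groups, each `list(channel =, cols =)`.
#' @export
default_feature_groups <- function(bundle, partition) {
  p <- length(partition)
  if (ncol(bundle$conn) != p * (p - 1) / 2)
    stop("partition size inconsistent with connectivity vector")
  groups <- list(
    connectivity = list(channel = "conn", cols = seq_len(ncol(bundle$conn))),
    graph = list(channel = "graph", cols = seq_len(ncol(bundle$graph))),
    motor = list(channel = "motor", cols = seq_len(ncol(bundle$motor))),
    cognitive = list(channel = "cog", cols = seq_len(ncol(bundle$cog)))
  )
  map <- upper_index_map(p, partition)
  for (bl in unique(map$block)) {
    groups[[paste0("conn:", bl)]] <-
      list(channel = "conn", cols = map$pos[map$block == bl])
  }
  groups
}
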