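#' Fixed order of the 12 graph-theory features
#' @return Character vector of length 12.
#' @export
graph_metric_names <- function() {
  c("global_efficiency", "local_efficiency", "clustering_coefficient",
    "characteristic_path_length", "small_worldness", "modularity_q",
    "modularity_z", "participation_mean", "participation_z",
    "within_module_degree_mean", "within_module_degree_z", "hub_score")
}

#' Proportional threshold of a connectivity matrix
#'
#' Zeroes negative weights and the diagonal, then retains the top `density`
#' fraction of the off-diagonal weights (ties broken by fixed index order so
#' the result is deterministic). Proportional thresholding equalizes edge
#' density across subjects, which matters when graph metrics are compared
#' between participants.
#'
#' @param m Symmetric connectivity matrix (unit diagonal allowed).
#' @param density Proportion of possible edges to retain, in (0, 1\].
#' @return Symmetric nonnegative adjacency matrix with zero diagonal and
#'   attributes `density` and (if present on the input) `network`.
#' @export
threshold_graph <- function(m, density = 0.15) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  p <- nrow(m)
  w <- vectorize_upper(m)
  w[w < 0] <- 0
  n_keep <- floor(density * length(w) + 1e-9)
  ord <- order(-w, seq_along(w))
  keep <- ord[seq_len(n_keep)]
  keep <- keep[w[keep] > 0]
  if (length(keep) == 0L) stop("graph is empty after thresholding")
  v <- numeric(length(w))
  v[keep] <- w[keep]
  adj <- unvectorize_upper(v, diag_value = 0)
  dimnames(adj) <- dimnames(m)
  attr(adj, "density") <- density
  attr(adj, "network") <- attr(m, "network")
  adj
}

as_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Weighted Newman modularity of a given partition
#'
#' Direct evaluation of Q = sum_m (w_in_m / W - (s_m / 2W)^2) over modules,
#' with W the total edge weight.
#'
#' @param adj Nonnegative symmetric adjacency matrix, zero diagonal.
#' @param labels Integer/factor module labels per node.
#' @return Scalar Q.
#' @export
modularity_q <- function(adj, labels) {
  labels <- as.integer(factor(labels))
  s <- rowSums(adj)
  w2 <- sum(s)                              # 2W
  if (w2 <= 0) return(0)
  q <- 0
  for (m in unique(labels)) {
    mm <- labels == m
    q <- q + sum(adj[mm, mm]) / w2 - (sum(s[mm]) / w2)^2
  }
  q
}

#' Louvain community partition with fixed seed
#'
#' Greedy weighted modularity maximization; the seed pins igraph's random
#' node sweep order so the labeling is reproducible.
#'
#' @param adj Weighted adjacency matrix (zero diagonal).
#' @param seed Integer seed.
#' @return List with `labels` (integer vector) and `q` (weighted modularity
#'   of the returned partition, evaluated by [modularity_q()]).
#' @export
community_partition <- function(adj, seed = 1L) {
  if (sum(adj) <= 0) stop("graph is empty")
  g <- as_igraph(adj)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  labels <- as.integer(igraph::membership(cl))
  list(labels = labels, q = modularity_q(adj, labels))
}

dist_matrix <- function(adj) {
  # all-pairs shortest paths with edge lengths 1/weight (compiled
  # Floyd-Warshall)
  .fw_dist_cpp(unname(as.matrix(adj)))
}

efficiency_from_dist <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  p <- nrow(d)
  if (p < 2L) return(0)
  sum(inv) / (p * (p - 1L))
}

char_path_length <- function(d, warn = TRUE) {
  off <- d[upper.tri(d)]
  fin <- off[is.finite(off)]
  if (length(fin) < length(off) && warn)
    warning("graph is disconnected; path length computed over finite pairs")
  if (length(fin) == 0L) return(Inf)
  mean(fin)
}

onnela_clustering <- function(adj) {
  k <- rowSums(adj > 0)
  wmax <- max(adj)
  if (wmax <= 0) return(0)
  w13 <- (adj / wmax)^(1 / 3)
  cyc <- diag(w13 %*% w13 %*% w13)
  ci <- ifelse(k >= 2, cyc / pmax(k * (k - 1), 1), 0)
  mean(ci)
}

local_efficiency <- function(adj) {
  .local_eff_cpp(unname(as.matrix(adj)))
}

node_module_stats <- function(adj, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  ind <- matrix(0, nrow(adj), k)
  ind[cbind(seq_len(nrow(adj)), labels)] <- 1
  kap <- adj %*% ind                       # strength into each module
  s <- rowSums(adj)
  frac <- kap / ifelse(s > 0, s, 1)
  participation <- ifelse(s > 0, 1 - rowSums(frac^2), 0)
  within <- kap[cbind(seq_len(nrow(adj)), labels)]
  within_frac <- ifelse(s > 0, within / s, 0)
  z <- numeric(nrow(adj))
  for (m in seq_len(k)) {
    mm <- labels == m
    mu <- mean(within[mm]); sg <- stats::sd(within[mm])
    z[mm] <- if (is.na(sg) || sg <= 0) 0 else (within[mm] - mu) / sg
  }
  list(participation = participation, within_frac = within_frac, wmd_z = z)
}

rewired_null <- function(g, weights, p) {
  # degree-preserving rewire of the binary structure, observed weights
  # shuffled onto the rewired edges; returns the graph and dense adjacency
  ne <- length(weights)
  rw <- igraph::rewire(g, igraph::keeping_degseq(niter = max(5L * ne, 100L)))
  wshuf <- sample(weights)
  igraph::E(rw)$weight <- wshuf
  el <- igraph::as_edgelist(rw, names = FALSE)
  na <- matrix(0, p, p)
  na[el] <- wshuf
  na[el[, 2:1]] <- wshuf
  list(graph = rw, adj = na)
}

#' Twelve scalar graph-theory features with null-ensemble normalization
#'
#' Computes the fixed 12-entry feature vector of a weighted graph: global
#' efficiency (mean inverse shortest-path distance with lengths 1/weight,
#' disconnected pairs contributing zero), local efficiency (mean
#' neighbor-subgraph efficiency), mean Onnela weighted clustering,
#' characteristic path length (mean finite distance, with a warning when
#' disconnected), small-worldness (C/C_null)/(L/L_null), weighted modularity
#' Q of the supplied partition, mean participation coefficient, mean
#' within-module degree fraction, their null-ensemble z-scores, and the hub
#' score (fraction of nodes with nodal within-module-degree z above 1).
#'
#' The null ensemble consists of `n_null` degree-sequence-preserving edge
#' rewirings with the observed weights shuffled onto the rewired edges; each
#' null graph is re-partitioned by Louvain before its modularity,
#' participation and within-module statistics are taken. A zero null SD
#' yields a z of 0 with a warning.
#'
#' @param adj Thresholded adjacency matrix ([threshold_graph()]).
#' @param labels Module labels (default: [community_partition()] at `seed`).
#' @param n_null Null-ensemble size (minimum 10, default 50).
#' @param seed Integer seed controlling partition and ensemble.
#' @param keep_nulls If TRUE, attach the list of null adjacency matrices and
#'   their per-null statistics as attributes (used by oracle tests).
#' @return Named numeric vector of length 12 in [graph_metric_names()]
#'   order.
#' @export
global_metrics <- function(adj, labels = NULL, n_null = 50L, seed = 1L,
                           keep_nulls = FALSE) {
  if (n_null < 10L) stop("n_null must be at least 10")
  if (is.null(labels)) labels <- community_partition(adj, seed)$labels
  d <- dist_matrix(adj)
  ge <- efficiency_from_dist(d)
  cpl <- char_path_length(d)
  cc <- onnela_clustering(adj)
  le <- local_efficiency(adj)
  q <- modularity_q(adj, labels)
  ns <- node_module_stats(adj, labels)
  set.seed(seed + 1L)
  g_obs <- as_igraph(adj)
  w_obs <- igraph::E(g_obs)$weight
  null_stats <- matrix(NA_real_, n_null, 4,
                       dimnames = list(NULL, c("C", "L", "Q", "P")))
  null_wmd <- numeric(n_null)
  nulls <- if (keep_nulls) vector("list", n_null) else NULL
  null_labels <- if (keep_nulls) vector("list", n_null) else NULL
  for (b in seq_len(n_null)) {
    nul <- rewired_null(g_obs, w_obs, nrow(adj))
    na <- nul$adj
    nl <- as.integer(igraph::membership(igraph::cluster_louvain(nul$graph)))
    nstats <- node_module_stats(na, nl)
    dn <- dist_matrix(na)
    null_stats[b, ] <- c(onnela_clustering(na), char_path_length(dn, warn = FALSE),
                         modularity_q(na, nl), mean(nstats$participation))
    null_wmd[b] <- mean(nstats$within_frac)
    if (keep_nulls) {
      nulls[[b]] <- na
      null_labels[[b]] <- nl
    }
  }
  zscore <- function(obs, nullv) {
    sg <- stats::sd(nullv)
    if (is.na(sg) || sg <= .Machine$double.eps^0.5) {
      warning("zero null SD; z-score reported as 0")
      return(0)
    }
    (obs - mean(nullv)) / sg
  }
  sw <- (cc / mean(null_stats[, "C"])) / (cpl / mean(null_stats[, "L"]))
  out <- c(
    global_efficiency = ge,
    local_efficiency = le,
    clustering_coefficient = cc,
    characteristic_path_length = cpl,
    small_worldness = sw,
    modularity_q = q,
    modularity_z = zscore(q, null_stats[, "Q"]),
    participation_mean = mean(ns$participation),
    participation_z = zscore(mean(ns$participation), null_stats[, "P"]),
    within_module_degree_mean = mean(ns$within_frac),
    within_module_degree_z = zscore(mean(ns$within_frac), null_wmd),
    hub_score = mean(ns$wmd_z > 1)
  )
  if (keep_nulls) {
    attr(out, "nulls") <- nulls
    attr(out, "null_labels") <- null_labels
    attr(out, "null_stats") <- cbind(null_stats, WMD = null_wmd)
    attr(out, "labels") <- labels
  }
  out
}

#' Graph feature vector straight from a connectivity matrix
#'
#' Convenience wrapper: proportional threshold, Louvain partition, then
#' [global_metrics()].
#'
#' @inheritParams global_metrics
#' @param m Connectivity matrix.
#' @param density Threshold density (default 0.15).
#' @return Named numeric vector of length 12.
#' @export
graph_features <- function(m, density = 0.15, n_null = 50L, seed = 1L) {
  adj <- threshold_graph(m, density)
  part <- community_partition(adj, seed)
  global_metrics(adj, labels = part$labels, n_null = n_null, seed = seed)
}
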