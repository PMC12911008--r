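# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's implementations: shortest paths by exhaustive
# relaxation, modularity/participation by direct summation, AUC by pair
# enumeration, partial correlation by explicit residualization.

# all-pairs shortest paths on lengths 1/w by Bellman-Ford relaxation
oracle_dist <- function(adj) {
  p <- nrow(adj)
  len <- ifelse(adj > 0, 1 / adj, Inf)
  d <- len
  diag(d) <- 0
  for (rep in seq_len(p)) {
    changed <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) {
      for (k in seq_len(p)) {
        if (is.finite(d[i, k]) && is.finite(len[k, j]) &&
            d[i, k] + len[k, j] < d[i, j] - 1e-15) {
          d[i, j] <- d[i, k] + len[k, j]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

oracle_global_eff <- function(adj) {
  d <- oracle_dist(adj)
  p <- nrow(adj)
  s <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  }
  s / (p * (p - 1))
}

oracle_cpl <- function(adj) {
  d <- oracle_dist(adj)
  vals <- c()
  p <- nrow(adj)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (is.finite(d[i, j])) vals <- c(vals, d[i, j])
  }
  mean(vals)
}

oracle_onnela <- function(adj) {
  p <- nrow(adj)
  wmax <- max(adj)
  ci <- numeric(p)
  for (i in seq_len(p)) {
    k <- sum(adj[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(p)) for (h in seq_len(p)) {
      if (j != i && h != i && j != h)
        s <- s + (adj[i, j] / wmax * adj[i, h] / wmax * adj[j, h] / wmax)^(1 / 3)
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

oracle_local_eff <- function(adj) {
  p <- nrow(adj)
  vals <- numeric(p)
  for (i in seq_len(p)) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) next
    vals[i] <- oracle_global_eff(adj[nb, nb, drop = FALSE])
  }
  mean(vals)
}

oracle_modularity <- function(adj, labels) {
  labels <- as.integer(factor(labels))
  p <- nrow(adj)
  s <- rowSums(adj)
  w2 <- sum(s)
  q <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (labels[i] == labels[j])
      q <- q + adj[i, j] / w2 - s[i] * s[j] / w2^2
  }
  q
}

oracle_participation <- function(adj, labels) {
  labels <- as.integer(factor(labels))
  p <- nrow(adj)
  out <- numeric(p)
  for (i in seq_len(p)) {
    s <- sum(adj[i, ])
    if (s <= 0) next
    acc <- 0
    for (m in unique(labels)) acc <- acc + (sum(adj[i, labels == m]) / s)^2
    out[i] <- 1 - acc
  }
  out
}

oracle_within_frac <- function(adj, labels) {
  labels <- as.integer(factor(labels))
  p <- nrow(adj)
  out <- numeric(p)
  for (i in seq_len(p)) {
    s <- sum(adj[i, ])
    if (s > 0) out[i] <- sum(adj[i, labels == labels[i]]) / s
  }
  out
}

oracle_wmd_z <- function(adj, labels) {
  labels <- as.integer(factor(labels))
  p <- nrow(adj)
  within <- vapply(seq_len(p), function(i) sum(adj[i, labels == labels[i]]),
                   numeric(1))
  z <- numeric(p)
  for (m in unique(labels)) {
    mm <- labels == m
    sg <- stats::sd(within[mm])
    z[mm] <- if (is.na(sg) || sg <= 0) 0 else (within[mm] - mean(within[mm])) / sg
  }
  z
}

# the seven partition/distance metrics, by brute force, in package order
oracle_core_metrics <- function(adj, labels) {
  c(global_efficiency = oracle_global_eff(adj),
    local_efficiency = oracle_local_eff(adj),
    clustering_coefficient = oracle_onnela(adj),
    characteristic_path_length = oracle_cpl(adj),
    modularity_q = oracle_modularity(adj, labels),
    participation_mean = mean(oracle_participation(adj, labels)),
    within_module_degree_mean = mean(oracle_within_frac(adj, labels)),
    hub_score = mean(oracle_wmd_z(adj, labels) > 1))
}

# AUC by exhaustive enumeration of positive/negative pairs (ties count half)
oracle_auc <- function(y, p) {
  pos <- which(y == 1); neg <- which(y == 0)
  s <- 0
  for (i in pos) for (j in neg) {
    s <- s + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
  }
  s / (length(pos) * length(neg))
}

# partial correlation by explicit residualization against lm()
oracle_partial_cor <- function(x, y, covariates) {
  d <- as.data.frame(covariates)
  rx <- stats::resid(stats::lm(x ~ ., data = d))
  ry <- stats::resid(stats::lm(y ~ ., data = d))
  stats::cor(rx, ry)
}

# P(X > 1, Y > 1) for standard bivariate normal with correlation rho,
# by one-dimensional numerical integration
oracle_orthant_upper <- function(rho) {
  if (rho >= 1 - 1e-12) return(1 - stats::pnorm(1))
  f <- function(x) stats::dnorm(x) *
    (1 - stats::pnorm((1 - rho * x) / sqrt(1 - rho^2)))
  stats::integrate(f, 1, Inf, rel.tol = 1e-10)$value
}

# deterministic small weighted graphs for the oracle suite
fixture_graphs <- function() {
  gs <- list()
  set.seed(88)
  for (p in c(5L, 6L, 8L)) {
    m <- matrix(0, p, p)
    ut <- upper.tri(m)
    w <- stats::runif(sum(ut), 0.1, 1)
    w[sample(length(w), floor(length(w) * 0.3))] <- 0   # some absent edges
    m[ut] <- w
    m <- m + t(m)
    gs[[paste0("random", p)]] <- m
  }
  # two 5-cliques joined by a single bridge edge
  cl <- matrix(0, 10, 10)
  cl[1:5, 1:5] <- 1; cl[6:10, 6:10] <- 1
  diag(cl) <- 0
  cl[5, 6] <- cl[6, 5] <- 0.5
  gs$two_cliques <- cl
  # complete K5, unit weights
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  gs$k5 <- k5
  gs
}

# quick synthetic feature bundle with a linearly separable signal
separable_bundle <- function(n = 200, L = 500, shift = 1, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  conn <- matrix(stats::rnorm(n * L), n, L)
  conn[y == 1, 1:50] <- conn[y == 1, 1:50] + shift
  graph <- matrix(stats::rnorm(n * 12), n, 12)
  graph[, 1] <- graph[, 1] + shift * y
  motor <- matrix(stats::rnorm(n * 16), n, 16)
  cog <- matrix(stats::rnorm(n * 12), n, 12)
  list(bundle = feature_bundle(conn, graph, motor, cog, seq_len(n)), y = y)
}

# small model configuration for unit tests (fast, CPU-friendly)
tiny_model_config <- function(variant = "multimodal", seed = 1L,
                              max_epochs = 30L, early_stop_patience = 6L,
                              ...) {
  model_config(variant = variant, conv_filters = 8L, conv_kernel = 7L,
               conv_stride = 7L, pool_size = 4L, conv_to_dense = 16L,
               fusion_widths = c(32L, 16L, 8L), max_epochs = max_epochs,
               early_stop_patience = early_stop_patience,
               learning_rate = 0.003, dropout_rate = 0.2, seed = seed, ...)
}
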