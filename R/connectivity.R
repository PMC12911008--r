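#' Pearson functional connectivity matrix from region time series
#'
#' Computes the region-by-region Pearson correlation matrix of a
#' region-by-time matrix. A constant (zero-variance) region is a hard error
#' naming the offending region rather than a silent NaN, since NaN entries
#' poison every downstream graph metric.
#'
#' @param timeseries P x T numeric matrix (regions in rows).
#' @param fisher_z If TRUE, apply the Fisher z-transform (`atanh`)
#'   elementwise and mask the diagonal with NA. Off by default: the modeling
#'   pipeline consumes raw correlations.
#' @return P x P connectivity matrix; any `network`/dimnames attributes of
#'   the input rows are carried through dimnames.
#' @export
fc_matrix <- function(timeseries, fisher_z = FALSE) {
  if (!is.matrix(timeseries)) stop("timeseries must be a matrix")
  if (ncol(timeseries) < 3L) stop("need at least 3 timepoints")
  v <- apply(timeseries, 1L, stats::var)
  if (any(v <= .Machine$double.eps)) {
    bad <- which(v <= .Machine$double.eps)
    lab <- rownames(timeseries)[bad] %||% as.character(bad)
    stop("constant time series for region(s): ", paste(lab, collapse = ", "))
  }
  m <- stats::cor(t(timeseries))
  if (fisher_z) {
    m <- suppressWarnings(atanh(pmax(pmin(m, 1 - 1e-15), -1 + 1e-15)))
    diag(m) <- NA_real_
  } else {
    diag(m) <- 1
  }
  m
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Extracts the strict upper triangle in row-major order (pairs (i, j) with
#' i < j, sorted by i then j). This order is fixed and shared with
#' [upper_index_map()] so feature-group bookkeeping (e.g. which vector
#' positions belong to a given network block) stays consistent everywhere.
#'
#' @param m Square symmetric matrix.
#' @return Numeric vector of length `P*(P-1)/2`.
#' @export
vectorize_upper <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  t(m)[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is set to `diag_value`.
#'
#' @param v Vector of length `P*(P-1)/2`.
#' @param diag_value Diagonal fill (default 1).
#' @return P x P symmetric matrix.
#' @export
unvectorize_upper <- function(v, diag_value = 1) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(p - round(p)) > 1e-8) stop("vector length is not P*(P-1)/2")
  p <- as.integer(round(p))
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- v
  m <- t(m)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Index map for the row-major upper-triangle vectorization
#'
#' @param p Number of regions.
#' @param partition Optional network partition factor of length `p`; adds a
#'   `block` label per edge ("A|B", names sorted).
#' @return data.frame with columns `pos`, `i`, `j` (and `block`).
#' @export
upper_index_map <- function(p, partition = NULL) {
  i <- rep(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(a) (a + 1L):p))
  out <- data.frame(pos = seq_along(i), i = i, j = j)
  if (!is.null(partition)) {
    a <- as.character(partition[i]); b <- as.character(partition[j])
    out$block <- ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
  }
  out
}

#' Motion quality-control filter
#'
#' Excludes scans with mean framewise displacement above 0.5 mm or more than
#' 20% of volumes above the 0.5 mm threshold. Both inequalities are strict:
#' a record exactly at a boundary is retained.
#'
#' @param mean_fd Numeric vector of mean FD (mm).
#' @param prop_over Proportion of volumes with FD above threshold.
#' @param fd_limit,prop_limit Exclusion thresholds (defaults 0.5 mm, 0.20).
#' @return List with `retained` and `excluded` index vectors and a
#'   data.frame `reasons` (index, reason) for each exclusion.
#' @export
qc_filter <- function(mean_fd, prop_over, fd_limit = 0.5, prop_limit = 0.20) {
  if (length(mean_fd) != length(prop_over)) stop("inputs must have equal length")
  if (any(mean_fd < 0) || any(prop_over < 0) || any(prop_over > 1))
    stop("mean_fd must be nonnegative and prop_over in [0, 1]")
  fd_bad <- mean_fd > fd_limit
  pv_bad <- prop_over > prop_limit
  excl <- which(fd_bad | pv_bad)
  reason <- ifelse(fd_bad[excl] & pv_bad[excl], "mean-FD and volume proportion",
                   ifelse(fd_bad[excl], "mean-FD", "volume proportion"))
  list(retained = setdiff(seq_along(mean_fd), excl), excluded = excl,
       reasons = data.frame(index = excl, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Write / read a dense connectivity matrix with a sidecar label file
#'
#' Plain-text I/O for connectivity matrices: a whitespace-delimited dense
#' matrix plus `<path>.labels.tsv` holding region labels and network
#' assignment, so the partition survives a round trip.
#'
#' @param m Connectivity matrix with optional `network` attribute.
#' @param path Output path for the matrix file.
#' @export
write_conn_matrix <- function(m, path) {
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  net <- attr(m, "network")
  lab <- data.frame(region = rownames(m) %||% paste0("R", seq_len(nrow(m))),
                    network = if (is.null(net)) NA else as.character(net))
  utils::write.table(lab, paste0(path, ".labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' @rdname write_conn_matrix
#' @param path Path written by [write_conn_matrix()].
#' @return The matrix with dimnames and `network` attribute restored.
#' @export
read_conn_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  lab <- utils::read.table(paste0(path, ".labels.tsv"), sep = "\t", header = TRUE)
  dimnames(m) <- list(lab$region, lab$region)
  if (!all(is.na(lab$network)))
    attr(m, "network") <- factor(lab$network, levels = unique(lab$network))
  m
}
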