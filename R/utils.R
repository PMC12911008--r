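#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out of one master seed into per-stage seeds so that
#' pipeline stages are individually reproducible without seed collisions.
#' The result is always a valid 32-bit integer seed.
#'
#' @param master Integer master seed.
#' @param stage Stage index (1-based) or stage name registered in
#'   [pipeline_stages()].
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage) {
  if (is.character(stage)) {
    stage <- match(stage, pipeline_stages())
    if (is.na(stage)) stop("unknown pipeline stage")
  }
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  # multiplicative hash mod a Mersenne prime keeps seeds < 2^31
  as.integer((abs(master) * 7919 + stage * 104729) %% 2147483647)
}

#' Ordered names of the pipeline stages
#' @return Character vector of stage names in execution order.
#' @export
pipeline_stages <- function() {
  c("simulate", "features", "composites", "cv", "importance",
    "trajectories", "report")
}

round_half_up <- function(x) floor(x + 0.5)

#' Nearest positive-definite repair of a symmetric matrix
#'
#' Clips negative eigenvalues to a small positive floor and rescales back to
#' a unit diagonal. Used when a target correlation matrix handed to the
#' time-series sampler is numerically indefinite.
#'
#' @param m Symmetric matrix.
#' @param eps Eigenvalue floor.
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @keywords internal
nearest_pd <- function(m, eps = 1e-8) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Benjamini-Hochberg adjustment
#'
#' Thin, named wrapper over [stats::p.adjust()] so contrast tables carry an
#' explicit FDR column.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

`%||%` <- function(a, b) if (is.null(a)) b else a
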