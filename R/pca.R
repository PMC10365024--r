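#' Z-scale edge weights across samples
#'
#' Standardizes every edge (row) across the cohort so that each edge has
#' mean 0 and standard deviation 1 (divisor N - 1). This puts all edges on
#' a common scale before PCA, so that edges with large absolute weights do
#' not dominate the decomposition. Edges that are constant across samples
#' carry no information and cannot be standardized; they are dropped and
#' their count reported in the `n_dropped` attribute.
#'
#' @param x Numeric matrix, edges x samples, N >= 3 samples.
#' @return The scaled matrix (possibly with fewer rows), with attribute
#'   `n_dropped` giving the number of zero-variance edges removed.
#' @examples
#' zscale_edges(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
zscale_edges <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 3L) .input_error("z-scaling requires at least 3 samples")
  if (anyNA(x)) .input_error("missing values in edge weights")
  xc <- x - rowMeans(x)
  s <- sqrt(rowSums(xc * xc) / (n - 1L))
  keep <- s > 0
  if (!any(keep)) {
    .degenerate("all edges have zero variance across samples")
  }
  out <- xc[keep, , drop = FALSE] / s[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Shared SVD of the sample-space view of a scaled edge matrix.
# Samples are the observations (rows of y), edges the variables; columns
# are centered (a no-op after zscale_edges, but kept for generality).
# Returns u, d, v restricted to k components plus the full spectrum d.
.sample_svd <- function(x, k) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) .input_error("need at least 2 edges for PCA")
  if (ncol(x) < 3L) .input_error("need at least 3 samples for PCA")
  y <- t(x)
  y <- y - rep(colMeans(y), each = nrow(y))
  sv <- svd(y, nu = k, nv = k)
  tot <- sum(sv$d^2)
  if (tot <= 0) .degenerate("rank-0 matrix: no variance to decompose")
  rank <- sum(sv$d > max(dim(y)) * .Machine$double.eps * sv$d[1L])
  if (rank < k) {
    .degenerate(sprintf("matrix rank %d < %d requested components", rank, k))
  }
  # Sign convention: within each component, the loading of largest
  # magnitude is positive; scores are flipped together with loadings.
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  list(u = sv$u, d = sv$d, v = sv$v, total = tot,
       edge_names = rownames(x), sample_names = colnames(x))
}

# Fast path used inside the permutation loop: PC1 variance fraction only.
.pc1_fraction <- function(x) {
  y <- t(as.matrix(x))
  y <- y - rep(colMeans(y), each = nrow(y))
  d2 <- svd(y, nu = 0, nv = 0)$d^2
  tot <- sum(d2)
  if (tot <= 0) .degenerate("rank-0 matrix: no variance to decompose")
  d2[1L] / tot
}

#' First-principal-component variance fraction of a scaled edge matrix
#'
#' The test statistic of the heterogeneity scan. Samples are treated as
#' observations in edge space and the covariance spectrum is computed by
#' singular value decomposition; the returned fraction is the leading
#' eigenvalue over the sum of all eigenvalues. With fewer samples than
#' edges there are at most N - 1 nonzero eigenvalues; no truncation
#' correction is applied.
#'
#' @param x Scaled matrix from [zscale_edges()] (edges x samples),
#'   at least 2 edges and 3 samples.
#' @return A list with `fraction` (in (0, 1]), `loadings` (unit-norm first
#'   eigenvector over edges, sign-fixed so its largest-magnitude entry is
#'   positive), and `scores` (sample projections onto it, mean 0).
#' @export
pc1_variance_fraction <- function(x) {
  sv <- .sample_svd(x, k = 1L)
  list(
    fraction = sv$d[1L]^2 / sv$total,
    loadings = stats::setNames(sv$v[, 1L], sv$edge_names),
    scores = stats::setNames(sv$u[, 1L] * sv$d[1L], sv$sample_names)
  )
}
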