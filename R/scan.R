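#' Extract the regulatory edges connected to a gene set
#'
#' Returns the rows of the cohort edge matrix whose TARGET gene belongs to
#' the given set — i.e. all incoming regulatory edges, from every TF, of
#' every matched gene. Pathway genes absent from the network are ignored.
#' Row order is deterministic: gene-major in the order genes appear in the
#' matrix, with TF order as in the matrix within each gene.
#'
#' @param m An [edge_matrix].
#' @param genes Character vector of target-gene identifiers.
#' @return The edge x sample weight sub-matrix, with attributes
#'   `matched_genes` (character) and `n_matched`.
#' @export
extract_pathway_edges <- function(m, genes) {
  stopifnot(inherits(m, "edge_matrix"))
  matched <- m$genes[m$genes %in% genes]
  if (length(matched) == 0L) {
    .empty_overlap("no pathway gene occurs among the network's target genes")
  }
  rows <- unlist(m$gene_rows[matched], use.names = FALSE)
  out <- m$weights[rows, , drop = FALSE]
  attr(out, "matched_genes") <- matched
  attr(out, "n_matched") <- length(matched)
  out
}

#' Permutation null distribution of the PC1 variance fraction
#'
#' Draws `n_perm` random gene sets of the given size (without replacement
#' within a set) from the sampling universe, and for each set extracts the
#' connected edges, z-scales them and computes the PC1 variance fraction.
#' The universe is the intersection of the collection's gene universe with
#' the network's target genes: edges exist only for network genes, and
#' sampling unmatched genes would silently shrink the null sets.
#'
#' @param m An [edge_matrix].
#' @param collection A [pathway_collection] (defines the gene universe).
#' @param set_size Number of genes per random set.
#' @param n_perm Number of random sets (default 1000).
#' @param seed Integer RNG seed; equal seeds and sizes give identical
#'   vectors regardless of which pathway requested the null.
#' @return Numeric vector of `n_perm` PC1 variance fractions.
#' @export
null_pc1_distribution <- function(m, collection, set_size, n_perm = 1000L,
                                  seed = 1L) {
  stopifnot(inherits(m, "edge_matrix"), inherits(collection, "pathway_collection"))
  if (!.is_count(set_size) || set_size < 1) .input_error("set_size must be a positive count")
  if (!.is_count(n_perm) || n_perm < 2) .input_error("n_perm must be >= 2")
  universe <- sort(intersect(collection$universe, m$genes))
  if (length(universe) < set_size) {
    .input_error(sprintf(
      "sampling universe (%d genes shared by collection and network) smaller than set_size %d",
      length(universe), set_size))
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  vapply(seq_len(n_perm), function(i) {
    g <- sample(universe, set_size)
    .pc1_fraction(zscale_edges(extract_pathway_edges(m, g)))
  }, 0)
}

# Save/restore the global RNG state around a seeded computation.
.Random.seed_guard <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' One-tailed t-test p-value of an observed PC1 fraction against its null
#'
#' Implemented as a one-sample Student t-test of the permutation null
#' vector against mu = observed, with alternative "null mean < observed":
#' t = (observed - mean(null)) / (sd(null) / sqrt(n)), and p is the upper
#' tail of the t distribution with n - 1 degrees of freedom. Small values
#' mean the observed fraction exceeds what random gene sets of the same
#' size achieve. The empirical alternative (#\{null >= observed\} + 1) /
#' (n + 1) is available for users who prefer a pure permutation p-value.
#'
#' @param observed Observed PC1 variance fraction.
#' @param null Numeric vector of null fractions (length >= 2, sd > 0).
#' @param method `"ttest"` (default) or `"empirical"`.
#' @return A p-value in (0, 1).
#' @export
heterogeneity_pvalue <- function(observed, null, method = c("ttest", "empirical")) {
  method <- match.arg(method)
  stopifnot(is.numeric(observed), length(observed) == 1L, is.numeric(null))
  n <- length(null)
  if (n < 2L) .input_error("null vector must have length >= 2")
  s <- stats::sd(null)
  if (!is.finite(s) || s <= 0) .degenerate("degenerate null: zero standard deviation")
  if (method == "empirical") {
    return((sum(null >= observed) + 1) / (n + 1))
  }
  t <- (observed - mean(null)) / (s / sqrt(n))
  stats::pt(t, df = n - 1L, lower.tail = FALSE)
}

#' Cohen's d effect size of an observed fraction against a permutation null
#'
#' d = (observed - mean(null)) / sd(null), with sd using divisor n - 1.
#' The value is signed: positive when the observed PC1 variance fraction
#' exceeds the null mean, so that downstream effect-size gates only pass
#' excess-variance pathways.
#'
#' @inheritParams heterogeneity_pvalue
#' @return Signed effect size.
#' @export
cohens_d <- function(observed, null) {
  stopifnot(is.numeric(observed), length(observed) == 1L, is.numeric(null))
  if (length(null) < 2L) .input_error("null vector must have length >= 2")
  s <- stats::sd(null)
  if (!is.finite(s) || s <= 0) .degenerate("degenerate null: zero standard deviation")
  (observed - mean(null)) / s
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate adjustment, returned in input
#' order. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    .input_error("p-values must be numbers in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric overlap test between two pathway sets
#'
#' Upper-tail probability P(X >= n_overlap) that two sets of sizes
#' `n_set_a` and `n_set_b`, drawn from a universe of `n_universe`
#' pathways, share at least `n_overlap` members by chance. Computed in
#' log space so extreme tails (p ~ 1e-30) do not underflow intermediate
#' terms. Used to test whether significant-pathway sets found in two
#' independent cohorts overlap more than expected.
#'
#' @param n_universe Size of the pathway universe.
#' @param n_set_a,n_set_b Sizes of the two sets.
#' @param n_overlap Observed overlap.
#' @param log.p Return the natural-log probability instead.
#' @return The tail probability (or its log).
#' @examples
#' overlap_significance(1455, 72, 91, 37)
#' @export
overlap_significance <- function(n_universe, n_set_a, n_set_b, n_overlap,
                                 log.p = FALSE) {
  for (v in list(n_universe, n_set_a, n_set_b, n_overlap)) {
    if (!.is_count(v)) .input_error("all counts must be non-negative integers")
  }
  if (n_set_a > n_universe || n_set_b > n_universe ||
      n_overlap > min(n_set_a, n_set_b)) {
    .input_error("inconsistent counts: need n_overlap <= min(set sizes) <= universe")
  }
  lp <- stats::phyper(n_overlap - 1, n_set_a, n_universe - n_set_a, n_set_b,
                      lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}
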