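#' Principal-component decomposition of one pathway's edges
#'
#' Convenience wrapper used by the interpretation layer and the CLI:
#' extracts the pathway's edges, z-scales them and computes the requested
#' number of leading components.
#'
#' @param m An [edge_matrix].
#' @param genes Character vector of the pathway's genes.
#' @param n_components Number of leading components (1 or 2).
#' @return List with `var_fractions`, `loadings` (edges x components),
#'   `scores` (samples x components), `edge_ids` (data frame tf, gene),
#'   `n_matched`, `n_dropped`.
#' @export
pathway_decomposition <- function(m, genes, n_components = 1L) {
  sub <- extract_pathway_edges(m, genes)
  scaled <- zscale_edges(sub)
  sv <- .sample_svd(scaled, k = n_components)
  ids <- do.call(rbind, strsplit(rownames(scaled), "\t", fixed = TRUE))
  list(
    var_fractions = sv$d[seq_len(n_components)]^2 / sv$total,
    loadings = matrix(sv$v[, seq_len(n_components)], ncol = n_components,
                      dimnames = list(rownames(scaled),
                                      paste0("pc", seq_len(n_components)))),
    scores = matrix(sv$u[, seq_len(n_components)] *
                      rep(sv$d[seq_len(n_components)], each = nrow(sv$u)),
                    ncol = n_components,
                    dimnames = list(colnames(scaled),
                                    paste0("pc", seq_len(n_components)))),
    edge_ids = data.frame(tf = ids[, 1L], gene = ids[, 2L],
                          stringsAsFactors = FALSE),
    n_matched = attr(sub, "n_matched"),
    n_dropped = attr(scaled, "n_dropped")
  )
}

#' Edge contribution profile of a pathway's first principal component
#'
#' The PC1 loading of each edge is its contribution score. Because the
#' loadings are a unit vector, the expected score under equal contribution
#' of all E edges is 1/sqrt(E); edges whose absolute loading exceeds 1.5x
#' this expected score are flagged as top contributors. TFs are then
#' grouped by how many of their edges are top contributors, and TFs with a
#' target count above the 95th percentile (computed over TFs having at
#' least one top edge, with linear interpolation) are labelled.
#'
#' Absolute loadings are used throughout: eigenvector signs are arbitrary,
#' so the top-edge set is invariant under a global sign flip.
#'
#' @param loadings Unit-norm numeric vector of PC1 loadings.
#' @param edge_ids Data frame with columns `tf` and `gene`, one row per
#'   loading, in the same order.
#' @return An object of class `contribution_profile`: list with `edges`
#'   (data frame tf, gene, loading, is_top), `expected_score`,
#'   `tf_target_counts` (named vector over TFs with >= 1 top edge) and
#'   `tf_labels`.
#' @export
edge_contributions <- function(loadings, edge_ids) {
  loadings <- as.numeric(loadings)
  if (!is.data.frame(edge_ids) || !all(c("tf", "gene") %in% names(edge_ids)) ||
      nrow(edge_ids) != length(loadings)) {
    .input_error("edge_ids must be a data frame (tf, gene) matching loadings")
  }
  nrm <- sqrt(sum(loadings^2))
  if (abs(nrm - 1) > 1e-6) {
    .input_error(sprintf("loadings are not unit-norm (|norm - 1| = %.3g)",
                         abs(nrm - 1)))
  }
  e <- length(loadings)
  expected <- 1 / sqrt(e)
  is_top <- abs(loadings) > 1.5 * expected
  counts <- if (any(is_top)) {
    tb <- table(edge_ids$tf[is_top])
    stats::setNames(as.integer(tb), names(tb))
  } else {
    stats::setNames(integer(0), character(0))
  }
  labels <- if (length(counts) > 0L) {
    q95 <- stats::quantile(counts, probs = 0.95, type = 7, names = FALSE)
    names(counts)[counts > q95]
  } else {
    character(0)
  }
  structure(list(
    edges = data.frame(tf = edge_ids$tf, gene = edge_ids$gene,
                       loading = loadings, is_top = is_top,
                       stringsAsFactors = FALSE),
    expected_score = expected,
    tf_target_counts = counts,
    tf_labels = labels
  ), class = "contribution_profile")
}

#' @export
print.contribution_profile <- function(x, ...) {
  cat(sprintf("contribution_profile: %d edges, expected score %.4g, %d top edges, %d labelled TFs\n",
              nrow(x$edges), x$expected_score, sum(x$edges$is_top),
              length(x$tf_labels)))
  invisible(x)
}

#' Summarize top-contributing edges by target gene
#'
#' Aggregates a contribution profile's top edges per target gene: how many
#' top edges point to the gene and the largest absolute loading among
#' them. Sorted by descending top-edge count, then descending maximum
#' absolute loading, then gene name.
#'
#' @param profile A [edge_contributions()] result.
#' @return Data frame with columns `gene`, `n_top_edges`, `max_abs_loading`
#'   (zero rows when the profile has no top edges).
#' @export
gene_contribution_summary <- function(profile) {
  stopifnot(inherits(profile, "contribution_profile"))
  top <- profile$edges[profile$edges$is_top, , drop = FALSE]
  if (nrow(top) == 0L) {
    return(data.frame(gene = character(), n_top_edges = integer(),
                      max_abs_loading = double(), stringsAsFactors = FALSE))
  }
  agg <- lapply(split(abs(top$loading), top$gene), function(v) {
    c(n = length(v), mx = max(v))
  })
  out <- data.frame(gene = names(agg),
                    n_top_edges = vapply(agg, `[[`, 0, "n"),
                    max_abs_loading = vapply(agg, `[[`, 0, "mx"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_top_edges, -out$max_abs_loading, out$gene,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample pathway heterogeneity scores
#'
#' Each pathway separates the cohort along its leading principal
#' components; a sample's coordinates on those axes are its pathway-based
#' heterogeneity scores, the basis for subtype clustering, covariate
#' association and survival modelling. Scores are projections of the
#' centered samples onto the leading eigenvectors, so each component has
#' mean 0 and components are mutually orthogonal; signs follow the same
#' convention as [pc1_variance_fraction()].
#'
#' @param scaled Scaled edge matrix from [zscale_edges()].
#' @param n_components 1 or 2.
#' @param pathway Optional pathway name recorded on the result.
#' @return An object of class `heterogeneity_scores`: a data frame with
#'   columns `sample`, `pc1` (and `pc2`), plus attributes `pathway` and
#'   `var_fractions`.
#' @export
patient_scores <- function(scaled, n_components = 1L, pathway = NULL) {
  if (!n_components %in% c(1L, 2L)) .input_error("n_components must be 1 or 2")
  sv <- .sample_svd(scaled, k = n_components)
  out <- data.frame(sample = sv$sample_names, stringsAsFactors = FALSE)
  for (j in seq_len(n_components)) {
    out[[paste0("pc", j)]] <- sv$u[, j] * sv$d[j]
  }
  attr(out, "pathway") <- pathway
  attr(out, "var_fractions") <- sv$d[seq_len(n_components)]^2 / sv$total
  class(out) <- c("heterogeneity_scores", "data.frame")
  out
}

#' Cluster samples into regulatory subtypes from heterogeneity scores
#'
#' Runs K-means (with multiple restarts) on the PC1/PC2 heterogeneity
#' scores for each candidate number of clusters and picks the k with the
#' largest mean silhouette width (Euclidean distance) — the average
#' silhouette method. Deterministic given the seed.
#'
#' @param scores A [patient_scores()] result.
#' @param k_range Candidate cluster counts (default 2:6).
#' @param seed Integer seed.
#' @param nstart K-means restarts per k (default 10).
#' @return List with `labels` (named integer vector), `chosen_k`,
#'   `silhouette` (data frame k, avg_silhouette), `centers`.
#' @export
cluster_subtypes <- function(scores, k_range = 2:6, seed = 1L, nstart = 10L) {
  stopifnot(inherits(scores, "heterogeneity_scores"))
  x <- as.matrix(scores[, grep("^pc", names(scores)), drop = FALSE])
  rownames(x) <- scores$sample
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    .input_error("k_range must lie within [2, n_samples - 1]")
  }
  if (n < max(k_range) + 1L) .input_error("too few samples for k_range")
  if (all(apply(x, 2L, function(col) max(col) - min(col)) == 0)) {
    .degenerate("all heterogeneity scores identical; nothing to cluster")
  }
  d <- stats::dist(x)
  fits <- list()
  avg_sil <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    old <- .Random.seed_guard(derive_seed(seed, paste0("kmeans", k)))
    fits[[i]] <- stats::kmeans(x, centers = k, nstart = nstart,
                               iter.max = 100L)
    old()
    sil <- cluster::silhouette(fits[[i]]$cluster, d)
    avg_sil[i] <- mean(sil[, "sil_width"])
  }
  best <- which.max(avg_sil)
  list(
    labels = stats::setNames(fits[[best]]$cluster, rownames(x)),
    chosen_k = k_range[best],
    silhouette = data.frame(k = k_range, avg_silhouette = avg_sil),
    centers = fits[[best]]$centers
  )
}

#' Associate pathway heterogeneity scores with sample covariates
#'
#' Tests each score component against each covariate on the samples shared
#' by the two tables: Kruskal-Wallis across levels for categorical
#' covariates, a Pearson correlation test for numerical ones. P-values are
#' Benjamini-Hochberg adjusted across all tests performed in the call and
#' flagged significant at adjusted p < 0.05. Covariates that are constant
#' (or, for categorical, have fewer than two levels) after intersection
#' are skipped with a reason.
#'
#' @param scores A [patient_scores()] result.
#' @param covars A [covariate_table].
#' @param use_pc2 Also test PC2 scores (default: PC1 only).
#' @param alpha Significance threshold on adjusted p-values.
#' @return Data frame (pathway, component, covariate, test, statistic,
#'   estimate, p_value, p_adjusted, significant) with attribute `skipped`.
#' @export
associate_covariates <- function(scores, covars, use_pc2 = FALSE,
                                 alpha = 0.05) {
  stopifnot(inherits(scores, "heterogeneity_scores"),
            inherits(covars, "covariate_table"))
  shared <- intersect(scores$sample, covars$sample)
  if (length(shared) < 3L) .input_error("fewer than 3 shared samples")
  types <- attr(covars, "types")
  comps <- if (use_pc2 && "pc2" %in% names(scores)) c("pc1", "pc2") else "pc1"
  pw <- attr(scores, "pathway")
  if (is.null(pw)) pw <- NA_character_
  si <- match(shared, scores$sample)
  ci <- match(shared, covars$sample)
  rows <- list()
  skipped <- list()
  for (comp in comps) {
    y <- scores[[comp]][si]
    for (cv in names(types)) {
      v <- covars[[cv]][ci]
      ok <- !is.na(v)
      if (sum(ok) < 3L) {
        skipped[[paste(comp, cv)]] <- "fewer than 3 non-missing samples"
        next
      }
      if (types[[cv]] == "categorical") {
        g <- factor(v[ok])
        if (nlevels(g) < 2L) {
          skipped[[paste(comp, cv)]] <- "constant after intersection"
          next
        }
        ht <- stats::kruskal.test(y[ok], g)
        rows[[paste(comp, cv)]] <- data.frame(
          pathway = pw, component = comp, covariate = cv,
          test = "kruskal_wallis",
          statistic = unname(ht$statistic), estimate = NA_real_,
          p_value = ht$p.value, stringsAsFactors = FALSE)
      } else {
        if (max(v[ok]) - min(v[ok]) == 0) {
          skipped[[paste(comp, cv)]] <- "constant after intersection"
          next
        }
        ht <- stats::cor.test(y[ok], v[ok], method = "pearson")
        rows[[paste(comp, cv)]] <- data.frame(
          pathway = pw, component = comp, covariate = cv, test = "pearson",
          statistic = unname(ht$statistic),
          estimate = unname(ht$estimate),
          p_value = ht$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(pathway = character(), component = character(),
               covariate = character(), test = character(),
               statistic = double(), estimate = double(),
               p_value = double(), stringsAsFactors = FALSE)
  if (nrow(out) > 0L) {
    out$p_adjusted <- bh_adjust(out$p_value)
    out$significant <- out$p_adjusted < alpha
  } else {
    out$p_adjusted <- double()
    out$significant <- logical()
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(
    test = names(skipped), reason = unlist(skipped, use.names = FALSE),
    stringsAsFactors = FALSE)
  out
}

#' Gene targeting scores
#'
#' The targeting score of a gene in a sample is the sum of the weights of
#' all edges pointing to that gene — the amount of regulation the gene
#' receives from the full TF set. Linear in the edge weights; genes with
#' no edges in the matrix are absent from the output.
#'
#' @param m An [edge_matrix].
#' @return Numeric matrix, genes x samples, rows in the matrix's gene
#'   order.
#' @export
gene_targeting_scores <- function(m) {
  stopifnot(inherits(m, "edge_matrix"))
  out <- rowsum(m$weights, group = factor(m$gene, levels = m$genes),
                reorder = FALSE)
  rownames(out) <- m$genes
  out
}
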