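#' Configuration for a pathway heterogeneity scan
#'
#' Defaults follow the published protocol for sample-specific regulatory
#' network cohorts: 1000 random gene sets per pathway, pathways larger
#' than 200 listed genes excluded, at least 3 pathway genes required in
#' the network, and significance gates FDR < 0.01, PC1 variance explained
#' >= 10 percent, effect size >= 2.
#'
#' @param n_perm Random gene sets per pathway (>= 2).
#' @param max_pathway_genes Skip pathways listing more genes than this.
#' @param min_pathway_genes Skip pathways with fewer genes matched in the
#'   network than this.
#' @param alpha_fdr Adjusted p-value gate.
#' @param min_var_explained PC1 variance-fraction gate.
#' @param min_effect_size Effect-size gate.
#' @param seed Global integer seed; per-pathway seeds are derived from it
#'   and the pathway name, so results are independent of pathway order.
#' @param pvalue_method `"ttest"` (default) or `"empirical"`; see
#'   [heterogeneity_pvalue()].
#' @param keep_null Retain every pathway's full null vector in the result
#'   (memory scales with pathways x n_perm).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(n_perm = 1000L, max_pathway_genes = 200L,
                        min_pathway_genes = 3L, alpha_fdr = 0.01,
                        min_var_explained = 0.10, min_effect_size = 2.0,
                        seed = 1L, pvalue_method = c("ttest", "empirical"),
                        keep_null = FALSE) {
  pvalue_method <- match.arg(pvalue_method)
  if (!.is_count(n_perm) || n_perm < 2) .input_error("n_perm must be >= 2")
  if (!.is_count(max_pathway_genes) || max_pathway_genes < 1) {
    .input_error("max_pathway_genes must be a positive count")
  }
  if (!.is_count(min_pathway_genes) || min_pathway_genes < 1) {
    .input_error("min_pathway_genes must be a positive count")
  }
  for (v in c(alpha_fdr, min_var_explained, min_effect_size)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      .input_error("thresholds must be positive numbers")
    }
  }
  structure(list(
    n_perm = as.integer(n_perm),
    max_pathway_genes = as.integer(max_pathway_genes),
    min_pathway_genes = as.integer(min_pathway_genes),
    alpha_fdr = alpha_fdr,
    min_var_explained = min_var_explained,
    min_effect_size = min_effect_size,
    seed = as.integer(seed),
    pvalue_method = pvalue_method,
    keep_null = isTRUE(keep_null)
  ), class = "scan_config")
}

#' Scan a pathway collection for regulatory heterogeneity
#'
#' For every eligible pathway: extract all network edges targeting the
#' pathway's genes, z-scale each edge across samples, compute the PC1
#' variance fraction, compare it against `n_perm` random gene sets of
#' equal size drawn from the shared gene universe, and summarize with a
#' one-tailed t-test p-value and a signed Cohen's d effect size.
#' Benjamini-Hochberg correction is applied across exactly the tested
#' pathways (skipped pathways are not part of the family).
#'
#' Pathways are skipped — with a reason recorded in `$skipped` — when they
#' list more than `max_pathway_genes` genes, match fewer than
#' `min_pathway_genes` network genes, or are degenerate (e.g. all matched
#' edges constant).
#'
#' @param m An [edge_matrix].
#' @param collection A [pathway_collection].
#' @param config A [scan_config()].
#' @return An object of class `pathway_scan`: list with `results` (data
#'   frame sorted by ascending adjusted p-value, then descending effect
#'   size, then name), `skipped` (pathway, reason), `config`, and — when
#'   `config$keep_null` — `nulls`, a named list of null vectors.
#' @export
scan_pathways <- function(m, collection, config = scan_config()) {
  stopifnot(inherits(m, "edge_matrix"),
            inherits(collection, "pathway_collection"),
            inherits(config, "scan_config"))
  if (length(intersect(collection$universe, m$genes)) == 0L) {
    .empty_overlap("pathway collection and network share no genes")
  }
  nms <- names(collection$pathways)
  skipped <- list()
  rows <- list()
  nulls <- list()
  for (nm in nms) {
    genes <- collection$pathways[[nm]]
    if (length(genes) > config$max_pathway_genes) {
      skipped[[nm]] <- sprintf("size>%d", config$max_pathway_genes)
      next
    }
    n_matched <- sum(genes %in% m$genes)
    if (n_matched < config$min_pathway_genes) {
      skipped[[nm]] <- sprintf("matched<%d", config$min_pathway_genes)
      next
    }
    res <- tryCatch({
      sub <- extract_pathway_edges(m, genes)
      scaled <- zscale_edges(sub)
      obs <- .pc1_fraction(scaled)
      null <- null_pc1_distribution(
        m, collection, set_size = n_matched, n_perm = config$n_perm,
        seed = derive_seed(config$seed, nm))
      list(obs = obs, null = null, n_edges = nrow(sub))
    }, pnv_degenerate_error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[nm]] <- paste0("degenerate: ", res)
      next
    }
    nm_null <- mean(res$null)
    sd_null <- stats::sd(res$null)
    if (!is.finite(sd_null) || sd_null <= 0) {
      skipped[[nm]] <- "degenerate: constant null distribution"
      next
    }
    if (config$keep_null) nulls[[nm]] <- res$null
    rows[[nm]] <- data.frame(
      pathway = nm,
      n_genes_in_pathway = length(genes),
      n_genes_in_network = n_matched,
      n_edges = res$n_edges,
      pc1_var_observed = res$obs,
      null_mean = nm_null,
      null_sd = sd_null,
      p_value = heterogeneity_pvalue(res$obs, res$null,
                                     method = config$pvalue_method),
      effect_size = (res$obs - nm_null) / sd_null,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    results <- data.frame(
      pathway = character(), n_genes_in_pathway = integer(),
      n_genes_in_network = integer(), n_edges = integer(),
      pc1_var_observed = double(), null_mean = double(), null_sd = double(),
      p_value = double(), p_adjusted = double(), effect_size = double(),
      stringsAsFactors = FALSE)
  } else {
    results <- do.call(rbind, rows)
    results$p_adjusted <- bh_adjust(results$p_value)
    ord <- order(results$p_adjusted, -results$effect_size, results$pathway,
                 method = "radix")
    results <- results[ord, c("pathway", "n_genes_in_pathway",
                              "n_genes_in_network", "n_edges",
                              "pc1_var_observed", "null_mean", "null_sd",
                              "p_value", "p_adjusted", "effect_size")]
    rownames(results) <- NULL
  }
  skipped_df <- data.frame(pathway = names(skipped),
                           reason = unlist(skipped, use.names = FALSE),
                           stringsAsFactors = FALSE)
  out <- list(results = results, skipped = skipped_df, config = config)
  if (config$keep_null) out$nulls <- nulls
  structure(out, class = "pathway_scan")
}

#' @export
print.pathway_scan <- function(x, ...) {
  sig <- filter_significant(x)
  cat(sprintf("pathway_scan: %d pathways tested, %d skipped, %d significant\n",
              nrow(x$results), nrow(x$skipped), nrow(sig)),
      sprintf("gates: FDR < %g, PC1 variance >= %g, effect size >= %g\n",
              x$config$alpha_fdr, x$config$min_var_explained,
              x$config$min_effect_size))
  if (nrow(x$results) > 0L) {
    print(utils::head(x$results, 5L))
  }
  invisible(x)
}

#' Filter scan results to significant pathways
#'
#' Keeps pathways passing all three gates: adjusted p-value below
#' `alpha_fdr`, observed PC1 variance fraction at or above
#' `min_var_explained`, and effect size at or above `min_effect_size`.
#' Input order is preserved.
#'
#' @param scan A `pathway_scan` object or its `results` data frame.
#' @param config A [scan_config()]; defaults to the scan's own.
#' @return The significant subset of the results data frame.
#' @export
filter_significant <- function(scan, config = NULL) {
  results <- if (inherits(scan, "pathway_scan")) scan$results else scan
  if (is.null(config)) {
    config <- if (inherits(scan, "pathway_scan")) scan$config else scan_config()
  }
  keep <- results$p_adjusted < config$alpha_fdr &
    results$pc1_var_observed >= config$min_var_explained &
    results$effect_size >= config$min_effect_size
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway-size bias report
#'
#' Splits pathways into size bins (fewer than 50, 50-100, 100-150,
#' 150-200 listed genes) and reports, per bin, the proportion of all
#' eligible pathways and the proportion of significant pathways, to check
#' whether detected heterogeneity is biased towards small pathways.
#'
#' @param scan A `pathway_scan` object.
#' @param collection The [pathway_collection] that was scanned.
#' @param max_genes Upper size bound on eligible pathways (default 200).
#' @return Data frame with columns `bin`, `n_eligible`, `prop_eligible`,
#'   `n_significant`, `prop_significant`. Each proportion column sums to 1
#'   when its count column is positive (significant proportions are `NA`
#'   when no pathway is significant).
#' @export
size_bias_report <- function(scan, collection, max_genes = 200L) {
  stopifnot(inherits(scan, "pathway_scan"),
            inherits(collection, "pathway_collection"))
  if (nrow(scan$results) == 0L) .input_error("scan has no tested pathways")
  sizes <- lengths(collection$pathways)
  eligible <- sizes[sizes >= 1L & sizes <= max_genes]
  sig <- filter_significant(scan)
  sig_sizes <- lengths(collection$pathways[sig$pathway])
  breaks <- c(1, 50, 100, 150, max_genes + 1L)
  labels <- c("<50", "50-100", "100-150", "150-200")
  bin <- function(x) table(cut(x, breaks = breaks, labels = labels,
                               right = FALSE, include.lowest = TRUE))
  n_eligible <- as.integer(bin(eligible))
  n_sig <- as.integer(bin(sig_sizes))
  data.frame(
    bin = labels,
    n_eligible = n_eligible,
    prop_eligible = n_eligible / sum(n_eligible),
    n_significant = n_sig,
    prop_significant = if (sum(n_sig) > 0L) n_sig / sum(n_sig) else
      rep(NA_real_, 4L),
    stringsAsFactors = FALSE
  )
}

#' Write a scan results table as TSV
#'
#' Columns: pathway, n_genes_in_pathway, n_genes_in_network, n_edges,
#' pc1_var_observed, null_mean, null_sd, p_value, p_adjusted, effect_size.
#' Numbers are serialized with 8 significant digits.
#'
#' @param results A `pathway_scan` object or non-empty results data frame.
#' @param path Output path.
#' @export
write_results_table <- function(results, path) {
  if (inherits(results, "pathway_scan")) results <- results$results
  if (!is.data.frame(results) || nrow(results) == 0L) {
    .input_error("results table is empty")
  }
  .write_atomic(path, function(tmp) {
    out <- results
    for (nm in names(out)) {
      if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.8g", out[[nm]])
    }
    utils::write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  })
}

#' Read back a results table written by [write_results_table()]
#' @param path Path to the TSV file.
#' @return Data frame of scan results.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) .format_error(sprintf("file not found: '%s'", path))
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}
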