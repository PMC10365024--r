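#' Cohort edge-weight matrix for sample-specific regulatory networks
#'
#' An `edge_matrix` holds a cohort of sample-specific bipartite
#' transcription-factor (TF) to target-gene networks as a single dense
#' matrix: one row per TF->gene edge, one column per sample, with
#' continuous (possibly negative) edge weights such as those produced by
#' PANDA+LIONESS. The object records the edge identity of every row and
#' the distinct TFs and target genes, and pre-indexes rows by target gene
#' because pathway extraction selects edges by target.
#'
#' @param tf Character vector of TF identifiers, one per edge.
#' @param gene Character vector of target-gene identifiers, one per edge.
#' @param weights Numeric matrix, edges x samples; no missing values.
#' @param samples Sample identifiers; defaults to `colnames(weights)`.
#' @return An object of class `edge_matrix` with components `tf`, `gene`,
#'   `weights`, `samples`, `tfs` (unique TFs, order of first appearance),
#'   `genes` (unique target genes, order of first appearance), and
#'   `gene_rows` (list mapping each gene to its row indices).
#' @examples
#' m <- edge_matrix(tf = c("T1", "T1", "T2", "T2"),
#'                  gene = c("A", "B", "A", "B"),
#'                  weights = matrix(rnorm(12), 4, 3,
#'                                   dimnames = list(NULL, c("s1", "s2", "s3"))))
#' dim(m$weights)
#' @export
edge_matrix <- function(tf, gene, weights, samples = colnames(weights)) {
  tf <- as.character(tf)
  gene <- as.character(gene)
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  if (length(tf) != nrow(weights) || length(gene) != nrow(weights)) {
    .input_error("tf, gene and rows of weights must have equal length")
  }
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(weights)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) .input_error("sample identifiers must be unique")
  if (ncol(weights) < 3L) {
    .input_error("at least 3 samples are required (PCA across samples)")
  }
  if (anyNA(weights)) {
    .input_error(sprintf("weights contain %d missing values", sum(is.na(weights))))
  }
  key <- paste(tf, gene, sep = "\t")
  if (anyDuplicated(key)) .input_error("duplicate (tf, gene) edges")
  dimnames(weights) <- list(key, samples)
  genes <- unique(gene)
  structure(list(
    tf = tf,
    gene = gene,
    weights = weights,
    samples = samples,
    tfs = unique(tf),
    genes = genes,
    gene_rows = split(seq_along(gene), factor(gene, levels = genes))
  ), class = "edge_matrix")
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("edge_matrix: %d edges (%d TFs x %d target genes), %d samples\n",
              nrow(x$weights), length(x$tfs), length(x$genes),
              length(x$samples)))
  invisible(x)
}

#' @export
dim.edge_matrix <- function(x) dim(x$weights)

#' Read a cohort edge-weight matrix from delimited text
#'
#' Two layouts are supported. `wide`: a TSV whose first two columns are
#' `tf` and `gene` and whose remaining columns are one sample each; edge
#' order is preserved as on disk. `long`: a TSV with columns
#' `tf`, `gene`, `sample`, `weight`; edges are sorted lexicographically by
#' (tf, gene) and samples ordered by first appearance.
#'
#' Missing weight cells are rejected by default because silently imputing
#' them would bias the downstream PCA; `on_missing = "drop"` instead drops
#' every edge with at least one missing value and reports the count.
#'
#' @param path Path to the file.
#' @param layout `"wide"` or `"long"`.
#' @param on_missing `"error"` (default) or `"drop"`.
#' @return An [edge_matrix]; when edges were dropped, the attribute
#'   `n_dropped_edges` carries the count.
#' @export
read_edge_matrix <- function(path, layout = c("wide", "long"),
                             on_missing = c("error", "drop")) {
  layout <- match.arg(layout)
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) .format_error(sprintf("file not found: '%s'", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (layout == "wide") {
    if (ncol(df) < 3L || !identical(tolower(names(df)[1:2]), c("tf", "gene"))) {
      .format_error("wide layout requires columns tf, gene, then samples")
    }
    w <- as.matrix(df[, -(1:2), drop = FALSE])
    storage.mode(w) <- "double"
    tf <- as.character(df[[1L]])
    gene <- as.character(df[[2L]])
  } else {
    need <- c("tf", "gene", "sample", "weight")
    if (!all(need %in% names(df))) {
      .format_error("long layout requires columns tf, gene, sample, weight")
    }
    key3 <- paste(df$tf, df$gene, df$sample, sep = "\t")
    if (anyDuplicated(key3)) {
      .format_error("duplicate (tf, gene, sample) records in long layout")
    }
    edges <- unique(df[, c("tf", "gene")])
    edges <- edges[order(edges$tf, edges$gene, method = "radix"), , drop = FALSE]
    samples <- unique(as.character(df$sample))
    w <- matrix(NA_real_, nrow(edges), length(samples),
                dimnames = list(paste(edges$tf, edges$gene, sep = "\t"), samples))
    w[cbind(match(paste(df$tf, df$gene, sep = "\t"), rownames(w)),
            match(as.character(df$sample), samples))] <- as.numeric(df$weight)
    tf <- as.character(edges$tf)
    gene <- as.character(edges$gene)
  }
  n_dropped <- 0L
  if (anyNA(w)) {
    if (on_missing == "error") {
      .format_error(sprintf("missing weight values in '%s' (%d cells)",
                            path, sum(is.na(w))))
    }
    bad <- rowSums(is.na(w)) > 0L
    n_dropped <- sum(bad)
    if (all(bad)) .format_error("all edges have missing values")
    w <- w[!bad, , drop = FALSE]
    tf <- tf[!bad]
    gene <- gene[!bad]
  }
  out <- edge_matrix(tf, gene, w)
  attr(out, "n_dropped_edges") <- n_dropped
  out
}

#' Write an edge matrix as a wide TSV
#'
#' Weights are serialized with 17 significant digits so that
#' `read_edge_matrix(write_edge_matrix(m))` reproduces the matrix
#' bit-exactly.
#'
#' @param m An [edge_matrix].
#' @param path Output path.
#' @export
write_edge_matrix <- function(m, path) {
  stopifnot(inherits(m, "edge_matrix"))
  .write_atomic(path, function(tmp) {
    con <- file(tmp, open = "wt")
    on.exit(close(con))
    writeLines(paste(c("tf", "gene", m$samples), collapse = "\t"), con)
    txt <- matrix(sprintf("%.17g", m$weights), nrow = nrow(m$weights))
    writeLines(paste(m$tf, m$gene,
                     apply(txt, 1L, paste, collapse = "\t"), sep = "\t"), con)
  })
}
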