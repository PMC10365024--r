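# Fixtures are generated in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir().

# Small deterministic cohort: full bipartite T TFs x G genes x N samples
# of pure noise edge weights.
tiny_edge_matrix <- function(n_tfs = 5L, n_genes = 4L, n_samples = 6L,
                             seed = 42L) {
  set.seed(seed)
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  genes <- sprintf("G%d", seq_len(n_genes))
  samples <- sprintf("S%d", seq_len(n_samples))
  w <- matrix(rnorm(n_tfs * n_genes * n_samples), n_tfs * n_genes, n_samples,
              dimnames = list(NULL, samples))
  edge_matrix(tf = rep(tfs, times = n_genes),
              gene = rep(genes, each = n_tfs),
              weights = w)
}

write_gmt_lines <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# A scaled matrix with a known number of edges/samples, standard normal.
random_scaled <- function(n_edges, n_samples, seed) {
  set.seed(seed)
  zscale_edges(matrix(rnorm(n_edges * n_samples), n_edges, n_samples,
                      dimnames = list(paste0("e", seq_len(n_edges)),
                                      paste0("s", seq_len(n_samples)))))
}

# Independent oracle: PC1 variance fraction via direct eigendecomposition
# of the sample covariance matrix (samples as observations).
oracle_pc1 <- function(scaled) {
  y <- t(scaled)
  yc <- sweep(y, 2, colMeans(y))
  ev <- eigen(crossprod(yc) / (nrow(yc) - 1), symmetric = TRUE)
  list(fraction = ev$values[1] / sum(ev$values),
       loadings = ev$vectors[, 1],
       scores = unname(drop(yc %*% ev$vectors[, 1])))
}

# Independent oracle: textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
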