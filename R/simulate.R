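#' Specification of a synthetic network cohort
#'
#' Describes a Gaussian generative model for a cohort of sample-specific
#' bipartite TF->gene networks: every edge has a fixed baseline weight
#' plus i.i.d. noise, and optionally the edges targeting (a fraction of)
#' one pathway's genes additionally load on a shared one-dimensional
#' latent factor. The weight of edge (tf, g) in sample s is
#'
#'   w = mu_edge + beta * l_edge * u_s * \[g planted\] + eps
#'
#' with mu ~ N(0, baseline_sd), latent factor u_s ~ N(0, 1), noise
#' eps ~ N(0, noise_sd), and edge loadings l ~ N(0, 1) rescaled to unit
#' root-mean-square, so that `beta` is the typical per-edge signal
#' standard deviation in noise-sd units: beta = noise_sd means signal and
#' noise contribute equally to a planted edge's variance.
#'
#' @param n_tfs,n_genes,n_samples Network and cohort dimensions.
#' @param n_pathways Number of random gene sets in the collection.
#' @param pathway_size_range Length-2 integer range of pathway sizes.
#' @param baseline_sd Spread of per-edge baseline weights.
#' @param noise_sd Per-sample noise standard deviation.
#' @param planted `NULL` (null cohort) or a list with `pathway` (index
#'   into the collection), `beta` (factor strength) and `fraction`
#'   (fraction of the pathway's genes affected, in (0, 1\]).
#' @param covariates Generate a covariate table: a 3-level categorical
#'   covariate unrelated to the factor and a numerical covariate linked to
#'   the latent factor (u plus N(0, 0.5) noise; pure noise in null mode).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_tfs = 20L, n_genes = 500L, n_samples = 40L,
                            n_pathways = 20L, pathway_size_range = c(10L, 50L),
                            baseline_sd = 1.0, noise_sd = 1.0,
                            planted = NULL, covariates = FALSE, seed = 1L) {
  for (v in list(n_tfs, n_genes, n_samples, n_pathways)) {
    if (!.is_count(v) || v < 1) .input_error("all counts must be positive")
  }
  if (n_samples < 3L) .input_error("n_samples must be >= 3")
  pathway_size_range <- as.integer(pathway_size_range)
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1L] < 1L ||
      pathway_size_range[2L] < pathway_size_range[1L] ||
      pathway_size_range[2L] > n_genes) {
    .input_error("invalid pathway_size_range")
  }
  if (baseline_sd < 0 || noise_sd <= 0) {
    .input_error("baseline_sd must be >= 0 and noise_sd > 0")
  }
  if (!is.null(planted)) {
    if (!is.list(planted) || is.null(planted$pathway) || is.null(planted$beta)) {
      .input_error("planted must be a list with pathway, beta and optional fraction")
    }
    if (is.null(planted$fraction)) planted$fraction <- 1.0
    if (!.is_count(planted$pathway) || planted$pathway < 1 ||
        planted$pathway > n_pathways) {
      .input_error("planted pathway index out of range")
    }
    if (planted$fraction <= 0 || planted$fraction > 1) {
      .input_error("planted fraction must be in (0, 1]")
    }
    if (planted$beta < 0) .input_error("planted beta must be >= 0")
  }
  structure(list(
    n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
    n_samples = as.integer(n_samples), n_pathways = as.integer(n_pathways),
    pathway_size_range = pathway_size_range,
    baseline_sd = baseline_sd, noise_sd = noise_sd,
    planted = planted, covariates = isTRUE(covariates),
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a random pathway collection over a gene universe
#'
#' Draws `n_pathways` gene sets, each sampled without replacement from the
#' universe with a size uniform over `size_range`; different pathways may
#' overlap, as real gene-set collections do.
#'
#' @param n_pathways Number of sets.
#' @param size_range Length-2 integer size range.
#' @param universe Character vector of gene identifiers.
#' @param seed Integer seed.
#' @return A [pathway_collection] with names `PW001`, `PW002`, ...
#' @export
simulate_null_pathways <- function(n_pathways, size_range, universe,
                                   seed = 1L) {
  if (!.is_count(n_pathways) || n_pathways < 1) {
    .input_error("n_pathways must be a positive count")
  }
  size_range <- as.integer(size_range)
  if (max(size_range) > length(universe)) {
    .input_error("pathway size exceeds gene universe")
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  size_choices <- seq.int(size_range[1L], size_range[2L])
  sizes <- size_choices[sample.int(length(size_choices), n_pathways,
                                   replace = TRUE)]
  sets <- lapply(sizes, function(k) sample(universe, k))
  names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
  pathway_collection(sets, source_description = "simulated null collection")
}

#' Simulate a cohort of sample-specific regulatory networks
#'
#' Generates the full bipartite edge-weight matrix (all TF x gene edges),
#' a random pathway collection over the gene universe, optional
#' covariates, and a truth record, following the model described in
#' [simulation_spec()]. With `planted = NULL` (or beta = 0) the cohort is
#' exchangeable across pathways — the null mode used for calibration
#' checks. Bit-identical outputs are produced for equal seeds.
#'
#' @param spec A [simulation_spec()].
#' @return List with `edges` ([edge_matrix]), `pathways`
#'   ([pathway_collection]), `covariates` ([covariate_table] or `NULL`)
#'   and `truth` (list: `latent_factor` u, `planted_pathway`,
#'   `planted_genes`, `edge_loadings`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .Random.seed_guard(spec$seed)
  on.exit(old(), add = TRUE)

  tfs <- sprintf("TF%03d", seq_len(spec$n_tfs))
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))

  collection <- simulate_null_pathways(
    spec$n_pathways, spec$pathway_size_range, genes,
    seed = derive_seed(spec$seed, "pathways"))

  # Gene-major edge order: for each gene, all TFs.
  tf_col <- rep(tfs, times = spec$n_genes)
  gene_col <- rep(genes, each = spec$n_tfs)
  n_edges <- spec$n_tfs * spec$n_genes

  mu <- stats::rnorm(n_edges, 0, spec$baseline_sd)
  w <- mu + matrix(stats::rnorm(n_edges * spec$n_samples, 0, spec$noise_sd),
                   n_edges, spec$n_samples)

  u <- stats::rnorm(spec$n_samples)
  truth <- list(latent_factor = stats::setNames(u, samples),
                planted_pathway = NA_character_,
                planted_genes = character(0),
                edge_loadings = numeric(0))
  if (!is.null(spec$planted) && spec$planted$beta > 0) {
    pw_name <- names(collection$pathways)[spec$planted$pathway]
    pw_genes <- collection$pathways[[pw_name]]
    n_aff <- max(1L, ceiling(spec$planted$fraction * length(pw_genes)))
    affected <- pw_genes[seq_len(n_aff)]
    rows <- which(gene_col %in% affected)
    l <- stats::rnorm(length(rows))
    l <- l / sqrt(mean(l^2))  # unit RMS: beta is the per-edge signal sd
    w[rows, ] <- w[rows, ] + spec$planted$beta * tcrossprod(l, u)
    truth$planted_pathway <- pw_name
    truth$planted_genes <- affected
    truth$edge_loadings <- stats::setNames(
      l, paste(tf_col[rows], gene_col[rows], sep = "\t"))
  }
  colnames(w) <- samples
  m <- edge_matrix(tf_col, gene_col, w)

  covars <- NULL
  if (spec$covariates) {
    grp <- sample(c("A", "B", "C"), spec$n_samples, replace = TRUE)
    linked <- if (!is.null(spec$planted) && spec$planted$beta > 0) {
      u + stats::rnorm(spec$n_samples, 0, 0.5)
    } else {
      stats::rnorm(spec$n_samples)
    }
    covars <- covariate_table(
      samples,
      data.frame(group = grp, factor_proxy = linked,
                 stringsAsFactors = FALSE),
      types = c(group = "categorical", factor_proxy = "numerical"))
  }

  list(edges = m, pathways = collection, covariates = covars, truth = truth)
}
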