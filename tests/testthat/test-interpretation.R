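test_that("edge contribution profiles apply the 1.5x expected-score rule on absolute loadings", {
  ids4 <- data.frame(tf = paste0("T", 1:4), gene = rep("G1", 4),
                     stringsAsFactors = FALSE)
  # equal contributions: expected score 1/sqrt(4), nothing exceeds 1.5x it
  prof <- edge_contributions(rep(0.5, 4), ids4)
  expect_equal(prof$expected_score, 0.5)
  expect_false(any(prof$edges$is_top))
  expect_length(prof$tf_target_counts, 0L)
  expect_length(prof$tf_labels, 0L)

  # one dominant edge; negative sign must not matter
  l <- c(-sqrt(0.97), sqrt(0.01), sqrt(0.01), sqrt(0.01))
  prof2 <- edge_contributions(l, ids4)
  expect_identical(prof2$edges$is_top, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(sum(prof2$tf_target_counts), 1L)

  expect_error(edge_contributions(c(0.5, 0.5), ids4[1:2, ]),
               "unit-norm", class = "pnv_input_error")
})

test_that("TF target counts and gene summaries match hand enumeration on a 3 TF x 4 gene toy", {
  tfs <- rep(paste0("T", 1:3), times = 4)
  genes <- rep(paste0("G", 1:4), each = 3)
  ids <- data.frame(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  # 12 edges; expected score 1/sqrt(12) ~ 0.2887, top threshold ~ 0.4330.
  # Put large loadings on (T1,G1), (T1,G2), (T2,G1); spread the rest.
  l <- rep(0.05, 12)
  l[ids$tf == "T1" & ids$gene == "G1"] <- 0.55
  l[ids$tf == "T1" & ids$gene == "G2"] <- 0.50
  l[ids$tf == "T2" & ids$gene == "G1"] <- -0.60
  l <- l / sqrt(sum(l^2))
  # after normalization (norm ~ 0.9669) the three big ones stay > 0.4330
  prof <- edge_contributions(l, ids)
  expect_equal(sum(prof$edges$is_top), 3L)
  expect_identical(prof$tf_target_counts[["T1"]], 2L)
  expect_identical(prof$tf_target_counts[["T2"]], 1L)
  expect_false("T3" %in% names(prof$tf_target_counts))
  expect_equal(sum(prof$tf_target_counts), sum(prof$edges$is_top))
  # 95th percentile over counts (2, 1) is 1.95 -> only T1 labelled
  expect_identical(prof$tf_labels, "T1")

  gs <- gene_contribution_summary(prof)
  expect_identical(gs$gene, c("G1", "G2"))
  expect_identical(gs$n_top_edges, c(2, 1))
  expect_equal(gs$max_abs_loading[1], max(abs(prof$edges$loading)),
               tolerance = 1e-12)

  # profile with no top edges -> empty summary
  empty <- gene_contribution_summary(edge_contributions(rep(0.5, 4),
                                                        ids[1:4, ]))
  expect_identical(nrow(empty), 0L)
})

test_that("sign flips leave |loading| summaries and top-edge sets invariant", {
  z <- random_scaled(12, 8, seed = 31)
  res <- pc1_variance_fraction(z)
  ids <- data.frame(tf = paste0("T", rep(1:3, 4)),
                    gene = paste0("G", rep(1:4, each = 3)),
                    stringsAsFactors = FALSE)
  p1 <- edge_contributions(res$loadings, ids)
  p2 <- edge_contributions(-res$loadings, ids)
  expect_identical(p1$edges$is_top, p2$edges$is_top)
  expect_identical(p1$tf_target_counts, p2$tf_target_counts)
  expect_identical(gene_contribution_summary(p1),
                   gene_contribution_summary(p2))
})

test_that("patient scores are centered orthogonal projections matching the eigen oracle", {
  for (seed in c(7, 8, 9)) {
    z <- random_scaled(5, 8, seed = seed)
    sc <- patient_scores(z, n_components = 2)
    orc <- oracle_pc1(z)
    s <- sign(sum(sc$pc1 * drop(orc$scores)))
    expect_equal(sc$pc1, s * unname(drop(orc$scores)), tolerance = 1e-8)
    expect_lt(abs(mean(sc$pc1)), 1e-8)
    expect_lt(abs(mean(sc$pc2)), 1e-8)
    expect_lt(abs(sum(sc$pc1 * sc$pc2)), 1e-8)
  }

  # rank-1 data: PC1 reproduces the 1-D geometry, PC2 request errors
  direction <- c(2, -1, 0.5, 1)
  pos <- c(-2, 1, 1)
  x <- t(outer(pos, direction))
  colnames(x) <- paste0("s", 1:3)
  sc1 <- patient_scores(x, n_components = 1)
  expect_gt(abs(cor(sc1$pc1, pos)), 1 - 1e-12)
  expect_error(patient_scores(x, n_components = 2),
               class = "pnv_degenerate_error")
})

test_that("subtype clustering picks k by average silhouette and is reproducible", {
  set.seed(12)
  n <- 30
  pc1 <- c(rnorm(n / 2, -5, 0.4), rnorm(n / 2, 5, 0.4))
  pc2 <- rnorm(n, 0, 0.4)
  scores <- data.frame(sample = sprintf("S%02d", 1:n), pc1 = pc1, pc2 = pc2)
  class(scores) <- c("heterogeneity_scores", "data.frame")
  cl <- cluster_subtypes(scores, k_range = 2:5, seed = 4)
  expect_identical(cl$chosen_k, 2L)
  truth <- rep(1:2, each = n / 2)
  expect_true(all(table(cl$labels, truth) %in% c(0L, n / 2)))

  cl2 <- cluster_subtypes(scores, k_range = 2:5, seed = 4)
  expect_identical(cl$labels, cl2$labels)

  # permuting sample order permutes labels identically (up to relabeling)
  perm <- sample(n)
  scores_p <- scores[perm, ]
  class(scores_p) <- c("heterogeneity_scores", "data.frame")
  cl3 <- cluster_subtypes(scores_p, k_range = 2:5, seed = 4)
  tab <- table(cl3$labels[match(scores$sample, scores_p$sample)], cl$labels)
  expect_true(all(rowSums(tab > 0) == 1L))

  # hand-computed silhouette on a 4-point, 2-cluster configuration:
  # cluster 1 = {0, 1}, cluster 2 = {10, 11} on a line.
  pts <- data.frame(sample = paste0("P", 1:4), pc1 = c(0, 1, 10, 11),
                    pc2 = rep(0, 4))
  class(pts) <- c("heterogeneity_scores", "data.frame")
  cl4 <- cluster_subtypes(pts, k_range = 2, seed = 1)
  # each point: a = 1, b = mean(d to other cluster) = (9 + 10)/2 or (10+11)/2
  s_hand <- mean(c(1 - 1 / 9.5, 1 - 1 / 10.5, 1 - 1 / 10.5, 1 - 1 / 9.5))
  expect_equal(cl4$silhouette$avg_silhouette, s_hand, tolerance = 1e-12)

  same <- data.frame(sample = paste0("P", 1:5), pc1 = rep(1, 5),
                     pc2 = rep(2, 5))
  class(same) <- c("heterogeneity_scores", "data.frame")
  expect_error(cluster_subtypes(same, k_range = 2),
               class = "pnv_degenerate_error")
})

test_that("covariate associations choose tests by type and correct within the call", {
  set.seed(77)
  n <- 20
  samples <- sprintf("S%02d", 1:n)
  scores <- data.frame(sample = samples, pc1 = rnorm(n))
  attr(scores, "pathway") <- "PW_X"
  class(scores) <- c("heterogeneity_scores", "data.frame")
  covars <- covariate_table(
    samples,
    data.frame(group = rep(c("a", "b"), each = n / 2),
               exact = scores$pc1,  # identical to PC1 -> r = 1
               const_num = rep(3.2, n),
               const_cat = rep("only", n),
               stringsAsFactors = FALSE))
  res <- associate_covariates(scores, covars)
  expect_identical(sort(res$covariate), c("exact", "group"))
  pearson <- res[res$covariate == "exact", ]
  expect_equal(pearson$estimate, 1, tolerance = 1e-12)
  expect_identical(pearson$test, "pearson")
  expect_identical(res$pathway, rep("PW_X", 2))
  # BH family = tests performed in the call (2 tests, 2 skips)
  expect_equal(res$p_adjusted, bh_adjust(res$p_value))
  expect_identical(nrow(attr(res, "skipped")), 2L)

  # identical score distributions across groups -> KW statistic 0
  s2 <- data.frame(sample = samples[1:6], pc1 = c(1, 2, 3, 1, 2, 3))
  class(s2) <- c("heterogeneity_scores", "data.frame")
  c2 <- covariate_table(samples[1:6],
                        data.frame(g = rep(c("x", "y"), each = 3)))
  r2 <- associate_covariates(s2, c2)
  expect_equal(r2$statistic, 0, tolerance = 1e-12)

  # hand-computed Kruskal-Wallis on a 2-group, 6-sample example with no
  # ties: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2
  y <- c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6)  # ranks 1..6
  g <- c("a", "a", "b", "a", "b", "b")  # ranks a: 1,2,4; b: 3,5,6
  h_hand <- 12 / (6 * 7) * 3 * ((7 / 3 - 3.5)^2 + (14 / 3 - 3.5)^2)
  s3 <- data.frame(sample = samples[1:6], pc1 = y)
  class(s3) <- c("heterogeneity_scores", "data.frame")
  r3 <- associate_covariates(s3, covariate_table(samples[1:6],
                                                 data.frame(g = g)))
  expect_equal(r3$statistic, h_hand, tolerance = 1e-12)
})

test_that("gene targeting scores are per-gene edge-weight sums and linear", {
  m <- tiny_edge_matrix(n_tfs = 3, n_genes = 4, n_samples = 5, seed = 55)
  ts <- gene_targeting_scores(m)
  expect_identical(dim(ts), c(4L, 5L))
  # brute-force oracle
  for (g in m$genes) {
    for (s in m$samples) {
      expect_equal(ts[g, s], sum(m$weights[m$gene == g, s]))
    }
  }
  # toy: a gene with weights (1, 2, 3) in one sample scores 6
  w <- matrix(0, 3, 3, dimnames = list(NULL, paste0("s", 1:3)))
  w[, 1] <- c(1, 2, 3)
  m2 <- edge_matrix(paste0("T", 1:3), rep("G1", 3), w)
  expect_equal(unname(gene_targeting_scores(m2)["G1", ]), c(6, 0, 0))

  # linearity: scores(A + B) = scores(A) + scores(B)
  mB <- m
  set.seed(96)
  mB$weights <- matrix(rnorm(length(m$weights)), nrow(m$weights),
                       dimnames = dimnames(m$weights))
  mAB <- m
  mAB$weights <- m$weights + mB$weights
  expect_equal(gene_targeting_scores(mAB),
               gene_targeting_scores(m) + gene_targeting_scores(mB),
               tolerance = 1e-12)
})
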