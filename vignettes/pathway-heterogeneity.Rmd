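---
title: "Detecting pathway-level regulatory heterogeneity with pathnetvar"
author: "pathnetvar maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pathway-level regulatory heterogeneity with pathnetvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathnetvar)
```

## The model

`pathnetvar` operates on a cohort of sample-specific bipartite regulatory
networks, stored as a single edges × samples matrix of continuous weights
$w_{e,s}$, where each edge $e = (\mathrm{tf}, g)$ connects a transcription
factor to a target gene. Such matrices are typically produced upstream by
PANDA + LIONESS; this package neither reconstructs networks nor
normalizes their weights.

The question it answers per pathway is whether the incoming regulation of
the pathway's genes varies *coordinately* across samples. The test
statistic is geometric: after z-scaling each pathway-connected edge
across samples (mean 0, unit variance, divisor $N-1$), the $N$ samples
become points in an $E_p$-dimensional edge space, all at comparable scale.
If inter-individual variability in the pathway's regulation is dominated
by one latent axis — a gradient or a split into subtypes — those points
concentrate near a line, and the fraction of total variance explained by
the first principal component,
$$v \;=\; \lambda_1 \Big/ \sum_i \lambda_i,$$
is large. Under unstructured noise, $v$ is small and governed mostly by
the dimensions $E_p \times N$.

Because $v$ depends strongly on $E_p$, the reference distribution is
built by permutation: `n_perm` random gene sets of the same size as the
pathway, drawn from the gene universe, pushed through the identical
extract → scale → PCA pipeline. The observed $v$ is then summarized by

* a one-tailed t-test of the null vector against $\mu = v$ with
  alternative "null mean $< v$": $t = (v - \bar v_0)/(s_0/\sqrt{n})$ with
  $n-1$ degrees of freedom, and
* a signed effect size $\mathrm{ES} = (v - \bar v_0)/s_0$, i.e. Cohen's
  d of the observed value against the permutation null.

P-values are Benjamini–Hochberg adjusted across exactly the tested
pathways, and a pathway is reported significant when all three gates
hold: adjusted $p <$ `alpha_fdr` (default 0.01), $v \ge$
`min_var_explained` (default 0.10), and $\mathrm{ES} \ge$
`min_effect_size` (default 2).

### Assumptions

* Samples are exchangeable under the null; there is no batch or subtype
  structure other than what the scan is meant to detect. Batch
  correction, if needed, belongs upstream.
* Edge weights are continuous and comparable across samples after
  per-edge standardization. Constant edges are uninformative and are
  dropped per pathway (their count is reported).
* Pathway membership is taken at face value from the GMT file; gene
  identifiers are opaque case-sensitive strings and must match between
  the GMT and the network.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `n_perm` | 1000 | permutation resolution; the t-test uses its mean and sd, so a few hundred already stabilizes ES |
| `max_pathway_genes` | 200 | very large gene sets dilute coordinated signal and dominate runtime; they are excluded up front |
| `min_pathway_genes` | 3 | below this the PC1 fraction is close to saturated and uninterpretable |
| `alpha_fdr` | 0.01 | gate on BH-adjusted p-values |
| `min_var_explained` | 0.10 | gate on the observed PC1 fraction (unitless fraction of variance) |
| `min_effect_size` | 2.0 | gate in null-sd units |
| `pvalue_method` | `"ttest"` | `"empirical"` switches to $(\#\{v_0 \ge v\}+1)/(n+1)$ |

All three significance gates matter, and they are deliberately redundant.
The t-test compares the observed value to the *standard error of the null
mean*, so under the null its statistic scales like $\sqrt{n_\mathrm{perm}}$
times a standard normal: raw t-test p-values on null data are extreme in
both directions and are *not* uniform, and with `n_perm = 1000` even a
modest excess clears FDR thresholds. The effect-size gate (in null-sd
units, not standard-error units) and the absolute variance gate are what
keep the false-positive rate at zero on null cohorts — this is visible in
any scan: runner-up pathways routinely show $p_\mathrm{adj} \sim 10^{-20}$
with ES $\approx 1$ and $v \approx 6\%$ and are correctly rejected. Users
who want calibrated per-pathway p-values should use
`pvalue_method = "empirical"`, whose null distribution is uniform by
construction (and is verified by a Kolmogorov–Smirnov check in the test
suite); its resolution is limited to $1/(n_\mathrm{perm}+1)$.

### Numerical choices

* PCA orientation: samples are observations, scaled edges are variables;
  this is forced by the per-edge standardization and by patient scores
  living on PC1. Covariance PCA on pre-scaled rows equals correlation
  PCA.
* The decomposition is a thin SVD of the $N \times E_p$ centered matrix;
  with $N \ll E_p$ at most $N-1$ eigenvalues are nonzero and the total
  variance is the full trace — no truncation correction.
* Eigenvector signs are fixed by making the largest-magnitude loading
  positive; loadings and scores always flip together, so
  magnitude-based summaries are sign-invariant.
* The permutation universe is the intersection of the GMT universe with
  the network's target genes: edges exist only for network genes, and
  sampling unmatched genes would silently shrink null sets. Random sets
  may include the tested pathway's own genes (pure random sampling).
* Per-pathway RNG seeds are derived from the global seed and the pathway
  name via a platform-stable string hash, so results are independent of
  pathway iteration order.
* Ties in the result ordering are broken by adjusted p-value, then
  descending effect size, then pathway name — fully deterministic.
* Standard deviations use divisor $n-1$ throughout (z-scaling, null sd).
* Degenerate pathways (all edges constant, constant null) are skipped
  with a recorded reason rather than failing the scan, and skipped
  pathways are excluded from the BH family.

## Interpretation layer

*Edge contributions.* PC1 loadings are the edge contribution scores;
since $\sum_e \ell_e^2 = 1$, equal contribution would give every edge
$1/\sqrt{E_p}$, and edges with $|\ell_e| > 1.5/\sqrt{E_p}$ are flagged as
top contributors. Absolute values are used because eigenvector signs are
arbitrary. TFs are grouped by their number of top edges; the 95th
percentile label threshold is computed (with linear interpolation) over
TFs having at least one top edge — TFs absent from the top-edge set are
not part of that population.

*Patient heterogeneity scores.* Projections of the centered samples onto
PC1 (and PC2): mean zero, mutually orthogonal. They support K-means
subtyping with the number of clusters chosen by the average silhouette
method over `k_range` (default 2–6, Euclidean distance, 10 restarts —
the restarts make the label assignment stable under sample permutation),
and covariate association: Kruskal–Wallis across levels for categorical
covariates, Pearson correlation tests for numerical ones, BH-corrected
across the tests actually performed in the call (constant covariates are
skipped with a reason, and skipped tests are not part of the BH family).
Association uses PC1 by default; PC2 sits behind a flag. Survival
modelling is intentionally out of scope — the scores export cleanly to
any survival tooling.

*Gene targeting scores.* Per sample, the sum of all edge weights pointing
to a gene — the weighted in-degree, a compact per-gene summary of how
much regulation it receives.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the scan
consumes, not a quantitative imitation of PANDA/LIONESS weight
distributions. Edge weights follow
$$w_{(tf,g),s} = \mu_{(tf,g)} + \beta\,\ell_{(tf,g)}\,u_s\,[g \in
\text{planted}] + \varepsilon_{(tf,g),s}$$
with per-edge baselines $\mu \sim N(0, \texttt{baseline\_sd})$, noise
$\varepsilon \sim N(0, \texttt{noise\_sd})$, a latent factor
$u_s \sim N(0,1)$ shared by all samples, and Gaussian edge loadings
$\ell$ rescaled to unit root-mean-square. The RMS normalization makes
$\beta$ directly interpretable as the typical per-edge signal standard
deviation in noise units: $\beta = \texttt{noise\_sd}$ means signal and
noise contribute equally to a planted edge's variance, and the planted
pathway's raw-covariance PC1 share has the closed form
$\beta^2\sum\ell^2 / (\beta^2\sum\ell^2 + E_p\,\sigma^2) =
\beta^2/(\beta^2 + \sigma^2)$, which the test suite verifies by
Monte-Carlo. (Normalizing $\ell$ to unit *norm* instead would make the
per-edge signal vanish as $1/E_p$ and no fixed $\beta$ would correspond
to a detectable effect across pathway sizes.)

Default study conditions — 20 TFs × 500 genes × 40 samples, 20 pathways
of 10–50 genes, unit baseline and noise sd — are sized so that a full
scan with `n_perm = 100` runs in seconds while the planted-signal and
null-calibration properties are comfortably testable; they emulate a
small cohort, not the 623 × 17,899 scale of real network compendia. The
test suite and the acceptance script state these sizes explicitly where
they use them.

What the generator does *not* emulate: heavy-tailed or skewed weight
distributions, correlated noise between edges of the same TF,
overlapping signal across pathways, or missing data. Passing tests on
synthetic cohorts therefore demonstrate the statistical machinery —
calibration under exchangeable noise and power against a planted
one-dimensional factor — not robustness to every artifact of real
network inference.

## Known limitations

* The default t-test p-value is a ranking device, not a calibrated tail
  probability (see above); the gates, or the empirical p-value, carry
  the inferential weight.
* Pathways sharing genes are tested marginally; overlapping pathways
  driven by the same latent factor will co-appear, and no attempt is
  made to deconvolve them.
* With very small cohorts ($N \lesssim 10$) the PC1 fraction saturates
  and the variance gate loses meaning; the scan requires $N \ge 3$ but
  is sensible from a few dozen samples upward.
* Computation is single-threaded; the per-pathway seed derivation makes
  results independent of any future parallelization of the pathway loop.
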