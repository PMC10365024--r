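Package: pathnetvar
Title: Pathway-Level Regulatory Heterogeneity in Sample-Specific Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scans collections of biological pathways for coordinated
    variability of regulatory edge weights across a cohort of
    sample-specific gene regulatory networks (for example networks
    estimated with PANDA and LIONESS). For each pathway the incoming
    edges of its genes are z-scaled across samples and decomposed by
    PCA; the variance explained by the first principal component is
    compared against a permutation null built from random gene sets of
    equal size using a one-tailed t-test and a Cohen's d style effect
    size, with Benjamini-Hochberg correction across pathways.
    Downstream tools rank edge, gene and transcription-factor
    contributions, compute per-sample pathway heterogeneity scores,
    cluster samples into regulatory subtypes, associate scores with
    clinical covariates, test the overlap of significant pathway sets
    between cohorts, and simulate synthetic cohorts with planted
    latent structure for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
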