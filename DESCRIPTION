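Package: nichegraph
Title: Bi-Level Graph Analysis of Spatial Single-Cell Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers recurring local cellular-neighborhood motifs (tumor
    microenvironment patterns) in spatial single-cell data such as imaging
    mass cytometry, using a soft relaxation of the Weisfeiler-Lehman subtree
    kernel. Each patient's tissue is modelled as a Gaussian-weighted cellular
    graph; subtree embeddings obtained by graph convolution are pooled across
    the cohort and clustered into patterns; pattern histograms define an
    inter-patient cosine kernel from which a k-NN/Jaccard population graph is
    built and patient subgroups are detected with the Louvain method.
    Includes characteristic-pattern identification via the Hodges-Lehmann
    statistic, survival analysis of subgroups (Kaplan-Meier, log-rank, Cox
    hazard ratios), projection of external cohorts onto a fitted model,
    comparator similarity schemes (phenotype abundance, pairwise proximity,
    niche-category abundance, classic Weisfeiler-Lehman subtree kernels),
    and a synthetic-cohort generator with planted niche archetypes,
    subgroup structure, and survival signal.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
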