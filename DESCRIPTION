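Package: spdvkit
Title: Spatial Proximity to Disease Variants and Structure-Based Variant
    Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes structure-based spatial-clustering features for
    missense variant interpretation: the Spatial Proximity to Disease
    Variants (SPDV) metric (mean Euclidean distance from a residue's
    alpha-carbon to its K nearest known disease-variant sites, in 3D
    intra-chain, 3D inter-chain and 1D sequence variants) and the Extent
    of Disease Clustering (EDC) ratio. Includes residue mapping between a
    human reference sequence and structure coordinates via pairwise
    alignments, labelled variant-dataset assembly, predictor score
    manipulation (segmentation with overlap averaging, rank
    normalisation), ROC AUC benchmarking of variant effect predictors,
    and gene-specific ACMG/AMP PP3/BP4 evidence assignment through
    bootstrap kernel-density likelihood ratios with a prior-derived
    evidence ladder. A synthetic-data generator provides structures with
    planted clustered or uniform disease sites and two-component score
    distributions so every analysis path can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
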