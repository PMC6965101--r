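Package: grpmnet
Title: Germline-Related Prognostic Modules from Survival GWAS by Network
    Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers germline-related prognostic modules (GRPMs) in cancer
    survival genome-wide association data. Per-variant Cox proportional-hazards
    statistics with left truncation, stratification and fixed-effects
    meta-analysis are aggregated into linkage-disequilibrium-aware gene-level
    P values (max- or sum-of-chi-squared with a Monte Carlo null), diffused
    over a protein-protein interaction network by insulated heat diffusion,
    and thresholded into candidate modules whose significance is assessed by a
    two-stage permutation test. Each module is summarised by a polygenic
    hazard score built by L1-penalised Cox variant selection and unpenalised
    refitting, validated in independent data, and linked to downstream
    transcriptional effects by expression correlation and pre-ranked gene-set
    enrichment. A fully seeded synthetic-cohort generator provides
    LD-structured genotypes, left-truncated survival with planted module
    effects, scale-free networks and correlated expression for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    glmnet,
    igraph,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
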