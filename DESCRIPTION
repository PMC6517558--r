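Package: rarecohort
Title: Cohort-Level Rare-Variant Burden and Phenotype Clustering for Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level analysis of rare variants on a candidate gene panel
    in case-only cohorts such as autism spectrum disorder gene-panel studies.
    Implements a quality/rarity/effect variant filter cascade over multi-sample
    VCFs, an exact binomial test for per-gene rare-variant carrier excess
    against reference carrier frequencies, genic-intolerance (RVIS percentile)
    weighted per-individual burden scores with phenotype association tests,
    mutual-information-kernel spectral clustering and kernel PCA of binarized
    clinical questionnaires, cluster-gene enrichment tests, and a synthetic
    cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
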