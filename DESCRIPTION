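Package: icsig
Title: Cross-Species Immune Checkpoint Expression Signatures
Version: 0.1.0
Authors@R:
    person("icsig", "developers", email = "icsig@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing immune checkpoint (IC) expression
    signatures across cancer types and species from bulk RNA-seq expression
    matrices. Implements median-of-ratios size-factor normalization, TPM
    conversion, log2 and per-gene z-score transforms, marker-based immune
    infiltrate composition and immune inhibition ratio scores, per-type median
    IC signatures clustered with Ward.D2 linkage on Pearson correlation
    distance, median- and mean-based differential IC expression between groups
    of cancer types, PCA with elbow and Horn parallel-analysis component
    retention and loading-based driver-gene identification, seeded UMAP
    embedding, and a seeded two-species synthetic cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    matrixStats,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
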