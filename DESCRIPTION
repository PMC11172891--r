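Package: tearosm
Title: Tear-Proteome Differential Expression and Ocular-Surface Microbiome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Label-free tear-fluid proteomics differential expression with the
    complete downstream chain used in ocular-surface studies: peptide-count and
    group-identification filtering, variance-stabilising affine-arsinh
    renormalisation, left-censored (downshift) Gaussian imputation, an
    empirical-Bayes moderated t-test with Benjamini-Hochberg adjustment, a
    fold-change-dependent significance curve, and imputation-stability flagging
    over repeated imputation cycles. Companion ocular-surface microbiome
    summaries on taxonomic relative-abundance tables: rank aggregation,
    rare-taxon lumping, Shannon diversity with Welch comparison, PCA, PERMANOVA,
    and Fisher exact presence/absence association. A synthetic-data module
    generates proteome and microbiome datasets with known ground truth so every
    stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
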