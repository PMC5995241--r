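Package: mibcSubtyper
Title: Molecular Subtyping and Survival Stratification of Muscle-Invasive Bladder Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for luminal/basal/infiltrated molecular subclassification of
    muscle-invasive bladder cancer (MIBC) from NanoString nCounter counts or
    microarray intensities. Implements the nCounter normalization chain
    (positive-control scaling, negative-control background subtraction,
    reference-gene scaling), quantile normalization, derivation of a
    cross-cohort consensus gene panel by Ward/Pearson gene clustering and Venn
    intersection, unsupervised subtype calling with nearest-centroid
    cross-cohort prediction, Kaplan-Meier/log-rank/Cox survival analysis with
    forward selection, exact r-by-c Fisher and Kruskal-Wallis association
    tests, a minimal gene-set enrichment analysis, and a synthetic-cohort
    generator reproducing the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
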