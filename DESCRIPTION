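Package: gselect
Title: Genomic Selection with GBLUP/RR-BLUP Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic selection in plant breeding programs:
    design-aware adjustment of plot-level phenotypes from replicated field
    trials (RCBD, alpha lattice, augmented designs) via linear mixed models,
    K-nearest-neighbour imputation of missing marker dosages, construction of
    the realized additive (VanRaden) relationship matrix, restricted maximum
    likelihood fitting of the GBLUP mixed model by spectral decomposition,
    narrow-sense heritability, k-fold cross-validation of prediction accuracy,
    genomic estimated breeding values (GEBVs) for selection candidates,
    multi-trait selection indices, phenotypic trait correlations, and a
    seeded simulator of breeding populations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    nlme,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
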