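Package: dynamicGP
Title: Genomic Prediction of Multi-Trait Developmental Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts time-resolved, multi-trait phenotypes of unseen
    genotypes from genome-wide markers. Per-genotype trait dynamics are
    summarised by a best-fit linear operator estimated with dynamic mode
    decomposition (classical and Schur-based, gap-aware), the entries of
    the low-rank Schur factors are treated as quantitative traits in
    ridge-regression BLUP genomic prediction models, and predicted factors
    are reassembled into an operator that forecasts whole trajectories
    iteratively or recursively. Includes VanRaden genomic relationship
    matrices, single-component REML heritability, Mantel-correlation and
    modularity-based trait panel reduction, cross-validated evaluation
    against a single-timepoint baseline, and a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
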