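Package: nicheflip
Title: Quantifying Syncytial Connectivity in a Glial Stem-Cell Niche
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for demonstrating and quantifying cytoplasmic
    connectivity in syncytial glial niches from live-imaging
    experiments. Implements the percentage-of-fluorescence-loss (%FL)
    statistic for fluorescence loss in photobleaching (FLIP) with a
    Monte-Carlo random-square null distribution and quantile threshold,
    photoconversion propagation detection, inference of compartment
    maps (connected / barrier / dynamic relations) from pairwise
    bleaching experiments, a stochastic simulator of glial clonal
    growth under endoreplication, acytokinetic mitosis and homotypic
    fusion with four-colour single-copy label induction, and
    membrane-per-stem-cell and individual-ensheathing quantifications
    on labelled 3D volumes. A seeded synthetic-movie generator built on
    a compartment-graph reaction model makes every stage testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    knitr
Config/testthat/edition: 3
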