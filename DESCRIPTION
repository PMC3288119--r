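Package: diallelgg
Title: Genetical Genomics for Partial Diallel Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for genetical-genomics experiments in
    outbred partial diallel pedigrees, modelled on two-colour microarray eQTL
    studies in conifers. Simulates multi-family pedigrees with planted eQTL and
    pQTL architectures over a framework linkage map, builds distant-pair
    two-colour hybridization designs with dye balancing, normalizes raw
    intensities (background subtraction, arsinh variance stabilization,
    cross-slide calibration) and residualizes fixed technical effects, maps
    pQTLs and eQTLs by single-marker LOD scans with per-parent detection and
    cis/trans classification, detects randomization-calibrated eQTL hotspots
    and their phenotype associations, calls positional candidate genes by
    collocation permutation tests, and infers shrinkage graphical-Gaussian
    co-expression networks with local-fdr edge probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
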