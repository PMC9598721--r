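Package: avnlbp
Title: Sector-Averaged Local Binary Patterns and Evolved Fuzzy ARTMAP for
    Texture Image Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Content-based retrieval of grayscale texture images built from
    three pieces: the AvN-LBP descriptor, a local binary pattern variant that
    averages the pixels of each angular sector of the neighborhood before
    thresholding, giving histograms that are robust to additive noise; a Fuzzy
    ARTMAP (FAM) incremental classifier with complement coding, vigilance and
    match tracking; and a differential-evolution optimizer (DEFAM) that evolves
    a population of trained FAM networks with a neighborhood-to-best mutation
    and a category-penalizing fitness, shrinking the network without losing
    accuracy. Includes retrieval scoring (precision, recall, ARP, ARR), a
    synthetic texture generator (sinusoidal gratings and Gaussian random
    fields) with stratified train/test/validation splits, and an end-to-end
    pipeline with YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
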