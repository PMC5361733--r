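Package: dsbfoci
Title: Quantification of DNA Double-Strand-Break Foci in 3D Fluorescence Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for counting gamma-H2AX and 53BP1 repair
    foci in three-dimensional multi-channel fluorescence image stacks.
    Nuclei are segmented from the nuclear-stain channel by Gaussian
    preprocessing, two-level Otsu thresholding, hysteresis and minimum-size
    filtering; foci are counted per nucleus with an extended-maxima
    (h-maxima) spot detector; cells are gated into G1 (EdU-negative) and
    S/G2 (EdU-positive) by an Otsu threshold on per-nucleus total EdU
    intensity; and the resulting per-cell counts feed a stratified
    statistics layer (condition-by-phase summaries, fold changes, Student's
    t, one-way ANOVA with Tukey HSD, and irradiation repair time courses).
    A synthetic-image generator with known ground truth emulates the
    acquisition geometry so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
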