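Package: mbstorm
Title: Molecular-Beacon FISH Probe Design and 3D-STORM Nanostructure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for super-resolution imaging of short non-repetitive
    genomic sequences with molecular-beacon (MB) FISH probes and astigmatic
    3D-STORM. Designs tiled 56-nt hairpin probes against a target locus under
    nearest-neighbor thermodynamic, uniqueness, folding and cross-hybridization
    constraints; simulates astigmatic single-molecule movies with blinking
    Alexa-647-like emitters, fiducial beads, stage drift and EMCCD noise;
    detects and fits spots per frame with elliptical Gaussians, assigns axial
    position from ellipticity, and applies stringent cleaning thresholds;
    corrects drift from fiducial bead traces; clusters localizations and calls
    labeled-DNA nanostructures under six acceptance criteria; and computes the
    associated summary statistics (event densities and false discovery ratio,
    time courses, pooled localization precision, hypergeometric detection
    specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    graphics,
    grDevices,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
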