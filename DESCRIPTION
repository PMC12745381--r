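Package: lfca
Title: Local-Field Calcium Analysis for Plate-Reader Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of calcium-oscillation movies from multi-well
    plate readers recorded with genetically encoded indicators such as
    GCaMP6f. Provides well-resolution network-spike detection based on
    peak prominence, acute drug-response metrics and four-parameter
    logistic dose-response fitting, plus a pixel-resolution local-field
    analysis that treats each pixel of the well growth area as a virtual
    electrode: active-pixel ranking, per-pixel spike detection with FWHM,
    classification of spikes inside versus outside network-spike windows,
    prominence-threshold sweeps, and pairwise pixel correlation resolved
    by distance and by network phase. Includes a synthetic plate-movie
    simulator with known ground truth, nuclei-count culture metrics
    (survival percentages, neuron-to-astrocyte ratios, cells per pixel),
    a Jensen-Shannon marker-specificity score, and the group-comparison
    statistics used to report such assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite,
    minpack.lm,
    car,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
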