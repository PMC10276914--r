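Package: tauscope
Title: Quantification Pipelines for Astrocytic Tau Uptake Microscopy and
    Synaptic Current Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Re-usable, tested implementations of the image and
    electrophysiology quantifications used to study astrocytic uptake and
    spreading of pathological tau: fluorescent inclusion (particle)
    analysis with integrated-density and size-class reporting normalized
    per living cell, DAPI-based live/condensed nucleus classification and
    condensed-nuclei accumulation scoring, skeletonization-based astrocyte
    branching morphometry, FRET-biosensor seeding readout normalized to
    cell-covered area, and template-fit detection of excitatory
    postsynaptic currents with an asymptotic test for equality of
    coefficients of variation. A synthetic-data generator emits
    multi-channel fields and current traces with exact ground-truth
    ledgers so every stage is verifiable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    generics,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    minpack.lm,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
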