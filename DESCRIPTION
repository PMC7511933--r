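Package: eaims
Title: Enzyme Activity Imaging Mass Spectrometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for enzyme-activity MALDI imaging mass
    spectrometry (EA-IMS), where a library of peptide substrates for
    proteases, kinases and phosphatases is applied to a tissue section and
    the spatial conversion of substrates into products is imaged.  The
    package computes expected substrate and product masses for a substrate
    library with modifications, validates the panel for low-mass background
    and m/z collisions, simulates ground-truth EA-IMS studies (imzML) with
    region-dependent first-order conversion kinetics, preprocesses spectra
    (convolution baseline removal, smoothing, interval intensity
    extraction), and derives ion images, conversion maps, region-of-interest
    statistics, time courses, detectability grades and control contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
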