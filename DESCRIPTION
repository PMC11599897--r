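Package: paleocycles
Title: Multicentennial Growth Cycles from Radiocarbon Records and Their
    Synchrony with Climate Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for reconstructing human population
    growth cycles from compilations of radiocarbon dates and comparing them
    with climate variability. Builds non-normalized summed probability
    distributions (SPDs) from calibrated dates, transforms them to relative
    growth rates, bandpass-filters and normalizes the series, and quantifies
    synchrony between series with Fourier spectra, trimmed (extremal)
    correlations and a tapered phase-overlap statistic. Includes spatial
    regionalization of growth rates via permutation tests and size-penalized
    k-means, reference-free multi-record dynamic time warping for aligning
    paleoclimate proxy chronologies, a principal-component climate stability
    index, and logistic boom/bust regression models. A synthetic-data module
    generates radiocarbon date tables, calibration curves, proxy ensembles
    and solar forcing series with known ground truth so that the whole
    pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
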