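Package: dcsnmr
Title: Difference Compressed Sensing for Serial 2D NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstruction of non-uniformly sampled 2D NMR spectra in serial
    experiments by compressed sensing of the difference between an undersampled
    target and a matched reference spectrum (difference compressed sensing, DCS),
    together with the surrounding toolchain: a synthetic HSQC series simulator,
    Poisson-gap sampling schedules with nested subsets, column-wise iterative
    soft-thresholding reconstruction with virtual echo, brute-force reference
    alignment (direct-dimension shift and Gaussian line broadening), and
    variable-temperature series analysis (relative peak intensities, bounded
    sigmoidal transition-temperature fits with rejection filters, normalized
    peak-height residuals).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
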