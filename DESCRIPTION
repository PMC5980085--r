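Package: prdcell
Title: Persistent Random Deformation Analysis of Crawling Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fourier shape-mode analysis of cell contours, a deformation-based
    cell migration law with least-squares estimation of its mobility
    coefficients, a stochastic simulator of the persistent random deformation
    (PRD) model driven by red-noise force multipoles, trajectory and shape
    statistics (mean squared displacement, autocorrelations, symmetrized
    densities, velocity-correlation persistence segmentation, rotation
    angles), and summary-statistic model fitting with a persistent random
    walk baseline. Includes a synthetic-data module generating contour
    movies and simulated track ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
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
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
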