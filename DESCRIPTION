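Package: ecominima
Title: Ecological Minimums via Partitioned Mahalanobis Distance and
    Circuit-Theory Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only species distribution modelling built on the
    partitioned Mahalanobis D-squared framework: bootstrap-averaged,
    sign-corrected principal components of the occurrence correlation matrix
    identify low-variance "ecological minimum" partitions; a chi-square
    rescaling maps the reduced-rank distance to a habitat similarity index
    (HSI) raster; model evaluation covers presence-background ROC/AUC,
    median-HSI summaries, dose-response curves with coverage thresholds,
    variable importance and group comparisons; and a circuit-theory solver
    converts the HSI surface to resistance and accumulates all-to-one
    current maps of population connectivity. A synthetic-landscape module
    generates spatially autocorrelated environmental rasters with a planted
    low-variance niche so the whole pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
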