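Package: ganglia
Title: Design-Based Stereology and Spatial Statistics for Sympathetic Ganglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative histology of autonomic ganglia: Cavalieri
    point-counting volume estimation with Gundersen-Jensen error prediction,
    optical-disector estimation of neuron and satellite-glia numbers with
    Z-axis guard-zone selection, TUNEL apoptotic-index computation,
    Voronoi-tessellation classification of neuronal spatial arrangement, and
    the group-comparison statistics used in stereological studies. A
    ground-truthed virtual-ganglion simulator (ellipsoidal phantoms, serial
    virtual sectioning with shrinkage) lets every estimator be validated
    against known truth without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    car,
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
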