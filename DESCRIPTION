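Package: centrodyn
Title: Population Dynamics of Centrosome Number Evolution in Newly
    Formed Tetraploid Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the early evolution of tetraploid cell populations
    generated by cytokinesis failure. Provides closed-form probabilities
    of nullisomy and monosomy in the daughters of multipolar divisions,
    linear ODE models of centrosome-class dynamics (with and without
    super-clustering cells), steady-state analysis via the leading
    eigenpair of the rate matrix, bounded least-squares fitting of free
    parameters to extra-centrosome time courses, parameter sensitivity
    scans, and a continuous-time stochastic lineage simulator that
    generates synthetic time courses and karyotype histograms. Named
    parameter presets carry published values for the DLD-1 and RPE-1
    p53-null cell lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
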