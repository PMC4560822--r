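Package: dynadapt
Title: Adaptive Inference of Phenomenological Dynamical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers phenomenological ordinary-differential-equation models of
    sparsely and noisily observed dynamical systems, possibly with hidden
    variables. Candidate models are drawn from an a-priori ordered, nested
    hierarchy within one of two complete classes (S-system power-law networks
    or continuous-time sigmoidal networks), fitted by a two-phase annealed
    search with warm starts, and scored with a generalized Bayesian
    Information Criterion that penalizes only parameter directions actually
    constrained by the data. Includes synthetic benchmark generators
    (Newtonian radial gravity, a 5-site multisite-phosphorylation network,
    and the 7-species yeast glycolysis oscillator), out-of-sample evaluation
    protocols, and JSON/SBML model export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    xml2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    readr
Config/testthat/edition: 3
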