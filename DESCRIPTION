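Package: efeunity
Title: Expected Float Entropy Minimisation and Model Unity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fitting primary relational models to small discrete
    systems by expected float entropy (EFE) minimisation, and for deciding
    whether a system has model unity, i.e. whether a single relational
    model stretched across the whole system outperforms every decomposition
    of the system into separately modelled subsystems. Provides the weighted
    relation algebra, float entropy and EFE evaluation with a sorted
    discontinuity profile, derivative-free optimisers (multistart
    Nelder-Mead and iterative grid search), full set-partition analysis of
    the unity functionals mu and M, maximal-subsystem and transitivity
    surveys, a mode-distance pseudometric, an image posterisation and grid
    sampling pipeline, and seeded synthetic corpus generators for
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
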