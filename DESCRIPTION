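Package: releaseopt
Title: Sustained-Release Formulation Modeling and Multi-Objective Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling and optimizing multi-component sustained-release
    formulations from mixture-design dissolution studies. Builds q-component
    centered-polynomial candidate term sets, screens terms by penalized least
    squares (LASSO, SCAD, MCP) with cluster-wise cross-validation, fits the
    repeated-measures release model by quadratic inference functions (QIF) with
    an AR(1) basis-matrix working correlation, turns the fitted model into
    exterior-penalty objective functions on the constant-sum simplex slice, and
    searches the composition space with three multi-objective metaheuristics
    (NSGA-III, MOGWO, NSWOA). Pooled Pareto candidates are screened against
    pharmacopoeia release limits and ranked by entropy-weighted TOPSIS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Rcpp,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite
Config/testthat/edition: 3
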