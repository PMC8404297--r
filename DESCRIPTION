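Package: mcarmap
Title: Joint Bayesian Mapping of Multiple Diseases with Multivariate CAR Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint (multiple-disease) Bayesian disease mapping on areal
    units. Builds stratified person-years and internally standardized
    expected counts from individual-level event records, fits a
    multivariate Poisson model whose disease-specific area effects follow
    a coregionalized Leroux conditional-autoregressive (CAR) prior by
    Metropolis-within-Gibbs MCMC, compares model variants by DIC, and
    summarizes smoothed standardized incidence ratio (SIR) surfaces with
    significance classes and between-disease conditional correlations.
    Includes a synthetic-data generator (areal lattice with islands,
    individual-level cohorts and aggregated count cubes) with known
    ground truth so that every stage is testable without restricted
    registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
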