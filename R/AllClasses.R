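## S4 classes for the central data objects. Validity methods enforce the
## structural invariants; statistical invariants (e.g. positive definiteness
## of a proposed covariance) are handled by the model code, which rejects
## invalid states rather than erroring.

#' Areal adjacency structure
#'
#' A symmetric binary neighbour matrix over a fixed, ordered set of areas,
#' together with a record of island links added beyond shared borders
#' (areas connected by ferry or bridge rather than a land border).
#'
#' @slot areaIds ordered character vector of unique area labels; all
#'   matrices and vectors in the package index areas in this order.
#' @slot W n x n binary matrix; \code{W[i, k] == 1} iff areas i and k are
#'   neighbours. Symmetric, zero diagonal.
#' @slot islandLinks two-column character matrix (island, linked area) of
#'   links added by \code{\link{linkIslands}}.
#' @seealso \code{\link{buildAdjacency}}, \code{\link{linkIslands}},
#'   \code{\link{neighbourCounts}}
#' @export
setClass("AdjacencyGraph",
  representation(areaIds = "character", W = "matrix", islandLinks = "matrix"))

setValidity("AdjacencyGraph", function(object) {
  ids <- object@areaIds
  W <- object@W
  msgs <- character()
  if (anyDuplicated(ids)) msgs <- c(msgs, "area ids must be unique")
  if (!is.numeric(W) || nrow(W) != length(ids) || ncol(W) != length(ids))
    msgs <- c(msgs, "W must be a numeric n x n matrix matching areaIds")
  else {
    if (!all(W %in% c(0, 1))) msgs <- c(msgs, "W entries must be 0 or 1")
    if (!isTRUE(all.equal(W, t(W)))) msgs <- c(msgs, "W must be symmetric")
    if (any(diag(W) != 0)) msgs <- c(msgs, "W diagonal must be 0")
  }
  il <- object@islandLinks
  if (ncol(il) != 2) msgs <- c(msgs, "islandLinks must have two columns")
  else if (nrow(il) > 0) {
    bad <- !(il[, 1] %in% ids) | !(il[, 2] %in% ids)
    if (any(bad)) msgs <- c(msgs, "islandLinks refer to unknown area ids")
    else {
      i <- match(il[, 1], ids); k <- match(il[, 2], ids)
      if (any(W[cbind(i, k)] != 1))
        msgs <- c(msgs, "islandLinks must be 1-entries of W")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Person-years at risk by area, disease and stratum
#'
#' The standardization backbone: person-years at risk T[i, j, k] per area
#' i, disease j and stratum k, where the 24 strata are the nested
#' sex (2) x age-group (4) x income-group (3) combinations.
#'
#' @slot py numeric array, areas x diseases x strata, entries >= 0, with
#'   dimnames.
#' @slot diseases character vector of disease labels.
#' @slot strata data.frame with columns \code{sex}, \code{ageGroup},
#'   \code{income} and \code{label}, one row per stratum in the fixed
#'   nested order (see \code{\link{defaultStrata}}).
#' @export
setClass("ExposureCube",
  representation(py = "array", diseases = "character", strata = "data.frame"))

setValidity("ExposureCube", function(object) {
  d <- dim(object@py)
  msgs <- character()
  if (length(d) != 3) msgs <- c(msgs, "py must be a 3-d array")
  else {
    if (d[2] != length(object@diseases))
      msgs <- c(msgs, "second dim of py must match diseases")
    if (d[3] != nrow(object@strata))
      msgs <- c(msgs, "third dim of py must match strata")
    if (any(object@py < 0)) msgs <- c(msgs, "person-years must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' National stratum-specific incidence rates
#'
#' @slot rates matrix, diseases x strata, of incidence rates per
#'   person-year (national cases in the stratum / national person-years).
#' @slot strata stratum descriptor data.frame (as in
#'   \code{\link{ExposureCube-class}}).
#' @export
setClass("NationalRates",
  representation(rates = "matrix", strata = "data.frame"))

setValidity("NationalRates", function(object) {
  if (any(object@rates < 0)) "rates must be >= 0" else TRUE
})

#' Observed incident case counts by area and disease
#'
#' @slot counts nonnegative integer matrix, areas x diseases, with
#'   dimnames.
#' @export
setClass("ObservedCounts", representation(counts = "matrix"))

setValidity("ObservedCounts", function(object) {
  y <- object@counts
  if (any(y < 0) || any(y != round(y)))
    "counts must be nonnegative integers" else TRUE
})

#' Expected case counts under internal standardization
#'
#' E[i, j] = sum_k R[j, k] * T[i, j, k]; when the national rates were
#' computed from the same data, column sums of E equal the national case
#' totals (the internal-standardization identity).
#'
#' @slot expected numeric matrix, areas x diseases, entries >= 0.
#' @export
setClass("ExpectedCounts", representation(expected = "matrix"))

setValidity("ExpectedCounts", function(object) {
  if (any(object@expected < 0)) "expected counts must be >= 0" else TRUE
})

#' Generating ground truth for synthetic datasets
#'
#' @slot variant one of "M1" (disease-specific spatial correlation,
#'   correlated diseases), "M2" (shared spatial correlation, correlated
#'   diseases), "M3" (independent diseases).
#' @slot beta disease intercepts (log relative scale).
#' @slot Sigma between-disease covariance of the area effects
#'   (symmetric positive definite).
#' @slot rho spatial correlation parameter(s) in [0, 1): scalar for M2, one
#'   per disease for M1/M3.
#' @slot uField areas x diseases matrix of latent unit-scale Leroux fields.
#' @slot phiField areas x diseases matrix of disease-specific area effects,
#'   phiField = uField %*% t(A) with A the lower Cholesky factor of Sigma.
#' @export
setClass("GroundTruth",
  representation(variant = "character", beta = "numeric", Sigma = "matrix",
                 rho = "numeric", uField = "matrix", phiField = "matrix"))

setValidity("GroundTruth", function(object) {
  msgs <- character()
  if (!object@variant %in% c("M1", "M2", "M3"))
    msgs <- c(msgs, "variant must be M1, M2 or M3")
  S <- object@Sigma
  if (!isTRUE(all.equal(S, t(S)))) msgs <- c(msgs, "Sigma must be symmetric")
  else if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    msgs <- c(msgs, "Sigma must be positive definite")
  if (any(object@rho < 0) || any(object@rho >= 1))
    msgs <- c(msgs, "rho must lie in [0, 1)")
  if (length(msgs) == 0) {
    A <- t(chol(S))
    if (!isTRUE(all.equal(object@phiField,
                          object@uField %*% t(A),
                          check.attributes = FALSE, tolerance = 1e-8)))
      msgs <- c(msgs, "phiField must equal uField %*% t(chol(Sigma))")
  }
  if (length(msgs)) msgs else TRUE
})

#' Model variant and priors for the multivariate CAR Poisson model
#'
#' @slot variant "M1", "M2" or "M3" (see \code{\link{GroundTruth-class}}).
#' @slot nDiseases number of jointly modelled diseases (3 in the standard
#'   analysis; 1 gives a univariate Leroux model).
#' @slot priorSdUpper upper bound of the uniform prior on the standard
#'   deviation parameters of Sigma (default 10; 100 in the sensitivity
#'   analysis).
#' @slot priorBetaPrecision precision of the zero-mean Gaussian prior on
#'   the intercepts (default 0.1, weakly informative).
#' @slot corrBounds support of the uniform prior on the pairwise
#'   correlations; \code{c(0, 1)} by default (nonnegative between-disease
#'   correlation), \code{c(-1, 1)} available as an extension.
#' @slot rhoBounds support of the uniform prior on the spatial correlation
#'   parameter(s); fixed at \code{c(0, 1)}.
#' @seealso \code{\link{mcarModelSpec}}
#' @export
setClass("MCARModelSpec",
  representation(variant = "character", nDiseases = "integer",
                 priorSdUpper = "numeric", priorBetaPrecision = "numeric",
                 corrBounds = "numeric", rhoBounds = "numeric"))

setValidity("MCARModelSpec", function(object) {
  msgs <- character()
  if (!object@variant %in% c("M1", "M2", "M3"))
    msgs <- c(msgs, "variant must be M1, M2 or M3")
  if (object@priorSdUpper <= 0) msgs <- c(msgs, "priorSdUpper must be > 0")
  if (object@priorBetaPrecision <= 0)
    msgs <- c(msgs, "priorBetaPrecision must be > 0")
  if (length(object@corrBounds) != 2 ||
      object@corrBounds[1] >= object@corrBounds[2])
    msgs <- c(msgs, "corrBounds must be an increasing pair")
  if (length(msgs)) msgs else TRUE
})

#' One state of the posterior sampler
#'
#' @slot beta disease intercepts.
#' @slot u areas x diseases matrix of unit-scale latent fields.
#' @slot sigmaSd standard deviation parameters (sqrt of diag(Sigma)).
#' @slot sigmaCorr pairwise correlations of Sigma in the order (1,2),
#'   (1,3), (2,3); all zero for M3 / univariate fits.
#' @slot rho spatial correlation parameter(s): scalar for M2, one per
#'   disease for M1/M3.
#' @export
setClass("PosteriorState",
  representation(beta = "numeric", u = "matrix", sigmaSd = "numeric",
                 sigmaCorr = "numeric", rho = "numeric"))

setValidity("PosteriorState", function(object) {
  msgs <- character()
  if (ncol(object@u) != length(object@beta))
    msgs <- c(msgs, "u must have one column per disease")
  if (length(object@sigmaSd) != length(object@beta))
    msgs <- c(msgs, "sigmaSd must have one entry per disease")
  if (any(!is.finite(object@beta)) || any(!is.finite(object@u)))
    msgs <- c(msgs, "state must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Retained MCMC draws and sampler metadata
#'
#' @slot chains list with one element per chain; each chain is a list of
#'   arrays of retained draws: \code{beta} (draws x diseases), \code{sd},
#'   \code{corr}, \code{rho}, \code{u} (draws x areas x diseases),
#'   \code{mu} (draws x areas x diseases fitted means
#'   \eqn{\mu_{ij} = E_{ij} exp(\beta_j + \phi_{ij})}) and
#'   \code{deviance}.
#' @slot spec the \code{\link{MCARModelSpec-class}} that was fitted.
#' @slot control sampler control list (iterations, burnIn, thin, seeds).
#' @slot accept per-chain acceptance rates of the adapted random-walk
#'   updates.
#' @slot seeds per-chain (and, for M3, per-disease) RNG seeds.
#' @slot areaIds area labels in model order.
#' @slot diseases disease labels.
#' @export
setClass("ChainOutput",
  representation(chains = "list", spec = "MCARModelSpec", control = "list",
                 accept = "list", seeds = "list", areaIds = "character",
                 diseases = "character"))

setValidity("ChainOutput", function(object) {
  if (length(object@chains) < 1) return("at least one chain required")
  ok <- vapply(object@chains, function(ch)
    all(c("beta", "sd", "rho", "u", "mu", "deviance") %in% names(ch)),
    logical(1))
  if (!all(ok)) "each chain must carry beta/sd/rho/u/mu/deviance draws"
  else TRUE
})

#' Posterior SIR surface
#'
#' Per (area, disease): posterior median standardized incidence ratio,
#' central credible interval, and significance class ("above 1" iff the
#' lower bound exceeds 1, "below 1" iff the upper bound is below 1, else
#' "not significant").
#'
#' @slot table data.frame with columns \code{area}, \code{disease},
#'   \code{sir_median}, \code{ci_low}, \code{ci_high}, \code{class}.
#' @slot level credible level used for the interval (default 0.95).
#' @export
setClass("SIRSurface",
  representation(table = "data.frame", level = "numeric"))

setValidity("SIRSurface", function(object) {
  tb <- object@table
  need <- c("area", "disease", "sir_median", "ci_low", "ci_high", "class")
  if (!all(need %in% names(tb))) return("surface table missing columns")
  ok <- stats::complete.cases(tb[, c("sir_median", "ci_low", "ci_high")])
  if (any(tb$ci_low[ok] > tb$sir_median[ok] + 1e-12) ||
      any(tb$sir_median[ok] > tb$ci_high[ok] + 1e-12))
    return("quantiles must be ordered ci_low <= median <= ci_high")
  TRUE
})

#' Between-disease conditional correlations at collocation
#'
#' @slot pairs data.frame with columns \code{pair}, \code{median},
#'   \code{ci_low}, \code{ci_high}: the posterior summary of each pairwise
#'   conditional correlation implied by Sigma.
#' @slot rho data.frame summarizing the spatial correlation parameter(s).
#' @slot variant model variant the summary was computed from.
#' @export
setClass("CorrelationSummary",
  representation(pairs = "data.frame", rho = "data.frame",
                 variant = "character"))

#' Individual-level synthetic cohort
#'
#' Emulates a register extract: fixed person attributes plus per-calendar-
#' year area and income assignments.
#'
#' @slot persons data.frame with columns \code{id}, \code{birthDate},
#'   \code{sex}, per-disease first-diagnosis date columns
#'   (\code{dx_<disease>}, NA when absent, possibly before study start),
#'   \code{deathDate} and \code{emigrationDate} (NA when absent).
#' @slot yearly data.frame with columns \code{id}, \code{year},
#'   \code{area}, \code{income}: the 1 January area assignment and the
#'   income group consumed for that calendar year.
#' @slot diseases disease labels (matching the \code{dx_} columns).
#' @export
setClass("SyntheticCohort",
  representation(persons = "data.frame", yearly = "data.frame",
                 diseases = "character"))

setValidity("SyntheticCohort", function(object) {
  p <- object@persons
  msgs <- character()
  dxCols <- paste0("dx_", object@diseases)
  if (!all(c("id", "birthDate", "sex", "deathDate", "emigrationDate",
             dxCols) %in% names(p)))
    msgs <- c(msgs, "persons table missing required columns")
  else {
    for (cc in dxCols) {
      both <- !is.na(p[[cc]])
      if (any(p[[cc]][both] <= p$birthDate[both]))
        msgs <- c(msgs, sprintf("%s must be after birth", cc))
      withDeath <- both & !is.na(p$deathDate)
      if (any(p[[cc]][withDeath] > p$deathDate[withDeath]))
        msgs <- c(msgs, sprintf("%s must be <= death date", cc))
    }
  }
  if (!all(c("id", "year", "area", "income") %in% names(object@yearly)))
    msgs <- c(msgs, "yearly table missing required columns")
  if (length(msgs)) msgs else TRUE
})

#' Study window
#'
#' @slot start first day at risk (events on it are incident).
#' @slot end last day of follow-up, inclusive.
#' @slot minAge minimum age in whole years at \code{start}; the study
#'   population is closed (fixed at the index date).
#' @export
setClass("StudyWindow",
  representation(start = "Date", end = "Date", minAge = "numeric"))

setValidity("StudyWindow", function(object) {
  msgs <- character()
  if (object@start > object@end) msgs <- c(msgs, "start must be <= end")
  if (object@minAge < 0) msgs <- c(msgs, "minAge must be >= 0")
  if (length(msgs)) msgs else TRUE
})
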