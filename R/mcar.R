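## Model definition, log-posterior, initial states and the MCMC driver.

#' Model specification constructor
#'
#' The three competing variants of the multivariate Poisson model with
#' coregionalized Leroux-CAR area effects:
#' \describe{
#'   \item{M1}{disease-specific spatial correlation parameters rho_j,
#'     correlated diseases (most complex; between-disease correlation is
#'     municipality specific);}
#'   \item{M2}{a single shared rho, correlated diseases (the separable
#'     model);}
#'   \item{M3}{no correlation between diseases (equivalent to univariate
#'     modelling of each disease), disease-specific rho_j.}
#' }
#'
#' @param variant "M1", "M2" or "M3".
#' @param nDiseases 3 for the joint analysis; 1 fits a univariate Leroux
#'   model.
#' @param priorSdUpper upper bound of the U(0, upper) prior on the sd
#'   parameters of Sigma (10 by default; 100 for the prior sensitivity
#'   analysis).
#' @param priorBetaPrecision precision of the N(0, 1/precision) intercept
#'   prior (0.1, weakly informative).
#' @param allowNegativeCorr if TRUE, widen the correlation prior from
#'   U(0, 1) to U(-1, 1) (extension, off by default: the reference prior
#'   restricts between-disease correlations to be nonnegative).
#' @return an \code{\link{MCARModelSpec-class}}.
#' @export
mcarModelSpec <- function(variant = c("M2", "M1", "M3"), nDiseases = 3L,
                          priorSdUpper = 10, priorBetaPrecision = 0.1,
                          allowNegativeCorr = FALSE) {
  variant <- match.arg(variant)
  new("MCARModelSpec", variant = variant, nDiseases = as.integer(nDiseases),
      priorSdUpper = priorSdUpper, priorBetaPrecision = priorBetaPrecision,
      corrBounds = if (allowNegativeCorr) c(-1, 1) else c(0, 1),
      rhoBounds = c(0, 1))
}

setMethod("show", "MCARModelSpec", function(object) {
  cat("MCARModelSpec", object@variant, "-", object@nDiseases, "diseases;",
      "priors: sd ~ U(0,", object@priorSdUpper, "), corr ~ U(",
      object@corrBounds[1], ",", object@corrBounds[2],
      "), rho ~ U(0, 1), beta ~ N(0, prec", object@priorBetaPrecision, ")\n")
})

#' Leroux CAR precision matrix
#'
#' Q(rho) = rho (D - W) + (1 - rho) I, where D is the diagonal matrix of
#' neighbour counts. Q interpolates between independence (rho = 0) and
#' the intrinsic CAR (rho -> 1) and is symmetric positive definite for
#' all rho in [0, 1).
#'
#' @param graph an \code{\link{AdjacencyGraph-class}}.
#' @param rho spatial correlation parameter in [0, 1).
#' @return dense n x n precision matrix with area-id dimnames.
#' @export
lerouxPrecision <- function(graph, rho) {
  stopifnot(is(graph, "AdjacencyGraph"))
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("rho must be a single value in [0, 1)")
  W <- graph@W
  D <- diag(rowSums(W), nrow(W))
  Q <- rho * (D - W) + (1 - rho) * diag(nrow(W))
  dimnames(Q) <- dimnames(W)
  Q
}

#' Posterior state constructor
#'
#' @param beta disease intercepts.
#' @param u areas x diseases matrix of unit-scale latent fields.
#' @param sigmaSd standard deviation parameters.
#' @param sigmaCorr pairwise correlations, order (1,2), (1,3), (2,3);
#'   zeros for M3/univariate.
#' @param rho spatial correlation parameter(s).
#' @return a \code{\link{PosteriorState-class}}.
#' @export
posteriorState <- function(beta, u, sigmaSd, sigmaCorr, rho) {
  new("PosteriorState", beta = beta, u = as.matrix(u), sigmaSd = sigmaSd,
      sigmaCorr = sigmaCorr, rho = rho)
}

#' Log-posterior density of one state
#'
#' Sum of (a) the Poisson log-likelihood over all (area, disease) cells
#' (cells with E = 0 and Y = 0 are dropped); (b) the Gaussian log-density
#' of each unit-scale latent field u_j under its Leroux precision
#' Q(rho_j), including the log-determinant; (c) the log-priors: the
#' Gaussian intercept prior and the (constant-inside-support) uniform
#' priors on sd, correlation and rho. Returns -Inf (never an error) when
#' any parameter is outside its prior support or the implied Sigma is not
#' positive definite.
#'
#' @param state a \code{\link{PosteriorState-class}}.
#' @param spec an \code{\link{MCARModelSpec-class}}.
#' @param Y an \code{ObservedCounts} (or matrix).
#' @param E an \code{ExpectedCounts} (or matrix).
#' @param graph the \code{AdjacencyGraph}.
#' @return scalar log posterior density (up to the constant uniform
#'   normalizers, which are included inside the support).
#' @export
logPosterior <- function(state, spec, Y, E, graph) {
  Ym <- if (is(Y, "ObservedCounts")) Y@counts else as.matrix(Y)
  Em <- if (is(E, "ExpectedCounts")) E@expected else as.matrix(E)
  J <- spec@nDiseases
  n <- nAreas(graph)
  stopifnot(ncol(Ym) == J, nrow(Ym) == n, all(dim(Ym) == dim(Em)))

  sd <- state@sigmaSd
  corr <- if (spec@variant == "M3" || J == 1) rep(0, max(J * (J - 1) / 2, 0))
          else state@sigmaCorr
  rho <- state@rho
  ## prior support
  if (any(sd <= 0) || any(sd >= spec@priorSdUpper)) return(-Inf)
  if (length(corr) &&
      (any(corr <= spec@corrBounds[1]) || any(corr >= spec@corrBounds[2])) &&
      !(spec@variant == "M3" || J == 1)) return(-Inf)
  if (any(rho <= 0) || any(rho >= 1)) return(-Inf)
  A <- cholFromSdCorr(sd, corr)
  if (is.null(A)) return(-Inf)

  rhoVec <- if (spec@variant == "M2" && J > 1) rep(rho[1], J)
            else rep(rho, length.out = J)

  phi <- state@u %*% t(A)
  lp <- 0
  ## (a) Poisson likelihood
  mu <- Em * exp(sweep(phi, 2, state@beta, "+"))
  keep <- !(Em == 0 & Ym == 0)
  if (any(Ym[!keep] > 0)) stop("cell with E = 0 but Y > 0: model undefined")
  lp <- lp + sum(stats::dpois(Ym[keep], mu[keep], log = TRUE))
  ## (b) latent fields under Q(rho_j), unit conditional scale
  W <- graph@W
  DW <- diag(rowSums(W), n) - W
  for (j in seq_len(J)) {
    Q <- rhoVec[j] * DW + (1 - rhoVec[j]) * diag(n)
    uj <- state@u[, j]
    lp <- lp + 0.5 * determinant(Q, logarithm = TRUE)$modulus -
      0.5 * drop(crossprod(uj, Q %*% uj)) - n / 2 * log(2 * pi)
  }
  ## (c) priors
  lp <- lp + sum(stats::dnorm(state@beta, 0,
                              sqrt(1 / spec@priorBetaPrecision), log = TRUE))
  lp <- lp - J * log(spec@priorSdUpper)
  if (length(corr) && !(spec@variant == "M3" || J == 1))
    lp <- lp - length(corr) * log(diff(spec@corrBounds))
  as.numeric(lp)
}

#' Initial states for the chains
#'
#' Chain 1 starts at a null state: beta_j = log(sum Y_j / sum E_j), u = 0,
#' sd = 0.5, correlations 0.1, rho = 0.5. Further chains are perturbed by
#' seeded overdispersed jitter (and redrawn until the implied Sigma is
#' positive definite), so chains start from genuinely different values.
#' For M3 (and univariate fits) the jitter stream is derived per disease,
#' which keeps a joint M3 fit draw-for-draw identical to three univariate
#' fits.
#'
#' @param spec an \code{\link{MCARModelSpec-class}}.
#' @param Y,E count and expected matrices (or their S4 wrappers).
#' @param nChains number of chains (>= 1).
#' @param seed integer seed for the jitter.
#' @param nAreasHint number of areas (needed to size u); inferred from Y.
#' @return list of \code{\link{PosteriorState-class}} objects.
#' @export
initialStates <- function(spec, Y, E, nChains = 2, seed = 1,
                          nAreasHint = NULL) {
  Ym <- if (is(Y, "ObservedCounts")) Y@counts else as.matrix(Y)
  Em <- if (is(E, "ExpectedCounts")) E@expected else as.matrix(E)
  J <- spec@nDiseases
  n <- if (is.null(nAreasHint)) nrow(Ym) else nAreasHint
  nc <- J * (J - 1) / 2
  beta0 <- log(pmax(colSums(Ym), 0.5) / colSums(Em))
  perDisease <- spec@variant == "M3" || J == 1
  out <- vector("list", nChains)
  for (ch in seq_len(nChains)) {
    if (ch == 1) {
      out[[ch]] <- posteriorState(
        beta = beta0, u = matrix(0, n, J), sigmaSd = rep(0.5, J),
        sigmaCorr = rep(if (spec@variant == "M3") 0 else 0.1, nc),
        rho = rep(0.5, if (spec@variant == "M2" && J > 1) 1 else J))
      next
    }
    jitterOne <- function(sd1) {  # one disease's jittered components
      list(db = stats::rnorm(1, 0, 0.5), u = stats::rnorm(n, 0, 0.1),
           sd = min(stats::runif(1, 0.2, 1.5), spec@priorSdUpper * 0.9),
           rho = stats::runif(1, 0.1, 0.9))
    }
    if (perDisease) {
      comp <- lapply(seq_len(J), function(j)
        withSeed(seed + (j - 1) + 104729 * ch, jitterOne()))
      out[[ch]] <- posteriorState(
        beta = beta0 + vapply(comp, `[[`, numeric(1), "db"),
        u = vapply(comp, `[[`, numeric(n), "u"),
        sigmaSd = vapply(comp, `[[`, numeric(1), "sd"),
        sigmaCorr = rep(0, nc),
        rho = vapply(comp, `[[`, numeric(1), "rho"))
    } else {
      out[[ch]] <- withSeed(seed + 104729 * ch, {
        sd1 <- pmin(stats::runif(J, 0.2, 1.5), spec@priorSdUpper * 0.9)
        repeat {
          corr1 <- stats::runif(nc, 0.05, 0.5)
          if (!is.null(cholFromSdCorr(sd1, corr1))) break
        }
        posteriorState(
          beta = beta0 + stats::rnorm(J, 0, 0.5),
          u = matrix(stats::rnorm(n * J, 0, 0.1), n, J),
          sigmaSd = sd1, sigmaCorr = corr1,
          rho = stats::runif(if (spec@variant == "M2") 1 else J, 0.1, 0.9))
      })
    }
  }
  out
}

#' MCMC control parameters
#'
#' Defaults are the scaled-down protocol used throughout the package:
#' 2 chains of 20,000 iterations, the first 10,000 discarded as burn-in,
#' thinning to every 10th sample (2 x 1,000 retained draws). The
#' full-scale protocol of the motivating analysis (10,000 retained draws
#' from 2 chains, burn-in 10,000, thinning 100) is
#' \code{mcmcControl(iterations = 510000, burnIn = 10000, thin = 100)}.
#'
#' @param nChains number of chains (2 by default).
#' @param iterations total iterations per chain.
#' @param burnIn burn-in iterations (step sizes adapt only here).
#' @param thin retain every thin-th post-burn-in draw.
#' @param seed integer master seed; per-chain (and for M3 per-disease)
#'   streams are derived from it.
#' @param adaptInterval step-size adaptation interval during burn-in.
#' @param updateHyper if FALSE, hold sd/corr/rho at their initial values
#'   (intercept-plus-field fits and closed-form checks).
#' @param likelihood "poisson" (the model) or "gaussian" (test harness
#'   with Y ~ N(beta + phi, gaussSd^2), no offset).
#' @param gaussSd known sd of the Gaussian test likelihood.
#' @return validated control list.
#' @export
mcmcControl <- function(nChains = 2, iterations = 20000, burnIn = 10000,
                        thin = 10, seed = 1, adaptInterval = 50,
                        updateHyper = TRUE,
                        likelihood = c("poisson", "gaussian"),
                        gaussSd = 1) {
  likelihood <- match.arg(likelihood)
  stopifnot(nChains >= 1, iterations > burnIn, burnIn >= 0, thin >= 1,
            adaptInterval >= 1, gaussSd > 0)
  list(nChains = as.integer(nChains), iterations = as.integer(iterations),
       burnIn = as.integer(burnIn), thin = as.integer(thin),
       seed = as.integer(seed), adaptInterval = as.integer(adaptInterval),
       updateHyper = isTRUE(updateHyper), likelihood = likelihood,
       gaussSd = gaussSd)
}

#' Fit the multivariate CAR Poisson model by MCMC
#'
#' Metropolis-within-Gibbs: single-site random-walk updates of the latent
#' fields, random-walk updates of the intercepts, and random-walk updates
#' of the sd / correlation / spatial-correlation parameters on log or
#' logit scales with Jacobians; Sigma positive definiteness is enforced
#' by rejection. Step sizes adapt towards 0.44 acceptance during burn-in
#' only and are frozen afterwards. Output is deterministic given the
#' control seed. For M3 each disease runs on its own derived RNG stream
#' (seed + j - 1), making the joint fit identical draw-for-draw to three
#' univariate fits.
#'
#' @param spec an \code{\link{MCARModelSpec-class}}.
#' @param Y an \code{ObservedCounts} (or count matrix), areas x diseases.
#' @param E an \code{ExpectedCounts} (or matrix), same shape, E > 0
#'   wherever Y > 0.
#' @param graph the \code{AdjacencyGraph} (after island linking).
#' @param control a \code{\link{mcmcControl}} list.
#' @param inits optional list of \code{PosteriorState}s (default:
#'   \code{\link{initialStates}}).
#' @return a \code{\link{ChainOutput-class}}.
#' @export
fitMcmc <- function(spec, Y, E, graph, control = mcmcControl(),
                    inits = NULL) {
  stopifnot(is(spec, "MCARModelSpec"), is(graph, "AdjacencyGraph"))
  Ym <- if (is(Y, "ObservedCounts")) Y@counts else as.matrix(Y)
  Em <- if (is(E, "ExpectedCounts")) E@expected else as.matrix(E)
  n <- nAreas(graph)
  J <- spec@nDiseases
  if (nrow(Ym) != n || ncol(Ym) != J || !all(dim(Ym) == dim(Em)))
    stop("Y/E must be ", n, " x ", J, " matching the graph and spec")
  if (any(Em == 0 & Ym > 0)) stop("cell with E = 0 but Y > 0: model undefined")
  diseases <- colnames(Ym)
  if (is.null(diseases)) diseases <- paste0("disease", seq_len(J))

  W <- graph@W
  deg <- rowSums(W)
  nbList <- lapply(seq_len(n), function(i) which(W[i, ] == 1) - 1L)
  eigDW <- eigen(diag(deg, n) - W, symmetric = TRUE, only.values = TRUE)$values

  if (is.null(inits))
    inits <- initialStates(spec, Ym, Em, control$nChains, control$seed)
  lik <- if (control$likelihood == "poisson") 0L else 1L
  perDisease <- spec@variant == "M3" && J > 1

  chains <- vector("list", control$nChains)
  accept <- vector("list", control$nChains)
  seeds <- vector("list", control$nChains)
  S <- (control$iterations - control$burnIn) %/% control$thin
  nc <- J * (J - 1) / 2

  for (ch in seq_len(control$nChains)) {
    st <- inits[[ch]]
    chainSeed <- control$seed + 7919 * (ch - 1)
    if (perDisease) {
      beta <- matrix(0, S, J); sdD <- matrix(0, S, J)
      rhoD <- matrix(0, S, J); dev <- numeric(S)
      uArr <- array(0, c(S, n, J)); muArr <- array(0, c(S, n, J))
      accJ <- list(); seedJ <- numeric(J)
      for (j in seq_len(J)) {
        seedJ[j] <- chainSeed + (j - 1)
        res <- mcarChainCpp(Ym[, j, drop = FALSE], Em[, j, drop = FALSE],
                            nbList, deg, eigDW,
                            sharedRho = TRUE, likelihood = lik,
                            gaussSd = control$gaussSd,
                            sdUpper = spec@priorSdUpper,
                            betaPrec = spec@priorBetaPrecision,
                            corrLo = spec@corrBounds[1],
                            corrHi = spec@corrBounds[2],
                            betaInit = st@beta[j],
                            uInit = st@u[, j, drop = FALSE],
                            sdInit = st@sigmaSd[j], corrInit = numeric(0),
                            rhoInit = st@rho[min(j, length(st@rho))],
                            iterations = control$iterations,
                            burnIn = control$burnIn, thin = control$thin,
                            updateHyper = control$updateHyper,
                            adaptInterval = control$adaptInterval,
                            seedD = seedJ[j])
        beta[, j] <- res$beta; sdD[, j] <- res$sd; rhoD[, j] <- res$rho
        dev <- dev + res$deviance
        uArr[, , j] <- res$u[, , 1]; muArr[, , j] <- res$mu[, , 1]
        accJ[[diseases[j]]] <- res$accept
      }
      chains[[ch]] <- list(beta = beta, sd = sdD,
                           corr = matrix(0, S, nc), rho = rhoD,
                           u = uArr, mu = muArr, deviance = dev)
      accept[[ch]] <- accJ
      seeds[[ch]] <- seedJ
    } else {
      res <- mcarChainCpp(Ym, Em, nbList, deg, eigDW,
                          sharedRho = (spec@variant == "M2" && J > 1),
                          likelihood = lik, gaussSd = control$gaussSd,
                          sdUpper = spec@priorSdUpper,
                          betaPrec = spec@priorBetaPrecision,
                          corrLo = spec@corrBounds[1],
                          corrHi = spec@corrBounds[2],
                          betaInit = st@beta, uInit = st@u,
                          sdInit = st@sigmaSd, corrInit = st@sigmaCorr,
                          rhoInit = st@rho,
                          iterations = control$iterations,
                          burnIn = control$burnIn, thin = control$thin,
                          updateHyper = control$updateHyper,
                          adaptInterval = control$adaptInterval,
                          seedD = chainSeed)
      chains[[ch]] <- res[c("beta", "sd", "corr", "rho", "u", "mu",
                            "deviance")]
      accept[[ch]] <- res$accept
      seeds[[ch]] <- chainSeed
    }
  }
  new("ChainOutput", chains = chains, spec = spec, control = control,
      accept = accept, seeds = seeds, areaIds = areaIds(graph),
      diseases = diseases)
}

## ---- ChainOutput accessors ------------------------------------------------

#' @describeIn retainedDraws pooled draws across chains; matrices get the
#'   draw dimension first, u/mu come back as draws x areas x diseases
#'   arrays.
#' @export
setMethod("retainedDraws", "ChainOutput", function(x, what = "beta") {
  stopifnot(what %in% c("beta", "sd", "corr", "rho", "u", "mu", "deviance"))
  parts <- lapply(x@chains, `[[`, what)
  if (what == "deviance") return(unlist(parts, use.names = FALSE))
  if (what %in% c("u", "mu")) {
    out <- do.call(abind0, parts)
    return(out)
  }
  do.call(rbind, parts)
})

## minimal first-dimension array bind (avoids an abind dependency)
abind0 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  S <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(S, d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @describeIn nDraws total retained draws across chains
#' @export
setMethod("nDraws", "ChainOutput", function(x)
  sum(vapply(x@chains, function(ch) length(ch$deviance), numeric(1))))

#' @describeIn diseaseLabels diseases of a fit
#' @export
setMethod("diseaseLabels", "ChainOutput", function(x) x@diseases)

setMethod("show", "ChainOutput", function(object) {
  cat("ChainOutput:", object@spec@variant, "fit,",
      length(object@chains), "chain(s) x",
      length(object@chains[[1]]$deviance), "retained draws;",
      length(object@areaIds), "areas x", length(object@diseases),
      "diseases\n")
  cat("  mean deviance:",
      round(mean(retainedDraws(object, "deviance")), 1), "\n")
})

#' Persist a fit as per-parameter CSV draw tables plus a JSON manifest
#'
#' @param chain a \code{ChainOutput}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeChainOutput <- function(chain, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (what in c("beta", "sd", "corr", "rho")) {
    d <- retainedDraws(chain, what)
    if (ncol(d) == 0) next
    colnames(d) <- switch(what,
      beta = paste0("beta.", chain@diseases),
      sd = paste0("sd.", chain@diseases),
      corr = pairLabels(chain@diseases),
      rho = if (ncol(d) == 1) "rho" else paste0("rho.", chain@diseases))
    utils::write.csv(as.data.frame(d), file.path(dir, paste0(what, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(data.frame(deviance = retainedDraws(chain, "deviance")),
                   file.path(dir, "deviance.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(variant = chain@spec@variant,
         control = chain@control[c("nChains", "iterations", "burnIn",
                                   "thin", "seed")],
         seeds = chain@seeds, accept = chain@accept,
         diseases = chain@diseases),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
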