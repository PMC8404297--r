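## Convergence assessment (Geweke, effective sample size, autocorrelation)
## and DIC model comparison.

## spectral density at zero of a scalar chain, estimated by a simple
## lag-window autocovariance sum; the window is a fraction of the segment
## length (4% by default), documented and configurable
.spectral0 <- function(x, lagFrac = 0.04) {
  n <- length(x)
  L <- max(1L, floor(lagFrac * n))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  ac[1] + 2 * sum(ac[-1])
}

#' Geweke convergence diagnostic
#'
#' z-test comparing the mean of an early chain segment against a late
#' segment: z = (mean_first - mean_last) / sqrt(se^2_first + se^2_last),
#' with spectral-density-at-zero standard errors. |z| values well beyond
#' 2-3 flag non-convergence.
#'
#' @param draws scalar chain (length >= 100).
#' @param firstFrac fraction of the chain in the early segment (0.1).
#' @param lastFrac fraction in the late segment (0.5).
#' @param lagFrac lag-window fraction for the spectral standard errors.
#' @return the z-score; \code{NaN} with attribute
#'   \code{degenerate = TRUE} for a zero-variance chain.
#' @export
gewekeZ <- function(draws, firstFrac = 0.1, lastFrac = 0.5,
                    lagFrac = 0.04) {
  n <- length(draws)
  if (n < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
  if (stats::var(draws) == 0) {
    z <- NaN
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  a <- draws[seq_len(floor(firstFrac * n))]
  b <- draws[seq.int(n - floor(lastFrac * n) + 1, n)]
  se2a <- .spectral0(a, lagFrac) / length(a)
  se2b <- .spectral0(b, lagFrac) / length(b)
  (mean(a) - mean(b)) / sqrt(se2a + se2b)
}

#' Effective sample size
#'
#' N / (1 + 2 sum_k rho_k), with the autocorrelation sum truncated by the
#' initial-positive-sequence rule (summation stops at the first
#' nonpositive estimated autocorrelation). Capped at N; a constant chain
#' reports N with attribute \code{degenerate = TRUE}.
#'
#' @param draws scalar chain (length >= 10).
#' @return effective sample size.
#' @export
effectiveSampleSize <- function(draws) {
  n <- length(draws)
  if (n < 10) stop("chain too short for an ESS estimate (need >= 10)")
  if (stats::var(draws) == 0) {
    out <- n
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  maxLag <- min(n - 1, max(50, floor(10 * log10(n))))
  rho <- stats::acf(draws, lag.max = maxLag, plot = FALSE,
                    demean = TRUE)$acf[-1, 1, 1]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  min(n, n / (1 + 2 * s))
}

#' Lag-k autocorrelations of a chain
#' @param draws scalar chain.
#' @param lags lags to report (1..50 by default).
#' @return named numeric vector of autocorrelations.
#' @export
chainAutocorrelation <- function(draws, lags = 1:50) {
  maxLag <- min(max(lags), length(draws) - 1)
  ac <- stats::acf(draws, lag.max = maxLag, plot = FALSE)$acf[-1, 1, 1]
  setNames(ac[lags[lags <= maxLag]], paste0("lag", lags[lags <= maxLag]))
}

#' Deviance information criterion
#'
#' D = -2 log Poisson likelihood. The mean deviance over retained draws
#' is Dbar; the effective number of parameters is pD = Dbar - D(mu_bar),
#' where mu_bar is the posterior mean of the fitted means mu_ij (the
#' standard WinBUGS-style plug-in); DIC = Dbar + pD. Lower is better.
#'
#' @param chain a \code{\link{ChainOutput-class}} with stored per-draw
#'   mu and deviance.
#' @param Y an \code{ObservedCounts} (or matrix).
#' @param E an \code{ExpectedCounts} (or matrix); cells with E = 0 and
#'   Y = 0 are dropped, as in the fit.
#' @return named list with \code{DIC}, \code{Dbar}, \code{pD} and
#'   \code{Dhat} (deviance at the posterior mean).
#' @export
dic <- function(chain, Y, E) {
  stopifnot(is(chain, "ChainOutput"))
  if (nDraws(chain) == 0) stop("empty chain")
  Ym <- if (is(Y, "ObservedCounts")) Y@counts else as.matrix(Y)
  Em <- if (is(E, "ExpectedCounts")) E@expected else as.matrix(E)
  dev <- retainedDraws(chain, "deviance")
  Dbar <- mean(dev)
  mu <- retainedDraws(chain, "mu")
  muBar <- apply(mu, c(2, 3), mean)
  keep <- !(Em == 0 & Ym == 0)
  if (chain@control$likelihood == "poisson") {
    Dhat <- -2 * sum(Ym[keep] * log(muBar[keep]) - muBar[keep] -
                       lgamma(Ym[keep] + 1))
  } else {
    g2 <- chain@control$gaussSd^2
    Dhat <- sum((Ym[keep] - muBar[keep])^2 / g2 + log(2 * pi * g2))
  }
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, Dbar = Dbar, pD = pD, Dhat = Dhat)
}

#' Convergence and fit report for a chain
#'
#' Per-parameter Geweke z-scores (per chain), effective sample sizes
#' (pooled), lag-1/5/10/50 autocorrelations, and the DIC decomposition.
#'
#' @param chain a \code{ChainOutput}.
#' @param Y,E data the model was fitted to.
#' @return list with elements \code{parameters} (data.frame) and
#'   \code{dic}.
#' @export
diagnosticsReport <- function(chain, Y, E) {
  pars <- list()
  d <- retainedDraws(chain, "beta")
  for (j in seq_len(ncol(d)))
    pars[[paste0("beta.", chain@diseases[j])]] <- d[, j]
  d <- retainedDraws(chain, "sd")
  for (j in seq_len(ncol(d)))
    pars[[paste0("sd.", chain@diseases[j])]] <- d[, j]
  d <- retainedDraws(chain, "corr")
  if (ncol(d) > 0 && chain@spec@variant != "M3") {
    labs <- pairLabels(chain@diseases)
    for (m in seq_len(ncol(d))) pars[[paste0("corr.", labs[m])]] <- d[, m]
  }
  d <- retainedDraws(chain, "rho")
  for (r in seq_len(ncol(d)))
    pars[[if (ncol(d) == 1) "rho" else
          paste0("rho.", chain@diseases[r])]] <- d[, r]

  rows <- lapply(names(pars), function(nm) {
    x <- pars[[nm]]
    zs <- vapply(seq_along(chain@chains), function(ci) {
      part <- .chainSlice(chain, nm, ci)
      if (stats::var(part) == 0) NaN else gewekeZ(part)
    }, numeric(1))
    ac <- chainAutocorrelation(x, c(1, 5, 10, 50))
    data.frame(parameter = nm, geweke_z = max(abs(zs)),
               ess = as.numeric(effectiveSampleSize(x)),
               acf1 = ac[["lag1"]],
               median = stats::median(x),
               ci_low = as.numeric(stats::quantile(x, 0.025)),
               ci_high = as.numeric(stats::quantile(x, 0.975)),
               stringsAsFactors = FALSE)
  })
  list(parameters = do.call(rbind, rows), dic = dic(chain, Y, E))
}

## one chain's draws of a named parameter
.chainSlice <- function(chain, name, ci) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  what <- parts[1]
  ch <- chain@chains[[ci]]
  d <- ch[[if (what == "corr") "corr" else what]]
  if (what == "rho" && ncol(d) == 1) return(d[, 1])
  lab <- paste(parts[-1], collapse = ".")
  idx <- switch(what,
    beta = , sd = , rho = match(lab, chain@diseases),
    corr = match(lab, pairLabels(chain@diseases)))
  d[, idx]
}

#' Write a diagnostics report as JSON plus per-parameter CSV
#' @param report output of \code{\link{diagnosticsReport}}.
#' @param jsonFile,csvFile output paths.
#' @return invisibly, the paths.
#' @export
writeDiagnostics <- function(report, jsonFile, csvFile) {
  jsonlite::write_json(list(dic = report$dic,
                            parameters = report$parameters),
                       jsonFile, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  utils::write.csv(report$parameters, csvFile, row.names = FALSE)
  invisible(c(jsonFile, csvFile))
}
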