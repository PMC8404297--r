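## small shared helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Generators in this package are pure functions of (config, seed): when a
#' seed is supplied, the global RNG state is saved, the seed set, and the
#' previous state restored afterwards, so calls do not perturb the
#' caller's stream.
#'
#' @param seed integer seed or NULL (use the current stream).
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

## add k whole years to a Date, mapping Feb 29 to Mar 1 in non-leap years
addYears <- function(date, k) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + k
  out <- as.Date(lt)
  bad <- is.na(out)
  if (any(bad)) {
    lt2 <- as.POSIXlt(date[bad])
    lt2$year <- lt2$year + k
    lt2$mon <- 2 - 1  # March
    lt2$mday <- 1
    out[bad] <- as.Date(lt2)
  }
  out
}

## lower-triangular Cholesky factor from sd/corr parameters; NULL if the
## implied Sigma is not positive definite
cholFromSdCorr <- function(sd, corr) {
  J <- length(sd)
  R <- diag(J)
  if (J > 1) {
    m <- 0
    for (a in seq_len(J - 1)) for (b in (a + 1):J) {
      m <- m + 1
      R[a, b] <- R[b, a] <- corr[m]
    }
  }
  S <- diag(sd, J) %*% R %*% diag(sd, J)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  t(ch)
}

## pair labels for the correlation parameters, order (1,2), (1,3), (2,3)
pairLabels <- function(diseases) {
  J <- length(diseases)
  if (J < 2) return(character())
  out <- character()
  for (a in seq_len(J - 1)) for (b in (a + 1):J)
    out <- c(out, paste(diseases[a], diseases[b], sep = ":"))
  out
}
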