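test_that("Leroux precision has the stated closed forms", {
  g <- pathGraph(4)
  expect_equal(unname(lerouxPrecision(g, 0)), diag(4))
  expect_equal(unname(lerouxPrecision(pairGraph(), 0.9)),
               rbind(c(1, -0.9), c(-0.9, 1)))
  expect_error(lerouxPrecision(g, 1), "rho")
  expect_error(lerouxPrecision(g, -0.01), "rho")
})

test_that("precision log-determinant matches the eigenvalue oracle", {
  g <- randomGraph(15, 30, seed = 9)
  W <- adjacencyMatrix(g)
  lam <- eigen(diag(rowSums(W)) - W, symmetric = TRUE,
               only.values = TRUE)$values
  for (rho in c(0.1, 0.5, 0.95)) {
    ld <- as.numeric(determinant(lerouxPrecision(g, rho),
                                 logarithm = TRUE)$modulus)
    expect_equal(ld, sum(log(rho * lam + 1 - rho)), tolerance = 1e-8)
  }
})

test_that("logPosterior equals a flat term-by-term oracle", {
  g <- pathGraph(3)
  set.seed(4)
  Y <- matrix(rpois(9, 8), 3, 3)
  E <- matrix(runif(9, 5, 12), 3, 3)
  spec <- mcarModelSpec("M2")
  st <- posteriorState(beta = c(0.1, -0.2, 0.05),
                       u = matrix(rnorm(9, 0, 0.5), 3, 3),
                       sigmaSd = c(0.4, 0.6, 0.5),
                       sigmaCorr = c(0.3, 0.2, 0.5), rho = 0.7)
  lp <- logPosterior(st, spec, Y, E, g)

  # independent flat re-summation
  R <- diag(3); R[1, 2] <- R[2, 1] <- 0.3
  R[1, 3] <- R[3, 1] <- 0.2; R[2, 3] <- R[3, 2] <- 0.5
  Sg <- diag(st@sigmaSd) %*% R %*% diag(st@sigmaSd)
  A <- t(chol(Sg))
  phi <- matrix(0, 3, 3)
  for (i in 1:3) for (l in 1:3) for (m in 1:3)
    phi[i, l] <- phi[i, l] + A[l, m] * st@u[i, m]
  ref <- 0
  for (i in 1:3) for (j in 1:3) {
    mu <- E[i, j] * exp(st@beta[j] + phi[i, j])
    ref <- ref + Y[i, j] * log(mu) - mu - lgamma(Y[i, j] + 1)
  }
  W <- adjacencyMatrix(g)
  Q <- 0.7 * (diag(rowSums(W)) - W) + 0.3 * diag(3)
  for (j in 1:3) {
    quad <- 0
    for (i in 1:3) for (k in 1:3) quad <- quad + st@u[i, j] * Q[i, k] * st@u[k, j]
    ref <- ref + 0.5 * log(det(Q)) - 0.5 * quad - 1.5 * log(2 * pi)
  }
  for (j in 1:3)
    ref <- ref + dnorm(st@beta[j], 0, sqrt(10), log = TRUE)
  ref <- ref - 3 * log(10) - 3 * log(1)
  expect_equal(lp, ref, tolerance = 1e-10)
})

test_that("logPosterior is -Inf outside the prior support", {
  g <- pathGraph(3)
  Y <- matrix(5, 3, 3); E <- matrix(5, 3, 3)
  spec <- mcarModelSpec("M2")
  base <- posteriorState(beta = rep(0, 3), u = matrix(0, 3, 3),
                         sigmaSd = rep(0.5, 3),
                         sigmaCorr = rep(0.2, 3), rho = 0.5)
  bad1 <- base; bad1@sigmaCorr <- c(1.01, 0.2, 0.2)
  expect_identical(logPosterior(bad1, spec, Y, E, g), -Inf)
  bad2 <- base; bad2@sigmaSd <- c(11, 0.5, 0.5)
  expect_identical(logPosterior(bad2, spec, Y, E, g), -Inf)
  bad3 <- base; bad3@rho <- 1.2
  expect_identical(logPosterior(bad3, spec, Y, E, g), -Inf)
  # correlations inside (0,1) individually but jointly non-positive-definite
  bad4 <- base; bad4@sigmaCorr <- c(0.95, 0.95, 0.05)
  expect_identical(logPosterior(bad4, spec, Y, E, g), -Inf)
  expect_true(is.finite(logPosterior(base, spec, Y, E, g)))
})

test_that("initial states differ across chains and are reproducible", {
  spec <- mcarModelSpec("M2")
  Y <- matrix(rpois(12, 10), 4, 3); E <- matrix(10, 4, 3)
  s1 <- initialStates(spec, Y, E, nChains = 2, seed = 5)
  s2 <- initialStates(spec, Y, E, nChains = 2, seed = 5)
  expect_false(identical(s1[[1]]@beta, s1[[2]]@beta))
  expect_identical(s1[[2]]@u, s2[[2]]@u)
  for (st in s1) {
    expect_true(all(is.finite(st@beta)))
    expect_false(is.null(mcarmap:::cholFromSdCorr(st@sigmaSd, st@sigmaCorr)))
  }
  # chain 1 is the documented null state
  expect_equal(s1[[1]]@beta, log(colSums(Y) / colSums(E)),
               ignore_attr = TRUE)
  expect_true(all(s1[[1]]@u == 0))
})

test_that("the sampler is bit-reproducible given the seed", {
  g <- latticeGraph(3, 3)
  truth <- makeGroundTruth(g, "M2", seed = 1)
  E <- uniformExpectedCounts(g, value = 50)
  Y <- simulateCounts(truth, E, seed = 2)
  ctrl <- mcmcControl(iterations = 1500, burnIn = 500, thin = 5, seed = 77)
  f1 <- fitMcmc(mcarModelSpec("M2"), Y, E, g, ctrl)
  f2 <- fitMcmc(mcarModelSpec("M2"), Y, E, g, ctrl)
  expect_identical(f1@chains, f2@chains)
})

test_that("retained draws never leave the prior support", {
  g <- latticeGraph(3, 4)
  truth <- makeGroundTruth(g, "M2", seed = 6)
  E <- uniformExpectedCounts(g, value = 80)
  Y <- simulateCounts(truth, E, seed = 7)
  fit <- fitMcmc(mcarModelSpec("M2"), Y, E, g,
                 mcmcControl(iterations = 4000, burnIn = 1000, thin = 3,
                             seed = 13))
  expect_true(all(retainedDraws(fit, "rho") > 0 &
                    retainedDraws(fit, "rho") < 1))
  expect_true(all(retainedDraws(fit, "sd") > 0 &
                    retainedDraws(fit, "sd") < 10))
  expect_true(all(retainedDraws(fit, "corr") > 0 &
                    retainedDraws(fit, "corr") < 1))
})

test_that("adapted acceptance rates land in the working range", {
  g <- syntheticMunicipalityMap()
  truth <- makeGroundTruth(g, "M2", seed = 8)
  E <- uniformExpectedCounts(g)
  Y <- simulateCounts(truth, E, seed = 9)
  fit <- fitMcmc(mcarModelSpec("M2"), Y, E, g,
                 mcmcControl(nChains = 1, iterations = 6000, burnIn = 3000,
                             thin = 10, seed = 15))
  acc <- unlist(fit@accept[[1]])
  expect_true(all(acc >= 0.1 & acc <= 0.6))
})

test_that("a saturated flat dataset concentrates all SIRs near 1", {
  g <- latticeGraph(3, 4)
  E <- uniformExpectedCounts(g, value = 1000)
  Y <- matrix(1000L, 12, 3,
              dimnames = list(areaIds(g), c("AMI", "stroke", "AF")))
  fit <- fitMcmc(mcarModelSpec("M2"), new("ObservedCounts", counts = Y),
                 E, g, mcmcControl(iterations = 8000, burnIn = 4000,
                                   thin = 4, seed = 21))
  tb <- surfaceTable(sirSurface(fit, E))
  expect_true(all(tb$sir_median >= 0.95 & tb$sir_median <= 1.05))
})

test_that("the single-area posterior matches 1-D/2-D quadrature", {
  g1 <- buildAdjacency(NULL, "a")
  ctrl <- mcmcControl(nChains = 2, iterations = 520000, burnIn = 20000,
                      thin = 50, seed = 4, updateHyper = FALSE)
  fit <- suppressWarnings(
    fitMcmc(mcarModelSpec("M2", nDiseases = 1), matrix(12, 1, 1),
            matrix(10, 1, 1), g1, ctrl))
  bMean <- mean(retainedDraws(fit, "beta"))
  # quadrature over (beta, u): Y ~ Pois(10 e^{beta + 0.5 u}),
  # beta ~ N(0, 10), u ~ N(0, 1/(1 - 0.5)) with sd fixed at the initial 0.5
  bs <- seq(-5, 5, 0.005); us <- seq(-8, 8, 0.005)
  ll <- outer(bs, us, function(b, u) dpois(12, 10 * exp(b + 0.5 * u),
                                           log = TRUE)) +
    outer(dnorm(bs, 0, sqrt(10), log = TRUE),
          dnorm(us, 0, sqrt(2), log = TRUE), "+")
  w <- exp(ll - max(ll))
  bQuad <- sum(rowSums(w) * bs) / sum(w)
  expect_lt(abs(bMean - bQuad), 0.02)
})

test_that("with a Gaussian likelihood the sampler matches the closed form", {
  # test harness: Y_i ~ N(beta + sd * u_i, 1) on a 4-area path,
  # hyperparameters fixed, so (beta, u) is jointly Gaussian
  g <- pathGraph(4)
  sdFix <- 0.7; rhoFix <- 0.5
  y <- c(0.8, -0.3, 1.2, 0.4)
  init <- posteriorState(beta = 0, u = matrix(0, 4, 1), sigmaSd = sdFix,
                         sigmaCorr = numeric(0), rho = rhoFix)
  ctrl <- mcmcControl(nChains = 2, iterations = 220000, burnIn = 20000,
                      thin = 20, seed = 31, updateHyper = FALSE,
                      likelihood = "gaussian", gaussSd = 1)
  fit <- fitMcmc(mcarModelSpec("M2", nDiseases = 1),
                 matrix(y, 4, 1), matrix(1, 4, 1), g, ctrl,
                 inits = list(init, init))
  # closed form: x = (beta, u), precision = M'M / g^2 + blockdiag(0.1, Q)
  M <- cbind(1, sdFix * diag(4))
  Q <- lerouxPrecision(g, rhoFix)
  P <- crossprod(M) + rbind(c(0.1, rep(0, 4)), cbind(0, Q))
  m <- solve(P, crossprod(M, y))
  bMean <- mean(retainedDraws(fit, "beta"))
  uMean <- apply(retainedDraws(fit, "u"), 2, mean)
  expect_lt(abs(bMean - m[1]), 0.05)
  expect_lt(max(abs(uMean - m[-1])), 0.05)
  V <- solve(P)
  expect_lt(abs(sd(retainedDraws(fit, "beta")) - sqrt(V[1, 1])), 0.05)
})

test_that("a joint M3 fit equals three univariate Leroux fits draw-for-draw", {
  g <- latticeGraph(3, 4)
  truth <- makeGroundTruth(g, "M3", sd = c(0.2, 0.3, 0.25),
                           rho = c(0.4, 0.6, 0.8), seed = 5)
  E <- uniformExpectedCounts(g, value = 120)
  Y <- simulateCounts(truth, E, seed = 6)
  ctrl <- mcmcControl(iterations = 3000, burnIn = 1000, thin = 5, seed = 33)
  fitJ <- fitMcmc(mcarModelSpec("M3"), Y, E, g, ctrl)
  Ym <- caseCounts(Y); Em <- expectedCases(E)
  for (j in 1:3) {
    cu <- ctrl; cu$seed <- ctrl$seed + (j - 1)
    fu <- fitMcmc(mcarModelSpec("M3", nDiseases = 1),
                  Ym[, j, drop = FALSE], Em[, j, drop = FALSE], g, cu)
    expect_identical(retainedDraws(fitJ, "beta")[, j],
                     drop(retainedDraws(fu, "beta")))
    expect_identical(retainedDraws(fitJ, "sd")[, j],
                     drop(retainedDraws(fu, "sd")))
    expect_identical(retainedDraws(fitJ, "rho")[, j],
                     drop(retainedDraws(fu, "rho")))
    expect_identical(fitJ@chains[[1]]$u[, , j], fu@chains[[1]]$u[, , 1])
    expect_identical(fitJ@chains[[2]]$mu[, , j], fu@chains[[2]]$mu[, , 1])
  }
})

test_that("fitMcmc validates its inputs", {
  g <- pathGraph(3)
  expect_error(fitMcmc(mcarModelSpec("M2"), matrix(1, 2, 3),
                       matrix(1, 2, 3), g), "3 x 3")
  Y <- matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  E <- matrix(1, 3, 3); E[1, 1] <- 0
  expect_error(fitMcmc(mcarModelSpec("M2"), Y, E, g), "E = 0")
})

test_that("chain output persists as CSV draw tables plus a manifest", {
  g <- latticeGraph(2, 3)
  truth <- makeGroundTruth(g, "M2", seed = 1)
  E <- uniformExpectedCounts(g, value = 40)
  Y <- simulateCounts(truth, E, seed = 2)
  fit <- fitMcmc(mcarModelSpec("M2"), Y, E, g,
                 mcmcControl(iterations = 600, burnIn = 100, thin = 5,
                             seed = 3))
  d <- withr::local_tempdir()
  writeChainOutput(fit, d)
  expect_true(all(file.exists(file.path(d, c("beta.csv", "sd.csv",
                                             "corr.csv", "rho.csv",
                                             "deviance.csv",
                                             "manifest.json")))))
  b <- read.csv(file.path(d, "beta.csv"))
  expect_equal(nrow(b), nDraws(fit))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$variant, "M2")
})
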