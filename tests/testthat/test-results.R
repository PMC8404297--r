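test_that("a surface with mu = E everywhere is flat and not significant", {
  E <- matrix(10, 4, 2)
  mu <- array(10, c(30, 4, 2))
  ch <- handChain(mu, Y = matrix(10L, 4, 2), E = E)
  tb <- surfaceTable(sirSurface(ch, E))
  expect_true(all(tb$sir_median == 1))
  expect_true(all(tb$class == "not significant"))
})

test_that("draws entirely above E give class above 1", {
  E <- matrix(10, 2, 1)
  mu <- array(runif(2 * 40, 11, 13), c(40, 2, 1))
  ch <- handChain(mu, Y = matrix(12L, 2, 1), E = E)
  tb <- surfaceTable(sirSurface(ch, E))
  expect_true(all(tb$class == "above 1"))
  expect_true(all(tb$ci_low > 1))
})

test_that("surface quantiles equal an independent sort-based oracle", {
  withr::with_seed(8, {
    mu <- array(rexp(100 * 5 * 2, 1 / 10), c(100, 5, 2))
  })
  E <- matrix(9, 5, 2)
  ch <- handChain(mu, Y = matrix(10L, 5, 2), E = E)
  tb <- surfaceTable(sirSurface(ch, E))
  # type-7 interpolation written out from sorted draws
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (j in 1:2) for (i in 1:5) {
    sir <- mu[, i, j] / 9
    row <- tb[tb$area == paste0("a", i) & tb$disease == paste0("d", j), ]
    expect_equal(row$sir_median, q7(sir, 0.5), tolerance = 1e-12)
    expect_equal(row$ci_low, q7(sir, 0.025), tolerance = 1e-12)
    expect_equal(row$ci_high, q7(sir, 0.975), tolerance = 1e-12)
  }
})

test_that("zero-expected cells are flagged, not summarized", {
  E <- matrix(c(0, 10), 2, 1)
  mu <- array(rep(c(0, 10), each = 5), c(5, 2, 1))
  ch <- handChain(mu, Y = matrix(c(0L, 10L), 2, 1), E = E)
  tb <- surfaceTable(sirSurface(ch, E))
  expect_equal(tb$class[tb$area == "a1"], "undefined")
  expect_true(is.na(tb$sir_median[tb$area == "a1"]))
})

test_that("exposure-weighted mean SIR equals the mu/E ratio draw by draw", {
  g <- latticeGraph(2, 3)
  truth <- makeGroundTruth(g, "M2", seed = 60)
  E <- uniformExpectedCounts(g, value = 70)
  Y <- simulateCounts(truth, E, seed = 61)
  fit <- fitMcmc(mcarModelSpec("M2"), Y, E, g,
                 mcmcControl(nChains = 1, iterations = 900, burnIn = 400,
                             thin = 5, seed = 62))
  mu <- retainedDraws(fit, "mu")
  Em <- expectedCases(E)
  for (j in 1:3) {
    lhs <- apply(mu[, , j], 1, function(m) sum(m) / sum(Em[, j]))
    rhs <- apply(sweep(mu[, , j], 2, Em[, j], "/"), 1,
                 function(s) sum(s * Em[, j]) / sum(Em[, j]))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("widening the credible level never creates significance", {
  g <- latticeGraph(3, 4)
  truth <- makeGroundTruth(g, "M2", seed = 63)
  E <- uniformExpectedCounts(g, value = 120)
  Y <- simulateCounts(truth, E, seed = 64)
  fit <- fitMcmc(mcarModelSpec("M2"), Y, E, g,
                 mcmcControl(nChains = 1, iterations = 3000, burnIn = 1000,
                             thin = 4, seed = 65))
  t95 <- surfaceTable(sirSurface(fit, E, level = 0.95))
  t99 <- surfaceTable(sirSurface(fit, E, level = 0.99))
  movedUp <- t95$class == "not significant" & t99$class != "not significant"
  expect_false(any(movedUp))
})

test_that("conditional correlations summarize the Sigma draws", {
  # constant Sigma over draws: medians equal its correlations exactly
  S <- 40
  corr <- matrix(rep(c(0.5, 0.2, 0.6), each = S), S, 3)
  mu <- array(10, c(S, 2, 3))
  ch <- handChain(mu, Y = matrix(10L, 2, 3), E = matrix(10, 2, 3),
                  corr = corr, variant = "M2",
                  diseases = c("AMI", "stroke", "AF"))
  cs <- conditionalCorrelation(ch)
  expect_equal(cs@pairs$median, c(0.5, 0.2, 0.6))
  expect_equal(cs@pairs$ci_low, cs@pairs$ci_high)
  expect_equal(cs@pairs$pair, c("AMI:stroke", "AMI:AF", "stroke:AF"))
})

test_that("M3 correlations are zero by construction", {
  mu <- array(10, c(20, 2, 3))
  ch <- handChain(mu, Y = matrix(10L, 2, 3), E = matrix(10, 2, 3),
                  variant = "M3", diseases = c("AMI", "stroke", "AF"))
  cs <- conditionalCorrelation(ch)
  expect_true(all(cs@pairs$median == 0))
  expect_true(all(cs@pairs$ci_high == 0))
  expect_error(conditionalCorrelation(ch, perArea = TRUE), "experimental")
})

test_that("percent deviation reproduces the presentation convention", {
  expect_equal(percentDeviation(0.76), -24)
  expect_equal(percentDeviation(1), 0)
  expect_equal(percentDeviation(1.35), 35)
  expect_error(percentDeviation(0), "> 0")
  # unrounded transform inverts exactly
  sir <- c(0.76, 0.9123, 1, 1.3487)
  pct <- percentDeviation(sir, digits = NA)
  expect_equal(pct / 100 + 1, sir, tolerance = 1e-12)
})

test_that("map export writes CSV, GeoJSON properties and round-trips", {
  sq <- function(x, y) list(list(list(x, y), list(x + 1, y),
                                 list(x + 1, y + 1), list(x, y + 1),
                                 list(x, y)))
  gj <- list(type = "FeatureCollection", features = lapply(1:4, function(i)
    list(type = "Feature", properties = list(id = paste0("a", i)),
         geometry = list(type = "Polygon",
                         coordinates = sq(i %% 2, i %/% 2)))))
  geo <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, geo, auto_unbox = TRUE)

  tb <- data.frame(area = paste0("a", 1:4), disease = "AMI",
                   sir_median = c(1.234567, 0.876543, 1.05, 0.99),
                   ci_low = c(1.1, 0.8, 0.9, 0.9),
                   ci_high = c(1.4, 0.95, 1.2, 1.1),
                   class = c("above 1", "below 1", "not significant",
                             "not significant"),
                   stringsAsFactors = FALSE)
  surf <- new("SIRSurface", table = tb, level = 0.95)
  d <- withr::local_tempdir()
  files <- exportMaps(surf, d, geometry = geo, png = TRUE)
  expect_true(file.exists(file.path(d, "sir_surface.csv")))
  expect_true(file.exists(file.path(d, "sir_AMI.geojson")))
  expect_true(file.exists(file.path(d, "sir_AMI.png")))
  back <- jsonlite::read_json(file.path(d, "sir_AMI.geojson"))
  sirs <- vapply(back$features, function(f)
    f$properties$sir_median, numeric(1))
  expect_equal(sirs, signif(tb$sir_median, 6))
  classes <- vapply(back$features, function(f) f$properties$class, "")
  expect_equal(sum(classes == "above 1"), 1)

  # unmatched ids are listed
  tb2 <- tb; tb2$area[1] <- "zz"
  expect_error(exportMaps(new("SIRSurface", table = tb2, level = 0.95),
                          d, geometry = geo, png = FALSE), "zz")
})
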