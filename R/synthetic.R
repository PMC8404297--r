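## Synthetic-data generation: exact Leroux field draws, aggregated count
## cubes under known ground truth, and individual-level cohorts emulating
## a national register extract.

#' Draw an exact sample from a Leroux CAR field
#'
#' One (or several) exact draws from the zero-mean Gaussian field with
#' precision Q(rho) = rho (D - W) + (1 - rho) I on the given graph, via
#' Cholesky factorization of Q.
#'
#' @param graph an \code{\link{AdjacencyGraph-class}}.
#' @param rho spatial correlation parameter in [0, 1).
#' @param seed integer seed (draws are deterministic given the seed) or
#'   NULL to use the current RNG stream.
#' @param draws number of independent field draws.
#' @return a numeric vector of length \code{nAreas(graph)} when
#'   \code{draws == 1}, otherwise a draws x areas matrix.
#' @export
sampleLerouxField <- function(graph, rho, seed = NULL, draws = 1) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < 0 || rho >= 1)
    stop("rho must be a single value in [0, 1)")
  Q <- lerouxPrecision(graph, rho)
  R <- chol(Q)  # upper triangular, t(R) %*% R == Q
  n <- nAreas(graph)
  withSeed(seed, {
    Z <- matrix(stats::rnorm(n * draws), n, draws)
    X <- backsolve(R, Z)  # cov(X) = Q^{-1}
    if (draws == 1) setNames(drop(X), areaIds(graph)) else t(X)
  })
}

#' Construct a generating ground truth
#'
#' Builds the latent fields and disease-specific area effects of one of
#' the three model variants: independent unit-scale Leroux fields u_j are
#' drawn on the graph and mixed through the lower Cholesky factor A of
#' the between-disease covariance Sigma, phi = u A' (the coregionalization
#' construction, so that Var(phi) has the Sigma (x) Q(rho)^{-1}
#' structure). Defaults reproduce the regime of the motivating analysis:
#' shared spatial correlation 0.67 and pairwise between-disease
#' correlations (0.47, 0.42, 0.65), with conditional scale 0.2 chosen to
#' give a realistic SIR spread (roughly 0.75 to 1.35 across 98 areas).
#'
#' @param graph an \code{AdjacencyGraph}.
#' @param variant "M1", "M2" or "M3".
#' @param beta disease intercepts.
#' @param sd conditional standard deviations (sqrt diag Sigma).
#' @param corr pairwise correlations in the order (1,2), (1,3), (2,3);
#'   ignored (forced to zero) for M3.
#' @param rho spatial correlation: scalar for M2; scalar or per-disease
#'   vector for M1/M3.
#' @param diseases disease labels.
#' @param seed integer seed for the field draws.
#' @return a \code{\link{GroundTruth-class}} object.
#' @export
makeGroundTruth <- function(graph, variant = c("M2", "M1", "M3"),
                            beta = c(0, 0, 0), sd = c(0.2, 0.2, 0.2),
                            corr = c(0.47, 0.42, 0.65), rho = 0.67,
                            diseases = c("AMI", "stroke", "AF"),
                            seed = NULL) {
  variant <- match.arg(variant)
  J <- length(diseases)
  stopifnot(length(beta) == J, length(sd) == J)
  if (variant == "M3") corr <- rep(0, J * (J - 1) / 2)
  if (variant == "M2") {
    if (length(rho) != 1) stop("M2 uses a single shared rho")
    rhoVec <- rep(rho, J)
  } else {
    rhoVec <- rep(rho, length.out = J)
    rho <- rhoVec
  }
  A <- cholFromSdCorr(sd, corr)
  if (is.null(A)) stop("sd/corr do not define a positive-definite Sigma")
  Sigma <- A %*% t(A)
  dimnames(Sigma) <- list(diseases, diseases)
  u <- withSeed(seed, {
    vapply(seq_len(J),
           function(j) sampleLerouxField(graph, rhoVec[j]),
           numeric(nAreas(graph)))
  })
  dimnames(u) <- list(areaIds(graph), diseases)
  phi <- u %*% t(A)
  dimnames(phi) <- dimnames(u)
  new("GroundTruth", variant = variant, beta = setNames(beta, diseases),
      Sigma = Sigma, rho = rho, uField = u, phiField = phi)
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth (", object@variant, "), ",
      nrow(object@uField), " areas x ", ncol(object@uField),
      " diseases\n", sep = "")
  cat("  rho:", paste(signif(object@rho, 3), collapse = ", "), "\n")
  cat("  sd: ", paste(signif(sqrt(diag(object@Sigma)), 3), collapse = ", "),
      "\n")
})

#' Uniform expected counts
#'
#' A flat expected-count surface (the same E in every area/disease cell),
#' used for aggregated synthetic runs where the cohort machinery is not
#' exercised.
#'
#' @param graph an \code{AdjacencyGraph}.
#' @param diseases disease labels.
#' @param value expected count per cell (default 200).
#' @return an \code{\link{ExpectedCounts-class}}.
#' @export
uniformExpectedCounts <- function(graph, diseases = c("AMI", "stroke", "AF"),
                                  value = 200) {
  stopifnot(value > 0)
  E <- matrix(value, nAreas(graph), length(diseases),
              dimnames = list(areaIds(graph), diseases))
  new("ExpectedCounts", expected = E)
}

#' Simulate observed counts under a ground truth
#'
#' Independent Poisson draws Y_ij ~ Poisson(E_ij exp(beta_j + phi_ij))
#' given the generating field.
#'
#' @param truth a \code{\link{GroundTruth-class}}.
#' @param expected an \code{ExpectedCounts} or numeric matrix of E_ij,
#'   all entries > 0. Alternatively supply \code{exposures} and
#'   \code{rates} to compute E first.
#' @param exposures optional \code{ExposureCube} (used with \code{rates}
#'   when \code{expected} is NULL).
#' @param rates optional \code{NationalRates}.
#' @param seed integer seed.
#' @return an \code{\link{ObservedCounts-class}}.
#' @export
simulateCounts <- function(truth, expected = NULL, exposures = NULL,
                           rates = NULL, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  if (is.null(expected)) {
    if (is.null(exposures) || is.null(rates))
      stop("supply either expected, or exposures plus rates")
    expected <- expectedCounts(rates, exposures)
  }
  E <- if (is(expected, "ExpectedCounts")) expected@expected
       else as.matrix(expected)
  if (any(E <= 0)) stop("all expected counts must be > 0")
  phi <- truth@phiField
  if (!all(dim(E) == dim(phi)))
    stop("expected counts and ground-truth field have different shapes")
  mu <- E * exp(sweep(phi, 2, truth@beta, "+"))
  Y <- withSeed(seed, matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu)))
  dimnames(Y) <- dimnames(phi)
  new("ObservedCounts", counts = Y)
}

## ---- individual-level cohort generator ------------------------------------

#' Default stratum-specific incidence rates
#'
#' Per-person-year rates for the 24 sex x age x income strata of each
#' disease, built from age-group base rates shaped like the published
#' national cohort (per 10,000 person-years: AMI 11.5/33.8/53.5/101.8,
#' stroke 13.6/45.6/90.5/205.4, AF 11.3/64.1/148.6/344.7 across the four
#' age groups) with multiplicative sex (female 0.8, male 1.2) and income
#' (Low 1.25, Medium 1, High 0.8) effects.
#'
#' @param diseases disease labels (3).
#' @return matrix diseases x 24 strata of rates per person-year, with the
#'   stratum labels of \code{\link{defaultStrata}} as column names.
#' @export
defaultStratumRates <- function(diseases = c("AMI", "stroke", "AF")) {
  ageBase <- rbind(c(11.5, 33.8, 53.5, 101.8),
                   c(13.6, 45.6, 90.5, 205.4),
                   c(11.3, 64.1, 148.6, 344.7)) / 1e4
  sexMult <- c(female = 0.8, male = 1.2)
  incMult <- c(Low = 1.25, Medium = 1, High = 0.8)
  st <- defaultStrata()
  R <- matrix(0, 3, nrow(st), dimnames = list(diseases, st$label))
  for (k in seq_len(nrow(st))) {
    a <- match(st$ageGroup[k], c("30-59", "60-69", "70-79", "80+"))
    R[, k] <- ageBase[, a] * sexMult[st$sex[k]] * incMult[st$income[k]]
  }
  R
}

#' Cohort generator configuration
#'
#' @param nPersons number of persons alive and resident at study start.
#' @param areas area ids (defaults to the 98-area synthetic map).
#' @param window a \code{\link{studyWindow}}.
#' @param diseases disease labels.
#' @param rates diseases x 24 matrix of stratum event rates per
#'   person-year (see \code{\link{defaultStratumRates}}).
#' @param priorPrevalence per-disease probability of a first diagnosis
#'   before study start (exercises the incident-exclusion rule).
#' @param deathRates annual death probabilities by age group.
#' @param emigrationRate annual emigration rate.
#' @param moveProb probability of moving to another area each 1 January.
#' @param incomeChangeProb probability that the income group is
#'   reassigned each calendar year.
#' @param ageRange age span (years) sampled at study start; includes ages
#'   below the study minimum so the age filter is exercised.
#' @return a validated config list.
#' @export
cohortConfig <- function(nPersons = 10000,
                         areas = NULL,
                         window = studyWindow(),
                         diseases = c("AMI", "stroke", "AF"),
                         rates = defaultStratumRates(diseases),
                         priorPrevalence = c(0.06, 0.05, 0.08),
                         deathRates = c("30-59" = 0.004, "60-69" = 0.012,
                                        "70-79" = 0.035, "80+" = 0.11),
                         emigrationRate = 0.005,
                         moveProb = 0.03,
                         incomeChangeProb = 0.08,
                         ageRange = c(25, 94)) {
  if (is.null(areas)) areas <- areaIds(syntheticMunicipalityMap())
  stopifnot(nPersons > 0, all(rates >= 0), all(priorPrevalence >= 0),
            all(priorPrevalence <= 1), all(deathRates >= 0),
            emigrationRate >= 0, moveProb >= 0, incomeChangeProb >= 0,
            length(diseases) == nrow(rates))
  list(nPersons = nPersons, areas = as.character(areas), window = window,
       diseases = diseases, rates = rates,
       priorPrevalence = setNames(priorPrevalence, diseases),
       deathRates = deathRates, emigrationRate = emigrationRate,
       moveProb = moveProb, incomeChangeProb = incomeChangeProb,
       ageRange = ageRange)
}

#' Simulate an individual-level cohort
#'
#' Generates a register-extract-shaped table: persons with birth date and
#' sex, per-calendar-year area and income assignments, possible
#' before-study first diagnoses, and piecewise-exponential event, death
#' and emigration times over the study window. Hazards are constant
#' within segments bounded by 1 January (area/income reassignment) and
#' age-group boundary birthdays, matching the stratification the cohort
#' module applies downstream. Diagnosis dates occurring after death or
#' emigration are unobservable and dropped.
#'
#' @param config a \code{\link{cohortConfig}} list.
#' @param seed integer seed.
#' @return a \code{\link{SyntheticCohort-class}}.
#' @export
simulateCohort <- function(config = cohortConfig(), seed = NULL) {
  withSeed(seed, .simulateCohortImpl(config))
}

.simulateCohortImpl <- function(config) {
  n <- config$nPersons
  w <- config$window
  start <- w@start
  endExcl <- w@end + 1L
  totalDays <- as.integer(endExcl - start)
  years <- as.integer(format(start, "%Y")):as.integer(format(w@end, "%Y"))
  ageGroups <- c("30-59", "60-69", "70-79", "80+")

  ages <- sample(config$ageRange[1]:config$ageRange[2], n, replace = TRUE,
                 prob = exp(-0.03 * (config$ageRange[1]:config$ageRange[2] -
                                       config$ageRange[1])))
  birthDate <- start - as.integer(round(ages * 365.25)) -
    sample(0:364, n, replace = TRUE)
  sex <- sample(c("female", "male"), n, replace = TRUE)

  ## per-calendar-year area and income
  nY <- length(years)
  area <- matrix("", n, nY)
  income <- matrix("", n, nY)
  area[, 1] <- sample(config$areas, n, replace = TRUE)
  income[, 1] <- sample(c("Low", "Medium", "High"), n, replace = TRUE,
                        prob = c(0.2, 0.6, 0.2))
  if (nY > 1) for (y in 2:nY) {
    mv <- stats::runif(n) < config$moveProb
    area[, y] <- area[, y - 1]
    if (any(mv)) area[mv, y] <- sample(config$areas, sum(mv), replace = TRUE)
    ch <- stats::runif(n) < config$incomeChangeProb
    income[, y] <- income[, y - 1]
    if (any(ch)) income[ch, y] <- sample(c("Low", "Medium", "High"), sum(ch),
                                         replace = TRUE, prob = c(0.2, 0.6, 0.2))
  }

  J <- length(config$diseases)
  priorDx <- matrix(FALSE, n, J)
  priorDate <- matrix(as.Date(NA), n, J)
  for (j in seq_len(J)) {
    priorDx[, j] <- stats::runif(n) < config$priorPrevalence[j]
    k <- sum(priorDx[, j])
    if (k > 0)
      priorDate[priorDx[, j], j] <- start - sample(30:3650, k, replace = TRUE)
  }

  ## piecewise-constant hazards: segment cuts at 1 January and at the single
  ## possible age-group boundary birthday inside the window
  ageAtStart <- floor(as.numeric(start - birthDate) / 365.25)
  segCutDay <- function(i) {
    cuts <- c(0L, totalDays)
    for (y in years[-1])
      cuts <- c(cuts, as.integer(as.Date(sprintf("%d-01-01", y)) - start))
    for (b in c(60, 70, 80)) {
      bd <- as.integer(addYears(birthDate[i], b) - start)
      if (bd > 0 && bd < totalDays) cuts <- c(cuts, bd)
    }
    sort(unique(cuts))
  }

  incomeIdx <- function(lab) match(lab, c("Low", "Medium", "High"))
  sexIdx <- function(s) match(s, c("female", "male"))
  strRates <- config$rates
  stratumCol <- function(s, a, g) (s - 1) * 12 + (a - 1) * 3 + g

  dxDay <- matrix(Inf, n, J)
  deathDay <- rep(Inf, n)
  emigDay <- rep(Inf, n)
  dailyEmig <- config$emigrationRate / 365.25

  for (i in seq_len(n)) {
    cuts <- segCutDay(i)
    si <- sexIdx(sex[i])
    bd <- as.integer(addYears(birthDate[i], c(60, 70, 80)) - start)
    for (s in seq_len(length(cuts) - 1)) {
      d0 <- cuts[s]; len <- cuts[s + 1] - d0
      yr <- as.integer(format(start + d0, "%Y")) - years[1] + 1
      ag <- 1L + sum(d0 >= bd)  # exact: boundaries are the 60/70/80 birthdays
      gi <- incomeIdx(income[i, yr])
      k <- stratumCol(si, ag, gi)
      if (is.finite(deathDay[i]) || is.finite(emigDay[i])) break
      dr <- config$deathRates[ageGroups[ag]] / 365.25
      if (dr > 0) {
        t <- stats::rexp(1) / dr
        if (t < len) deathDay[i] <- d0 + t
      }
      if (dailyEmig > 0) {
        t <- stats::rexp(1) / dailyEmig
        if (t < len) emigDay[i] <- min(emigDay[i], d0 + t)
      }
      for (j in seq_len(J)) {
        if (priorDx[i, j] || is.finite(dxDay[i, j])) next
        r <- strRates[j, k] / 365.25
        if (r > 0) {
          t <- stats::rexp(1) / r
          if (t < len) dxDay[i, j] <- d0 + t
        }
      }
      if (is.finite(deathDay[i]) || is.finite(emigDay[i])) break
    }
  }

  toDate <- function(day) {
    out <- as.Date(rep(NA, length(day)))
    f <- is.finite(day)
    out[f] <- start + floor(day[f])
    out
  }
  deathDate <- toDate(deathDay)
  emigrationDate <- toDate(emigDay)
  ## an emigration after death never happens (loop stops), but guard anyway
  emigrationDate[!is.na(deathDate) & !is.na(emigrationDate) &
                   emigrationDate >= deathDate] <- NA

  persons <- data.frame(id = sprintf("P%06d", seq_len(n)),
                        birthDate = birthDate, sex = sex,
                        deathDate = deathDate,
                        emigrationDate = emigrationDate,
                        stringsAsFactors = FALSE)
  for (j in seq_len(J)) {
    dx <- toDate(dxDay[, j])
    ## diagnosis observable only up to death/emigration
    dx[!is.na(dx) & !is.na(deathDate) & dx > deathDate] <- NA
    dx[!is.na(dx) & !is.na(emigrationDate) & dx > emigrationDate] <- NA
    dx[priorDx[, j]] <- priorDate[priorDx[, j], j]
    persons[[paste0("dx_", config$diseases[j])]] <- dx
  }

  yearly <- data.frame(
    id = rep(persons$id, nY),
    year = rep(years, each = n),
    area = as.vector(area),
    income = as.vector(income),
    stringsAsFactors = FALSE)

  new("SyntheticCohort", persons = persons, yearly = yearly,
      diseases = config$diseases)
}

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", nrow(object@persons), "persons,",
      length(unique(object@yearly$year)), "calendar years,",
      length(object@diseases), "diseases (",
      paste(object@diseases, collapse = ", "), ")\n")
})

#' @describeIn diseaseLabels diseases of a synthetic cohort
#' @export
setMethod("diseaseLabels", "SyntheticCohort", function(x) x@diseases)

## ---- ground truth / cohort serialization ----------------------------------

#' Write a ground truth as JSON
#' @param truth a \code{GroundTruth}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(variant = truth@variant, beta = truth@beta,
         Sigma = truth@Sigma, rho = truth@rho,
         u_field = truth@uField, phi_field = truth@phiField,
         area_ids = rownames(truth@uField),
         diseases = colnames(truth@uField)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a synthetic cohort as CSV files
#'
#' One persons CSV for fixed fields and one person-year CSV for the
#' time-varying area and income assignments.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param personsFile,yearlyFile output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(cohort, personsFile, yearlyFile) {
  utils::write.csv(cohort@persons, personsFile, row.names = FALSE)
  utils::write.csv(cohort@yearly, yearlyFile, row.names = FALSE)
  invisible(c(personsFile, yearlyFile))
}

#' Read a synthetic cohort from CSV files written by \code{writeCohort}
#' @param personsFile,yearlyFile CSV paths.
#' @param diseases disease labels; default inferred from \code{dx_}
#'   columns.
#' @return a \code{SyntheticCohort}.
#' @export
readCohort <- function(personsFile, yearlyFile, diseases = NULL) {
  p <- utils::read.csv(personsFile, stringsAsFactors = FALSE)
  dateCols <- c("birthDate", "deathDate", "emigrationDate",
                grep("^dx_", names(p), value = TRUE))
  for (cc in dateCols) p[[cc]] <- as.Date(p[[cc]])
  y <- utils::read.csv(yearlyFile, stringsAsFactors = FALSE)
  if (is.null(diseases))
    diseases <- sub("^dx_", "", grep("^dx_", names(p), value = TRUE))
  new("SyntheticCohort", persons = p, yearly = y, diseases = diseases)
}
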