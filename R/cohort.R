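## Cohort engine: study populations with prior-diagnosis exclusion,
## person-years at risk split by calendar year / age-group birthday /
## exit, national stratum rates, internally standardized expected counts,
## and the crude-rate summary table.
##
## Date convention: follow-up intervals are half-open [entry, exit + 1 day)
## (the reported exit date is the last day at risk); person-years are
## days / 365.25. This makes fragments additive without double counting
## and means events on the study start date are incident.

#' Study window constructor
#'
#' @param start first day at risk.
#' @param end last day of follow-up, inclusive.
#' @param minAge minimum age in years at \code{start}. The population is
#'   a closed cohort fixed at the index date: persons turning
#'   \code{minAge} during the study are not enrolled late.
#' @return a \code{\link{StudyWindow-class}}.
#' @export
studyWindow <- function(start = "2014-01-01", end = "2015-12-31",
                        minAge = 30) {
  new("StudyWindow", start = as.Date(start), end = as.Date(end),
      minAge = minAge)
}

#' The 24 analysis strata
#'
#' Sexes (female, male) x age groups (30-59, 60-69, 70-79, 80+) x income
#' groups (Low, Medium, High) in fixed nested order: sex varies slowest,
#' income fastest, so stratum k = (sex-1)*12 + (age-1)*3 + income.
#'
#' @return data.frame with columns \code{sex}, \code{ageGroup},
#'   \code{income}, \code{label} (24 rows).
#' @export
defaultStrata <- function() {
  g <- expand.grid(income = c("Low", "Medium", "High"),
                   ageGroup = c("30-59", "60-69", "70-79", "80+"),
                   sex = c("female", "male"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("sex", "ageGroup", "income")]
  g$label <- paste(g$sex, g$ageGroup, g$income, sep = ".")
  rownames(g) <- NULL
  g
}

.personsOf <- function(cohort) {
  if (is(cohort, "SyntheticCohort")) cohort@persons else cohort$persons
}
.yearlyOf <- function(cohort) {
  if (is(cohort, "SyntheticCohort")) cohort@yearly else cohort$yearly
}

#' Build a disease-specific study population
#'
#' Applies the population definition: alive and resident at the window
#' start, aged at least \code{minAge} there, and with no diagnosis of
#' this disease before the window start (incident-exclusion). Follow-up
#' then runs to the first of incident diagnosis, death, emigration or the
#' administrative end of the window; on same-day ties the event takes
#' precedence (outcomes are also captured from cause-of-death data), then
#' death, then emigration.
#'
#' @param cohort a \code{\link{SyntheticCohort-class}} (or a list with
#'   \code{persons}/\code{yearly} tables of the same schema).
#' @param disease disease label (a \code{dx_<disease>} column must
#'   exist).
#' @param window a \code{\link{studyWindow}}.
#' @return data.frame with columns \code{id}, \code{entry}, \code{exit}
#'   (the last day at risk), \code{reason} in \code{event}, \code{death},
#'   \code{emigration}, \code{admin} and logical \code{event}.
#' @export
buildStudyPopulation <- function(cohort, disease, window = studyWindow()) {
  p <- .personsOf(cohort)
  dxCol <- paste0("dx_", disease)
  if (!dxCol %in% names(p)) stop("no diagnosis column for disease ", disease)
  start <- window@start
  end <- window@end

  aliveAtStart <- is.na(p$deathDate) | p$deathDate >= start
  presentAtStart <- is.na(p$emigrationDate) | p$emigrationDate >= start
  oldEnough <- addYears(p$birthDate, window@minAge) <= start
  noPrior <- is.na(p[[dxCol]]) | p[[dxCol]] >= start
  keep <- aliveAtStart & presentAtStart & oldEnough & noPrior
  p <- p[keep, , drop = FALSE]

  inWin <- function(d) !is.na(d) & d >= start & d <= end
  big <- as.numeric(end) + 1e6
  dEvent <- ifelse(inWin(p[[dxCol]]), as.numeric(p[[dxCol]]), big)
  dDeath <- ifelse(inWin(p$deathDate), as.numeric(p$deathDate), big)
  dEmig <- ifelse(inWin(p$emigrationDate), as.numeric(p$emigrationDate), big)
  exitNum <- pmin(dEvent, dDeath, dEmig, as.numeric(end))
  reason <- rep("admin", nrow(p))
  reason[exitNum == dEmig] <- "emigration"
  reason[exitNum == dDeath] <- "death"
  reason[exitNum == dEvent] <- "event"

  out <- data.frame(id = p$id, entry = rep(start, nrow(p)),
                    exit = as.Date(exitNum, origin = "1970-01-01"),
                    reason = reason, event = reason == "event",
                    stringsAsFactors = FALSE)
  bad <- out$exit < out$entry
  if (any(bad))
    stop("exit before entry for record(s): ",
         paste(out$id[bad], collapse = ", "))
  rownames(out) <- NULL
  out
}

## Split every follow-up interval of every population at 1 January (area
## and income reassignment), at age-group boundary birthdays, and at exit;
## accumulate fragment person-years and tally incident cases by the
## stratum and area of the fragment in which the event occurred.
.tabulateCohort <- function(populations, cohort, areaIds = NULL,
                            strata = defaultStrata()) {
  persons <- .personsOf(cohort)
  yearly <- .yearlyOf(cohort)
  if (is.null(areaIds)) {
    areaIds <- sort(unique(yearly$area))
    message("area order taken as sorted area ids of the cohort")
  }
  diseases <- names(populations)
  nA <- length(areaIds); J <- length(diseases); K <- nrow(strata)
  py <- array(0, dim = c(nA, J, K),
              dimnames = list(areaIds, diseases, strata$label))
  cases <- matrix(0L, J, K, dimnames = list(diseases, strata$label))
  Y <- matrix(0L, nA, J, dimnames = list(areaIds, diseases))
  totalPY <- setNames(numeric(J), diseases)

  yKey <- paste(yearly$id, yearly$year, sep = "\r")
  yArea <- match(yearly$area, areaIds)
  yIncome <- match(yearly$income, c("Low", "Medium", "High"))

  for (j in seq_len(J)) {
    pop <- populations[[j]]
    if (nrow(pop) == 0) next
    pi <- match(pop$id, persons$id)
    sexI <- match(persons$sex[pi], c("female", "male"))
    birth <- persons$birthDate[pi]
    bd60 <- as.numeric(addYears(birth, 60))
    bd70 <- as.numeric(addYears(birth, 70))
    bd80 <- as.numeric(addYears(birth, 80))
    entry <- as.numeric(pop$entry)
    exitEx <- as.numeric(pop$exit) + 1  # half-open [entry, exit + 1)
    yrs <- as.integer(format(min(pop$entry), "%Y")):
           as.integer(format(max(pop$exit), "%Y"))
    jan1 <- as.numeric(as.Date(sprintf("%d-01-01", c(yrs, max(yrs) + 1L))))
    year0 <- yrs[1]
    nYr <- length(yrs)
    ## person x year lookup into the yearly table, resolved once
    lk <- matrix(match(paste(rep(pop$id, each = nYr), rep(yrs, nrow(pop)),
                             sep = "\r"), yKey), nrow = nYr)

    for (r in seq_len(nrow(pop))) {
      cuts <- c(entry[r], exitEx[r],
                jan1[jan1 > entry[r] & jan1 < exitEx[r]])
      for (b in c(bd60[r], bd70[r], bd80[r]))
        if (b > entry[r] && b < exitEx[r]) cuts <- c(cuts, b)
      cuts <- sort(unique(cuts))
      lastK <- NA_integer_; lastA <- NA_integer_
      for (f in seq_len(length(cuts) - 1)) {
        fs <- cuts[f]
        yi <- findInterval(fs, jan1)
        yr <- year0 + yi - 1L
        row <- if (yi >= 1 && yi <= nYr) lk[yi, r] else NA_integer_
        if (is.na(row))
          stop("no area/income assignment for person ", pop$id[r],
               " in year ", yr)
        a <- yArea[row]; g <- yIncome[row]
        if (is.na(a)) stop("unknown area for person ", pop$id[r])
        if (is.na(g)) stop("unknown income group for person ", pop$id[r])
        ag <- 1L + (fs >= bd60[r]) + (fs >= bd70[r]) + (fs >= bd80[r])
        k <- (sexI[r] - 1L) * 12L + (ag - 1L) * 3L + g
        frag <- (cuts[f + 1] - fs) / 365.25
        py[a, j, k] <- py[a, j, k] + frag
        totalPY[j] <- totalPY[j] + frag
        lastK <- k; lastA <- a
      }
      if (isTRUE(pop$event[r])) {
        cases[j, lastK] <- cases[j, lastK] + 1L
        Y[lastA, j] <- Y[lastA, j] + 1L
      }
    }
  }
  list(py = py, cases = cases, Y = Y, totalPY = totalPY,
       strata = strata, areaIds = areaIds, diseases = diseases)
}

#' Person-years at risk by area, disease and stratum
#'
#' Each person's follow-up is split at every 1 January (when area and
#' income are reassigned), at every age-group boundary birthday, and at
#' exit; fragment lengths in years (days / 365.25) accumulate into the
#' exposure cube. Person-time is conserved exactly: the cube sums to the
#' total follow-up of each study population.
#'
#' @param populations named list (by disease) of study-population tables
#'   from \code{\link{buildStudyPopulation}}.
#' @param cohort the cohort the populations were built from.
#' @param areaIds fixed area ordering; default: sorted ids observed in
#'   the cohort (with a message).
#' @param strata stratum descriptor (default \code{\link{defaultStrata}}).
#' @return an \code{\link{ExposureCube-class}}.
#' @export
personYearsByStratum <- function(populations, cohort, areaIds = NULL,
                                 strata = defaultStrata()) {
  tab <- .tabulateCohort(populations, cohort, areaIds, strata)
  new("ExposureCube", py = tab$py, diseases = tab$diseases, strata = strata)
}

#' Incident case counts by area and disease
#'
#' Cases are assigned to the area of the calendar year in which the event
#' occurred (the area of the final follow-up fragment).
#'
#' @inheritParams personYearsByStratum
#' @return an \code{\link{ObservedCounts-class}}.
#' @export
observedCounts <- function(populations, cohort, areaIds = NULL,
                           strata = defaultStrata()) {
  tab <- .tabulateCohort(populations, cohort, areaIds, strata)
  new("ObservedCounts", counts = tab$Y)
}

#' Incident case counts by stratum
#'
#' @inheritParams personYearsByStratum
#' @return matrix diseases x strata of case counts (the stratum is the
#'   one the person occupied when the event occurred).
#' @export
casesByStratum <- function(populations, cohort, strata = defaultStrata()) {
  tab <- .tabulateCohort(populations, cohort, areaIds = NULL, strata = strata)
  tab$cases
}

#' National stratum-specific incidence rates
#'
#' R[j, k] = national cases of disease j in stratum k divided by national
#' person-years in that stratum. Strata with no cases have rate 0.
#'
#' @param cases diseases x strata matrix of national case counts (see
#'   \code{\link{casesByStratum}}).
#' @param exposures an \code{\link{ExposureCube-class}}.
#' @return a \code{\link{NationalRates-class}}.
#' @export
nationalRates <- function(cases, exposures) {
  stopifnot(is(exposures, "ExposureCube"))
  pyNat <- apply(exposures@py, c(2, 3), sum)  # diseases x strata
  if (any(cases > 0 & pyNat == 0))
    stop("stratum with cases but zero person-years")
  R <- ifelse(pyNat > 0, cases / pyNat, 0)
  dimnames(R) <- dimnames(pyNat)
  new("NationalRates", rates = R, strata = exposures@strata)
}

#' Expected counts by internal standardization
#'
#' E[i, j] = sum over the 24 strata of R[j, k] * T[i, j, k]. When the
#' rates were computed from the same data, column sums of E equal the
#' national case totals per disease exactly.
#'
#' @param rates a \code{\link{NationalRates-class}} (or diseases x strata
#'   matrix).
#' @param exposures an \code{\link{ExposureCube-class}}.
#' @return an \code{\link{ExpectedCounts-class}}.
#' @export
expectedCounts <- function(rates, exposures) {
  stopifnot(is(exposures, "ExposureCube"))
  R <- if (is(rates, "NationalRates")) rates@rates else as.matrix(rates)
  T_ <- exposures@py
  d <- dim(T_)
  if (!all(dim(R) == d[2:3])) stop("rate and exposure shapes do not align")
  E <- matrix(0, d[1], d[2], dimnames = dimnames(T_)[1:2])
  for (j in seq_len(d[2])) E[, j] <- T_[, j, ] %*% R[j, ]
  new("ExpectedCounts", expected = E)
}

## ---- crude rate table -----------------------------------------------------

.marginGroups <- function(strata) {
  list(Total = seq_len(nrow(strata)),
       Female = which(strata$sex == "female"),
       Male = which(strata$sex == "male"),
       `30-59` = which(strata$ageGroup == "30-59"),
       `60-69` = which(strata$ageGroup == "60-69"),
       `70-79` = which(strata$ageGroup == "70-79"),
       `80+` = which(strata$ageGroup == "80+"),
       Low = which(strata$income == "Low"),
       Medium = which(strata$income == "Medium"),
       High = which(strata$income == "High"))
}

#' @describeIn crudeRateTable from cohort-derived study populations: pass
#'   the named population list plus \code{cohort} (and optionally
#'   \code{areaIds}, \code{strata}). Rows: Total, sexes, age groups,
#'   income groups, per disease; IR = cases / PY x 10,000 to one decimal
#'   (0 when there are no person-years).
#' @param cohort cohort object (list method).
#' @param areaIds area ordering (list method).
#' @param strata stratum descriptor (list method).
#' @export
setMethod("crudeRateTable", "list",
  function(x, cohort, areaIds = NULL, strata = defaultStrata(), ...) {
    tab <- .tabulateCohort(x, cohort, areaIds, strata)
    pyJK <- apply(tab$py, c(2, 3), sum)
    groups <- .marginGroups(strata)
    out <- NULL
    for (j in seq_along(tab$diseases)) for (gn in names(groups)) {
      ks <- groups[[gn]]
      cs <- sum(tab$cases[j, ks])
      py <- sum(pyJK[j, ks])
      out <- rbind(out, data.frame(
        disease = tab$diseases[j], group = gn, cases = cs, py = py,
        ir = if (py > 0) round(cs / py * 1e4, 1) else 0,
        stringsAsFactors = FALSE))
    }
    rownames(out) <- NULL
    out
  })

#' @describeIn crudeRateTable from a pre-aggregated data.frame with
#'   \code{cases} and \code{py} columns (e.g. published table cells): the
#'   \code{ir} column (per 10,000 PY, one decimal) is (re)computed and
#'   appended.
#' @export
setMethod("crudeRateTable", "data.frame", function(x, ...) {
  stopifnot(all(c("cases", "py") %in% names(x)))
  x$ir <- ifelse(x$py > 0, round(x$cases / x$py * 1e4, 1), 0)
  x
})

## ---- accessors / show -----------------------------------------------------

#' @describeIn nAreas areas of an exposure cube
#' @export
setMethod("nAreas", "ExposureCube", function(x) dim(x@py)[1])

#' @describeIn areaIds area order of an exposure cube
#' @export
setMethod("areaIds", "ExposureCube", function(x) dimnames(x@py)[[1]])

#' @describeIn personYears the areas x diseases x strata array
#' @export
setMethod("personYears", "ExposureCube", function(x) x@py)

#' @describeIn diseaseLabels diseases of an exposure cube
#' @export
setMethod("diseaseLabels", "ExposureCube", function(x) x@diseases)

setMethod("show", "ExposureCube", function(object) {
  d <- dim(object@py)
  cat("ExposureCube:", d[1], "areas x", d[2], "diseases x", d[3],
      "strata;", format(round(sum(object@py)), big.mark = ","),
      "total person-years\n")
})

#' @describeIn caseCounts the areas x diseases count matrix
#' @export
setMethod("caseCounts", "ObservedCounts", function(x) x@counts)

setMethod("show", "ObservedCounts", function(object) {
  cat("ObservedCounts:", nrow(object@counts), "areas x",
      ncol(object@counts), "diseases;",
      paste(colnames(object@counts), colSums(object@counts),
            sep = "=", collapse = ", "), "\n")
})

#' @describeIn expectedCases the areas x diseases expected matrix
#' @export
setMethod("expectedCases", "ExpectedCounts", function(x) x@expected)

setMethod("show", "ExpectedCounts", function(object) {
  cat("ExpectedCounts:", nrow(object@expected), "areas x",
      ncol(object@expected), "diseases; column totals",
      paste(signif(colSums(object@expected), 6), collapse = ", "), "\n")
})

#' @describeIn rateMatrix the diseases x strata rate matrix
#' @export
setMethod("rateMatrix", "NationalRates", function(x) x@rates)

setMethod("show", "NationalRates", function(object) {
  cat("NationalRates:", nrow(object@rates), "diseases x",
      ncol(object@rates), "strata (per person-year)\n")
})

## ---- tidy CSV serialization ----------------------------------------------

#' Write an exposure cube as tidy CSV
#' @param exposures an \code{ExposureCube}.
#' @param path output CSV (columns area, disease, stratum, py).
#' @return invisibly, the path.
#' @export
writeExposureCube <- function(exposures, path) {
  d <- dimnames(exposures@py)
  df <- expand.grid(area = d[[1]], disease = d[[2]], stratum = d[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$py <- as.vector(exposures@py)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an exposure cube from tidy CSV
#' @param path CSV written by \code{\link{writeExposureCube}}.
#' @param strata stratum descriptor matching the stratum labels.
#' @return an \code{ExposureCube}.
#' @export
readExposureCube <- function(path, strata = defaultStrata()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  areas <- unique(df$area); diseases <- unique(df$disease)
  arr <- array(0, dim = c(length(areas), length(diseases), nrow(strata)),
               dimnames = list(areas, diseases, strata$label))
  idx <- cbind(match(df$area, areas), match(df$disease, diseases),
               match(df$stratum, strata$label))
  arr[idx] <- df$py
  new("ExposureCube", py = arr, diseases = diseases, strata = strata)
}

#' Write an area x disease matrix (counts or expected) as tidy CSV
#' @param x an \code{ObservedCounts}, \code{ExpectedCounts} or matrix.
#' @param path output CSV (columns area, disease, value).
#' @return invisibly, the path.
#' @export
writeAreaDiseaseCsv <- function(x, path) {
  m <- if (is(x, "ObservedCounts")) x@counts
       else if (is(x, "ExpectedCounts")) x@expected else as.matrix(x)
  df <- expand.grid(area = rownames(m), disease = colnames(m),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- as.vector(m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an area x disease matrix from tidy CSV
#' @param path CSV with columns area, disease, value.
#' @param what "counts" for \code{ObservedCounts} (integer), "expected"
#'   for \code{ExpectedCounts}.
#' @return the requested object.
#' @export
readAreaDiseaseCsv <- function(path, what = c("counts", "expected")) {
  what <- match.arg(what)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  areas <- unique(df$area); diseases <- unique(df$disease)
  m <- matrix(0, length(areas), length(diseases),
              dimnames = list(areas, diseases))
  m[cbind(match(df$area, areas), match(df$disease, diseases))] <- df$value
  if (what == "counts") new("ObservedCounts", counts = m)
  else new("ExpectedCounts", expected = m)
}

#' Disease code lists
#'
#' Reads the configurable diagnosis-code metadata (ICD-8 / ICD-10 code
#' strings per disease) used to document which diagnosis column maps to
#' which disease. The packaged default carries the standard code lists
#' for AMI, stroke and atrial fibrillation.
#'
#' @param path YAML file; default: the packaged
#'   \code{extdata/disease_codes.yaml}.
#' @return named list per disease with \code{icd8}/\code{icd10} entries.
#' @export
diseaseCodes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "disease_codes.yaml", package = "mcarmap")
  yaml::read_yaml(path)
}
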