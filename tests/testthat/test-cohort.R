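w2014 <- studyWindow("2014-01-01", "2015-12-31", 30)

test_that("a diagnosis before the window excludes only that disease", {
  ch <- handCohort(list(
    list(id = "p1", birth = "1960-03-15", sex = "male",
         dxAMI = "2013-05-01"),
    list(id = "p2", birth = "1955-08-01", sex = "female")))
  popAMI <- buildStudyPopulation(ch, "AMI", w2014)
  popStroke <- buildStudyPopulation(ch, "stroke", w2014)
  popAF <- buildStudyPopulation(ch, "AF", w2014)
  expect_identical(popAMI$id, "p2")
  expect_setequal(popStroke$id, c("p1", "p2"))
  expect_setequal(popAF$id, c("p1", "p2"))
})

test_that("death without an event ends follow-up with reason death", {
  ch <- handCohort(list(
    list(id = "p1", birth = "1950-01-10", sex = "male",
         death = "2014-06-30")))
  pop <- buildStudyPopulation(ch, "AMI", w2014)
  expect_equal(pop$exit, as.Date("2014-06-30"))
  expect_equal(pop$reason, "death")
  expect_false(pop$event)
})

test_that("event takes precedence over death on the same day", {
  ch <- handCohort(list(
    list(id = "p1", birth = "1950-01-10", sex = "male",
         dxAMI = "2014-06-30", death = "2014-06-30")))
  pop <- buildStudyPopulation(ch, "AMI", w2014)
  expect_equal(pop$reason, "event")
})

test_that("events on the window start date are incident", {
  ch <- handCohort(list(
    list(id = "p1", birth = "1950-01-10", sex = "male",
         dxAMI = "2014-01-01")))
  pop <- buildStudyPopulation(ch, "AMI", w2014)
  expect_equal(pop$reason, "event")
  expect_equal(pop$exit, as.Date("2014-01-01"))
})

test_that("deaths before the study start empty all populations", {
  ch <- handCohort(list(
    list(id = "p1", birth = "1950-01-10", sex = "male",
         death = "2013-12-31"),
    list(id = "p2", birth = "1940-07-07", sex = "female",
         death = "2013-12-31")))
  for (d in c("AMI", "stroke", "AF"))
    expect_equal(nrow(buildStudyPopulation(ch, d, w2014)), 0)
})

test_that("persons under the minimum age at the index date are excluded", {
  ch <- handCohort(list(
    list(id = "young", birth = "1985-06-01", sex = "male"),
    list(id = "exact", birth = "1984-01-01", sex = "male"),
    list(id = "old", birth = "1950-01-02", sex = "male")))
  pop <- buildStudyPopulation(ch, "AMI", w2014)
  expect_setequal(pop$id, c("exact", "old"))  # 30th birthday on the index day
})

test_that("study population matches a row-by-row filter oracle", {
  cfg <- cohortConfig(nPersons = 1000, areas = sprintf("A%02d", 1:5))
  ch <- simulateCohort(cfg, seed = 44)
  pop <- buildStudyPopulation(ch, "stroke", w2014)
  p <- ch@persons
  keep <- logical(nrow(p))
  for (i in seq_len(nrow(p))) {
    ok <- TRUE
    if (!is.na(p$deathDate[i]) && p$deathDate[i] < w2014@start) ok <- FALSE
    if (!is.na(p$emigrationDate[i]) && p$emigrationDate[i] < w2014@start)
      ok <- FALSE
    if (addYears(p$birthDate[i], 30) > w2014@start) ok <- FALSE
    if (!is.na(p$dx_stroke[i]) && p$dx_stroke[i] < w2014@start) ok <- FALSE
    keep[i] <- ok
  }
  expect_setequal(pop$id, p$id[keep])
})

test_that("follow-up splits exactly at age-group boundary birthdays", {
  # aged 59.5 at 2014-01-01 (born 1954-07-01): 60th birthday 2014-07-01
  ch <- handCohort(list(
    list(id = "p1", birth = "1954-07-01", sex = "female")))
  pops <- list(AMI = buildStudyPopulation(ch, "AMI", w2014))
  cube <- personYearsByStratum(pops, ch, areaIds = "X1")
  T_ <- personYears(cube)
  st <- defaultStrata()
  k1 <- which(st$sex == "female" & st$ageGroup == "30-59" &
                st$income == "Medium")
  k2 <- which(st$sex == "female" & st$ageGroup == "60-69" &
                st$income == "Medium")
  expect_equal(T_[1, 1, k1], 181 / 365.25)   # 2014-01-01 .. 2014-07-01
  expect_equal(T_[1, 1, k2], 549 / 365.25)   # 2014-07-01 .. 2016-01-01
  expect_equal(T_[1, 1, k1], 0.5, tolerance = 0.01)
  expect_equal(T_[1, 1, k2], 1.5, tolerance = 0.01)
  expect_equal(sum(T_), 730 / 365.25)
})

test_that("a move on 1 January splits person-years equally by area", {
  yearly <- data.frame(id = "p1", year = 2014:2015,
                       area = c("X1", "X2"), income = "Medium",
                       stringsAsFactors = FALSE)
  ch <- handCohort(list(list(id = "p1", birth = "1949-02-01",
                             sex = "male")), yearly = yearly)
  pops <- list(AMI = buildStudyPopulation(ch, "AMI", w2014))
  cube <- personYearsByStratum(pops, ch, areaIds = c("X1", "X2"))
  T_ <- personYears(cube)
  expect_equal(sum(T_[1, 1, ]), 365 / 365.25)
  expect_equal(sum(T_[2, 1, ]), 365 / 365.25)
})

test_that("unknown area or income assignments are rejected with the id", {
  yearly <- data.frame(id = "p1", year = 2014:2015,
                       area = c("X1", "XX"), income = "Medium",
                       stringsAsFactors = FALSE)
  ch <- handCohort(list(list(id = "p1", birth = "1949-02-01",
                             sex = "male")), yearly = yearly)
  pops <- list(AMI = buildStudyPopulation(ch, "AMI", w2014))
  expect_error(personYearsByStratum(pops, ch, areaIds = "X1"), "p1")
})

test_that("person-time is conserved and monotone in the population", {
  cfg <- cohortConfig(nPersons = 800, areas = sprintf("A%02d", 1:6))
  ch <- simulateCohort(cfg, seed = 3)
  pop <- buildStudyPopulation(ch, "AF", w2014)
  cube <- personYearsByStratum(list(AF = pop), ch, areaIds = cfg$areas)
  total <- sum(as.numeric(pop$exit) + 1 - as.numeric(pop$entry)) / 365.25
  expect_equal(sum(personYears(cube)), total, tolerance = 1e-9)
  # dropping persons never increases any cell
  cubeSub <- personYearsByStratum(list(AF = pop[1:400, ]), ch,
                                  areaIds = cfg$areas)
  expect_true(all(personYears(cubeSub) <= personYears(cube) + 1e-12))
})

test_that("national rates equal an independent group-by oracle", {
  cfg <- cohortConfig(nPersons = 2000, areas = sprintf("A%02d", 1:6))
  ch <- simulateCohort(cfg, seed = 19)
  pops <- setNames(lapply(cfg$diseases, function(d)
    buildStudyPopulation(ch, d, w2014)), cfg$diseases)
  cube <- personYearsByStratum(pops, ch, areaIds = cfg$areas)
  cases <- casesByStratum(pops, ch)
  rates <- nationalRates(cases, cube)
  pyNat <- apply(personYears(cube), c(2, 3), sum)
  ref <- ifelse(pyNat > 0, cases / pyNat, 0)
  expect_equal(unname(rateMatrix(rates)), unname(ref))
  expect_true(all(rateMatrix(rates)[cases == 0] == 0))
})

test_that("expected counts match hand computation and a triple loop", {
  # two areas, one disease, two strata with hand-set numbers
  st <- defaultStrata()[1:2, ]
  T_ <- array(0, c(2, 1, 2),
              dimnames = list(c("a", "b"), "AMI", st$label))
  T_[1, 1, ] <- c(100, 50)
  T_[2, 1, ] <- c(200, 10)
  cube <- new("ExposureCube", py = T_, diseases = "AMI", strata = st)
  R <- matrix(c(0.01, 0.02), 1, 2,
              dimnames = list("AMI", st$label))
  E <- expectedCases(expectedCounts(R, cube))
  expect_equal(unname(E[, 1]), c(2.0, 2.2))

  # simulated cube vs brute-force triple loop
  cfg <- cohortConfig(nPersons = 600, areas = sprintf("A%02d", 1:4))
  ch <- simulateCohort(cfg, seed = 23)
  pops <- setNames(lapply(cfg$diseases, function(d)
    buildStudyPopulation(ch, d, w2014)), cfg$diseases)
  cube <- personYearsByStratum(pops, ch, areaIds = cfg$areas)
  rates <- nationalRates(casesByStratum(pops, ch), cube)
  E2 <- expectedCases(expectedCounts(rates, cube))
  Rm <- rateMatrix(rates); Tm <- personYears(cube)
  ref <- matrix(0, dim(Tm)[1], dim(Tm)[2])
  for (i in seq_len(dim(Tm)[1]))
    for (j in seq_len(dim(Tm)[2]))
      for (k in seq_len(dim(Tm)[3]))
        ref[i, j] <- ref[i, j] + Rm[j, k] * Tm[i, j, k]
  expect_equal(unname(E2), ref, tolerance = 1e-12)
})

test_that("internal standardization: expected and observed totals agree", {
  cfg <- cohortConfig(nPersons = 3000, areas = sprintf("A%02d", 1:8))
  ch <- simulateCohort(cfg, seed = 29)
  pops <- setNames(lapply(cfg$diseases, function(d)
    buildStudyPopulation(ch, d, w2014)), cfg$diseases)
  cube <- personYearsByStratum(pops, ch, areaIds = cfg$areas)
  rates <- nationalRates(casesByStratum(pops, ch), cube)
  E <- expectedCounts(rates, cube)
  Y <- observedCounts(pops, ch, areaIds = cfg$areas)
  expect_equal(colSums(expectedCases(E)), colSums(caseCounts(Y)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a single-area map gives expected counts equal to the totals", {
  cfg <- cohortConfig(nPersons = 500, areas = "A01")
  ch <- simulateCohort(cfg, seed = 37)
  pops <- setNames(lapply(cfg$diseases, function(d)
    buildStudyPopulation(ch, d, w2014)), cfg$diseases)
  cube <- personYearsByStratum(pops, ch, areaIds = "A01")
  cases <- casesByStratum(pops, ch)
  E <- expectedCases(expectedCounts(nationalRates(cases, cube), cube))
  expect_equal(unname(E[1, ]), unname(rowSums(cases)), tolerance = 1e-12)
})

test_that("the aggregated crude-rate method recomputes printed rates", {
  tb <- table1Fixture()
  out <- crudeRateTable(tb[, c("disease", "group", "cases", "py")])
  expect_equal(out$ir, tb$ir_published)
})

test_that("an empty population yields an all-zero crude table", {
  ch <- handCohort(list(
    list(id = "p1", birth = "1950-01-10", sex = "male",
         death = "2013-12-31")))
  pops <- setNames(lapply(c("AMI", "stroke", "AF"), function(d)
    buildStudyPopulation(ch, d, w2014)), c("AMI", "stroke", "AF"))
  tab <- crudeRateTable(pops, ch, areaIds = "X1")
  expect_true(all(tab$cases == 0))
  expect_true(all(tab$py == 0))
  expect_true(all(tab$ir == 0))
})

test_that("cohort-derived crude table margins are self-consistent", {
  cfg <- cohortConfig(nPersons = 1500, areas = sprintf("A%02d", 1:4))
  ch <- simulateCohort(cfg, seed = 41)
  pops <- setNames(lapply(cfg$diseases, function(d)
    buildStudyPopulation(ch, d, w2014)), cfg$diseases)
  tab <- crudeRateTable(pops, ch, areaIds = cfg$areas)
  for (d in cfg$diseases) {
    sub <- tab[tab$disease == d, ]
    tot <- sub$cases[sub$group == "Total"]
    expect_equal(sum(sub$cases[sub$group %in% c("Female", "Male")]), tot)
    expect_equal(sum(sub$cases[sub$group %in%
                                 c("30-59", "60-69", "70-79", "80+")]), tot)
    expect_equal(sum(sub$py[sub$group %in% c("Low", "Medium", "High")]),
                 sub$py[sub$group == "Total"], tolerance = 1e-9)
  }
})

test_that("exposure cube and count matrices survive CSV round trips", {
  cfg <- cohortConfig(nPersons = 400, areas = sprintf("A%02d", 1:3))
  ch <- simulateCohort(cfg, seed = 53)
  pops <- setNames(lapply(cfg$diseases, function(d)
    buildStudyPopulation(ch, d, w2014)), cfg$diseases)
  cube <- personYearsByStratum(pops, ch, areaIds = cfg$areas)
  f1 <- withr::local_tempfile(fileext = ".csv")
  writeExposureCube(cube, f1)
  cube2 <- readExposureCube(f1)
  expect_equal(personYears(cube2), personYears(cube), tolerance = 1e-12)
  Y <- observedCounts(pops, ch, areaIds = cfg$areas)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeAreaDiseaseCsv(Y, f2)
  Y2 <- readAreaDiseaseCsv(f2, "counts")
  expect_equal(caseCounts(Y2), caseCounts(Y))
})

test_that("the packaged disease code metadata is complete", {
  codes <- diseaseCodes()
  expect_setequal(names(codes), c("AMI", "stroke", "AF"))
  expect_equal(codes$AMI$icd10, "I21")
  expect_length(codes$stroke$icd8, 5)
})
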