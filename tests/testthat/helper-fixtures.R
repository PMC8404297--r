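# shared fixtures, all built in code

pairGraph <- function() buildAdjacency(cbind("a", "b"), c("a", "b"))

pathGraph <- function(k) {
  ids <- sprintf("p%02d", seq_len(k))
  buildAdjacency(cbind(ids[-k], ids[-1]), ids)
}

# deterministic random graph on n areas with m edges
randomGraph <- function(n, m, seed) {
  ids <- sprintf("R%03d", seq_len(n))
  withr::with_seed(seed, {
    pairs <- t(combn(n, 2))
    pick <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    buildAdjacency(cbind(ids[pick[, 1]], ids[pick[, 2]]), ids)
  })
}

# a small handcrafted cohort: persons list built from rows
# (id, birth, sex, dxAMI, dxStroke, dxAF, death, emig), yearly assignments
# constant unless overridden
handCohort <- function(persons, years = 2014:2015, area = "X1",
                       income = "Medium", yearly = NULL) {
  p <- do.call(rbind, lapply(persons, function(r)
    data.frame(id = r$id, birthDate = as.Date(r$birth), sex = r$sex,
               deathDate = as.Date(if (is.null(r$death)) NA else r$death),
               emigrationDate = as.Date(if (is.null(r$emig)) NA else r$emig),
               dx_AMI = as.Date(if (is.null(r$dxAMI)) NA else r$dxAMI),
               dx_stroke = as.Date(if (is.null(r$dxStroke)) NA else r$dxStroke),
               dx_AF = as.Date(if (is.null(r$dxAF)) NA else r$dxAF),
               stringsAsFactors = FALSE)))
  if (is.null(yearly))
    yearly <- expand.grid(id = p$id, year = years,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.null(yearly$area)) yearly$area <- area
  if (is.null(yearly$income)) yearly$income <- income
  new("SyntheticCohort", persons = p, yearly = yearly,
      diseases = c("AMI", "stroke", "AF"))
}

# hand-built ChainOutput around given per-draw fitted means (S x n x J),
# with deviance consistent with Y/E so DIC identities hold
handChain <- function(mu, Y, E, corr = NULL, rho = NULL, variant = "M2",
                      diseases = NULL, areas = NULL) {
  S <- dim(mu)[1]; n <- dim(mu)[2]; J <- dim(mu)[3]
  if (is.null(diseases)) diseases <- paste0("d", seq_len(J))
  if (is.null(areas)) areas <- paste0("a", seq_len(n))
  if (is.null(rho)) rho <- matrix(0.5, S, 1)
  nc <- J * (J - 1) / 2
  if (is.null(corr)) corr <- matrix(0, S, nc)
  keep <- !(E == 0 & Y == 0)
  dev <- vapply(seq_len(S), function(s) {
    m <- matrix(mu[s, , ], n, J)
    -2 * sum(dpois(Y[keep], m[keep], log = TRUE))
  }, numeric(1))
  spec <- mcarModelSpec(variant, nDiseases = J)
  new("ChainOutput",
      chains = list(list(beta = matrix(0, S, J), sd = matrix(0.5, S, J),
                         corr = corr, rho = rho, u = array(0, dim(mu)),
                         mu = mu, deviance = dev)),
      spec = spec, control = mcmcControl(), accept = list(list()),
      seeds = list(1), areaIds = areas, diseases = diseases)
}

table1Fixture <- function() {
  read.csv(system.file("extdata", "table1_cohort_summary.csv",
                       package = "mcarmap"), stringsAsFactors = FALSE)
}
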