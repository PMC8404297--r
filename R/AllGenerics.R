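## Generics and accessors. Slots are never reached into by user code;
## these accessors are the supported surface.

#' Number of areas
#' @param x an \code{AdjacencyGraph} or \code{ExposureCube}.
#' @return integer count of areas.
#' @export
setGeneric("nAreas", function(x) standardGeneric("nAreas"))

#' Ordered area labels
#' @param x an object carrying area labels.
#' @return character vector in model order.
#' @export
setGeneric("areaIds", function(x) standardGeneric("areaIds"))

#' Binary neighbour matrix
#' @param x an \code{AdjacencyGraph}.
#' @return the symmetric 0/1 matrix W with area-id dimnames.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Island links recorded on a graph
#' @param x an \code{AdjacencyGraph}.
#' @return two-column character matrix (island, linked area).
#' @export
setGeneric("islandLinks", function(x) standardGeneric("islandLinks"))

#' Per-area neighbour counts (degrees)
#'
#' Element i is the row sum of W row i; these are the diagonal entries of
#' the D matrix in the Leroux precision rho (D - W) + (1 - rho) I.
#'
#' @param x an \code{AdjacencyGraph}.
#' @return named integer vector of degrees.
#' @export
setGeneric("neighbourCounts", function(x) standardGeneric("neighbourCounts"))

#' Person-years array of an exposure cube
#' @param x an \code{ExposureCube}.
#' @return numeric array areas x diseases x strata.
#' @export
setGeneric("personYears", function(x) standardGeneric("personYears"))

#' Disease labels
#' @param x an object carrying disease labels.
#' @return character vector.
#' @export
setGeneric("diseaseLabels", function(x) standardGeneric("diseaseLabels"))

#' Observed case count matrix
#' @param x an \code{ObservedCounts}.
#' @return integer matrix areas x diseases.
#' @export
setGeneric("caseCounts", function(x) standardGeneric("caseCounts"))

#' Expected case count matrix
#' @param x an \code{ExpectedCounts}.
#' @return numeric matrix areas x diseases.
#' @export
setGeneric("expectedCases", function(x) standardGeneric("expectedCases"))

#' National stratum rate matrix
#' @param x a \code{NationalRates}.
#' @return numeric matrix diseases x strata (rates per person-year).
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' Crude rate table
#'
#' Cases, person-years and incidence rate per 10,000 person-years
#' (reported to one decimal), by total / sex / age group / income group
#' and disease. Dispatches on either cohort-derived inputs (a list of
#' study-population tables plus an \code{ExposureCube}) or a
#' pre-aggregated data.frame of (cases, py) cells.
#'
#' @param x a list of study populations (see
#'   \code{\link{buildStudyPopulation}}) or a data.frame with columns
#'   \code{cases} and \code{py}.
#' @param ... further arguments passed to methods.
#' @return data.frame with columns \code{disease}, \code{group},
#'   \code{cases}, \code{py}, \code{ir}.
#' @export
setGeneric("crudeRateTable", function(x, ...) standardGeneric("crudeRateTable"))

#' Pooled retained draws of one sampled quantity
#' @param x a \code{ChainOutput}.
#' @param what one of "beta", "sd", "corr", "rho", "u", "mu", "deviance".
#' @return draws pooled across chains (matrix or array with the draw
#'   dimension first).
#' @export
setGeneric("retainedDraws", function(x, what = "beta")
  standardGeneric("retainedDraws"))

#' Total number of retained draws across chains
#' @param x a \code{ChainOutput}.
#' @return integer.
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' Surface table of a SIR surface
#' @param x a \code{SIRSurface}.
#' @return the underlying data.frame.
#' @export
setGeneric("surfaceTable", function(x) standardGeneric("surfaceTable"))
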