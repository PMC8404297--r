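## Areal adjacency: construction, island linking, readers/writers, and the
## synthetic 98-area lattice map used throughout the package.

#' Build an adjacency graph from an edge list
#'
#' Constructs the symmetric binary neighbour matrix W over a fixed,
#' caller-supplied area ordering: a non-diagonal entry is 1 iff the two
#' areas share a border (appear as a pair in \code{edges}), diagonal
#' entries are 0.
#'
#' @param edges two-column matrix or data.frame of unordered area-id
#'   pairs (may have zero rows).
#' @param areaIds ordered character vector of unique area ids; this order
#'   is fixed once and indexes every matrix and vector downstream.
#' @return an \code{\link{AdjacencyGraph-class}} object.
#' @examples
#' g <- buildAdjacency(cbind("a", "b"), c("a", "b"))
#' adjacencyMatrix(g)
#' @export
buildAdjacency <- function(edges, areaIds) {
  areaIds <- as.character(areaIds)
  if (anyDuplicated(areaIds)) stop("area ids must be unique")
  if (is.null(edges) || length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("edges must have two columns")
    storage.mode(edges) <- "character"
  }
  unknown <- setdiff(c(edges), areaIds)
  if (length(unknown))
    stop("unknown area id(s) in edges: ", paste(unknown, collapse = ", "))
  if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2]))
    stop("self-pairs are not allowed: ",
         paste(unique(edges[edges[, 1] == edges[, 2], 1]), collapse = ", "))
  n <- length(areaIds)
  W <- matrix(0, n, n, dimnames = list(areaIds, areaIds))
  if (nrow(edges) > 0) {
    i <- match(edges[, 1], areaIds)
    k <- match(edges[, 2], areaIds)
    W[cbind(i, k)] <- 1
    W[cbind(k, i)] <- 1
  }
  new("AdjacencyGraph", areaIds = areaIds, W = W,
      islandLinks = matrix(character(), ncol = 2,
                           dimnames = list(NULL, c("island", "linked"))))
}

#' Link islands to the mainland
#'
#' Areas with no shared border (degree 0, e.g. islands) are linked to the
#' area they are connected to by ferry or bridge, so that the smoothing
#' field is defined everywhere. Only true islands (degree 0 before
#' linking) may be linked; the links are recorded on the graph.
#'
#' @param graph an \code{\link{AdjacencyGraph-class}}.
#' @param links two-column matrix or data.frame of (island id, linked
#'   area id) pairs; may have zero rows.
#' @return the augmented graph. If degree-0 areas remain after linking, a
#'   warning is issued (such a graph is still usable because the Leroux
#'   model with rho < 1 is proper, but the areas are unsmoothed).
#' @export
linkIslands <- function(graph, links) {
  stopifnot(is(graph, "AdjacencyGraph"))
  ids <- graph@areaIds
  W <- graph@W
  if (is.null(links) || length(links) == 0) {
    links <- matrix(character(), ncol = 2)
  } else {
    links <- as.matrix(links)
    storage.mode(links) <- "character"
    if (ncol(links) != 2) stop("links must have two columns")
  }
  if (nrow(links) > 0) {
    unknown <- setdiff(c(links), ids)
    if (length(unknown))
      stop("unknown area id(s) in links: ", paste(unknown, collapse = ", "))
    if (any(links[, 1] == links[, 2]))
      stop("an island cannot be linked to itself")
    deg <- rowSums(W)
    isl <- match(links[, 1], ids)
    if (any(deg[isl] > 0))
      stop("only degree-0 areas may be island-linked; offending: ",
           paste(links[deg[isl] > 0, 1], collapse = ", "))
    ml <- match(links[, 2], ids)
    W[cbind(isl, ml)] <- 1
    W[cbind(ml, isl)] <- 1
  }
  if (any(rowSums(W) == 0))
    warning("graph still has degree-0 area(s): ",
            paste(ids[rowSums(W) == 0], collapse = ", "))
  new("AdjacencyGraph", areaIds = ids, W = W,
      islandLinks = rbind(graph@islandLinks,
                          matrix(links, ncol = 2,
                                 dimnames = list(NULL, c("island", "linked")))))
}

#' @describeIn nAreas number of areas in the graph
#' @export
setMethod("nAreas", "AdjacencyGraph", function(x) length(x@areaIds))

#' @describeIn areaIds area order of the graph
#' @export
setMethod("areaIds", "AdjacencyGraph", function(x) x@areaIds)

#' @describeIn adjacencyMatrix the W matrix
#' @export
setMethod("adjacencyMatrix", "AdjacencyGraph", function(x) x@W)

#' @describeIn islandLinks recorded ferry/bridge links
#' @export
setMethod("islandLinks", "AdjacencyGraph", function(x) x@islandLinks)

#' @describeIn neighbourCounts row sums of W
#' @export
setMethod("neighbourCounts", "AdjacencyGraph", function(x) {
  d <- rowSums(x@W)
  names(d) <- x@areaIds
  d
})

setMethod("show", "AdjacencyGraph", function(object) {
  d <- rowSums(object@W)
  cat("AdjacencyGraph with", length(object@areaIds), "areas,",
      sum(object@W) / 2, "edges\n")
  cat("  degrees: min", min(d), "median", stats::median(d), "max", max(d), "\n")
  if (nrow(object@islandLinks))
    cat("  island links:",
        paste(object@islandLinks[, 1], "->", object@islandLinks[, 2],
              collapse = ", "), "\n")
})

## ---- readers / writers ----------------------------------------------------

#' Read an adjacency edge list from CSV
#'
#' Expects a header with columns \code{area_a}, \code{area_b}.
#'
#' @param edgeFile CSV path.
#' @param areaIds ordered area ids; if NULL, the sorted union of ids seen
#'   in the edge list is used (with a message, since the ordering then
#'   depends on the file).
#' @return an \code{AdjacencyGraph}.
#' @export
readEdgeList <- function(edgeFile, areaIds = NULL) {
  ed <- utils::read.csv(edgeFile, colClasses = "character")
  if (!all(c("area_a", "area_b") %in% names(ed)))
    stop("edge CSV must have columns area_a, area_b")
  if (is.null(areaIds)) {
    areaIds <- sort(unique(c(ed$area_a, ed$area_b)))
    message("area order taken as sorted ids from the edge list")
  }
  buildAdjacency(ed[, c("area_a", "area_b")], areaIds)
}

#' Write an adjacency graph as CSV edge list plus JSON sidecar
#'
#' The sidecar records the area ordering and island links, so that
#' read-back reconstructs the graph exactly.
#'
#' @param graph an \code{AdjacencyGraph}.
#' @param edgeFile CSV path to write (columns \code{area_a},
#'   \code{area_b}; each edge once, in lower-triangle order).
#' @param metaFile JSON sidecar path.
#' @return invisibly, the two paths.
#' @export
writeAdjacency <- function(graph, edgeFile, metaFile) {
  stopifnot(is(graph, "AdjacencyGraph"))
  W <- graph@W
  idx <- which(W == 1 & upper.tri(W), arr.ind = TRUE)
  ed <- data.frame(area_a = graph@areaIds[idx[, 1]],
                   area_b = graph@areaIds[idx[, 2]])
  utils::write.csv(ed[order(ed$area_a, ed$area_b), , drop = FALSE],
                   edgeFile, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(area_ids = graph@areaIds,
         island_links = apply(graph@islandLinks, 1, as.list)),
    metaFile, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(edgeFile, metaFile))
}

#' Read an adjacency graph written by \code{writeAdjacency}
#' @param edgeFile CSV edge list path.
#' @param metaFile JSON sidecar path.
#' @return an \code{AdjacencyGraph} identical (area order, W, island
#'   links) to the one written.
#' @export
readAdjacency <- function(edgeFile, metaFile) {
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE)
  g <- readEdgeList(edgeFile, areaIds = as.character(meta$area_ids))
  il <- meta$island_links
  if (length(il)) {
    if (is.data.frame(il))
      il <- cbind(island = il$island, linked = il$linked)
    else
      il <- matrix(unlist(il), ncol = 2, byrow = TRUE,
                   dimnames = list(NULL, c("island", "linked")))
    g@islandLinks <- il
    validObject(g)
  }
  g
}

## ---- polygon (GeoJSON) input ----------------------------------------------

#' Read area polygons from GeoJSON
#'
#' One feature per area; the area id is taken from a named property.
#' Polygon and MultiPolygon geometries are supported; only the outer
#' rings are used for contiguity.
#'
#' @param path GeoJSON file.
#' @param idProperty name of the feature property holding the area id.
#' @return named list (by area id) of lists of ring coordinate matrices.
#' @export
readAreaPolygons <- function(path, idProperty = "id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    id <- f$properties[[idProperty]]
    if (is.null(id)) stop("feature without property '", idProperty, "'")
    geom <- f$geometry
    ringsOf <- function(coords) # coords: list of rings
      lapply(coords, function(r)
        do.call(rbind, lapply(r, function(p) c(p[[1]], p[[2]]))))
    rings <- switch(geom$type,
      Polygon = ringsOf(geom$coordinates)[1],
      MultiPolygon = lapply(geom$coordinates, function(pg) ringsOf(pg)[[1]]),
      stop("unsupported geometry type: ", geom$type))
    out[[as.character(id)]] <- rings
  }
  out
}

#' Rook-contiguity adjacency from polygons
#'
#' Two areas are neighbours iff their polygons share a boundary segment of
#' nonzero length (an edge between two consecutive vertices present in
#' both outlines). Point-touching corners do not count as a shared border.
#'
#' @param polygons named list as returned by \code{\link{readAreaPolygons}}.
#' @param areaIds area ordering; defaults to the polygon list names.
#' @param digits coordinate rounding used when matching shared vertices.
#' @return an \code{AdjacencyGraph}.
#' @export
polygonAdjacency <- function(polygons, areaIds = names(polygons), digits = 9) {
  segKeys <- function(rings) {
    keys <- character()
    for (r in rings) {
      v <- round(r, digits)
      if (nrow(v) < 2) next
      a <- apply(v[-nrow(v), , drop = FALSE], 1, paste, collapse = ",")
      b <- apply(v[-1, , drop = FALSE], 1, paste, collapse = ",")
      keys <- c(keys, ifelse(a < b, paste(a, b, sep = "|"),
                             paste(b, a, sep = "|")))
    }
    unique(keys)
  }
  keys <- lapply(polygons[areaIds], segKeys)
  n <- length(areaIds)
  edges <- NULL
  for (i in seq_len(n - 1))
    for (k in (i + 1):n)
      if (length(intersect(keys[[i]], keys[[k]])) > 0)
        edges <- rbind(edges, c(areaIds[i], areaIds[k]))
  buildAdjacency(edges, areaIds)
}

## ---- synthetic lattice map ------------------------------------------------

#' Rook-contiguity lattice graph
#'
#' @param nrow,ncol lattice dimensions.
#' @param prefix id prefix; ids are \code{prefix} plus a zero-padded
#'   row-major index.
#' @return an \code{AdjacencyGraph} with nrow * ncol areas.
#' @export
latticeGraph <- function(nrow, ncol, prefix = "A") {
  n <- nrow * ncol
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  cell <- function(r, c) (r - 1) * ncol + c
  edges <- NULL
  for (r in seq_len(nrow))
    for (c in seq_len(ncol)) {
      if (c < ncol) edges <- rbind(edges, c(cell(r, c), cell(r, c + 1)))
      if (r < nrow) edges <- rbind(edges, c(cell(r, c), cell(r + 1, c)))
    }
  g <- buildAdjacency(cbind(ids[edges[, 1]], ids[edges[, 2]]), ids)
  attr(g@W, "latticeDim") <- NULL
  g
}

## fixed island cells of the default 7 x 14 map (row, col) and the cell each
## is ferry-linked to; chosen once, spread over the lattice
.defaultIslands <- list(
  c(1, 1, 1, 2), c(1, 14, 2, 14), c(3, 7, 3, 8), c(4, 1, 4, 2),
  c(5, 14, 5, 13), c(7, 4, 7, 5), c(7, 11, 6, 11))

#' Default synthetic 98-area map
#'
#' A 7 x 14 rook-contiguity lattice (98 areas, mirroring the 98 Danish
#' municipalities) with 7 designated islands: all their lattice edges are
#' removed and each island is then ferry-linked to a single neighbouring
#' area via \code{\link{linkIslands}}, reproducing the island mechanics of
#' a real municipal map without shapefiles.
#'
#' @return an \code{AdjacencyGraph} with 98 areas, 7 recorded island
#'   links, and no degree-0 areas.
#' @export
syntheticMunicipalityMap <- function() {
  nr <- 7; nc <- 14
  g <- latticeGraph(nr, nc)
  ids <- areaIds(g)
  cell <- function(r, c) ids[(r - 1) * nc + c]
  W <- g@W
  islands <- vapply(.defaultIslands, function(x) cell(x[1], x[2]), "")
  W[islands, ] <- 0
  W[, islands] <- 0
  g2 <- new("AdjacencyGraph", areaIds = ids, W = W,
            islandLinks = matrix(character(), ncol = 2,
                                 dimnames = list(NULL, c("island", "linked"))))
  links <- t(vapply(.defaultIslands,
                    function(x) c(cell(x[1], x[2]), cell(x[3], x[4])),
                    character(2)))
  linkIslands(g2, links)
}

#' Lattice layout of the default synthetic map
#'
#' Row/column coordinates of each area of \code{\link{syntheticMunicipalityMap}}
#' (used by \code{\link{exportMaps}} to draw heat grids).
#'
#' @param graph a graph with 98 row-major lattice ids.
#' @return data.frame with columns \code{area}, \code{row}, \code{col}.
#' @export
latticeLayout <- function(graph) {
  n <- nAreas(graph)
  nc <- 14
  if (n != 98) nc <- ceiling(sqrt(n))
  idx <- seq_len(n)
  data.frame(area = areaIds(graph),
             row = (idx - 1) %/% nc + 1,
             col = (idx - 1) %% nc + 1)
}
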