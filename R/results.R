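## Posterior summarization: SIR surfaces with significance classes,
## between-disease conditional correlations, percent-deviation
## presentation, and map exports.

#' Posterior SIR surface
#'
#' Per retained draw, the standardized incidence ratio of each cell is
#' SIR_ij = mu_ij / E_ij, the fitted relative risk exp(beta_j + phi_ij)
#' (the fitted mean is used, not a posterior-predictive count draw, so
#' the surface is smooth). Cells are summarized by the posterior median
#' and a central credible interval; an area is classed "above 1" when
#' the interval lies entirely above 1, "below 1" when entirely below.
#'
#' @param chain a \code{\link{ChainOutput-class}}.
#' @param E the \code{ExpectedCounts} used in the fit.
#' @param level credible level for the interval (default 0.95).
#' @return a \code{\link{SIRSurface-class}}. Areas with E = 0 are
#'   flagged: their SIR columns are NA and class is "undefined".
#' @export
sirSurface <- function(chain, E, level = 0.95) {
  stopifnot(is(chain, "ChainOutput"), level > 0, level < 1)
  Em <- if (is(E, "ExpectedCounts")) E@expected else as.matrix(E)
  mu <- retainedDraws(chain, "mu")
  nA <- dim(mu)[2]; J <- dim(mu)[3]
  alpha <- (1 - level) / 2
  out <- NULL
  for (j in seq_len(J)) for (i in seq_len(nA)) {
    if (Em[i, j] == 0) {
      out <- rbind(out, data.frame(
        area = chain@areaIds[i], disease = chain@diseases[j],
        sir_median = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        class = "undefined", stringsAsFactors = FALSE))
      next
    }
    sir <- mu[, i, j] / Em[i, j]
    q <- stats::quantile(sir, c(alpha, 0.5, 1 - alpha), names = FALSE)
    cls <- if (q[1] > 1) "above 1" else if (q[3] < 1) "below 1"
           else "not significant"
    out <- rbind(out, data.frame(
      area = chain@areaIds[i], disease = chain@diseases[j],
      sir_median = q[2], ci_low = q[1], ci_high = q[3], class = cls,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  new("SIRSurface", table = out, level = level)
}

#' @describeIn surfaceTable the per-(area, disease) summary table
#' @export
setMethod("surfaceTable", "SIRSurface", function(x) x@table)

setMethod("show", "SIRSurface", function(object) {
  tb <- object@table
  cat("SIRSurface (", object@level * 100, "% credible level): ",
      length(unique(tb$area)), " areas x ",
      length(unique(tb$disease)), " diseases\n", sep = "")
  print(table(tb$disease, tb$class))
})

#' Between-disease conditional correlations at collocation
#'
#' The conditional correlation between two diseases at the same area is
#' derived per draw from the 3 x 3 covariance matrix Sigma:
#' corr_jk = Sigma_jk / sqrt(Sigma_jj Sigma_kk), i.e. the sampled
#' correlation parameters themselves. For M2 this is the collocated
#' conditional correlation (the same in every area); for M1 the same
#' Sigma-based summary is reported (the per-area version is exposed by
#' the experimental \code{perArea} flag and is not part of the reference
#' outputs); M3 returns zeros by construction. The spatial correlation
#' parameter(s) are summarized alongside.
#'
#' @param chain a \code{ChainOutput}.
#' @param perArea experimental: for M1, also return per-area
#'   correlations (not implemented for the reference path; default
#'   FALSE).
#' @param level credible level (default 0.95).
#' @return a \code{\link{CorrelationSummary-class}}.
#' @export
conditionalCorrelation <- function(chain, perArea = FALSE, level = 0.95) {
  stopifnot(is(chain, "ChainOutput"))
  if (perArea)
    stop("per-area correlations for M1 are experimental and not part of ",
         "the reference outputs")
  alpha <- (1 - level) / 2
  labs <- pairLabels(chain@diseases)
  variant <- chain@spec@variant
  if (variant == "M3" || length(labs) == 0) {
    pairs <- data.frame(pair = labs, median = rep(0, length(labs)),
                        ci_low = 0, ci_high = 0, stringsAsFactors = FALSE)
  } else {
    d <- retainedDraws(chain, "corr")
    pairs <- do.call(rbind, lapply(seq_along(labs), function(m) {
      q <- stats::quantile(d[, m], c(alpha, 0.5, 1 - alpha), names = FALSE)
      data.frame(pair = labs[m], median = q[2], ci_low = q[1],
                 ci_high = q[3], stringsAsFactors = FALSE)
    }))
  }
  rd <- retainedDraws(chain, "rho")
  rho <- do.call(rbind, lapply(seq_len(ncol(rd)), function(r) {
    q <- stats::quantile(rd[, r], c(alpha, 0.5, 1 - alpha), names = FALSE)
    data.frame(parameter = if (ncol(rd) == 1) "rho"
               else paste0("rho.", chain@diseases[r]),
               median = q[2], ci_low = q[1], ci_high = q[3],
               stringsAsFactors = FALSE)
  }))
  new("CorrelationSummary", pairs = pairs, rho = rho, variant = variant)
}

setMethod("show", "CorrelationSummary", function(object) {
  cat("CorrelationSummary (", object@variant, ")\n", sep = "")
  for (r in seq_len(nrow(object@pairs)))
    cat(sprintf("  %s: %.2f (%.2f; %.2f)\n", object@pairs$pair[r],
                object@pairs$median[r], object@pairs$ci_low[r],
                object@pairs$ci_high[r]))
  for (r in seq_len(nrow(object@rho)))
    cat(sprintf("  %s: %.2f (%.2f; %.2f)\n", object@rho$parameter[r],
                object@rho$median[r], object@rho$ci_low[r],
                object@rho$ci_high[r]))
})

#' SIR as signed percent deviation from the national rate
#'
#' (sir - 1) x 100: an SIR of 0.76 is 24 percent below the national
#' rate, 1.35 is 35 percent above.
#'
#' @param sir positive SIR value(s).
#' @param digits rounding for reporting (0 = nearest integer, the
#'   presentation convention; use NA for no rounding).
#' @return signed percent deviation(s).
#' @export
percentDeviation <- function(sir, digits = 0) {
  if (any(sir <= 0)) stop("SIR must be > 0")
  pct <- (sir - 1) * 100
  if (is.na(digits)) pct else round(pct, digits)
}

#' Export a SIR surface as CSV, GeoJSON and map images
#'
#' Without geometry: a tidy surface CSV plus a lattice heat-grid PNG per
#' disease (areas placed by \code{\link{latticeLayout}}). With geometry
#' (a GeoJSON file with one feature per area): a GeoJSON copy whose
#' features carry \code{sir_median}, \code{ci_low}, \code{ci_high} and
#' \code{class} properties (numbers written with 6 significant digits),
#' plus the PNGs.
#'
#' @param surface a \code{\link{SIRSurface-class}}.
#' @param dir output directory.
#' @param geometry optional GeoJSON path.
#' @param idProperty feature property holding the area id.
#' @param png write heat-grid images (default TRUE).
#' @return invisibly, a character vector of written files.
#' @export
exportMaps <- function(surface, dir, geometry = NULL, idProperty = "id",
                       png = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tb <- surface@table
  written <- character()
  csv <- file.path(dir, "sir_surface.csv")
  utils::write.csv(tb, csv, row.names = FALSE)
  written <- c(written, csv)

  if (!is.null(geometry)) {
    gj <- jsonlite::read_json(geometry)
    ids <- vapply(gj$features, function(f)
      as.character(f$properties[[idProperty]]), "")
    unmatched <- setdiff(unique(tb$area), ids)
    if (length(unmatched))
      stop("area id(s) missing from geometry: ",
           paste(unmatched, collapse = ", "))
    for (dz in unique(tb$disease)) {
      sub <- tb[tb$disease == dz, ]
      gj2 <- gj
      for (f in seq_along(gj2$features)) {
        r <- sub[sub$area == ids[f], ]
        if (nrow(r) == 0) next
        gj2$features[[f]]$properties$sir_median <- signif(r$sir_median, 6)
        gj2$features[[f]]$properties$ci_low <- signif(r$ci_low, 6)
        gj2$features[[f]]$properties$ci_high <- signif(r$ci_high, 6)
        gj2$features[[f]]$properties$class <- r$class
      }
      out <- file.path(dir, paste0("sir_", dz, ".geojson"))
      jsonlite::write_json(gj2, out, auto_unbox = TRUE, digits = 6)
      written <- c(written, out)
    }
  }

  if (png) {
    lay <- latticeLayout0(unique(tb$area))
    for (dz in unique(tb$disease)) {
      sub <- tb[tb$disease == dz, ]
      m <- matrix(NA_real_, max(lay$row), max(lay$col))
      m[cbind(lay$row, lay$col)] <- sub$sir_median[match(lay$area, sub$area)]
      f <- file.path(dir, paste0("sir_", dz, ".png"))
      grDevices::png(f, width = 720, height = 420)
      graphics::image(t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
                      col = grDevices::hcl.colors(21, "Blue-Red 2"),
                      axes = FALSE, main = paste("SIR:", dz))
      grDevices::dev.off()
      written <- c(written, f)
    }
  }
  invisible(written)
}

## grid layout for an arbitrary area set (row-major)
latticeLayout0 <- function(areas) {
  n <- length(areas)
  nc <- if (n == 98) 14 else ceiling(sqrt(n))
  idx <- seq_len(n)
  data.frame(area = areas, row = (idx - 1) %/% nc + 1,
             col = (idx - 1) %% nc + 1, stringsAsFactors = FALSE)
}

#' Write a correlation summary as JSON
#' @param summary a \code{CorrelationSummary}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCorrelationSummary <- function(summary, path) {
  jsonlite::write_json(list(variant = summary@variant,
                            pairs = summary@pairs, rho = summary@rho),
                       path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
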