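#' Construct a PoolCounts object
#'
#' @param counts named list of six loci x pools integer matrices, in sync
#'   column order `A,T,C,G,N,del`
#' @param loci data.frame with columns `chrom`, `pos` (1-based), `ref`
#' @param poolMeta data.frame with columns `name`, `n_individuals`,
#'   `latitude`, `longitude`
#' @return a [PoolCounts-class]
#' @export
PoolCounts <- function(counts, loci, poolMeta) {
  stopifnot(is.list(counts), identical(names(counts), SYNC_BASES))
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(NULL, poolMeta$name)
    m
  })
  rr <- GRanges(seqnames = as.character(loci$chrom),
                ranges = IRanges(start = as.integer(loci$pos), width = 1L),
                ref = as.character(loci$ref))
  cd <- DataFrame(n_individuals = as.integer(poolMeta$n_individuals),
                  latitude = as.numeric(poolMeta$latitude),
                  longitude = as.numeric(poolMeta$longitude),
                  row.names = poolMeta$name)
  se <- SummarizedExperiment(assays = counts, rowRanges = rr, colData = cd)
  new("PoolCounts", se)
}

#' @describeIn PoolCounts-class pool names, in sync column order
#' @export
setMethod("poolNames", "SummarizedExperiment", function(x) colnames(x))

#' @describeIn PoolCounts-class diploid individuals per pool
#' @export
setMethod("poolSizes", "SummarizedExperiment",
          function(x) stats::setNames(colData(x)$n_individuals, colnames(x)))

#' @describeIn PoolCounts-class loci x pools nucleotide coverage (A+T+C+G;
#'   `N` and deletion reads are excluded)
#' @export
setMethod("poolCoverage", "PoolCounts", function(x) {
  assay(x, "A") + assay(x, "T") + assay(x, "C") + assay(x, "G")
})

setMethod("show", "PoolCounts", function(object) {
  cat(sprintf("PoolCounts: %d loci x %d pools\n", nrow(object), ncol(object)))
  cat(" pools:", paste(utils::head(colnames(object), 8), collapse = " "),
      if (ncol(object) > 8) "..." else "", "\n")
  cat(" chroms:", paste(unique(as.character(seqnames(rowRanges(object)))),
                        collapse = " "), "\n")
})

#' @describeIn PoolFreqs-class pools x loci minor-allele frequency matrix
#'   (pools as rows, the orientation used by the ordination functions)
#' @export
setMethod("freqMatrix", "PoolFreqs", function(x) t(assay(x, "freq")))

#' @describeIn PoolFreqs-class pools x loci coverage of the biallelic pair
#' @export
setMethod("coverageMatrix", "PoolFreqs", function(x) t(assay(x, "cov")))

setMethod("show", "PoolFreqs", function(object) {
  cat(sprintf("PoolFreqs: %d biallelic loci x %d pools\n",
              nrow(object), ncol(object)))
  if (nrow(object)) {
    gm <- rowData(object)$global_maf
    cat(sprintf(" global minor-allele frequency: %.3f-%.3f\n",
                min(gm), max(gm)))
  }
})

#' Construct an EnvGrid raster
#'
#' @param grid numeric matrix, row 1 = northernmost row; `NA` marks nodata
#' @param xll,yll lower-left corner in decimal degrees
#' @param cellsize cell edge in decimal degrees
#' @param nodata nodata sentinel written on serialization
#' @return an [EnvGrid-class]
#' @export
EnvGrid <- function(grid, xll, yll, cellsize, nodata = -9999) {
  new("EnvGrid", grid = grid, xll = as.numeric(xll), yll = as.numeric(yll),
      cellsize = as.numeric(cellsize), nodata = as.numeric(nodata))
}

#' @describeIn EnvGrid-class the value matrix (NA = nodata)
#' @export
setMethod("gridValues", "EnvGrid", function(x) x@grid)

setMethod("show", "EnvGrid", function(object) {
  g <- object@grid
  cat(sprintf("EnvGrid: %d rows x %d cols, cellsize %g, origin (%g, %g)\n",
              nrow(g), ncol(g), object@cellsize, object@xll, object@yll))
  cat(sprintf(" values: %s, %d nodata cells\n",
              if (all(is.na(g))) "all nodata"
              else sprintf("%.4g..%.4g", min(g, na.rm = TRUE),
                           max(g, na.rm = TRUE)),
              sum(is.na(g))))
})

#' @describeIn EnvGrid-class check that two rasters share header and shape
#' @param a,b two `EnvGrid` objects
#' @export
gridsAligned <- function(a, b) {
  identical(dim(a@grid), dim(b@grid)) &&
    isTRUE(all.equal(c(a@xll, a@yll, a@cellsize),
                     c(b@xll, b@yll, b@cellsize), tolerance = 1e-9))
}

#' Map sites to raster cells
#'
#' Nearest-cell-center lookup: a site is assigned the cell whose center is
#' closest to its coordinates. Sites outside the raster extent are an error.
#'
#' @param grid an [EnvGrid-class]
#' @param latitude,longitude site coordinates, decimal degrees
#' @return integer matrix with columns `row`, `col`
#' @export
siteCells <- function(grid, latitude, longitude) {
  g <- grid@grid
  col <- floor((longitude - grid@xll) / grid@cellsize) + 1L
  row <- nrow(g) - floor((latitude - grid@yll) / grid@cellsize)
  bad <- col < 1L | col > ncol(g) | row < 1L | row > nrow(g)
  if (any(bad))
    stop("sites outside raster extent: ", paste(which(bad), collapse = ", "))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at site locations
#'
#' @inheritParams siteCells
#' @return numeric vector of cell values (NA where the cell is nodata)
#' @export
extractSiteValues <- function(grid, latitude, longitude) {
  rc <- siteCells(grid, latitude, longitude)
  grid@grid[rc]
}

cellCenterLat <- function(grid, row) {
  grid@yll + (nrow(grid@grid) - row + 0.5) * grid@cellsize
}

cellCenterLon <- function(grid, col) {
  grid@xll + (col - 0.5) * grid@cellsize
}

setMethod("show", "PredictorSet", function(object) {
  cat(sprintf("PredictorSet: %d sites x %d predictors (%s)\n",
              nrow(object@X), ncol(object@X),
              paste(colnames(object@X), collapse = ", ")))
  if (ncol(object@conditioning))
    cat(" conditioning on:", paste(colnames(object@conditioning),
                                   collapse = ", "), "\n")
  if (length(object@dropped))
    cat(" dropped:", paste(object@dropped, collapse = "; "), "\n")
})

setMethod("show", "RdaFit", function(object) {
  cat(sprintf("RdaFit: %d sites, %d predictors, %d conditioning columns\n",
              object@n, object@q, object@q0))
  cat(sprintf(" constrained axes: %d; eigenvalues: %s\n", length(object@eig),
              paste(signif(object@eig, 4), collapse = " ")))
  p <- object@proportions
  cat(sprintf(" variance: conditioned %.3f | constrained %.3f | unconstrained %.3f\n",
              p[1], p[2], p[3]))
  cat(sprintf(" R2 = %.4f, adjusted R2 = %.4f\n", object@r2, object@r2adj))
})

#' @describeIn RdaFit-class constrained-axis eigenvalues
#' @export
setMethod("eigenvalues", "RdaFit", function(x) x@eig)

#' @describeIn RdaFit-class site (pool) scores
#' @export
setMethod("siteScores", "RdaFit", function(x) x@siteScores)

#' @describeIn RdaFit-class locus scores (scaled by singular values)
#' @export
setMethod("locusScores", "RdaFit", function(x) x@locusScores)

#' @describeIn RdaFit-class predictor biplot scores
#' @export
setMethod("predictorLoadings", "RdaFit", function(x) x@predictorLoadings)

#' @describeIn RdaFit-class conditioned/constrained/unconstrained proportions
#' @export
setMethod("varianceProportions", "RdaFit", function(x) x@proportions)

setMethod("show", "AdaptiveIndex", function(object) {
  cat(sprintf("AdaptiveIndex [%s]: %d axes\n", object@scenario,
              length(object@grids)))
})

setMethod("show", "OffsetRaster", function(object) {
  cat(sprintf("OffsetRaster: %s -> %s, %d axes, combination rule '%s'\n",
              object@scenarios[1], object@scenarios[2],
              length(object@perAxis), object@rule))
  g <- object@combined@grid
  if (any(!is.na(g)))
    cat(sprintf(" combined offset: %.4g..%.4g\n",
                min(g, na.rm = TRUE), max(g, na.rm = TRUE)))
})

setMethod("show", "PopTree", function(object) {
  cat(sprintf("PopTree: %d pools, %s linkage\n",
              nrow(object@omega), object@linkage))
})

setMethod("show", "FreqPca", function(object) {
  cat(sprintf("FreqPca: %d pools, %d axes (%d monomorphic loci dropped)\n",
              nrow(object@scores), ncol(object@scores), object@nDropped))
  cat(" variance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(object@varExplained, 5)),
            collapse = " "), "\n")
})
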