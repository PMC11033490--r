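#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames
#'   rowRanges colData rowData
NULL

SYNC_BASES <- c("A", "T", "C", "G", "N", "del")
NUC_BASES <- c("A", "T", "C", "G")

#' PoolCounts: per-locus, per-pool read counts from a sync file
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one integer assay
#' per sync column (`A`, `T`, `C`, `G`, `N`, `del`), loci as rows (a `GRanges`
#' with the reference base in `mcols()$ref`) and pools as columns. Pool
#' metadata (`n_individuals`, `latitude`, `longitude`) lives in `colData`.
#'
#' Coverage is defined as A+T+C+G: the `N` and `del` columns are parsed and
#' round-tripped but never enter any estimator, which act on nucleotide
#' alleles only.
#'
#' @aliases PoolCounts-class
#' @exportClass PoolCounts
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

setValidity("PoolCounts", function(object) {
  msg <- character()
  if (!identical(assayNames(object), SYNC_BASES))
    msg <- c(msg, sprintf("assays must be exactly %s in that order",
                          paste(SYNC_BASES, collapse = ",")))
  else {
    for (b in SYNC_BASES) {
      a <- assay(object, b)
      if (any(a < 0) || any(a != round(a)))
        msg <- c(msg, sprintf("assay '%s' must hold non-negative integers", b))
    }
  }
  cd <- colData(object)
  if (!all(c("n_individuals", "latitude", "longitude") %in% colnames(cd)))
    msg <- c(msg, "colData needs n_individuals, latitude, longitude")
  else {
    if (any(cd$n_individuals <= 0 | cd$n_individuals != round(cd$n_individuals)))
      msg <- c(msg, "n_individuals must be positive integers")
    if (any(abs(cd$latitude) > 90)) msg <- c(msg, "|latitude| must be <= 90")
    if (any(abs(cd$longitude) > 180)) msg <- c(msg, "|longitude| must be <= 180")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "pool names must be unique")
  if (nrow(object) > 1L) {
    chr <- as.character(seqnames(rowRanges(object)))
    pos <- start(rowRanges(object))
    same <- chr[-1L] == chr[-length(chr)]
    if (any(same & diff(pos) <= 0))
      msg <- c(msg, "positions must be strictly increasing within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' PoolFreqs: filtered biallelic minor-allele frequencies
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding, for loci that
#' survived filtering, the per-pool minor-allele frequency (`freq` assay) and
#' the per-pool coverage of the biallelic pair (`cov` assay). `rowData` records
#' the major/minor bases and the pooled global minor-allele frequency.
#'
#' @aliases PoolFreqs-class
#' @exportClass PoolFreqs
setClass("PoolFreqs", contains = "RangedSummarizedExperiment")

setValidity("PoolFreqs", function(object) {
  msg <- character()
  if (!all(c("freq", "cov") %in% assayNames(object)))
    msg <- c(msg, "assays 'freq' and 'cov' are required")
  else {
    f <- assay(object, "freq")
    if (any(f < 0 | f > 1, na.rm = TRUE))
      msg <- c(msg, "frequencies must lie in [0, 1]")
  }
  if (!all(c("major", "minor") %in% colnames(rowData(object))))
    msg <- c(msg, "rowData needs 'major' and 'minor' allele columns")
  if (length(msg)) msg else TRUE
})

#' EnvGrid: an ESRI ASCII raster held in memory
#'
#' Row 1 of `grid` is the northernmost row (the ESRI convention); missing
#' cells are `NA` internally and serialized as the `nodata` token. Cell
#' centers sit at `xll + (col - 0.5) * cellsize` and
#' `yll + (nrows - row + 0.5) * cellsize`.
#'
#' @slot grid numeric matrix (nrows x ncols), NA marks nodata
#' @slot xll,yll lower-left corner, decimal degrees
#' @slot cellsize cell edge, decimal degrees
#' @slot nodata value used for missing cells on disk
#' @aliases EnvGrid-class
#' @exportClass EnvGrid
setClass("EnvGrid", representation(
  grid = "matrix", xll = "numeric", yll = "numeric",
  cellsize = "numeric", nodata = "numeric"))

setValidity("EnvGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@grid)) msg <- c(msg, "grid must be numeric")
  for (s in c("xll", "yll", "cellsize", "nodata"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a finite scalar", s))
  if (length(object@cellsize) == 1L && object@cellsize <= 0)
    msg <- c(msg, "cellsize must be positive")
  if (length(msg)) msg else TRUE
})

#' PredictorSet: standardized, pruned environmental predictors
#'
#' @slot X sites x predictors, each column standardized to mean 0, sd 1
#' @slot center,scale the standardization constants, named by predictor
#' @slot conditioning sites x q0 matrix of conditioning covariates (0 columns
#'   when the ordination is unconditioned)
#' @slot dropped character log of predictors removed by the correlation and
#'   VIF screens, as "name (reason)"
#' @aliases PredictorSet-class
#' @exportClass PredictorSet
setClass("PredictorSet", representation(
  X = "matrix", center = "numeric", scale = "numeric",
  conditioning = "matrix", dropped = "character"))

setValidity("PredictorSet", function(object) {
  msg <- character()
  if (ncol(object@X) > 0) {
    m <- colMeans(object@X)
    if (any(abs(m) > 1e-8)) msg <- c(msg, "columns of X must be centered")
    if (any(colnames(object@conditioning) %in% colnames(object@X)))
      msg <- c(msg, "conditioning columns must be disjoint from predictors")
  }
  if (nrow(object@conditioning) > 0 &&
      nrow(object@conditioning) != nrow(object@X))
    msg <- c(msg, "conditioning and X must have the same number of sites")
  if (length(msg)) msg else TRUE
})

#' RdaFit: a constrained ordination of allele frequencies
#'
#' @slot eig non-increasing eigenvalues of the constrained axes
#' @slot siteScores sites x axes (left singular vectors of fitted values)
#' @slot locusScores loci x axes, right singular vectors scaled by the
#'   singular values (a scaling-2 analogue)
#' @slot predictorLoadings predictors x axes biplot scores (correlations of
#'   the standardized predictors with the site scores)
#' @slot r2 constrained proportion of the total (pre-conditioning) variance
#' @slot r2adj Ezekiel-adjusted R squared
#' @slot proportions named proportions (conditioned, constrained,
#'   unconstrained), summing to 1
#' @slot n,q,q0 number of sites, predictors and conditioning columns
#' @slot totalSS total sum of squares of the centered response
#' @slot predictors the [PredictorSet-class] the model was fitted with
#' @aliases RdaFit-class
#' @exportClass RdaFit
setClass("RdaFit", representation(
  eig = "numeric", siteScores = "matrix", locusScores = "matrix",
  predictorLoadings = "matrix", r2 = "numeric", r2adj = "numeric",
  proportions = "numeric", n = "integer", q = "integer", q0 = "integer",
  totalSS = "numeric", predictors = "PredictorSet"))

setValidity("RdaFit", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eig), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eig < -1e-12)) msg <- c(msg, "eigenvalues must be >= 0")
  p <- object@proportions
  if (!identical(names(p), c("conditioned", "constrained", "unconstrained")))
    msg <- c(msg, "proportions must be named conditioned/constrained/unconstrained")
  else if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-9 | p > 1 + 1e-9))
    msg <- c(msg, "proportions must lie in [0,1] and sum to 1")
  if (length(msg)) msg else TRUE
})

#' AdaptiveIndex: per-axis adaptive-index rasters for one climate scenario
#'
#' @slot grids list of [EnvGrid-class], one per retained ordination axis
#' @slot eig the eigenvalues of those axes (used to weight the combined
#'   genomic offset)
#' @slot scenario free-text tag, e.g. "current" or "RCP8.5"
#' @aliases AdaptiveIndex-class
#' @exportClass AdaptiveIndex
setClass("AdaptiveIndex", representation(
  grids = "list", eig = "numeric", scenario = "character"))

setValidity("AdaptiveIndex", function(object) {
  msg <- character()
  if (length(object@grids) != length(object@eig))
    msg <- c(msg, "one eigenvalue per axis grid is required")
  if (!all(vapply(object@grids, is, logical(1), class2 = "EnvGrid")))
    msg <- c(msg, "grids must all be EnvGrid objects")
  if (length(msg)) msg else TRUE
})

#' OffsetRaster: genomic offset between two climate scenarios
#'
#' @slot perAxis list of per-axis |future - current| adaptive-index grids
#' @slot combined single [EnvGrid-class] after applying the combination rule
#' @slot rule one of "eigen-euclidean", "max", "sum"
#' @slot scenarios character(2): the current and future scenario tags
#' @aliases OffsetRaster-class
#' @exportClass OffsetRaster
setClass("OffsetRaster", representation(
  perAxis = "list", combined = "EnvGrid", rule = "character",
  scenarios = "character"))

#' PopTree: covariance-matrix population tree
#'
#' Holds the empirical covariance of standardized allele frequencies across
#' loci (Omega), its correlation form, the 1 - correlation dissimilarity, and
#' the agglomerative tree built from it.
#'
#' @slot omega,correlation,dissimilarity pools x pools matrices
#' @slot tree an [ape::phylo] tree with branch lengths from merge heights
#' @slot linkage the agglomeration criterion used
#' @aliases PopTree-class
#' @exportClass PopTree
setClass("PopTree", representation(
  omega = "matrix", correlation = "matrix", dissimilarity = "matrix",
  tree = "ANY", linkage = "character"))

#' FreqPca: principal components of population allele frequencies
#'
#' @slot scores pools x axes principal-component scores
#' @slot loadings loci x axes
#' @slot varExplained proportion of variance per axis
#' @slot nDropped loci removed because their cross-pool mean frequency was
#'   0 or 1 after subsetting
#' @aliases FreqPca-class
#' @exportClass FreqPca
setClass("FreqPca", representation(
  scores = "matrix", loadings = "matrix", varExplained = "numeric",
  nDropped = "integer"))
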