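#' @rdname PoolCounts-class
#' @param x a poolscape object
#' @export
setGeneric("poolNames", function(x) standardGeneric("poolNames"))

#' @rdname PoolCounts-class
#' @export
setGeneric("poolSizes", function(x) standardGeneric("poolSizes"))

#' @rdname PoolCounts-class
#' @export
setGeneric("poolCoverage", function(x) standardGeneric("poolCoverage"))

#' @rdname PoolFreqs-class
#' @param x a poolscape object
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname PoolFreqs-class
#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

#' @rdname EnvGrid-class
#' @param x an `EnvGrid`
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RdaFit-class
#' @param x an `RdaFit` (or other ordination object)
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname RdaFit-class
#' @export
setGeneric("siteScores", function(x) standardGeneric("siteScores"))

#' @rdname RdaFit-class
#' @export
setGeneric("locusScores", function(x) standardGeneric("locusScores"))

#' @rdname RdaFit-class
#' @export
setGeneric("predictorLoadings", function(x) standardGeneric("predictorLoadings"))

#' @rdname RdaFit-class
#' @export
setGeneric("varianceProportions", function(x) standardGeneric("varianceProportions"))
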