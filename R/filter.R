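#' SNP filtering configuration
#'
#' Thresholds follow the usual pool-seq conventions: a per-pool coverage
#' window, a minimum read support for the minor allele summed over pools
#' (the PoPoolation2 convention; set `perPool = TRUE` for the per-pool
#' variant), and a global pooled minor-allele-frequency cut.
#'
#' @param minCount minimum minor-allele read count (summed over pools)
#' @param minCov,maxCov per-pool nucleotide coverage bounds
#' @param maf global minor-allele frequency threshold in [0, 0.5]
#' @param perPool if TRUE, `minCount` must be met in every pool separately
#' @return a `filter_config` list
#' @export
filterConfig <- function(minCount = 4L, minCov = 20L, maxCov = 500L,
                         maf = 0.05, perPool = FALSE) {
  if (minCov <= 0 || maxCov < minCov) stop("need 0 < minCov <= maxCov")
  if (maf < 0 || maf > 0.5) stop("maf must lie in [0, 0.5]")
  structure(list(minCount = as.integer(minCount), minCov = as.integer(minCov),
                 maxCov = as.integer(maxCov), maf = maf,
                 perPool = isTRUE(perPool)), class = "filter_config")
}

# loci x pools matrix of counts for the base picked per locus (idx in 1..4)
.pickBase <- function(nuc, idx) {
  out <- matrix(0L, length(idx), ncol(nuc[[1]]))
  for (b in seq_along(NUC_BASES)) {
    rows <- which(idx == b)
    if (length(rows)) out[rows, ] <- nuc[[b]][rows, , drop = FALSE]
  }
  out
}

#' Filter loci and compute biallelic minor-allele frequencies
#'
#' Per locus, the two bases with the highest read counts summed over all
#' pools define the biallelic pair (ties broken in sync column order
#' A, T, C, G). A locus is dropped when any pool's nucleotide coverage falls
#' outside `[minCov, maxCov]`, when the global minor-allele count is below
#' `minCount`, when the global minor-allele frequency (minor reads over
#' minor+major reads, pooled) is below `maf`, or when a third allele exceeds
#' `minCount` reads. The per-pool minor-allele frequency is
#' minor / (minor + major).
#'
#' @param x a [PoolCounts-class]
#' @param config a [filterConfig()]
#' @return a [PoolFreqs-class] over the retained loci
#' @export
poolFrequencies <- function(x, config = filterConfig()) {
  stopifnot(is(x, "PoolCounts"), inherits(config, "filter_config"))
  if (ncol(x) == 0L) stop("no pools in count table")
  nuc <- lapply(NUC_BASES, function(b) assay(x, b))
  names(nuc) <- NUC_BASES
  L <- nrow(x); P <- ncol(x)
  totals <- vapply(nuc, rowSums, numeric(L))
  if (L == 0L) totals <- matrix(0, 0, 4, dimnames = list(NULL, NUC_BASES))
  if (L == 1L) totals <- matrix(totals, 1, 4, dimnames = list(NULL, NUC_BASES))
  # rank bases per locus by total, first-wins tie-break = sync column order
  t1 <- totals
  majorIdx <- max.col(t1, ties.method = "first")
  t1[cbind(seq_len(L), majorIdx)] <- -Inf
  minorIdx <- max.col(t1, ties.method = "first")
  t1[cbind(seq_len(L), minorIdx)] <- -Inf
  thirdIdx <- max.col(t1, ties.method = "first")
  majTot <- totals[cbind(seq_len(L), majorIdx)]
  minTot <- totals[cbind(seq_len(L), minorIdx)]
  thirdTot <- totals[cbind(seq_len(L), thirdIdx)]

  cov <- poolCoverage(x)
  keep <- rowSums(cov >= config$minCov & cov <= config$maxCov) == P
  minorMat <- .pickBase(nuc, minorIdx)
  if (config$perPool) {
    keep <- keep & (rowSums(minorMat >= config$minCount) == P)
  } else {
    keep <- keep & (minTot >= config$minCount)
  }
  globalMaf <- ifelse(majTot + minTot > 0, minTot / (majTot + minTot), 0)
  keep <- keep & (globalMaf >= config$maf)
  keep <- keep & (thirdTot <= config$minCount)
  kept <- which(keep)
  if (!length(kept) && L > 0L)
    warning("all loci removed by filtering; returning an empty PoolFreqs")

  majorMat <- .pickBase(nuc, majorIdx)
  maj <- majorMat[kept, , drop = FALSE]
  mnr <- minorMat[kept, , drop = FALSE]
  covPair <- maj + mnr
  freq <- ifelse(covPair > 0, mnr / covPair, NA_real_)
  storage.mode(covPair) <- "double"
  dimnames(freq) <- dimnames(covPair) <- list(NULL, colnames(x))
  rr <- rowRanges(x)[kept]
  rd <- DataFrame(major = NUC_BASES[majorIdx[kept]],
                  minor = NUC_BASES[minorIdx[kept]],
                  global_maf = globalMaf[kept])
  S4Vectors::mcols(rr) <- cbind(S4Vectors::mcols(rr), rd)
  se <- SummarizedExperiment(assays = list(freq = freq, cov = covPair),
                             rowRanges = rr, colData = colData(x))
  new("PoolFreqs", se)
}
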