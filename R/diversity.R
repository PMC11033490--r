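#' Windowed nucleotide diversity (pi) for one pool
#'
#' Site heterozygosity for a retained SNP is `h = (C/(C-1)) * 2 f (1-f)`
#' with the pool's own biallelic pair (its two highest-count bases), and
#' window pi is `sum(h) / windowSize`: the denominator is the full window
#' length including invariant sites, matching the sliding-window tools this
#' mirrors. Computing pi from variant sites only in this way biases it
#' downward in absolute terms, so treat it as a comparative statistic among
#' pools rather than an absolute estimate.
#'
#' A site enters a window when the pool's nucleotide coverage lies within
#' the configured bounds and its own minor-allele count reaches `minCount`
#' (the per-pool reading of the threshold, as in single-pool sliding-window
#' analysis). Empty windows report pi = 0 with `n_snps = 0`.
#'
#' @param x a [PoolCounts-class]
#' @param pool pool name or index
#' @param windowSize window length in bp
#' @param config a [filterConfig()]; `minCount` is applied within this pool
#' @return data.frame: `chrom`, `start`, `end` (half-open), `pi`, `n_snps`
#' @export
windowPi <- function(x, pool, windowSize = 10000L,
                     config = filterConfig(minCount = 2L)) {
  stopifnot(is(x, "PoolCounts"), windowSize >= 1L)
  cnt <- vapply(NUC_BASES, function(b) assay(x, b)[, pool], numeric(nrow(x)))
  if (nrow(x) == 1L) cnt <- matrix(cnt, 1, 4)
  C <- rowSums(cnt)
  tmp <- cnt
  majIdx <- max.col(tmp, ties.method = "first")
  maj <- tmp[cbind(seq_len(nrow(tmp)), majIdx)]
  tmp[cbind(seq_len(nrow(tmp)), majIdx)] <- -1
  mnr <- tmp[cbind(seq_len(nrow(tmp)), max.col(tmp, ties.method = "first"))]
  ok <- C >= config$minCov & C <= config$maxCov & mnr >= config$minCount
  pair <- maj + mnr
  f <- ifelse(pair > 0, mnr / pair, 0)
  h <- ifelse(pair > 1, (pair / (pair - 1)) * 2 * f * (1 - f), 0)
  pos <- start(rowRanges(x)); chrom <- as.character(seqnames(rowRanges(x)))
  res <- list()
  for (chr in unique(chrom)) {
    sel <- chrom == chr
    starts <- seq(1L, max(pos[sel]), by = windowSize)
    idx <- findInterval(pos[sel], starts)
    hv <- ifelse(ok[sel], h[sel], 0)
    sums <- tapply(hv, idx, sum)
    ns <- tapply(ok[sel], idx, sum)
    pi <- rep(0, length(starts)); n <- rep(0L, length(starts))
    pi[as.integer(names(sums))] <- as.numeric(sums) / windowSize
    n[as.integer(names(ns))] <- as.integer(ns)
    res[[chr]] <- data.frame(chrom = chr, start = starts,
                             end = starts + windowSize, pi = pi, n_snps = n)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Tajima (1989) normalization coefficients for n chromosomes
tajimaCoefficients <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from per-site derived-allele counts
#'
#' Classic Tajima's D on `nChrom` effective chromosomes: mean pairwise
#' differences versus Watterson's theta, normalized by the standard
#' coefficients. Inputs are per-site derived-allele counts (1..nChrom-1);
#' counts of 0 or nChrom are ignored as non-segregating. With no segregating
#' sites D is undefined and `NA` is returned.
#'
#' This deliberately works on site-frequency-spectrum-style inputs with
#' `nChrom = 2 * n_individuals` rather than re-deriving a pooled-read
#' correction; it is used comparatively (sign and magnitude), which is also
#' how windowed D is interpreted downstream.
#'
#' @param sfsCounts integer vector of derived-allele counts per site
#' @param nChrom number of chromosomes (>= 4)
#' @return Tajima's D (scalar), or `NA` when no site segregates
#' @export
tajimasD <- function(sfsCounts, nChrom) {
  if (nChrom < 4L) stop("nChrom must be >= 4")
  k <- sfsCounts[sfsCounts > 0 & sfsCounts < nChrom]
  S <- length(k)
  if (S == 0L) return(NA_real_)
  co <- tajimaCoefficients(nChrom)
  piHat <- sum(2 * k * (nChrom - k)) / (nChrom * (nChrom - 1))
  thetaW <- S / co$a1
  D <- (piHat - thetaW) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
  D
}
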