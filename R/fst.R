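#' Per-SNP and sliding-window classic F_ST between two pools
#'
#' Implements the per-site estimator used by sliding-window pool-seq tools:
#' each pool's heterozygosity is `H = (C/(C-1)) (1 - f^2 - (1-f)^2)` with
#' coverage `C` and allele frequency `f`; `Pi_within` is the mean of the two
#' pools' H; `Pi_total` the H of the pooled counts at combined coverage; and
#' `F_ST = (Pi_total - Pi_within) / Pi_total`, clamped at 0 from below
#' (identical pools give slightly negative raw values under the `C/(C-1)`
#' correction; the unclamped mean is kept in `fst_raw`). Windowed values are
#' SNP means over half-open windows `[start, start + size)`; windows with no
#' SNPs are omitted. Sites monomorphic across both pools are skipped.
#'
#' @param freqs a [PoolFreqs-class]
#' @param poolA,poolB pool names or indices
#' @param windowSize window width in bp (1 = per SNP)
#' @param step step between window starts; defaults to `windowSize`
#' @return data.frame: `chrom`, `start`, `end`, `fst` (clamped mean),
#'   `fst_raw` (unclamped mean), `n_snps`
#' @export
perSnpFst <- function(freqs, poolA, poolB, windowSize = 1L,
                      step = windowSize) {
  stopifnot(is(freqs, "PoolFreqs"), windowSize >= 1L, step >= 1L)
  f <- assay(freqs, "freq"); C <- assay(freqs, "cov")
  f1 <- f[, poolA]; f2 <- f[, poolB]
  C1 <- C[, poolA]; C2 <- C[, poolB]
  m1 <- f1 * C1; m2 <- f2 * C2
  ok <- !is.na(f1) & !is.na(f2) & C1 > 1 & C2 > 1
  H <- function(fq, cv) (cv / (cv - 1)) * (1 - fq^2 - (1 - fq)^2)
  piW <- (H(f1, C1) + H(f2, C2)) / 2
  Ct <- C1 + C2
  ft <- (m1 + m2) / Ct
  piT <- H(ft, Ct)
  ok <- ok & piT > 0                       # monomorphic across the pair
  raw <- (piT - piW) / piT
  snp <- data.frame(chrom = as.character(seqnames(rowRanges(freqs))),
                    pos = start(rowRanges(freqs)),
                    raw = raw, clamped = pmax(raw, 0))[ok, , drop = FALSE]
  winStat(snp, windowSize, step)
}

# aggregate per-SNP F_ST into half-open windows [start, start+size); the
# per-site clamp happens before window averaging
winStat <- function(snp, windowSize, step) {
  res <- list()
  for (chr in unique(snp$chrom)) {
    s <- snp[snp$chrom == chr, , drop = FALSE]
    if (!nrow(s)) next
    starts <- seq(1L, max(s$pos), by = step)
    idx <- findInterval(s$pos, starts)
    # a window only covers positions < start + windowSize
    inWin <- s$pos < starts[idx] + windowSize
    s <- s[inWin, , drop = FALSE]; idx <- idx[inWin]
    agg <- tapply(s$clamped, idx, mean)
    aggRaw <- tapply(s$raw, idx, mean)
    n <- tapply(s$raw, idx, length)
    w <- as.integer(names(agg))
    res[[chr]] <- data.frame(chrom = chr, start = starts[w],
                             end = starts[w] + windowSize,
                             fst = as.numeric(agg),
                             fst_raw = as.numeric(aggRaw),
                             n_snps = as.integer(n))
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), fst = numeric(), fst_raw = numeric(),
                      n_snps = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Two-stage per-pair variance components at each locus. Reads within a pool
# are a two-stage sample (chromosomes within pool, then reads); the MS
# denominators below make E[MSI] = 2pq(1-F) and E[MSP] = 2pq(1+(nc-1)F),
# so the ratio of summed components is unbiased for F.
.pairComponents <- function(f1, f2, C1, C2, n1, n2) {
  SumC <- C1 + C2
  fbar <- (C1 * f1 + C2 * f2) / SumC
  SSI <- 2 * (C1 * f1 * (1 - f1) + C2 * f2 * (1 - f2))
  SSP <- 2 * (C1 * (f1 - fbar)^2 + C2 * (f2 - fbar)^2)
  dI <- (C1 - 1) * (n1 - 1) / n1 + (C2 - 1) * (n2 - 1) / n2
  w1 <- C1 - C1^2 / SumC; w2 <- C2 - C2^2 / SumC
  b1 <- (1 - 1 / n1) * (1 - 1 / C1); b2 <- (1 - 1 / n2) * (1 - 1 / C2)
  dP <- w1 * (1 - b1) + w2 * (1 - b2)
  nc <- 1 + (w1 * b1 + w2 * b2) / dP
  MSI <- SSI / dI
  MSP <- SSP / dP
  sigP <- (MSP - MSI) / nc        # among-pool component
  list(num = sigP, den = sigP + MSI)
}

#' Pairwise F_ST by the ANOVA (variance-components) method
#'
#' A pooled-data analysis-of-variance estimator that corrects for the two
#' sampling stages of pool-seq: the 2n chromosomes entering each pool, and
#' the reads drawn from them. Per locus and pair, within- and among-pool
#' mean squares are formed with denominators chosen so that the among
#' component has expectation `2pq F` and the total `2pq`; loci are combined
#' as a ratio of summed components (not a mean of per-locus ratios), the
#' standard choice for stability. Small negative estimates are legitimate
#' for an unbiased estimator and are not clamped.
#'
#' @param x a [PoolCounts-class] (pool sizes are taken from its `colData`)
#' @param config a [filterConfig()] applied before estimation
#' @param freqs optionally, a precomputed [PoolFreqs-class] (then `config`
#'   is ignored)
#' @return list: `fst` (symmetric pools x pools matrix, diagonal 0),
#'   `n_loci` (informative loci per pair), `low_confidence` (logical matrix,
#'   TRUE where a pair had fewer than 50 informative loci)
#' @export
pairwiseFstAnova <- function(x, config = filterConfig(), freqs = NULL) {
  if (is.null(freqs)) freqs <- poolFrequencies(x, config)
  P <- ncol(freqs)
  if (P < 2L) stop("at least two pools are required")
  f <- assay(freqs, "freq"); C <- assay(freqs, "cov")
  nHap <- 2 * poolSizes(freqs)
  fst <- matrix(0, P, P, dimnames = list(colnames(freqs), colnames(freqs)))
  nl <- matrix(0L, P, P, dimnames = dimnames(fst))
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    ok <- !is.na(f[, i]) & !is.na(f[, j]) & C[, i] > 1 & C[, j] > 1
    # informative = polymorphic within the pair
    ok <- ok & (f[, i] > 0 | f[, j] > 0) & (f[, i] < 1 | f[, j] < 1)
    cmp <- .pairComponents(f[ok, i], f[ok, j], C[ok, i], C[ok, j],
                           nHap[i], nHap[j])
    fst[i, j] <- fst[j, i] <- sum(cmp$num) / sum(cmp$den)
    nl[i, j] <- nl[j, i] <- sum(ok)
  }
  low <- nl < 50L & !diag(TRUE, P)
  list(fst = fst, n_loci = nl, low_confidence = low)
}

#' Slatkin's linearization of F_ST
#'
#' `F / (1 - F)`, which grows linearly with distance under isolation by
#' distance in one- and two-dimensional stepping-stone models.
#'
#' @param fst F_ST value(s) in `[0, 1)`; matrices are transformed
#'   elementwise with the diagonal left at 0
#' @return transformed value(s)
#' @export
slatkinLinearize <- function(fst) {
  if (any(fst >= 1, na.rm = TRUE))
    stop("F_ST >= 1 cannot be linearized (infinite)")
  fst / (1 - fst)
}
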