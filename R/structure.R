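# center per locus and scale by 1/sqrt(pbar(1-pbar)); drops loci fixed
# across the (sub)set of pools
standardizeFreqs <- function(F) {
  pbar <- colMeans(F)
  keep <- pbar > 0 & pbar < 1
  Fc <- sweep(F[, keep, drop = FALSE], 2, pbar[keep])
  Fs <- sweep(Fc, 2, sqrt(pbar[keep] * (1 - pbar[keep])), "/")
  list(X = Fs, nDropped = sum(!keep))
}

#' Principal component analysis of population allele frequencies
#'
#' Loci are centered across pools and scaled by `1/sqrt(pbar(1-pbar))` with
#' `pbar` the cross-pool mean frequency (the binomial-variance scaling used
#' for allele-frequency PCA); the singular-value decomposition of the
#' resulting pools x loci matrix gives scores (`U D`) and per-axis variance
#' proportions. Loci monomorphic across the selected pools are dropped with
#' their count recorded. Hierarchical analyses (all pools / a regional
#' subset) are expressed through the `subset` argument.
#'
#' @param freqs a [PoolFreqs-class] or a pools x loci frequency matrix
#' @param subset optional character vector of pool names (or indices) to
#'   analyse; default all pools
#' @return a [FreqPca-class]
#' @export
pcaFrequencies <- function(freqs, subset = NULL) {
  F <- if (is(freqs, "PoolFreqs")) freqMatrix(freqs) else as.matrix(freqs)
  if (!is.null(subset)) F <- F[subset, , drop = FALSE]
  if (nrow(F) < 3L) stop("at least 3 pools are required after subsetting")
  st <- standardizeFreqs(F)
  sv <- svd(st$X)
  keep <- sv$d > max(sv$d) * 1e-9
  d <- sv$d[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(d, length(d))
  dimnames(scores) <- list(rownames(F), paste0("PC", seq_along(d)))
  loadings <- sv$v[, keep, drop = FALSE]
  colnames(loadings) <- colnames(scores)
  new("FreqPca", scores = scores, loadings = loadings,
      varExplained = d^2 / sum(sv$d^2), nDropped = st$nDropped)
}

#' Covariance-matrix population tree
#'
#' Omega is the empirical pools x pools covariance, across loci, of the
#' centered and binomial-scaled allele frequencies; it is converted to a
#' correlation matrix, then to the dissimilarity `1 - correlation`, and
#' clustered agglomeratively (average linkage by default, the UPGMA
#' convention). The tree is returned as an `ape` phylo object with branch
#' lengths taken from the merge heights.
#'
#' @param freqs a [PoolFreqs-class] or pools x loci frequency matrix
#' @param linkage `"average"`, `"complete"` or `"single"`
#' @return a [PopTree-class]
#' @export
popCovarianceTree <- function(freqs,
                              linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  F <- if (is(freqs, "PoolFreqs")) freqMatrix(freqs) else as.matrix(freqs)
  if (nrow(F) < 3L) stop("at least 3 pools are required")
  st <- standardizeFreqs(F)
  L <- ncol(st$X)
  omega <- tcrossprod(st$X) / (L - 1)
  dimnames(omega) <- list(rownames(F), rownames(F))
  v <- diag(omega)
  if (any(v <= 0))
    stop("zero-variance pool(s): ",
         paste(rownames(F)[v <= 0], collapse = ", "))
  corr <- stats::cov2cor(omega)
  diss <- 1 - corr
  hc <- stats::hclust(stats::as.dist(diss), method = linkage)
  tree <- ape::as.phylo(hc)
  new("PopTree", omega = omega, correlation = corr, dissimilarity = diss,
      tree = tree, linkage = linkage)
}

#' Newick serialization of a PopTree
#'
#' @param x a [PopTree-class]
#' @return single newick string
#' @export
popTreeNewick <- function(x) {
  stopifnot(is(x, "PopTree"))
  ape::write.tree(x@tree)
}
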