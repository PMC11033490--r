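#' Mahalanobis RDA outlier detection
#'
#' Each locus's score on the first `K` constrained axes is compared with the
#' cloud of all loci: `D^2` is the Mahalanobis distance from the column
#' means under the empirical K x K covariance, p-values are upper-tail
#' chi-squared with K degrees of freedom, and q-values are
#' Benjamini-Hochberg. Loci with `q < fdr` are flagged. An optional
#' genomic-inflation rescaling (`rescale = TRUE`) divides `D^2` by
#' `median(D^2)/qchisq(0.5, K)`; it is off by default.
#'
#' @param scores loci x axes matrix of locus scores (an [RdaFit-class] is
#'   accepted and its locus scores used)
#' @param K number of leading axes (default 2)
#' @param fdr flag threshold on the q-value (default 0.05)
#' @param rescale apply median-based genomic-inflation rescaling
#' @return data.frame: `D2`, `p`, `q`, `outlier`
#' @export
mahalanobisOutliers <- function(scores, K = 2L, fdr = 0.05, rescale = FALSE) {
  if (is(scores, "RdaFit")) scores <- locusScores(scores)
  scores <- as.matrix(scores)
  if (K < 1L || K > ncol(scores))
    stop("K must be between 1 and the number of axes")
  if (nrow(scores) < K + 2L) stop("need at least K + 2 loci")
  S <- scores[, seq_len(K), drop = FALSE]
  ctr <- colMeans(S)
  Sig <- stats::cov(S)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-12)
    stop("singular score covariance; reduce the number of axes K")
  D2 <- stats::mahalanobis(S, ctr, Sig)
  if (rescale) D2 <- D2 / (stats::median(D2) / stats::qchisq(0.5, K))
  p <- stats::pchisq(D2, df = K, lower.tail = FALSE)
  q <- bhFdr(p)
  out <- data.frame(D2 = D2, p = p, q = q, outlier = q < fdr)
  rownames(out) <- rownames(scores)
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: `q_(i) = min_{j >= i} min(1, p_(j) m / j)`, mapped back
#' to the input order (computed through [stats::p.adjust()]).
#'
#' @param p p-values in (0, 1]
#' @return q-values, same order as `p`
#' @export
bhFdr <- function(p) {
  if (any(p <= 0 | p > 1 | is.na(p)))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Adaptive-index rasters along retained RDA axes
#'
#' For axis k and pixel x, `AI_k(x) = sum_j loading_jk * z_j(x)` where
#' `z_j` standardizes the pixel's value of predictor j with the mean and sd
#' recorded from the site-level predictor table used to fit the ordination
#' (never from the raster's own distribution), so sites and pixels -- and
#' the current and future scenarios -- share one scale. Nodata propagates:
#' a pixel missing any predictor is nodata in every axis.
#'
#' @param model an [RdaFit-class]
#' @param rasters named list of [EnvGrid-class], one per model predictor,
#'   all sharing the same header
#' @param axes which constrained axes to map (default the first two, or all
#'   if fewer)
#' @param scenario free-text tag stored with the result
#' @return an [AdaptiveIndex-class]
#' @export
adaptiveIndex <- function(model, rasters, axes = NULL, scenario = "current") {
  stopifnot(is(model, "RdaFit"))
  preds <- rownames(predictorLoadings(model))
  if (is.null(axes)) axes <- seq_len(min(2L, length(eigenvalues(model))))
  if (!all(preds %in% names(rasters)))
    stop("rasters missing for predictor(s): ",
         paste(setdiff(preds, names(rasters)), collapse = ", "))
  rasters <- rasters[preds]
  ref <- rasters[[1]]
  for (r in rasters) if (!gridsAligned(ref, r))
    stop("predictor rasters are not aligned (header/shape mismatch)")
  ctr <- model@predictors@center[preds]
  scl <- model@predictors@scale[preds]
  zs <- mapply(function(r, m, s) (r@grid - m) / s, rasters, ctr, scl,
               SIMPLIFY = FALSE)
  grids <- lapply(axes, function(k) {
    ai <- Reduce(`+`, mapply(function(z, w) w * z,
                             zs, predictorLoadings(model)[, k],
                             SIMPLIFY = FALSE))
    EnvGrid(ai, ref@xll, ref@yll, ref@cellsize, ref@nodata)
  })
  new("AdaptiveIndex", grids = grids, eig = eigenvalues(model)[axes],
      scenario = scenario)
}

#' Genomic offset between current and future adaptive indices
#'
#' Per axis the offset is `|AI_future - AI_current|` per pixel. Axes are
#' combined by the chosen rule: `eigen-euclidean` (default) takes
#' `sqrt(sum_k w_k O_k^2)` with `w_k = eig_k / sum(eig)`; `max` the
#' pixelwise maximum; `sum` the plain sum. An optional mask is applied
#' last: pixels where the mask is nodata or 0 become nodata.
#'
#' @param current,future [AdaptiveIndex-class] objects over the same axes
#'   and grids
#' @param mask optional [EnvGrid-class]; positive non-missing cells are kept
#' @param rule combination rule
#' @return an [OffsetRaster-class]
#' @export
genomicOffset <- function(current, future, mask = NULL,
                          rule = c("eigen-euclidean", "max", "sum")) {
  rule <- match.arg(rule)
  stopifnot(is(current, "AdaptiveIndex"), is(future, "AdaptiveIndex"))
  if (length(current@grids) != length(future@grids))
    stop("current and future must cover the same axes")
  ref <- current@grids[[1]]
  perAxis <- mapply(function(c, f) {
    if (!gridsAligned(c, f)) stop("current/future grids are not aligned")
    EnvGrid(abs(f@grid - c@grid), ref@xll, ref@yll, ref@cellsize, ref@nodata)
  }, current@grids, future@grids, SIMPLIFY = FALSE)
  O <- lapply(perAxis, gridValues)
  comb <- switch(rule,
    "eigen-euclidean" = {
      w <- current@eig / sum(current@eig)
      sqrt(Reduce(`+`, mapply(function(o, wk) wk * o^2, O, w,
                              SIMPLIFY = FALSE)))
    },
    "max" = Reduce(pmax, O),
    "sum" = Reduce(`+`, O))
  if (!is.null(mask)) {
    if (!gridsAligned(ref, mask)) stop("mask grid is not aligned")
    drop <- is.na(mask@grid) | mask@grid == 0
    comb[drop] <- NA_real_
    perAxis <- lapply(perAxis, function(g) {
      g@grid[drop] <- NA_real_; g
    })
  }
  new("OffsetRaster", perAxis = perAxis,
      combined = EnvGrid(comb, ref@xll, ref@yll, ref@cellsize, ref@nodata),
      rule = rule,
      scenarios = c(current@scenario, future@scenario))
}
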