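#' Build a standardized predictor set, with correlation and VIF pruning
#'
#' Zero-variance predictors are dropped with a warning. Then, for any pair
#' with `|Pearson r| >= rMax`, the later-listed member is dropped,
#' iterating until no such pair remains. Finally the predictor with the
#' largest variance inflation factor (`1/(1-R^2)` from regressing it on the
#' others) is dropped repeatedly until all VIF fall below `vifMax`.
#' Survivors are standardized to mean 0, sd 1 and the constants recorded so
#' raster pixels can be placed on the same scale later.
#'
#' @param env data.frame or matrix of site x predictor values
#' @param rMax pairwise correlation threshold (default 0.85)
#' @param vifMax VIF threshold (default 10)
#' @param conditioning optional site x q0 matrix/data.frame of conditioning
#'   covariates (e.g. longitude/latitude, or PC axes); kept unstandardized
#' @return a [PredictorSet-class]
#' @export
prunePredictors <- function(env, rMax = 0.85, vifMax = 10,
                            conditioning = NULL) {
  X <- as.matrix(as.data.frame(env))
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (nrow(X) < 2L) stop("at least 2 sites are required")
  if (anyNA(X)) stop("missing predictor values are not allowed")
  dropped <- character(0)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance predictor(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    dropped <- c(dropped, sprintf("%s (zero variance)",
                                  colnames(X)[sds == 0]))
    X <- X[, sds > 0, drop = FALSE]
  }
  repeat {
    if (ncol(X) < 2L) break
    r <- abs(stats::cor(X)); r[!upper.tri(r)] <- 0
    hit <- which(r >= rMax, arr.ind = TRUE)
    if (!nrow(hit)) break
    # first offending pair in column order; drop its later-listed member
    hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
    j <- hit[1, 2]
    dropped <- c(dropped, sprintf("%s (|r| >= %g with %s)", colnames(X)[j],
                                  rMax, colnames(X)[hit[1, 1]]))
    X <- X[, -j, drop = FALSE]
  }
  repeat {
    if (ncol(X) < 2L) break
    vif <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
      1 / max(1 - r2, 1e-12)
    }, numeric(1))
    if (all(vif < vifMax)) break
    j <- which.max(vif)
    dropped <- c(dropped, sprintf("%s (VIF %.2f)", colnames(X)[j], vif[j]))
    X <- X[, -j, drop = FALSE]
  }
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Xs <- scale(X, center = ctr, scale = scl)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  cond <- if (is.null(conditioning))
    matrix(numeric(0), nrow(X), 0) else as.matrix(as.data.frame(conditioning))
  clash <- colnames(cond) %in% colnames(Xs)
  if (any(clash))   # e.g. auto-generated names on plain matrices
    colnames(cond)[clash] <- paste0(colnames(cond)[clash], "_cond")
  new("PredictorSet", X = Xs, center = ctr, scale = scl,
      conditioning = cond, dropped = dropped)
}

# residualize columns of M on [1, Z]
.residOn <- function(M, Z) {
  q <- qr(cbind(1, Z))
  qr.resid(q, M)
}

# promote a plain predictor matrix to a standardized PredictorSet
.asPredictorSet <- function(predictors) {
  if (is(predictors, "PredictorSet")) return(predictors)
  X0 <- as.matrix(predictors)
  if (is.null(colnames(X0)))
    colnames(X0) <- paste0("pred", seq_len(ncol(X0)))
  Xs <- scale(X0)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  new("PredictorSet", X = Xs, center = colMeans(X0),
      scale = apply(X0, 2, stats::sd),
      conditioning = matrix(numeric(0), nrow(X0), 0),
      dropped = character(0))
}

#' Fit a redundancy analysis of allele frequencies on predictors
#'
#' The response `Y` (sites x loci minor-allele frequencies) is centered per
#' locus but not rescaled. With conditioning covariates present, both `Y`
#' and the predictors are first replaced by their residuals on the
#' conditioning matrix (partial RDA). The constrained ordination is the
#' singular-value decomposition of the least-squares fitted values
#' `Yhat = X B`: eigenvalues are `d_k^2/(n-1)`, site scores the left
#' singular vectors, locus scores the right singular vectors scaled by the
#' singular values, and predictor loadings the correlations between the
#' standardized predictors and the site scores. Variance proportions
#' (conditioned / constrained / unconstrained) partition the total sum of
#' squares of the centered response; `R^2` is the constrained proportion
#' and `R^2_adj` its Ezekiel correction.
#'
#' By default loci are not rescaled (the usual ordination convention for
#' allele frequencies, and what the variance-partition table reports).
#' `scaling = "binomial"` divides each locus by `sqrt(pbar(1-pbar))`, with
#' `pbar` its cross-site mean frequency: this equalizes the binomial
#' sampling variance across loci so that locus scores are homoscedastic,
#' which is what the chi-squared calibration of the Mahalanobis outlier
#' test assumes. The outlier-detection path therefore uses the binomial
#' scaling; the variance-partition models use the default.
#'
#' @param freqs a [PoolFreqs-class] or sites x loci numeric matrix
#' @param predictors a [PredictorSet-class] (see [prunePredictors()]), or a
#'   plain matrix of predictors which will be standardized without pruning
#' @param scaling `"none"` (default) or `"binomial"` (see Details)
#' @return an [RdaFit-class]
#' @export
fitRda <- function(freqs, predictors, scaling = c("none", "binomial")) {
  scaling <- match.arg(scaling)
  Y <- if (is(freqs, "PoolFreqs")) freqMatrix(freqs) else as.matrix(freqs)
  if (scaling == "binomial") {
    pbar <- colMeans(Y)
    if (any(pbar <= 0 | pbar >= 1))
      stop("binomial scaling needs frequencies with cross-site mean in (0,1); ",
           "filter fixed loci first")
    Y <- sweep(Y, 2, sqrt(pbar * (1 - pbar)), "/")
  }
  predictors <- .asPredictorSet(predictors)
  X <- predictors@X
  Z <- predictors@conditioning
  n <- nrow(Y); q <- ncol(X); q0 <- ncol(Z)
  if (nrow(X) != n) stop("sites of freqs and predictors do not align")
  if (ncol(Y) < 1L) stop("at least one locus is required")
  if (q > n - 1L - q0)
    stop("more predictors than sites - 1 - conditioning columns")
  Yc <- sweep(Y, 2, colMeans(Y))
  totalSS <- sum(Yc^2)
  if (q0 > 0L) {
    Yr <- .residOn(Yc, Z)
    Xr <- .residOn(X, Z)
  } else {
    Yr <- Yc; Xr <- X
  }
  qrX <- qr(Xr)
  if (qrX$rank < q)
    stop("predictors are rank-deficient after conditioning; collinear: ",
         paste(colnames(X), collapse = ", "))
  Yhat <- qr.fitted(qrX, Yr)
  sv <- svd(Yhat)
  keep <- sv$d > max(sv$d[1], 1e-300) * 1e-9 & seq_along(sv$d) <= qrX$rank
  d <- sv$d[keep]
  axes <- paste0("RDA", seq_along(d))
  siteScores <- sv$u[, keep, drop = FALSE]
  dimnames(siteScores) <- list(rownames(Y), axes)
  locusScores <- sv$v[, keep, drop = FALSE] %*% diag(d, length(d))
  dimnames(locusScores) <- list(colnames(Y), axes)
  loadings <- suppressWarnings(stats::cor(X, siteScores))
  loadings[is.na(loadings)] <- 0
  dimnames(loadings) <- list(colnames(X), axes)
  constrSS <- sum(Yhat^2)
  condSS <- totalSS - sum(Yr^2)
  unconSS <- totalSS - condSS - constrSS
  props <- c(conditioned = condSS, constrained = constrSS,
             unconstrained = unconSS) / totalSS
  r2 <- constrSS / totalSS
  r2adj <- adjustedR2(r2, n - q0, q)
  new("RdaFit", eig = d^2 / (n - 1), siteScores = siteScores,
      locusScores = locusScores, predictorLoadings = loadings,
      r2 = r2, r2adj = r2adj, proportions = props,
      n = as.integer(n), q = as.integer(q), q0 = as.integer(q0),
      totalSS = totalSS, predictors = predictors)
}

#' Ezekiel-adjusted R squared
#'
#' `1 - (1 - R^2)(n - 1)/(n - p - 1)`. Deterministic closed form; for
#' unconditioned models it coincides asymptotically with the
#' permutation-based adjustment some ordination software reports.
#'
#' @param r2 unadjusted R squared
#' @param nSites number of sites
#' @param nPredictors number of predictors
#' @return adjusted R squared (can be negative)
#' @export
adjustedR2 <- function(r2, nSites, nPredictors) {
  if (nSites - nPredictors - 1 <= 0)
    stop("need nSites - nPredictors - 1 > 0")
  1 - (1 - r2) * (nSites - 1) / (nSites - nPredictors - 1)
}

# constrained and residual SS of Yr regressed on Xr (projection via qr);
# the residual is clamped at zero so that an exactly explained response
# yields F = Inf rather than a sign flip from rounding
.rdaSS <- function(qrX, Yr) {
  cSS <- sum(qr.fitted(qrX, Yr)^2)
  c(constrained = cSS, residual = max(sum(Yr^2) - cSS, 0))
}

#' ANOVA-like permutation test for an RDA
#'
#' The global pseudo-F is `(constrained SS / q) / (residual SS / (n - q -
#' q0 - 1))`. Without conditioning, rows of the centered response are
#' permuted freely; with conditioning, residuals of the reduced
#' (conditioning-only) model are permuted, the standard scheme for
#' conditioned ordination. `p = (1 + #{F_perm >= F}) / (nPerm + 1)`.
#' Marginal per-predictor tests treat the remaining predictors (plus any
#' conditioning) as the reduced model.
#'
#' @param freqs a [PoolFreqs-class] or sites x loci matrix
#' @param predictors a [PredictorSet-class] or plain predictor matrix
#' @param nPerm number of permutations (default 999)
#' @param seed optional integer seed
#' @param marginal also run per-predictor marginal tests (default TRUE)
#' @param scaling locus scaling, as in [fitRda()]
#' @return list: `F`, `p`, `nPerm`, and (when `marginal`) data.frame
#'   `terms` with per-predictor `F` and `p`
#' @export
rdaPermutationTest <- function(freqs, predictors, nPerm = 999L, seed = NULL,
                               marginal = TRUE,
                               scaling = c("none", "binomial")) {
  scaling <- match.arg(scaling)
  Y <- if (is(freqs, "PoolFreqs")) freqMatrix(freqs) else as.matrix(freqs)
  if (scaling == "binomial") {
    pbar <- colMeans(Y)
    Y <- sweep(Y, 2, sqrt(pbar * (1 - pbar)), "/")
  }
  predictors <- .asPredictorSet(predictors)
  X <- predictors@X; Z <- predictors@conditioning
  n <- nrow(Y); q <- ncol(X); q0 <- ncol(Z)
  dfRes <- n - q - q0 - 1L
  if (dfRes <= 0L) stop("residual degrees of freedom <= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  Yc <- sweep(Y, 2, colMeans(Y))
  one <- function(Xfull, Zc, Yin) {
    # returns observed F and a closure giving permuted F values
    if (ncol(Zc) > 0L) {
      Yr <- .residOn(Yin, Zc); Xr <- .residOn(Xfull, Zc)
    } else {
      Yr <- Yin; Xr <- Xfull
    }
    qrX <- qr(Xr)
    qz <- if (ncol(Zc) > 0L) qr(cbind(1, Zc)) else NULL
    qEff <- qrX$rank
    dfR <- n - qEff - ncol(Zc) - 1L
    ss <- .rdaSS(qrX, Yr)
    Fobs <- (ss[1] / qEff) / (ss[2] / dfR)
    permF <- function() {
      idx <- sample.int(n)
      Yp <- Yr[idx, , drop = FALSE]
      if (!is.null(qz)) Yp <- qr.resid(qz, Yp)
      ssp <- .rdaSS(qrX, Yp)
      (ssp[1] / qEff) / (ssp[2] / dfR)
    }
    list(F = unname(Fobs), permF = permF)
  }
  glob <- one(X, Z, Yc)
  ge <- 0L
  for (b in seq_len(nPerm)) if (glob$permF() >= glob$F) ge <- ge + 1L
  out <- list(F = glob$F, p = (1 + ge) / (nPerm + 1),
              nPerm = as.integer(nPerm))
  if (marginal && q > 1L) {
    terms <- data.frame(predictor = colnames(X), F = NA_real_, p = NA_real_)
    for (j in seq_len(q)) {
      Zj <- cbind(Z, X[, -j, drop = FALSE])
      mj <- one(X[, j, drop = FALSE], Zj, Yc)
      gej <- 0L
      for (b in seq_len(nPerm)) if (mj$permF() >= mj$F) gej <- gej + 1L
      terms$F[j] <- mj$F
      terms$p[j] <- (1 + gej) / (nPerm + 1)
    }
    out$terms <- terms
  }
  out
}
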