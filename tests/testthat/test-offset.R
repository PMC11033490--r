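test_that("Mahalanobis distances and chi-squared tails are computed exactly", {
  set.seed(1)
  S <- matrix(rnorm(400), 200, 2)
  out <- mahalanobisOutliers(S, K = 2)
  # direct evaluation with the same empirical moments
  D2 <- stats::mahalanobis(S, colMeans(S), cov(S))
  expect_equal(out$D2, D2, tolerance = 1e-12)
  # chi-squared with 2 df: survival is exp(-x/2); D2 = 2 gives p = 1/e
  expect_equal(out$p, exp(-out$D2 / 2), tolerance = 1e-12)
  # appending the centroid leaves the mean unchanged, so that locus sits
  # at distance zero with p = 1
  out3 <- mahalanobisOutliers(rbind(S, colMeans(S)), K = 2)
  expect_equal(out3$D2[nrow(S) + 1], 0, tolerance = 1e-10)
  expect_equal(out3$p[nrow(S) + 1], 1)
})

test_that("singular score clouds are rejected with advice", {
  S <- cbind(1:50, 2 * (1:50))
  expect_error(mahalanobisOutliers(S, K = 2), "singular")
})

test_that("BH step-up reproduces the hand-computed example", {
  expect_equal(bhFdr(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04))
  expect_equal(bhFdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  p <- runif(100)
  q <- bhFdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in sorted p
  expect_true(all(q >= p - 1e-12))
  expect_error(bhFdr(c(0.5, 0)), "p-values")
  expect_error(bhFdr(c(0.5, 1.2)), "p-values")
})

test_that("the adaptive index is the loading-weighted standardized field", {
  load <- matrix(c(0.5, -0.5), 2, 1,
                 dimnames = list(c("t", "s"), "RDA1"))
  fit <- fakeRdaFit(load, eig = 1, center = c(t = 10, s = 30),
                    scale = c(t = 2, s = 1))
  rasters <- list(t = flatGrid(14), s = flatGrid(31))   # z = (2, 1)
  ai <- adaptiveIndex(fit, rasters, axes = 1)
  expect_equal(gridValues(ai@grids[[1]]),
               matrix(0.5 * 2 - 0.5 * 1, 4, 4))
  # homogeneity: doubling every standardized value doubles the index
  rasters2 <- list(t = flatGrid(18), s = flatGrid(32))  # z = (4, 2)
  ai2 <- adaptiveIndex(fit, rasters2, axes = 1)
  expect_equal(gridValues(ai2@grids[[1]]), 2 * gridValues(ai@grids[[1]]))
  # zero loadings give a flat zero index
  fit0 <- fakeRdaFit(load * 0, eig = 1, center = c(t = 10, s = 30),
                     scale = c(t = 2, s = 1))
  expect_equal(gridValues(adaptiveIndex(fit0, rasters, axes = 1)@grids[[1]]),
               matrix(0, 4, 4))
})

test_that("nodata propagates and misaligned inputs are errors", {
  load <- matrix(c(1, 1), 2, 1, dimnames = list(c("t", "s"), NULL))
  fit <- fakeRdaFit(load, eig = 1, center = c(t = 0, s = 0),
                    scale = c(t = 1, s = 1))
  gt <- flatGrid(1); gs <- flatGrid(2)
  gt@grid[2, 2] <- NA
  ai <- adaptiveIndex(fit, list(t = gt, s = gs), axes = 1)
  expect_true(is.na(gridValues(ai@grids[[1]])[2, 2]))
  expect_false(anyNA(gridValues(ai@grids[[1]])[-6]))
  expect_error(adaptiveIndex(fit, list(t = gt), axes = 1), "missing")
  gsBad <- flatGrid(2, nr = 5)
  expect_error(adaptiveIndex(fit, list(t = gt, s = gsBad), "aligned"))
})

test_that("genomic offset: identity, |delta|, and the combination rules", {
  mk <- function(vals, eig) new("AdaptiveIndex",
    grids = lapply(vals, flatGrid), eig = eig, scenario = "x")
  cur <- mk(list(0.5, 0.1), c(1, 1))
  futSame <- mk(list(0.5, 0.1), c(1, 1))
  off0 <- genomicOffset(cur, futSame)
  expect_true(all(gridValues(off0@combined) == 0))

  fut <- mk(list(-0.3, 0.5), c(1, 1))
  off <- genomicOffset(cur, fut)
  expect_equal(gridValues(off@perAxis[[1]])[1, 1], 0.8)
  expect_equal(gridValues(off@perAxis[[2]])[1, 1], 0.4)
  # equal eigenvalues: weights 0.5 each
  expect_equal(gridValues(off@combined)[1, 1],
               sqrt(0.5 * 0.8^2 + 0.5 * 0.4^2))
  # the worked 0.3/0.4 example
  off2 <- genomicOffset(mk(list(0, 0), c(1, 1)), mk(list(0.3, 0.4), c(1, 1)))
  expect_equal(gridValues(off2@combined)[1, 1], sqrt(0.5 * 0.09 + 0.5 * 0.16),
               tolerance = 1e-12)
  expect_equal(gridValues(genomicOffset(cur, fut, rule = "max")@combined)[1, 1],
               0.8)
  expect_equal(gridValues(genomicOffset(cur, fut, rule = "sum")@combined)[1, 1],
               1.2)
})

test_that("offset grows monotonically with a single-predictor perturbation", {
  load <- matrix(c(0.7, -0.2), 2, 1, dimnames = list(c("t", "s"), NULL))
  fit <- fakeRdaFit(load, eig = 1, center = c(t = 8, s = 30),
                    scale = c(t = 2, s = 1))
  cur <- adaptiveIndex(fit, list(t = flatGrid(8), s = flatGrid(30)), axes = 1)
  offs <- vapply(c(0, 0.5, 1, 2, 4), function(dt) {
    fut <- adaptiveIndex(fit, list(t = flatGrid(8 + dt), s = flatGrid(30)),
                         axes = 1, scenario = "future")
    gridValues(genomicOffset(cur, fut)@combined)[1, 1]
  }, numeric(1))
  expect_equal(offs[1], 0)
  expect_true(all(diff(offs) > 0))
})

test_that("masking turns blocked pixels to nodata, after combination", {
  mk <- function(vals) new("AdaptiveIndex", grids = lapply(vals, flatGrid),
                           eig = 1, scenario = "x")
  mask <- flatGrid(1)
  mask@grid[1, 1] <- 0; mask@grid[2, 2] <- NA
  off <- genomicOffset(mk(list(0)), mk(list(0.5)), mask = mask)
  cg <- gridValues(off@combined)
  expect_true(is.na(cg[1, 1]) && is.na(cg[2, 2]))
  expect_equal(cg[3, 3], 0.5)
})

test_that("planted environmental loci are recovered with controlled FDR", {
  cfg <- simConfig(nPops = 21, nLoci = 5050, nOutlierLoci = 50, beta = 1.5,
                   seed = 1)
  st <- simulatePoolseqStudy(cfg)
  fr <- poolFrequencies(st$counts, filterConfig())
  fit <- fitRda(fr, prunePredictors(st$env), scaling = "binomial")
  out <- mahalanobisOutliers(fit, K = 2)
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(fr))
  planted <- (pos / 100) %in% st$truth$outlierIds
  power <- sum(out$outlier & planted) /
    sum(st$truth$outlierIds %in% (pos / 100))
  fdr <- sum(out$outlier & !planted) / max(sum(out$outlier), 1)
  expect_gte(power, 0.8)
  expect_lte(fdr, 0.15)
})

test_that("outlier p-values are uniform when no locus tracks the environment", {
  cfg <- simConfig(nPops = 21, nLoci = 5000, nOutlierLoci = 0, beta = 0,
                   seed = 2)
  st <- simulatePoolseqStudy(cfg)
  fr <- poolFrequencies(st$counts, filterConfig())
  fit <- fitRda(fr, prunePredictors(st$env), scaling = "binomial")
  out <- mahalanobisOutliers(fit, K = 2)
  expect_gt(ks.test(out$p, "punif")$p.value, 0.01)
})

test_that("largest simulated climate deltas produce the largest offsets", {
  cfg <- simConfig(nPops = 21, nLoci = 3050, nOutlierLoci = 50, beta = 1.5,
                   seed = 3)
  st <- simulatePoolseqStudy(cfg)
  fr <- poolFrequencies(st$counts, filterConfig())
  ps <- prunePredictors(st$env)
  fit <- fitRda(fr, ps, scaling = "binomial")
  out <- mahalanobisOutliers(fit, K = 2)
  sel <- which(out$outlier)
  fitOut <- fitRda(freqMatrix(fr)[, sel, drop = FALSE], ps)
  k <- seq_len(min(2, length(eigenvalues(fitOut))))
  aiC <- adaptiveIndex(fitOut, st$rasters$current, axes = k)
  aiF <- adaptiveIndex(fitOut, st$rasters$future, axes = k,
                       scenario = "future")
  off <- gridValues(genomicOffset(aiC, aiF)@combined)
  # deltas grow toward the north (row 1); the southern edge has delta 0
  north <- mean(off[1, ]); south <- mean(off[nrow(off), ])
  expect_gt(north, south)
  expect_lt(south, 1e-10)
  expect_true(all(off[1, ] > off[nrow(off), ]))
})
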