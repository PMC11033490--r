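test_that("predictor pruning: duplicates, high correlation, VIF, zero variance", {
  set.seed(1)
  n <- 20
  a <- rnorm(n)
  env <- data.frame(a = a, b = a, c = rnorm(n))      # b duplicates a
  ps <- prunePredictors(env)
  expect_equal(colnames(ps@X), c("a", "c"))
  expect_match(ps@dropped, "b", all = FALSE)

  # r = 0.9 pair with rMax = 0.85: the later-listed member goes
  b2 <- 0.9 * scale(a)[, 1] + sqrt(1 - 0.81) * scale(rnorm(n))[, 1]
  env2 <- data.frame(a = scale(a)[, 1], b = b2)
  expect_gte(abs(cor(env2$a, env2$b)), 0.85)
  ps2 <- prunePredictors(env2, rMax = 0.85)
  expect_equal(colnames(ps2@X), "a")

  # orthogonal predictors all survive with VIF 1
  q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  ps3 <- prunePredictors(data.frame(x = q[, 1], y = q[, 2], z = q[, 3]))
  expect_equal(ncol(ps3@X), 3L)

  expect_warning(prunePredictors(data.frame(a = a, k = rep(2, n))),
                 "zero-variance")
})

test_that("standardization is recorded and applied", {
  env <- data.frame(t = c(2, 4, 6, 8), s = c(30, 31, 29, 30))
  ps <- prunePredictors(env)
  expect_equal(unname(colMeans(ps@X)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(ps@X, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(ps@center[["t"]], 5)
  expect_equal(ps@scale[["t"]], sd(c(2, 4, 6, 8)))
})

test_that("one predictor, one locus: R2 equals the squared correlation", {
  set.seed(2)
  y <- matrix(rnorm(9), 9, 1)
  x <- matrix(rnorm(9), 9, 1)
  fit <- fitRda(y, x)
  expect_equal(fit@r2, cor(y, x)[1]^2, tolerance = 1e-10)
})

test_that("exact and orthogonal responses hit the R2 boundaries", {
  set.seed(3)
  n <- 10
  X <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(2 * 5), 2, 5)
  fitExact <- fitRda(scale(X, scale = FALSE) %*% B, X)
  expect_equal(unname(varianceProportions(fitExact)[["constrained"]]), 1,
               tolerance = 1e-10)
  expect_equal(unname(varianceProportions(fitExact)[["unconstrained"]]), 0,
               tolerance = 1e-10)
  # build Y orthogonal to [1, X]
  Q <- qr.Q(qr(cbind(1, X)))
  Y0 <- matrix(rnorm(n * 4), n, 4)
  Yorth <- Y0 - Q %*% crossprod(Q, Y0)
  fit0 <- fitRda(Yorth, X)
  expect_lt(max(eigenvalues(fit0)), 1e-10)
  expect_lt(fit0@r2, 1e-10)
})

test_that("fitRda matches an independent regression+eigen oracle", {
  set.seed(4)
  n <- 8; L <- 40
  Y <- matrix(runif(n * L), n, L)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fitRda(Y, X)
  # oracle: per-locus lm() fits, then eigen of the fitted crossproduct
  Xs <- scale(X)
  Yc <- scale(Y, scale = FALSE)
  Yhat <- sapply(seq_len(L), function(l) fitted(lm(Yc[, l] ~ Xs)))
  ev <- eigen(tcrossprod(Yhat), symmetric = TRUE)
  k <- length(eigenvalues(fit))
  expect_equal(eigenvalues(fit), ev$values[1:k] / (n - 1), tolerance = 1e-8)
  expect_equal(abs(siteScores(fit)), abs(ev$vectors[, 1:k]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # right singular vectors scaled by singular values equal Yhat' U
  lsOracle <- crossprod(Yhat, ev$vectors[, 1:k])
  expect_equal(abs(locusScores(fit)), abs(lsOracle),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit@r2, sum(Yhat^2) / sum(Yc^2), tolerance = 1e-10)
})

test_that("fitRda agrees with vegan on eigenvalues, R2 and partitioning", {
  set.seed(5)
  n <- 9; L <- 30
  Y <- matrix(runif(n * L), n, L)
  env <- data.frame(e1 = rnorm(n), e2 = rnorm(n), lat = rnorm(n))
  fit <- fitRda(Y, prunePredictors(env[, 1:2],
                                   conditioning = env[, 3, drop = FALSE]))
  vr <- vegan::rda(Y ~ e1 + e2 + Condition(lat),
                   data = cbind(as.data.frame(scale(env[, 1:2])),
                                env[, 3, drop = FALSE]))
  expect_equal(unname(eigenvalues(fit)), unname(vr$CCA$eig), tolerance = 1e-8)
  pr <- varianceProportions(fit)
  expect_equal(unname(pr[["conditioned"]]), vr$pCCA$tot.chi / vr$tot.chi,
               tolerance = 1e-8)
  expect_equal(unname(pr[["constrained"]]), vr$CCA$tot.chi / vr$tot.chi,
               tolerance = 1e-8)
})

test_that("variance partition sums to one and site scores are orthogonal", {
  set.seed(6)
  for (q0 in 0:1) {
    n <- 12
    Y <- matrix(runif(n * 25), n, 25)
    X <- matrix(rnorm(n * 3), n, 3)
    Z <- if (q0) matrix(rnorm(n), n, 1) else NULL
    ps <- prunePredictors(as.data.frame(X), conditioning = Z)
    fit <- fitRda(Y, ps)
    expect_equal(sum(varianceProportions(fit)), 1, tolerance = 1e-8)
    g <- crossprod(siteScores(fit))
    expect_equal(g, diag(diag(g)), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("rank-deficient or oversized predictor sets are errors", {
  set.seed(7)
  Y <- matrix(runif(5 * 10), 5, 10)
  Xbig <- matrix(rnorm(5 * 5), 5, 5)
  expect_error(fitRda(Y, Xbig), "predictors")
})

test_that("the permutation F matches a sums-of-squares oracle", {
  set.seed(8)
  n <- 6; L <- 10; q <- 2
  Y <- matrix(runif(n * L), n, L)
  X <- matrix(rnorm(n * q), n, q)
  pt <- rdaPermutationTest(Y, X, nPerm = 9, marginal = FALSE)
  # oracle: explicit hat matrix on the centered data
  Yc <- scale(Y, scale = FALSE); Xs <- scale(X)
  H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
  ssC <- sum((H %*% Yc)^2); ssR <- sum(Yc^2) - ssC
  Foracle <- (ssC / q) / (ssR / (n - q - 1))
  expect_equal(pt$F, Foracle, tolerance = 1e-10)
})

test_that("a perfectly explained response reaches the minimal p", {
  set.seed(9)
  n <- 10
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- scale(X, scale = FALSE) %*% matrix(rnorm(2 * 6), 2, 6)
  pt <- rdaPermutationTest(Y, X, nPerm = 999, seed = 1, marginal = FALSE)
  expect_equal(pt$p, 1 / 1000)
})

test_that("permutation p-values are reproducible under a seed", {
  set.seed(10)
  Y <- matrix(runif(8 * 12), 8, 12)
  X <- matrix(rnorm(8 * 2), 8, 2)
  a <- rdaPermutationTest(Y, X, nPerm = 49, seed = 5)
  b <- rdaPermutationTest(Y, X, nPerm = 49, seed = 5)
  expect_identical(a, b)
})

test_that("marginal term tests single out the informative predictor", {
  set.seed(11)
  n <- 16
  x1 <- rnorm(n); x2 <- rnorm(n)
  Y <- outer(x1, rnorm(12)) + matrix(rnorm(n * 12, sd = 0.2), n, 12)
  pt <- rdaPermutationTest(Y, cbind(x1 = x1, x2 = x2), nPerm = 199, seed = 2)
  expect_lt(pt$terms$p[pt$terms$predictor == "x1"], 0.05)
  expect_gt(pt$terms$p[pt$terms$predictor == "x2"], 0.05)
})

test_that("Ezekiel adjustment: boundary and worked values", {
  expect_equal(adjustedR2(1, 21, 4), 1)
  expect_equal(adjustedR2(0.5, 21, 4), 0.375)
  expect_lte(adjustedR2(0, 15, 3), 0)
  expect_error(adjustedR2(0.5, 5, 4), "nSites")
})
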