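# Small builders shared across test files. Everything is generated in code;
# no fixture touches disk except through tempfile().

tinyPoolMeta <- function(n = 2L, size = 30L) {
  data.frame(name = sprintf("p%d", seq_len(n)),
             n_individuals = rep_len(size, n),
             latitude = seq(44, 44 + 0.5 * (n - 1), by = 0.5)[seq_len(n)],
             longitude = rep(-64, n))
}

writeSyncLines <- function(lines) {
  path <- tempfile(fileext = ".sync")
  writeLines(lines, path)
  path
}

# all permutations of a small vector (for exhaustive Mantel enumeration)
allPerms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in allPerms(v[-i])) out <- c(out, list(c(v[i], rest)))
  out
}

# minimal RdaFit with chosen loadings/eigenvalues/standardization, for
# exercising the adaptive-index arithmetic in isolation
fakeRdaFit <- function(loadings, eig, center, scale) {
  nSites <- 5L
  ps <- new("PredictorSet",
            X = matrix(0, nSites, nrow(loadings),
                       dimnames = list(NULL, rownames(loadings))),
            center = center, scale = scale,
            conditioning = matrix(numeric(0), nSites, 0),
            dropped = character(0))
  new("RdaFit", eig = eig,
      siteScores = matrix(0, nSites, ncol(loadings)),
      locusScores = matrix(0, 10, ncol(loadings)),
      predictorLoadings = loadings,
      r2 = 0.5, r2adj = 0.4,
      proportions = c(conditioned = 0, constrained = 0.5,
                      unconstrained = 0.5),
      n = nSites, q = nrow(loadings), q0 = 0L, totalSS = 1,
      predictors = ps)
}

flatGrid <- function(value, nr = 4L, nc = 4L, xll = -65, yll = 44,
                     cellsize = 0.5) {
  EnvGrid(matrix(value, nr, nc), xll, yll, cellsize)
}
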