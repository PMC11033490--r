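#' Configuration for the synthetic pool-seq generator
#'
#' The defaults emulate the study design the package targets: about twenty
#' pools of 30-54 diploids sampled along a coastal latitudinal gradient,
#' sequenced to 50-100x, with a small minority of loci whose frequencies
#' track an environmental gradient.
#'
#' @param nPops number of pools
#' @param nLoci number of biallelic loci
#' @param drift per-pool Balding-Nichols differentiation parameter c in
#'   (0, 1); equals the expected F_ST of that pool against the ancestral
#'   frequency. Recycled to `nPops`.
#' @param nOutlierLoci number of environment-associated loci
#' @param beta effect size on the logit of the allele frequency per unit of
#'   standardized environment
#' @param envGradient per-pool standardized environmental values z; `NULL`
#'   defers to the site values extracted from the simulated rasters (or, when
#'   simulating without rasters, to standardized latitude)
#' @param poolSizes diploid individuals per pool, recycled
#' @param depthMean expected read depth per site per pool (Poisson)
#' @param seqError per-read error rate toward the other allele, in [0, 0.01]
#' @param latitude,longitude pool coordinates; defaults place the pools on a
#'   south-to-north transect
#' @param seed integer seed fixing all randomness end-to-end
#' @return a `sim_config` list
#' @export
simConfig <- function(nPops = 21L, nLoci = 10000L, drift = 0.05,
                      nOutlierLoci = 50L, beta = 1.5, envGradient = NULL,
                      poolSizes = 40L, depthMean = 60, seqError = 0.001,
                      latitude = NULL, longitude = NULL, seed = 1L) {
  nPops <- as.integer(nPops); nLoci <- as.integer(nLoci)
  if (nPops < 1L || nLoci < 0L) stop("nPops >= 1 and nLoci >= 0 required")
  drift <- rep_len(drift, nPops)
  if (any(drift <= 0 | drift >= 1)) stop("drift values must lie in (0, 1)")
  if (nOutlierLoci > nLoci) stop("nOutlierLoci must be <= nLoci")
  if (seqError < 0 || seqError > 0.01) stop("seqError must lie in [0, 0.01]")
  poolSizes <- rep_len(as.integer(poolSizes), nPops)
  if (any(poolSizes < 1L)) stop("poolSizes must be positive")
  if (is.null(latitude)) latitude <- seq(42, 55, length.out = nPops)
  if (is.null(longitude)) longitude <- rep(-64.5, nPops)
  if (!is.null(envGradient)) envGradient <- rep_len(envGradient, nPops)
  structure(list(
    nPops = nPops, nLoci = nLoci, drift = drift,
    nOutlierLoci = as.integer(nOutlierLoci), beta = beta,
    envGradient = envGradient, poolSizes = poolSizes,
    depthMean = depthMean, seqError = seqError,
    latitude = rep_len(latitude, nPops), longitude = rep_len(longitude, nPops),
    seed = as.integer(seed)), class = "sim_config")
}

simPoolMeta <- function(config) {
  data.frame(name = sprintf("pool%02d", seq_len(config$nPops)),
             n_individuals = config$poolSizes,
             latitude = config$latitude, longitude = config$longitude)
}

resolvedGradient <- function(config) {
  z <- config$envGradient
  if (is.null(z)) z <- as.numeric(scale(config$latitude))
  z
}

#' Simulate population allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each pool draws its
#' frequency from Beta(p0(1-c)/c, (1-p0)(1-c)/c), so the expected F_ST
#' between two pools with common drift c is c. Environment-associated
#' ("outlier") loci additionally shift logit(p) by `beta * z_pop`, clipped to
#' [0.001, 0.999] to avoid fixation.
#'
#' @param config a [simConfig()] list
#' @return a `sim_truth` list: `trueFreqs` (pools x loci), `outlierIds`,
#'   `ancestralFreqs`, `env` (per-pool standardized gradient), `poolMeta`
#' @export
simulatePopulationFrequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$nLoci; P <- config$nPops
  p0 <- stats::runif(L, 0.05, 0.95)
  freqs <- matrix(NA_real_, P, L)
  for (i in seq_len(P)) {
    c_i <- config$drift[i]
    freqs[i, ] <- stats::rbeta(L, p0 * (1 - c_i) / c_i,
                               (1 - p0) * (1 - c_i) / c_i)
  }
  outlierIds <- integer(0)
  z <- resolvedGradient(config)
  if (config$nOutlierLoci > 0L) {
    outlierIds <- sort(sample.int(L, config$nOutlierLoci))
    p <- pmin(pmax(freqs[, outlierIds, drop = FALSE], 1e-9), 1 - 1e-9)
    shifted <- stats::plogis(stats::qlogis(p) + config$beta * z)
    freqs[, outlierIds] <- pmin(pmax(shifted, 0.001), 0.999)
  }
  meta <- simPoolMeta(config)
  structure(list(trueFreqs = freqs, outlierIds = outlierIds,
                 ancestralFreqs = p0, env = z, poolMeta = meta),
            class = "sim_truth")
}

#' Simulate pooled read counts from true population frequencies
#'
#' Two-stage sampling per pool and locus: the pool's 2n chromosomes carry
#' `k ~ Binomial(2n, p)` copies of the alternate allele; read depth is
#' `C ~ Poisson(depthMean)`; alternate reads are
#' `Binomial(C, (k/2n)(1-e) + (1-k/2n)e)` with sequencing error `e`, the
#' remainder going to the reference base. Reference base is fixed to A and
#' the alternate to T for every simulated locus (the simplest valid sync);
#' downstream code must not rely on base identity.
#'
#' @param truth a `sim_truth` from [simulatePopulationFrequencies()]
#' @param config the same [simConfig()]
#' @return a [PoolCounts-class]
#' @export
simulatePoolCounts <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  L <- config$nLoci; P <- config$nPops
  A <- Tm <- matrix(0L, L, P)
  for (i in seq_len(P)) {
    nChrom <- 2L * config$poolSizes[i]
    k <- stats::rbinom(L, nChrom, truth$trueFreqs[i, ])
    C <- stats::rpois(L, config$depthMean)
    pAlt <- (k / nChrom) * (1 - config$seqError) +
      (1 - k / nChrom) * config$seqError
    alt <- stats::rbinom(L, C, pAlt)
    Tm[, i] <- alt
    A[, i] <- C - alt
  }
  zero <- matrix(0L, L, P)
  PoolCounts(list(A = A, T = Tm, C = zero, G = zero, N = zero, del = zero),
             loci = data.frame(chrom = "chr1", pos = 100L * seq_len(max(L, 0L)),
                               ref = "A")[seq_len(L), , drop = FALSE],
             poolMeta = truth$poolMeta)
}

#' Default raster specification for the synthetic study region
#'
#' A 1/2-degree grid spanning the simulated transect, with a warm/salty south
#' to cold/fresh north gradient in two variables and future deltas that grow
#' toward the north (mimicking stronger projected warming at high latitude;
#' the southern edge is left unchanged).
#'
#' @param config a [simConfig()]
#' @return a `grid_spec` list
#' @export
defaultGridSpec <- function(config) {
  list(nrows = 32L, ncols = 10L,
       xll = floor(min(config$longitude)) - 2, yll = floor(min(config$latitude)) - 1,
       cellsize = 0.5,
       variables = list(
         temperature = list(south = 18, north = 1, noiseSd = 0.2,
                            deltaSouth = 0, deltaNorth = 3.5),
         salinity = list(south = 31, north = 15, noiseSd = 0.2,
                         sinAmp = 4, sinCycles = 2.5,
                         deltaSouth = 0, deltaNorth = -2)))
}

#' Simulate current and future environmental rasters plus site values
#'
#' Current rasters are linear latitudinal gradients (value interpolated
#' between the `south` and `north` endpoints at the row centers) plus an
#' optional sinusoidal along-coast component (`sinAmp`, `sinCycles`; used
#' so that different variables are not collinear across sites, as bay-scale
#' salinity varies on top of the broad thermal gradient) and optional iid
#' noise; the future raster adds a deterministic delta field,
#' itself linear in latitude between `deltaSouth` and `deltaNorth`. Site
#' values are nearest-cell extractions at the pool coordinates.
#'
#' @param config a [simConfig()]
#' @param gridSpec a raster specification, see [defaultGridSpec()]
#' @return list with `current` and `future` (named lists of
#'   [EnvGrid-class]), `delta` (named list of delta fields), and `sites`
#'   (data.frame of current site values, pools as rows)
#' @export
simulateEnvRasters <- function(config, gridSpec = defaultGridSpec(config)) {
  set.seed(config$seed + 2L)
  nr <- gridSpec$nrows; nc <- gridSpec$ncols
  latC <- gridSpec$yll + (nr - seq_len(nr) + 0.5) * gridSpec$cellsize
  south <- min(latC); north <- max(latC)
  frac <- if (north > south) (latC - south) / (north - south) else rep(0, nr)
  current <- future <- delta <- list()
  for (v in names(gridSpec$variables)) {
    sp <- gridSpec$variables[[v]]
    base <- sp$south + (sp$north - sp$south) * frac
    if (isTRUE(sp$sinAmp > 0))   # along-coast variation (estuaries, bays)
      base <- base + sp$sinAmp * sin(2 * pi * sp$sinCycles * frac)
    noise <- if (isTRUE(sp$noiseSd > 0))
      matrix(stats::rnorm(nr * nc, 0, sp$noiseSd), nr, nc) else 0
    cur <- matrix(base, nr, nc) + noise
    dS <- if (is.null(sp$deltaSouth)) 0 else sp$deltaSouth
    dN <- if (is.null(sp$deltaNorth)) 0 else sp$deltaNorth
    d <- matrix(dS + (dN - dS) * frac, nr, nc)
    current[[v]] <- EnvGrid(cur, gridSpec$xll, gridSpec$yll, gridSpec$cellsize)
    future[[v]] <- EnvGrid(cur + d, gridSpec$xll, gridSpec$yll,
                           gridSpec$cellsize)
    delta[[v]] <- d
  }
  sites <- as.data.frame(lapply(current, extractSiteValues,
                                latitude = config$latitude,
                                longitude = config$longitude))
  rownames(sites) <- simPoolMeta(config)$name
  list(current = current, future = future, delta = delta, sites = sites)
}

#' Simulate per-site derived-allele counts with a chosen frequency spectrum
#'
#' `equilibrium` draws derived counts i in 1..nChrom-1 with probability
#' proportional to 1/i (the neutral constant-size expectation); `expansion`
#' uses 1/i^2, a singleton-skewed spectrum typical of growing populations.
#'
#' @param nChrom number of sampled chromosomes (>= 4)
#' @param nSites number of segregating sites to draw
#' @param shape `"equilibrium"` or `"expansion"`
#' @param seed integer seed
#' @return integer vector of derived-allele counts, length `nSites`
#' @export
simulateSfsWindow <- function(nChrom, nSites,
                              shape = c("equilibrium", "expansion"),
                              seed = 1L) {
  shape <- match.arg(shape)
  if (nChrom < 4L) stop("nChrom must be >= 4")
  set.seed(as.integer(seed))
  i <- seq_len(nChrom - 1L)
  prob <- switch(shape, equilibrium = 1 / i, expansion = 1 / i^2)
  sample(i, nSites, replace = TRUE, prob = prob)
}

#' Simulate a full synthetic pool-seq study
#'
#' Wires the pieces together in the order the truth flows: environmental
#' rasters and site values first, then (unless the user fixed one) the
#' standardized site values of the first variable become the environmental
#' gradient that shapes the outlier loci, then population frequencies, then
#' pooled read counts.
#'
#' @param config a [simConfig()]
#' @param gridSpec raster spec, see [defaultGridSpec()]
#' @return list: `counts` ([PoolCounts-class]), `truth`, `env` (site x
#'   variable data.frame), `rasters` (output of [simulateEnvRasters()]),
#'   `poolMeta`
#' @export
simulatePoolseqStudy <- function(config, gridSpec = defaultGridSpec(config)) {
  rasters <- simulateEnvRasters(config, gridSpec)
  if (is.null(config$envGradient)) {
    v1 <- rasters$sites[[1]]
    config$envGradient <- as.numeric(scale(v1))
  }
  truth <- simulatePopulationFrequencies(config)
  counts <- simulatePoolCounts(truth, config)
  list(counts = counts, truth = truth, env = rasters$sites,
       rasters = rasters, poolMeta = truth$poolMeta)
}
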