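#' Assemble (or read) a pipeline configuration
#'
#' Either pass a YAML file path or a nested list. Missing sections fall
#' back to defaults. Sections: `seed`, `out`, `simulate` (arguments of
#' [simConfig()]), `filter` ([filterConfig()]), `stats`
#' (`windowSize`, `mantelPermutations`), `rda` (`nPerm`, `rMax`, `vifMax`,
#' `condition`: "none" or "geo"), `offset` (`K`, `fdr`, `combine`, `mask`
#' path or NULL).
#'
#' @param config YAML path or list; NULL for all defaults
#' @param seed optional override of the global seed
#' @param out optional override of the output directory
#' @return validated config list
#' @export
pipelineConfig <- function(config = NULL, seed = NULL, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a YAML path or a list")
  def <- list(
    seed = 1L, out = "poolscape_out",
    simulate = list(),
    filter = list(),
    stats = list(windowSize = 10000L, mantelPermutations = 199L),
    rda = list(nPerm = 199L, rMax = 0.85, vifMax = 10, condition = "none"),
    offset = list(K = 2L, fdr = 0.05, combine = "eigen-euclidean",
                  mask = NULL))
  known <- names(def)
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  for (sec in c("stats", "rda", "offset")) {
    extra <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(extra))
      stop(sprintf("unknown key(s) in '%s': %s", sec,
                   paste(extra, collapse = ", ")))
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out)) cfg$out <- out
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.wtsv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  path
}

.wmat <- function(m, path, rowLabel = "pool") {
  dt <- data.table::as.data.table(as.data.frame(m), keep.rownames = rowLabel)
  data.table::fwrite(dt, path, sep = ",")
  path
}

.need <- function(files, stage, neededBy) {
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop(sprintf("stage '%s' needs outputs of stage '%s'; run it first (missing: %s)",
                 neededBy, stage, paste(basename(missing), collapse = ", ")))
}

#' Run the pool-seq analysis pipeline end to end
#'
#' Stages communicate through files in the output directory, so any suffix
#' of the stage list can be re-run later against an existing directory.
#' Requesting a stage whose upstream artifacts are absent is an error that
#' names the stage to run first. Re-running with an identical configuration
#' and seed reproduces byte-identical outputs.
#'
#' @param config a [pipelineConfig()] (list or YAML path)
#' @param stages subset of `c("simulate", "stats", "structure", "rda",
#'   "offset")`, in canonical order
#' @param seed,out optional overrides, see [pipelineConfig()]
#' @param verbose log stage progress to stderr
#' @return invisibly, the manifest (also written to `manifest.json`): files
#'   written per stage, the configuration, and the seed
#' @export
runPipeline <- function(config = NULL,
                        stages = c("simulate", "stats", "structure", "rda",
                                   "offset"),
                        seed = NULL, out = NULL, verbose = FALSE) {
  cfg <- pipelineConfig(config, seed = seed, out = out)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  P <- function(...) file.path(cfg$out, ...)
  say <- function(fmt, ...) if (verbose)
    message(sprintf(paste0("[poolscape] ", fmt), ...))
  # the output path is where the manifest lives, not part of the analysis:
  # keeping it out makes runs into different directories byte-comparable
  manifest <- list(seed = cfg$seed, config = cfg[names(cfg) != "out"],
                   files = list())
  simCfg <- do.call(simConfig, c(cfg$simulate, list(seed = cfg$seed)))
  fCfg <- do.call(filterConfig, cfg$filter)

  loadCounts <- function(neededBy) {
    .need(P(c("sim.sync", "pools.csv")), "simulate", neededBy)
    readSync(P("sim.sync"),
             as.data.frame(data.table::fread(P("pools.csv"))))
  }
  loadEnv <- function(neededBy) {
    .need(P("env_sites.csv"), "simulate", neededBy)
    readStudyTables(P("pools.csv"), P("env_sites.csv"))$env
  }

  if ("simulate" %in% stages) {
    say("simulate: %d pools x %d loci (seed %d)", simCfg$nPops, simCfg$nLoci,
        cfg$seed)
    study <- simulatePoolseqStudy(simCfg)
    files <- c(
      writeSync(study$counts, P("sim.sync")),
      .wtsv(study$poolMeta, P("pools.csv")),
      .wtsv(cbind(site = rownames(study$env), study$env),
            P("env_sites.csv")))
    for (v in names(study$rasters$current)) {
      files <- c(files,
                 writeAsciiGrid(study$rasters$current[[v]],
                                P(sprintf("current_%s.asc", v))),
                 writeAsciiGrid(study$rasters$future[[v]],
                                P(sprintf("future_%s.asc", v))))
    }
    truth <- list(outlier_ids = study$truth$outlierIds,
                  ancestral_freqs = round(study$truth$ancestralFreqs, 6),
                  env_gradient = round(study$truth$env, 6))
    jsonlite::write_json(truth, P("truth.json"), auto_unbox = FALSE,
                         digits = NA)
    manifest$files$simulate <- basename(c(files, P("truth.json")))
  }

  if ("stats" %in% stages) {
    counts <- loadCounts("stats")
    say("stats: filtering %d loci", nrow(counts))
    freqs <- poolFrequencies(counts, fCfg)
    piTabs <- lapply(colnames(counts), function(pl) {
      cbind(pool = pl, windowPi(counts, pl, cfg$stats$windowSize,
                                filterConfig(minCount = 2L,
                                             minCov = fCfg$minCov,
                                             maxCov = fCfg$maxCov)))
    })
    anova <- pairwiseFstAnova(counts, freqs = freqs)
    dGeo <- geoDistances(counts)
    mant <- mantelTest(slatkinLinearize(pmax(anova$fst, 0)), dGeo,
                       nPerm = cfg$stats$mantelPermutations,
                       seed = cfg$seed + 3L)
    files <- c(
      .wtsv(do.call(rbind, piTabs), P("pi_windows.tsv")),
      .wmat(anova$fst, P("fst_pairwise.csv")),
      .wmat(slatkinLinearize(pmax(anova$fst, 0)), P("fst_slatkin.csv")),
      .wmat(dGeo, P("geo_distances.csv"), rowLabel = "site"),
      .wtsv(data.frame(metric = "euclidean", mantel_r = mant$r,
                       p = mant$p, n_perm = mant$nPerm),
            P("mantel_ibd.tsv")))
    manifest$files$stats <- basename(files)
  }

  if ("structure" %in% stages) {
    counts <- loadCounts("structure")
    freqs <- poolFrequencies(counts, fCfg)
    say("structure: PCA + covariance tree on %d loci", nrow(freqs))
    pca <- pcaFrequencies(freqs)
    tree <- popCovarianceTree(freqs)
    files <- c(
      .wmat(pca@scores, P("pca_scores.tsv")),
      .wtsv(data.frame(axis = seq_along(pca@varExplained),
                       var_explained = pca@varExplained),
            P("pca_scree.tsv")),
      .wmat(tree@correlation, P("pop_correlation.csv")))
    writeLines(popTreeNewick(tree), P("pop_tree.nwk"))
    manifest$files$structure <- basename(c(files, P("pop_tree.nwk")))
  }

  if ("rda" %in% stages) {
    counts <- loadCounts("rda")
    env <- loadEnv("rda")
    freqs <- poolFrequencies(counts, fCfg)
    say("rda: %d loci, predictors: %s", nrow(freqs),
        paste(names(env), collapse = ", "))
    cond <- switch(cfg$rda$condition,
      geo = data.frame(longitude = colData(counts)$longitude,
                       latitude = colData(counts)$latitude),
      pcs = pcaFrequencies(freqs)@scores[, 1:2, drop = FALSE],
      NULL)
    ps <- prunePredictors(env, rMax = cfg$rda$rMax, vifMax = cfg$rda$vifMax,
                          conditioning = cond)
    fit <- fitRda(freqs, ps)
    # variance-equalized fit whose locus scores feed the outlier test
    fitScaled <- fitRda(freqs, ps, scaling = "binomial")
    perm <- rdaPermutationTest(freqs, ps, nPerm = cfg$rda$nPerm,
                               seed = cfg$seed + 4L)
    files <- c(
      .wtsv(data.frame(
        statistic = c("R2", "R2_adj", "F", "p",
                      names(varianceProportions(fit)),
                      paste0("eig_", seq_along(eigenvalues(fit)))),
        value = c(fit@r2, fit@r2adj, perm$F, perm$p,
                  varianceProportions(fit), eigenvalues(fit))),
        P("rda_summary.tsv")),
      .wmat(siteScores(fit), P("rda_site_scores.tsv"), rowLabel = "site"),
      .wmat(locusScores(fit), P("rda_locus_scores.tsv"), rowLabel = "locus"),
      .wmat(locusScores(fitScaled), P("rda_locus_scores_scaled.tsv"),
            rowLabel = "locus"),
      .wmat(predictorLoadings(fit), P("rda_predictor_loadings.tsv"),
            rowLabel = "predictor"))
    if (!is.null(perm$terms))
      files <- c(files, .wtsv(perm$terms, P("rda_marginal_terms.tsv")))
    model <- list(predictors = colnames(ps@X),
                  center = as.list(ps@center), scale = as.list(ps@scale),
                  eig = eigenvalues(fit),
                  loadings = apply(predictorLoadings(fit), 2, as.list))
    jsonlite::write_json(model, P("rda_model.json"), auto_unbox = TRUE,
                         digits = 12)
    manifest$files$rda <- basename(c(files, P("rda_model.json")))
  }

  if ("offset" %in% stages) {
    .need(P(c("rda_locus_scores_scaled.tsv", "rda_model.json")), "rda",
          "offset")
    counts <- loadCounts("offset")
    env <- loadEnv("offset")
    freqs <- poolFrequencies(counts, fCfg)
    ls <- as.data.frame(data.table::fread(P("rda_locus_scores_scaled.tsv")))
    scores <- as.matrix(ls[, -1, drop = FALSE])
    K <- min(cfg$offset$K, ncol(scores))
    say("offset: Mahalanobis outliers on %d axes", K)
    outl <- mahalanobisOutliers(scores, K = K, fdr = cfg$offset$fdr)
    rr <- rowRanges(freqs)
    outTab <- cbind(chrom = as.character(seqnames(rr)), pos = start(rr),
                    outl)
    # refit the ordination on the outlier loci only, then map it
    envPs <- prunePredictors(env, rMax = cfg$rda$rMax,
                             vifMax = cfg$rda$vifMax)
    sel <- which(outl$outlier)
    if (length(sel) < 2L) {
      warning("fewer than 2 outlier loci; using all loci for the adaptive index")
      sel <- seq_len(nrow(freqs))
    }
    fitOut <- fitRda(freqMatrix(freqs)[, sel, drop = FALSE], envPs)
    vars <- rownames(predictorLoadings(fitOut))
    curFiles <- P(sprintf("current_%s.asc", vars))
    futFiles <- P(sprintf("future_%s.asc", vars))
    .need(c(curFiles, futFiles), "simulate", "offset")
    cur <- stats::setNames(lapply(curFiles, readAsciiGrid), vars)
    fut <- stats::setNames(lapply(futFiles, readAsciiGrid), vars)
    kAxes <- seq_len(min(K, length(eigenvalues(fitOut))))
    aiC <- adaptiveIndex(fitOut, cur, axes = kAxes, scenario = "current")
    aiF <- adaptiveIndex(fitOut, fut, axes = kAxes, scenario = "future")
    mask <- if (!is.null(cfg$offset$mask)) readAsciiGrid(cfg$offset$mask)
    off <- genomicOffset(aiC, aiF, mask = mask, rule = cfg$offset$combine)
    files <- .wtsv(outTab, P("outliers.tsv"))
    for (k in seq_along(aiC@grids)) {
      files <- c(files,
                 writeAsciiGrid(aiC@grids[[k]],
                                P(sprintf("ai_current_RDA%d.asc", k))),
                 writeAsciiGrid(aiF@grids[[k]],
                                P(sprintf("ai_future_RDA%d.asc", k))),
                 writeAsciiGrid(off@perAxis[[k]],
                                P(sprintf("offset_RDA%d.asc", k))))
    }
    files <- c(files, writeAsciiGrid(off@combined, P("offset_combined.asc")))
    manifest$files$offset <- basename(files)
  }

  jsonlite::write_json(manifest, P("manifest.json"), auto_unbox = TRUE,
                       digits = 12, null = "null")
  invisible(manifest)
}
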