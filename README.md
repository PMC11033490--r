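# poolscape

Pool-seq population genomics and climate genomic offset, end to end, in R.

Pooled whole-genome resequencing (pool-seq) sequences a pool of tens of
individuals per population and recovers population allele frequencies from
read counts — no individual genotypes, two layers of sampling noise (which
chromosomes entered the pool, which reads sampled them). poolscape is for
researchers running seascape/landscape-genomics studies on such data:
population structure and gene flow from a synchronized allele-count file,
genotype–environment association by constrained ordination, and maps of
how far allele frequencies would have to shift under projected climates.

## What it computes

* **I/O** — PoPoolation2-style sync files, pool/environment metadata
  tables, ESRI ASCII grid rasters; all containers are Bioconductor-style
  S4 (`PoolCounts` and `PoolFreqs` extend `RangedSummarizedExperiment`).
* **Filtering & frequencies** — biallelic SNP calling with per-pool
  coverage bounds, minor-allele count and MAF thresholds.
* **Differentiation** — per-SNP and sliding-window classic
  F<sub>ST</sub> = (Π<sub>T</sub> − Π<sub>W</sub>)/Π<sub>T</sub> with the
  C/(C−1) correction; a pairwise ANOVA estimator with variance components
  corrected for both pool-size (2n chromosomes) and read-depth sampling,
  combined across loci as a ratio of sums; Slatkin's F/(1−F).
* **Diversity** — windowed π with corrected heterozygosity
  h = C/(C−1)·2f(1−f), and Tajima's D from site-frequency spectra.
* **Isolation by distance** — Mantel tests against great-circle
  (haversine, R = 6371 km) or least-cost ocean distances (shortest paths
  over 8-connected sea cells of a mask raster).
* **Structure** — allele-frequency PCA with binomial scaling
  1/√(p̄(1−p̄)); covariance → correlation → 1−r dissimilarity →
  UPGMA tree (newick via `ape`).
* **GEA** — redundancy analysis (RDA) built from first principles
  (regression + SVD of fitted values), correlation/VIF predictor pruning,
  partial RDA with conditioning covariates, ANOVA-like permutation tests,
  Ezekiel-adjusted R².
* **Outliers & offset** — Mahalanobis D² of locus scores on the first two
  RDA axes, χ² p-values, Benjamini–Hochberg FDR; adaptive-index rasters
  AI<sub>k</sub> = Σ<sub>j</sub> loading<sub>jk</sub>·z<sub>j</sub>(pixel);
  genomic offset |AI<sup>future</sup> − AI<sup>current</sup>| per axis,
  combined by an eigenvalue-weighted Euclidean norm, with optional
  coastal masking.
* **Synthetic truth** — a fully seeded generator (Balding–Nichols
  frequencies where the drift parameter *is* the expected F<sub>ST</sub>,
  binomial pool/read sampling, gridded environments with future deltas)
  so every claim above is tested against known truth.

## Worked example

A synthetic study in the package's default design — 21 pools of 40
diploids at 60× along a south-to-north gradient, 5,000 loci of which 50
track temperature (logit effect β = 1.5 per sd):

```r
library(poolscape)

cfg   <- simConfig(nPops = 21, nLoci = 5000, nOutlierLoci = 50,
                   beta = 1.5, seed = 1)
study <- simulatePoolseqStudy(cfg)
freqs <- poolFrequencies(study$counts, filterConfig())
freqs
#> PoolFreqs: 4934 biallelic loci x 21 pools
#>  global minor-allele frequency: 0.050-0.500

fst <- pairwiseFstAnova(study$counts, freqs = freqs)
round(range(fst$fst[upper.tri(fst$fst)]), 4)
#> [1] 0.0463 0.0627

d <- geoDistances(study$counts)                 # great-circle km
mantelTest(slatkinLinearize(pmax(fst$fst, 0)), d, nPerm = 999, seed = 2)[c("r", "p")]
#> $r
#> [1] 0.8380787
#> $p
#> [1] 0.001

fit <- fitRda(freqs, prunePredictors(study$env))
fit
#> RdaFit: 21 sites, 2 predictors, 0 conditioning columns
#>  constrained axes: 2; eigenvalues: 6.105 3.53
#>  variance: conditioned 0.000 | constrained 0.133 | unconstrained 0.867
#>  R2 = 0.1327, adjusted R2 = 0.0364

out <- mahalanobisOutliers(fitRda(freqs, prunePredictors(study$env),
                                  scaling = "binomial"), K = 2)
sum(out$outlier)
#> [1] 48

fitOut <- fitRda(freqMatrix(freqs)[, out$outlier], prunePredictors(study$env))
aiC <- adaptiveIndex(fitOut, study$rasters$current, axes = 1:2)
aiF <- adaptiveIndex(fitOut, study$rasters$future,  axes = 1:2,
                     scenario = "future")
genomicOffset(aiC, aiF)
#> OffsetRaster: current -> future, 2 axes, combination rule 'eigen-euclidean'
#>  combined offset: 0..0.487
```

Reading the numbers: pairwise F<sub>ST</sub> clusters around the simulated
drift (0.05); the linearized F<sub>ST</sub> correlates with distance
because the 50 environment-tracking loci follow the latitudinal gradient
(Mantel r = 0.84, p = 0.001); the ordination attributes 13% of frequency
variance to the two predictors; 48 of the 50 planted loci are recovered at
q < 0.05; and the offset map is exactly zero at the southern edge (where
the simulated future deltas vanish) and largest in the north, where the
projected change is greatest.

The same analysis runs file-to-file through the pipeline driver:

```r
runPipeline("inst/extdata/demo_config.yaml", out = "demo_out")
```

or from a shell via the thin wrapper
`inst/scripts/poolscape-pipeline.R --config ... --seed ... --out ...`.
Each stage writes TSV/CSV/newick/ASCII-grid artifacts plus a
`manifest.json`; re-running with the same configuration and seed
reproduces every output byte for byte.

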