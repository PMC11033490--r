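---
title: "Methods behind poolscape: pool-seq statistics, constrained ordination and genomic offset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind poolscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscape)
```

poolscape analyses pooled whole-genome resequencing (pool-seq) data: read
counts per site per pool stand in for population allele frequencies, and the
questions are the classic ones of seascape/landscape genomics — how
differentiated are the populations, does differentiation track geography,
which loci track the environment, and how far would allele frequencies have
to move to keep up with a projected climate. This vignette explains the
statistical machinery, the choices we made where the design was genuinely
open, and what the synthetic data generator does and does not emulate.

## Data model

A sync file gives, per genomic site and pool, six read counts
(`A:T:C:G:N:del`). We keep all six through I/O but define coverage as
`C = A+T+C+G`: the estimators below act on nucleotide alleles, so `N` and
deletion reads never enter any statistic. Positions are 1-based (the mpileup
convention) and windows are half-open `[start, start + size)`. Sync files
carry no pool names; the metadata table supplies them, and the column order
must match — only the column count can be validated.

SNP filtering mirrors common pool-seq practice. Per locus the two bases with
the highest counts summed over pools form the biallelic pair (ties broken in
sync column order); a locus is kept when every pool's coverage lies within
`[minCov, maxCov]`, the pooled minor-allele count reaches `minCount`
(summed over pools by default, the PoPoolation2 reading; a per-pool variant
is a flag), the pooled minor-allele frequency reaches `maf`, and no third
allele exceeds `minCount` reads. Defaults are `minCount = 4`,
`minCov = 20`, `maxCov = 500`, `maf = 0.05`. Whether the MAF threshold
should be pooled or per-population is ambiguous in common usage; we use the
pooled (global) frequency.

## Differentiation

**Per-SNP F_ST** uses the classic pooled form: per pool
$H = \frac{C}{C-1}\bigl(1 - f^2 - (1-f)^2\bigr)$, with $\Pi_W$ the mean of
the two pools' $H$ and $\Pi_T$ the $H$ of the pooled counts;
$F_{ST} = (\Pi_T - \Pi_W)/\Pi_T$. Identical pools give slightly *negative*
raw values under the $C/(C-1)$ correction, so per-site values are clamped
at zero (the unclamped mean is kept in a `fst_raw` column for diagnostics).
Windowed values average SNPs within half-open windows; windows without SNPs
are omitted.

**Pairwise ANOVA F_ST** corrects for both sampling stages of pool-seq: the
$2n$ chromosomes entering the pool and the $C$ reads drawn from them. Two
reads drawn from a pool come from the same chromosome with probability
$1/2n$, so the naive read-level heterozygosity underestimates nothing and
overestimates nothing only after both corrections. Per locus we form the
within-pool sum of squares $SSI = 2\sum_i C_i f_i(1-f_i)$ and the
among-pool $SSP = 2\sum_i C_i (f_i - \bar f)^2$, and divide by denominators
chosen so that, under a model with $\mathrm{Var}(p_i) = F\,p(1-p)$,
$E[MSI] = 2pq(1-F)$ and $E[MSP] = 2pq\,(1 + (n_c - 1)F)$ exactly:

* $MSI = SSI \,/\, \sum_i (C_i - 1)\frac{n_i-1}{n_i}$ (haploid sizes $n_i = 2 \times$ individuals),
* $MSP = SSP \,/\, \sum_i w_i (1-\beta_i)$ with $w_i = C_i - C_i^2/\sum C$,
  $\beta_i = (1 - 1/n_i)(1 - 1/C_i)$, and
  $n_c = 1 + \sum w_i \beta_i / \sum w_i(1-\beta_i)$.

The among component $\hat\sigma^2_P = (MSP - MSI)/n_c$ has expectation
$2pqF$ and the total $\hat\sigma^2_P + MSI$ expectation $2pq$, so the
multi-locus estimate is the **ratio of sums** of these components — not the
mean of per-locus ratios, which is unstable when weakly polymorphic loci
enter. Small negative multi-locus estimates are legitimate for an unbiased
estimator and are not clamped. Pairs with fewer than 50 informative
(within-pair polymorphic) loci are flagged low-confidence.

A consequence worth knowing: feeding the estimator two *literally
identical* count tables yields about $-1/(n_c - 1)$, not zero, because
identical tables are "too similar" relative to the sampling model. The
correct no-differentiation check — two pools sampled independently from the
same frequencies — is unbiased around zero, and that is what the test suite
verifies. Recovery of the Balding–Nichols parameter $c \in \{0.02, 0.05,
0.10, 0.30\}$ is verified within $\pm 0.02$ at 2 pools × 20,000 loci,
$n = 30$ diploids, 60× depth. The recovery experiment deliberately uses a
permissive filter (no MAF cut): a MAF threshold conditions on realized
frequencies and measures the filter's ascertainment, not the estimator.

Slatkin's linearization $F/(1-F)$ feeds the isolation-by-distance Mantel
test against great-circle (haversine, spherical Earth $R = 6371$ km) or
least-cost sea distances. Least-cost paths run over 8-connected sea cells
of a mask raster with each step costed at the true great-circle distance
between cell centers — no $\sqrt 2$ shortcut, which would distort
diagonal steps on a lon/lat grid. The Mantel test permutes rows and columns
of the second matrix jointly and reports the one-sided upper-tail
$p = (1 + \#\{r_\pi \ge r\})/(n_{perm} + 1)$; with few sites the sampled
permutations necessarily revisit symmetric relabelings, so the attainable
minimum $p$ is bounded below by the matrix's symmetry group, not by
$1/(n_{perm}+1)$.

## Diversity

Windowed nucleotide diversity uses the corrected site heterozygosity
$h = \frac{C}{C-1} 2f(1-f)$ summed over retained SNPs and divided by the
*full window length*, invariant sites included — matching the sliding-window
tools this mirrors. Because only variant sites contribute to the numerator,
absolute values are biased downward; π is intended as a comparative
statistic among pools, not an absolute estimate.

Tajima's D is computed on site-frequency-spectrum-style inputs with
$n_{chrom} = 2 \times$ individuals, using the classic coefficients. We
deliberately did not re-derive a pooled-read correction: D is used
comparatively (sign and magnitude), and the generator provides equilibrium
($P(i) \propto 1/i$) and expansion ($P(i) \propto 1/i^2$) spectra to pin
down its behaviour — near zero for equilibrium, strongly negative
(mean $\approx -2$ at $n_{chrom}=40$, 500 sites) for the singleton-skewed
spectrum.

## Population structure

PCA of population allele frequencies centers each locus and scales by
$1/\sqrt{\bar p(1-\bar p)}$ — the binomial standardization — then takes the
SVD; scores are $U D$ and the per-axis variance proportions $d_k^2/\sum
d^2$. Loci fixed across the analysed subset are dropped with a count.
Hierarchical analyses (all pools, a regional subset) are a `subset`
argument, not hard-coded site lists.

The population tree chain is: empirical covariance $\Omega$ of the
standardized frequencies across loci, correlation by `cov2cor`,
dissimilarity $1 - r$, agglomerative clustering. We chose $1 - r$ over
$\sqrt{1-r^2}$ and average linkage (UPGMA) as defaults because neither the
transform nor the linkage is canonical in this pipeline's tradition; both
choices are recorded in the output and `complete`/`single` are available.
Replacing a Markov-chain estimate of $\Omega$ by the direct empirical
covariance is a deliberate design simplification: the downstream
correlation → dissimilarity → tree chain is unchanged, and the empirical
estimator is deterministic and fast at the locus counts involved.

## Constrained ordination

`fitRda` implements redundancy analysis from first principles so that every
quantity is testable against an independent oracle: center the response
per locus (sites × loci), optionally residualize response and predictors on
a conditioning matrix (partial RDA), regress on the standardized
predictors, and take the SVD of the fitted values. Eigenvalues are
$d_k^2/(n-1)$; site scores the left singular vectors; locus scores the
right singular vectors scaled by singular values (a scaling-2 analogue, so
that the Mahalanobis step sees variance-weighted loadings); predictor
loadings are correlations of predictors with site scores. The variance
partition (conditioned / constrained / unconstrained) refers to the total
sum of squares of the centered response, and the whole stack is verified to
agree with an independent per-locus regression + eigendecomposition oracle
to 1e-8 and with `vegan::rda` on shared quantities.

Predictor screening drops one member of any pair with $|r| \ge 0.85$
(the later-listed one) and then iteratively removes the largest variance
inflation factor until all VIF < 10. Standardization constants (mean, sd
per predictor) are stored: raster pixels are later placed on exactly this
scale.

The adjusted $R^2$ is the closed-form Ezekiel correction
$1-(1-R^2)(n-1)/(n-p-1)$ rather than a permutation-based estimate: it is
deterministic and testable, and the difference vanishes for unconditioned
models. The significance test is the ANOVA-like permutation test with
pseudo-$F = (SS_{constr}/q)/(SS_{resid}/(n-q-q_0-1))$; without conditioning
rows of the centered response are permuted freely, with conditioning we
permute reduced-model residuals (the standard scheme for conditioned
ordination — the choice is recorded in output metadata). Marginal
per-predictor tests treat the other predictors as conditioners. Type-I
error is verified at 0.046 over 500 null replicates at $\alpha = 0.05$.

## Outlier detection and genomic offset

Outliers are loci whose scores on the first $K = 2$ constrained axes are
extreme: Mahalanobis $D^2$ against the empirical score covariance,
upper-tail $\chi^2_K$ p-values, Benjamini–Hochberg q-values, flag at
$q < 0.05$. Two calibration choices matter:

* **Locus scaling.** Raw frequency responses give locus scores whose
  variance depends on $\bar p(1-\bar p)$; the score cloud is then a scale
  mixture and $D^2$ is heavier-tailed than $\chi^2$, inflating small
  p-values. The outlier path therefore fits the RDA with
  `scaling = "binomial"` (each locus divided by $\sqrt{\bar p(1-\bar p)}$),
  which restores the $\chi^2$ calibration: under a null simulation with no
  environment-associated loci the p-values are uniform (KS $p > 0.3$ at
  5,000 loci), while the variance-partition models keep the conventional
  unscaled response. Both fits are reported by the pipeline.
* **Robustness and inflation.** The covariance is the plain empirical one,
  and no genomic-inflation rescaling is applied by default (a median-based
  rescale is a flag): with a correctly specified null both are no-ops, and
  neither is prescribed by the tradition this follows.

Detection is conditioned or not on neutral structure by passing population
PC axes 1–2 as the conditioning matrix (`condition: pcs` in the pipeline);
the default is unconditioned.

The **adaptive index** maps an ordination axis across a raster: per pixel,
$AI_k = \sum_j \mathrm{loading}_{jk}\, z_j$, where $z_j$ standardizes the
pixel's predictor value with the *site-table* constants, so sites, pixels,
and both climate scenarios share one scale. Nodata propagates through all
arithmetic. The **genomic offset** per axis is $|AI_k^{fut} - AI_k^{cur}|$
per pixel. How per-axis offsets combine into one map is genuinely open; we
default to the eigenvalue-weighted Euclidean norm
$\sqrt{\sum_k w_k O_k^2}$, $w_k = \lambda_k/\sum\lambda$, with `max` and
`sum` as tagged alternatives — the weighted norm preserves "zero iff no
predictor moved" and respects the axes' explanatory shares. A sea/coastline
mask raster, applied last, replaces shapefile buffering: geometry
generation is out of scope and a mask raster expresses the same constraint.

## The synthetic generator

The generator exists so every stage is testable with known truth, at the
scale of the study design it emulates: ~21 pools of 40 diploids
(30–54 supported) at 60× expected depth, $10^3$–$10^5$ biallelic loci, a
south-to-north environmental gradient, and a ~1% minority of loci tracking
it.

* **Population frequencies** follow the Balding–Nichols model: ancestral
  $p_0 \sim U(0.05, 0.95)$, pool frequency
  $\mathrm{Beta}\bigl(p_0(1-c)/c, (1-p_0)(1-c)/c\bigr)$. The drift
  parameter $c$ *is* the expected F_ST against the ancestral pool, which is
  why this model rather than a coalescent simulator backs the estimator
  tests: the target quantity is a model parameter. Environment-associated
  loci additionally shift $\mathrm{logit}(p)$ by $\beta z$ (clipped to
  [0.001, 0.999] so no "outlier" is degenerate); $\beta = 1.5$ per sd of
  environment is the default planted effect.
* **Counts** are the two-stage sample: $k \sim \mathrm{Bin}(2n, p)$
  chromosomes, $C \sim \mathrm{Pois}(60)$ reads,
  alternate reads $\sim \mathrm{Bin}(C, \frac{k}{2n}(1-\varepsilon) +
  (1-\frac{k}{2n})\varepsilon)$ with $\varepsilon = 0.001$. The reference
  base is always A and the alternate T — the simplest valid sync — and no
  test relies on base identity.
* **Rasters** are linear latitudinal gradients for temperature and
  salinity; salinity additionally carries a sinusoidal along-coast
  component so the two predictors are not collinear across sites (bay-scale
  salinity structure on top of the broad thermal gradient) and survive the
  $r < 0.85$ screen as a pair. Future scenarios add a deterministic delta
  field growing from zero at the southern edge to its maximum in the north,
  mimicking stronger projected high-latitude change; this gives the
  qualitative truth the offset tests assert (largest offsets where the
  projected change is largest, exactly zero where nothing changes).
* **Site-frequency spectra** for the Tajima's D tests are drawn separately
  (`simulateSfsWindow`), because Beta-distributed frequencies carry no
  realistic SFS.

One seed fixes everything; internal stages derive sub-seeds by fixed small
offsets, so the full pipeline is byte-reproducible (verified by comparing
entire output directories of two runs).

What the generator does **not** emulate — and hence what green tests do not
establish about real data: linkage disequilibrium (loci are independent),
clonal replicates within pools (real seagrass meadows contain ramets of one
genet; their effect on π and D is unquantifiable without genotypes and is
deliberately not simulated), hierarchical migration structure beyond the
star-shaped Balding–Nichols model (the two-cluster PCA test builds its
hierarchy explicitly), reference bias, mapping error, and indel artefacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by design, at sizes where the
properties are decisive yet the whole suite completes in minutes on one
CPU: estimator recovery at 2 × 20,000 loci; outlier operating
characteristics at 21 × 5,050 loci with 50 planted; null calibration at
5,000 loci; permutation calibration over 500 replicates of a 12 × 30
response; the end-to-end pipeline at 21 × 50,000 loci (under a minute per
run). Rank decisions use a relative singular-value tolerance of 1e-9;
degenerate inputs (monomorphic sites, empty windows, zero-variance pools or
predictors, unreachable sea cells, sites on land) are either skipped with
accounting or raised as named errors, never silently imputed.

## Known limitations

* π and D are comparative, not absolute (variant-only numerators; no
  pooled correction for D).
* The ANOVA F_ST assumes equal contribution of individuals to the pool
  (equimolar pooling); unequal DNA contributions would act like a smaller
  effective pool.
* The adaptive index extrapolates a linear frequency–environment
  relationship to unsampled pixels; offsets in regions far from any site
  are extrapolations and should be read accordingly.
* Least-cost distances depend on mask resolution; coarse masks lengthen
  narrow passages or close them entirely (pairs then report `Inf` with a
  warning).
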