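syncFixture <- function(lines, nPools = 2) {
  readSync(writeSyncLines(lines), tinyPoolMeta(nPools))
}

test_that("biallelic filtering applies coverage, count and MAF rules", {
  x <- syncFixture(c(
    "chr1\t10\tT\t10:30:0:0:0:0\t10:30:0:0:0:0",   # kept, minor A f=0.25
    "chr1\t20\tT\t2:8:0:0:0:0\t10:30:0:0:0:0",     # pool1 coverage 10 < 20
    "chr1\t30\tT\t1:39:0:0:0:0\t1:39:0:0:0:0",     # global maf 0.025 < 0.05
    "chr1\t40\tT\t0:40:0:0:0:0\t40:0:0:0:0:0",     # kept; A/T totals tie
    "chr1\t50\tT\t10:20:10:0:0:0\t10:20:10:0:0:0"  # third allele 20 > minCount
  ))
  fr <- poolFrequencies(x, filterConfig(minCount = 4, minCov = 20,
                                        maxCov = 500, maf = 0.05))
  expect_equal(nrow(fr), 2L)
  rr <- SummarizedExperiment::rowRanges(fr)
  expect_equal(GenomicRanges::start(rr), c(10L, 40L))
  # at the tie the sync column order breaks it: A major, T minor
  expect_equal(rr$minor, c("A", "T"))
  f <- SummarizedExperiment::assay(fr, "freq")
  expect_equal(unname(f[1, ]), c(0.25, 0.25))
  expect_equal(unname(f[2, ]), c(1, 0))
  expect_equal(unname(SummarizedExperiment::assay(fr, "cov")[1, ]), c(40, 40))
})

test_that("filtering everything warns and returns an empty PoolFreqs", {
  x <- syncFixture("chr1\t10\tT\t1:9:0:0:0:0\t1:9:0:0:0:0")
  expect_warning(fr <- poolFrequencies(x, filterConfig()), "all loci")
  expect_equal(nrow(fr), 0L)
})

test_that("per-SNP classic F_ST matches the hand-derived values", {
  x <- syncFixture(c(
    "chr1\t10\tA\t15:5:0:0:0:0\t5:15:0:0:0:0",
    "chr1\t20\tA\t20:0:0:0:0:0\t0:20:0:0:0:0",   # reciprocal fixation
    "chr1\t30\tA\t10:10:0:0:0:0\t10:10:0:0:0:0", # identical pools
    "chr1\t40\tA\t20:0:0:0:0:0\t20:0:0:0:0:0"    # monomorphic: skipped
  ))
  fr <- poolFrequencies(x, filterConfig(minCount = 0, minCov = 10,
                                        maxCov = 100, maf = 0))
  res <- perSnpFst(fr, "p1", "p2")
  expect_equal(nrow(res), 3L)   # the monomorphic site is dropped
  # (Pi_T - Pi_W)/Pi_T with the C/(C-1) correction at 15:5 vs 5:15
  expect_equal(res$fst[res$start == 10], 0.2303, tolerance = 2e-4)
  expect_equal(res$fst[res$start == 20], 1)
  # identical pools: raw negative, clamped to zero
  expect_lt(res$fst_raw[res$start == 30], 0)
  expect_equal(res$fst[res$start == 30], 0)
})

test_that("windowed F_ST averages SNPs and omits empty windows", {
  x <- syncFixture(c(
    "chr1\t10\tA\t15:5:0:0:0:0\t5:15:0:0:0:0",
    "chr1\t90\tA\t20:0:0:0:0:0\t0:20:0:0:0:0",
    "chr1\t250\tA\t20:0:0:0:0:0\t0:20:0:0:0:0"
  ))
  fr <- poolFrequencies(x, filterConfig(minCount = 0, minCov = 10,
                                        maxCov = 100, maf = 0))
  w <- perSnpFst(fr, "p1", "p2", windowSize = 100, step = 100)
  expect_equal(nrow(w), 2L)     # window [101,201) holds no SNP
  expect_equal(w$start, c(1, 201))
  expect_equal(w$fst[1], mean(c(0.23026316, 1)), tolerance = 1e-6)
  expect_equal(w$n_snps, c(2L, 1L))
})

test_that("ANOVA pairwise F_ST hits the boundary cases", {
  # reciprocally fixed at every locus
  lines <- sprintf("chr1\t%d\tA\t60:0:0:0:0:0\t0:60:0:0:0:0",
                   seq(10, 1000, by = 10))
  x <- syncFixture(lines)
  est <- pairwiseFstAnova(x, filterConfig(minCount = 1, minCov = 10,
                                          maxCov = 1000, maf = 0))
  expect_gt(est$fst["p1", "p2"], 0.99)
  expect_equal(diag(est$fst), c(p1 = 0, p2 = 0))
  expect_false(est$low_confidence["p1", "p2"])  # 100 informative loci

  # two pools independently sampled from identical population frequencies:
  # no differentiation, estimator unbiased around zero
  cfg <- simConfig(nPops = 1, nLoci = 10000, drift = 0.3, nOutlierLoci = 0,
                   depthMean = 100, seqError = 0, seed = 21)
  tr <- simulatePopulationFrequencies(cfg)
  tr2 <- tr
  tr2$trueFreqs <- rbind(tr$trueFreqs, tr$trueFreqs)   # same frequencies
  tr2$poolMeta <- tinyPoolMeta(2, size = 30)
  cfg2 <- simConfig(nPops = 2, nLoci = 10000, drift = 0.3, nOutlierLoci = 0,
                    depthMean = 100, seqError = 0, seed = 21)
  x2 <- simulatePoolCounts(tr2, cfg2)
  est2 <- pairwiseFstAnova(x2, filterConfig(minCount = 1, minCov = 10,
                                            maxCov = 1000, maf = 0))
  expect_lt(abs(est2$fst[1, 2]), 0.01)
})

test_that("ANOVA estimator recovers the Balding-Nichols parameter", {
  cfg <- simConfig(nPops = 2, nLoci = 20000, drift = 0.10, nOutlierLoci = 0,
                   poolSizes = 30, depthMean = 60, seed = 1)
  x <- simulatePoolCounts(simulatePopulationFrequencies(cfg), cfg)
  est <- pairwiseFstAnova(x, filterConfig(minCount = 1, minCov = 10,
                                          maxCov = 1000, maf = 0))
  expect_equal(est$fst[1, 2], 0.10, tolerance = 0.02)
})

test_that("pairs with few informative loci are flagged low-confidence", {
  lines <- sprintf("chr1\t%d\tA\t30:30:0:0:0:0\t20:40:0:0:0:0",
                   seq(10, 100, by = 10))
  x <- syncFixture(lines)
  est <- pairwiseFstAnova(x, filterConfig(minCount = 1, minCov = 10,
                                          maxCov = 1000, maf = 0))
  expect_true(est$low_confidence["p1", "p2"])
  expect_equal(est$n_loci["p1", "p2"], 10L)
})

test_that("Slatkin linearization is F/(1-F) and rejects F >= 1", {
  expect_equal(slatkinLinearize(0), 0)
  expect_equal(slatkinLinearize(0.2), 0.25)
  expect_equal(slatkinLinearize(0.54), 0.54 / 0.46)
  m <- matrix(c(0, 0.2, 0.2, 0), 2)
  expect_equal(slatkinLinearize(m), matrix(c(0, 0.25, 0.25, 0), 2))
  expect_error(slatkinLinearize(1), "linearized")
})
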