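# Demo pipeline configuration: a small synthetic seascape study.
# Run with:
#   Rscript inst/scripts/poolscape-pipeline.R --config inst/extdata/demo_config.yaml --out demo_out
seed: 1
simulate:
  nPops: 21
  nLoci: 5000
  nOutlierLoci: 50
  beta: 1.5
  drift: 0.05
  poolSizes: 40
  depthMean: 60
  seqError: 0.001
filter:
  minCount: 4
  minCov: 20
  maxCov: 500
  maf: 0.05
stats:
  windowSize: 10000
  mantelPermutations: 199
rda:
  nPerm: 199
  rMax: 0.85
  vifMax: 10
  condition: none
offset:
  K: 2
  fdr: 0.05
  combine: eigen-euclidean
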