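# A small trained two-bin bundle shared by the prediction/ensemble tests.
# Built once per test run; all seeds fixed.

.testCache <- new.env(parent = emptyenv())

testSim <- function() {
  if (is.null(.testCache$sim)) {
    lo <- simulateReads(genomeLength = 40000, geneDensity = 0.7,
                        gcTarget = 40, codonBiasStrength = 2,
                        coverage = 1, seed = 101, prefix = "lo")
    hi <- simulateReads(genomeLength = 40000, geneDensity = 0.7,
                        gcTarget = 65, codonBiasStrength = 2,
                        coverage = 1, seed = 202, prefix = "hi")
    .testCache$sim <- list(lo = lo, hi = hi,
                           fragments = c(lo$fragments, hi$fragments),
                           truth = rbind(lo$truth, hi$truth))
  }
  .testCache$sim
}

testBundle <- function() {
  if (is.null(.testCache$bundle)) {
    sim <- testSim()
    lab <- makeLabelledOrfs(sim$fragments, sim$truth)
    X <- extractFeatures(lab$orfs, sim$fragments)
    gc <- gcPercent(sim$fragments)[match(lab$orfs$fragment_id,
                                         names(sim$fragments))]
    .testCache$bundle <- trainEnsemble(
      X, lab$labels, gc, binning = GcBinning(52), kFeatures = 40,
      selectionSubsample = 1500, gridSubsample = 600,
      costs = c(1, 10), gammas = c(0.01, 0.05), folds = 3, seed = 7)
  }
  .testCache$bundle
}

testHeldOut <- function() {
  if (is.null(.testCache$held)) {
    sim <- testSim()
    a <- fragmentGenome(sim$lo$genome, fragmentLength = 700,
                        coverage = 0.4, seed = 303, prefix = "tlo")
    b <- fragmentGenome(sim$hi$genome, fragmentLength = 700,
                        coverage = 0.4, seed = 404, prefix = "thi")
    .testCache$held <- list(fragments = c(a$fragments, b$fragments),
                            truth = rbind(a$truth, b$truth))
  }
  .testCache$held
}
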