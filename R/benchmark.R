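## Desk-scale end-to-end recovery benchmark on synthetic metagenomes.
##
## Two GC regimes (low / high), each emulated by several source genomes
## with distinct codon-usage profiles, are fragmented into 700-bp reads.
## A two-bin GC-stratified ensemble and a single pooled model are trained
## on the same labelled ORFs and evaluated on held-out reads.  This is the
## package's stand-in for benchmarking against real annotated genomes:
## it verifies that the full pipeline recovers strongly codon-biased genes
## and that GC stratification does not hurt when coding statistics vary
## with GC.

#' Run the synthetic end-to-end recovery benchmark
#'
#' Simulates a small metagenome (by default six 140-kb genomes forming a
#' GC continuum from 42 to 62 percent, three on each side of the bin
#' boundary, each with its own codon-usage profile; 0.7 coding density,
#' strong codon bias), trains (a) a two-bin GC-stratified ensemble and
#' (b) a single pooled model on more than 5,000 labelled ORFs per GC bin,
#' predicts genes on held-out reads from the same genomes, and evaluates
#' both against the truth annotations.
#'
#' @param seed Integer master seed; every stochastic step derives a named
#'   substream from it.
#' @param gcLow,gcHigh GC targets (percent) of the source genomes in the
#'   two regimes.
#' @param genomeLength Length of each source genome (nt).
#' @param geneDensity Coding fraction of each genome.
#' @param codonBiasStrength Codon-usage bias sharpness
#'   ([makeCodonProfile()]).
#' @param coverage Training read coverage per genome (fold).
#' @param testCoverage Held-out read coverage per genome (fold).
#' @param binBoundary GC boundary (percent) separating the two ensemble
#'   bins.
#' @param kFeatures mRMR features per bin.
#' @param costs,gammas Grid-search grids.
#' @param verbose Print stage progress.
#' @return A list: `ensemble` and `single` ([EvalReport-class]),
#'   `nTrainOrfs`, `nTrainCoding`, `binSizes`, `nTestFragments`,
#'   `nTestGenes` (evaluable truth genes), `nCallsEnsemble`.
#' @export
runRecoveryBenchmark <- function(seed = 1L,
                                 gcLow = c(42, 46, 50),
                                 gcHigh = c(54, 58, 62),
                                 genomeLength = 140000L,
                                 geneDensity = 0.7,
                                 codonBiasStrength = 2,
                                 coverage = 1,
                                 testCoverage = 0.8,
                                 binBoundary = 52,
                                 kFeatures = 150L,
                                 costs = c(1, 10, 100),
                                 gammas = c(0.005, 0.02, 0.05),
                                 verbose = FALSE) {
  if (verbose) {
    old <- options(MetaGeneSVM.verbose = TRUE)
    on.exit(options(old))
  }
  gcs <- c(gcLow, gcHigh)
  tags <- sprintf("g%02d", seq_along(gcs))
  sims <- lapply(seq_along(gcs), function(i) {
    mgsLog("simulating genome ", tags[i], " at GC ", gcs[i])
    simulateReads(genomeLength = genomeLength, geneDensity = geneDensity,
                  gcTarget = gcs[i], codonBiasStrength = codonBiasStrength,
                  coverage = coverage,
                  seed = substreamSeed(seed, tags[i]), prefix = tags[i])
  })
  fragments <- do.call(c, lapply(sims, `[[`, "fragments"))
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  mgsLog("labelling ORFs on ", length(fragments), " training reads")
  lab <- makeLabelledOrfs(fragments, truth)
  X <- extractFeatures(lab$orfs, fragments)
  gc <- gcPercent(fragments)[lab$orfs$fragment_id]
  # both models share one random stream (common random numbers), so their
  # comparison is paired: subsampling, CV-fold and calibration-split noise
  # largely cancels in the difference of the two harmonic means
  train <- function(binning) {
    trainEnsemble(X, lab$labels, gc, binning = binning,
                  kFeatures = kFeatures, selectionSubsample = 3000L,
                  trainSubsample = 6000L, gridSubsample = 2000L,
                  costs = costs, gammas = gammas, folds = 3L,
                  seed = substreamSeed(seed, "train"))
  }
  mgsLog("training the two-bin ensemble")
  ens <- train(GcBinning(binBoundary))
  mgsLog("training the single pooled model")
  # a boundary above every observed GC routes all reads to one bin
  sgl <- train(GcBinning(99.9))

  tests <- lapply(seq_along(sims), function(i) {
    fragmentGenome(sims[[i]]$genome, fragmentLength = 700L,
                   coverage = testCoverage,
                   seed = substreamSeed(seed, paste0("test-", tags[i])),
                   prefix = paste0("t", tags[i]))
  })
  testFrags <- do.call(c, lapply(tests, `[[`, "fragments"))
  testTruth <- do.call(rbind, lapply(tests, `[[`, "truth"))
  mgsLog("predicting on ", length(testFrags), " held-out reads")
  callsEns <- predictFragments(testFrags, ens)
  callsSgl <- predictFragments(testFrags, sgl)
  bins <- assignBin(gc, gcBinning(ens))
  list(ensemble = evaluateCalls(callsEns, testTruth),
       single = evaluateCalls(callsSgl, testTruth),
       nTrainOrfs = nrow(lab$orfs),
       nTrainCoding = sum(lab$labels),
       binSizes = as.integer(table(factor(bins, levels = seq_len(nBins(gcBinning(ens)))))),
       nTestFragments = length(testFrags),
       nTestGenes = sum(testTruth$end - testTruth$start >= 60L),
       nCallsEnsemble = nrow(callsEns))
}
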