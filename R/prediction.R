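## Scoring and post-processing: every candidate ORF of a fragment is scored
## by the GC-appropriate bin model (Platt posterior of the RBF-SVM decision
## value); candidates above the probability threshold enter a greedy
## highest-probability-first selection that enforces a maximum pairwise
## overlap between accepted calls.

## score a feature matrix with one bin model
scoreWithBinModel <- function(m, X) {
  Xs <- scale(as.matrix(X[, c(m$selected, N_USAGE + 1:3), drop = FALSE]),
              m$center, m$scale)
  dv <- attr(predict(m$svm, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  plattPosterior(m$platt, m$flip * dv)
}

#' Score every candidate ORF of each fragment
#'
#' Extracts ORFs, computes features, routes each fragment to the model of
#' its GC bin and returns the Platt posterior probability that each ORF is
#' coding.  Scoring is deterministic: repeated calls on the same bundle
#' give identical probabilities.
#'
#' @param fragments A named [Biostrings::DNAStringSet].
#' @param bundle A trained [ModelBundle-class].
#' @param minLen Minimum ORF length (nt).
#' @param startCodons,stopCodons Codon sets for [extractOrfs()].
#' @return The [extractOrfs()] `data.frame` with extra columns
#'   `probability` and `bin`.
#' @export
scoreOrfs <- function(fragments, bundle, minLen = 60L,
                      startCodons = DEFAULT_START_CODONS,
                      stopCodons = STOP_CODONS) {
  orfs <- extractOrfs(fragments, minLen = minLen,
                      startCodons = startCodons, stopCodons = stopCodons)
  if (nrow(orfs) == 0L) {
    orfs$probability <- numeric(0)
    orfs$bin <- integer(0)
    return(orfs)
  }
  X <- extractFeatures(orfs, fragments)
  gc <- gcPercent(fragments)
  fragBin <- assignBin(gc, gcBinning(bundle))
  bin <- fragBin[match(orfs$fragment_id, names(fragments))]
  prob <- numeric(nrow(orfs))
  for (b in sort(unique(bin))) {
    m <- binModels(bundle)[[b]]
    if (is.null(m)) {
      stop("no trained model for GC bin ", b,
           " (fragment GC out of the trained ranges)", call. = FALSE)
    }
    rows <- which(bin == b)
    prob[rows] <- scoreWithBinModel(m, X[rows, , drop = FALSE])
  }
  orfs$probability <- prob
  orfs$bin <- bin
  orfs
}

#' Greedy overlap resolution of candidate genes
#'
#' Repeatedly moves the highest-probability candidate to the final gene
#' list and discards every remaining candidate of the same fragment that
#' overlaps it by more than `oMax` nucleotides.  Overlap is measured on
#' forward-strand fragment coordinates regardless of strand and frame.
#' Probability ties are broken toward the longer ORF, then the smaller
#' start coordinate, then strand `+`, making the output unique.
#'
#' @param candidates `data.frame` with at least `fragment_id`, `start`,
#'   `end`, `strand`, `probability` (all candidates above threshold).
#' @param oMax Maximum permitted pairwise overlap in nt (default 60, the
#'   conventional minimum gene length).
#' @return The selected subset, sorted by fragment and start coordinate.
#' @export
greedySelect <- function(candidates, oMax = 60L) {
  if (nrow(candidates) == 0L) return(candidates)
  byFrag <- factor(candidates$fragment_id,
                   levels = unique(candidates$fragment_id))
  pieces <- lapply(split(seq_len(nrow(candidates)), byFrag),
                   function(rows) {
    df <- candidates[rows, , drop = FALSE]
    ord <- order(-df$probability, -(df$end - df$start), df$start,
                 match(df$strand, c("+", "-")))
    df <- df[ord, , drop = FALSE]
    keep <- integer(0)
    alive <- seq_len(nrow(df))
    while (length(alive) > 0L) {
      top <- alive[1L]
      keep <- c(keep, top)
      ov <- intervalOverlap(df$start[top], df$end[top],
                            df$start[alive], df$end[alive])
      alive <- setdiff(alive[ov <= oMax], top)
    }
    df[sort(keep), , drop = FALSE][order(df$start[sort(keep)]), , drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Predict genes in metagenomic fragments
#'
#' Full prediction chain: six-frame ORF extraction, featurization,
#' GC-routed SVM scoring, probability thresholding and greedy overlap
#' resolution.  Start sites are the leftmost in-frame start codon of each
#' ORF; start-site refinement is left to downstream tools.
#'
#' @inheritParams scoreOrfs
#' @param threshold Posterior probability above which an ORF becomes a
#'   candidate gene (default 0.5).
#' @param oMax Maximum permitted overlap between accepted calls (nt).
#' @return A `data.frame` of gene calls: the [scoreOrfs()] columns,
#'   restricted to accepted calls and sorted by fragment and start.
#' @export
predictFragments <- function(fragments, bundle, threshold = 0.5, oMax = 60L,
                             minLen = 60L,
                             startCodons = DEFAULT_START_CODONS,
                             stopCodons = STOP_CODONS) {
  scored <- scoreOrfs(fragments, bundle, minLen = minLen,
                      startCodons = startCodons, stopCodons = stopCodons)
  cand <- scored[scored$probability > threshold, , drop = FALSE]
  calls <- greedySelect(cand, oMax = oMax)
  rownames(calls) <- NULL
  calls
}
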