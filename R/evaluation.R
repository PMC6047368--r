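## Gene-level evaluation: a predicted call is a true positive when it
## overlaps an annotated gene by at least 60 bp on the same strand and in
## the same reading frame.  Matching is one-to-one, greedy by descending
## overlap, so one long call cannot claim several genes.  Truth genes with
## fewer than `minOverlap` nt inside the fragment are undetectable under
## this rule and are excluded from the false-negative count.

#' Match gene calls against truth annotations
#'
#' @param calls `data.frame` of calls with `fragment_id`, `start`, `end`,
#'   `strand`, `frame`.
#' @param truth `data.frame` of truth annotations in fragment coordinates
#'   (same columns; see [readAnnotations()] / [fragmentGenome()]).
#' @param minOverlap Minimum same-frame overlap (nt) for a true positive.
#' @return A list with integer counts `tp`, `fp`, `fn` and the `data.frame`
#'   `pairs` of matched call/truth row indices and overlap widths.
#' @export
matchCalls <- function(calls, truth, minOverlap = 60L) {
  evaluable <- which((truth$end - truth$start) >= minOverlap)
  dropped <- nrow(truth) - length(evaluable)
  if (dropped > 0L) {
    mgsLog(dropped, " truth gene(s) with < ", minOverlap,
           " nt inside the fragment excluded from FN counting")
  }
  if (nrow(calls) == 0L || length(evaluable) == 0L) {
    return(list(tp = 0L, fp = nrow(calls), fn = length(evaluable),
                pairs = data.frame(call = integer(), truth = integer(),
                                   overlap = integer())))
  }
  tr <- truth[evaluable, , drop = FALSE]
  key <- function(d) paste(d$fragment_id, d$strand, d$frame, sep = "\r")
  ck <- key(calls); tk <- key(tr)
  common <- intersect(unique(ck), unique(tk))
  cand <- list()
  for (k in common) {
    ci <- which(ck == k); ti <- which(tk == k)
    grid <- expand.grid(call = ci, truth = ti)
    ov <- intervalOverlap(calls$start[grid$call], calls$end[grid$call],
                          tr$start[grid$truth], tr$end[grid$truth])
    keep <- ov >= minOverlap
    if (any(keep)) {
      cand[[length(cand) + 1L]] <-
        data.frame(call = grid$call[keep], truth = grid$truth[keep],
                   overlap = ov[keep])
    }
  }
  pairs <- data.frame(call = integer(), truth = integer(), overlap = integer())
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$overlap, cand$call, cand$truth), , drop = FALSE]
    usedC <- logical(nrow(calls)); usedT <- logical(nrow(tr))
    sel <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!usedC[cand$call[i]] && !usedT[cand$truth[i]]) {
        sel[i] <- TRUE
        usedC[cand$call[i]] <- TRUE
        usedT[cand$truth[i]] <- TRUE
      }
    }
    pairs <- cand[sel, , drop = FALSE]
    pairs$truth <- evaluable[pairs$truth]
    rownames(pairs) <- NULL
  }
  tp <- nrow(pairs)
  list(tp = tp, fp = nrow(calls) - tp, fn = length(evaluable) - tp,
       pairs = pairs)
}

#' Sensitivity, specificity and harmonic mean from match counts
#'
#' `Sn = 100 * TP/(TP+FN)`, `Sp = 100 * TP/(TP+FP)`,
#' `H.M. = 2 * Sn * Sp / (Sn + Sp)`, all in percent.  A zero denominator
#' yields `NaN` with a warning.
#'
#' @param tp,fp,fn Integer counts.
#' @return An [EvalReport-class].
#' @export
#' @examples
#' evalMetrics(9, 0, 1)
evalMetrics <- function(tp, fp, fn) {
  mgsAssert(all(c(tp, fp, fn) >= 0), "counts must be non-negative")
  if (tp + fn == 0L) warning("no evaluable truth genes; sensitivity undefined")
  if (tp + fp == 0L) warning("no calls; specificity undefined")
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tp / (tp + fp)
  hm <- if (is.finite(sn) && is.finite(sp) && (sn + sp) > 0) {
    2 * sn * sp / (sn + sp)
  } else if (isTRUE(sn == 0) || isTRUE(sp == 0)) 0 else NaN
  new("EvalReport", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), sensitivity = sn, specificity = sp,
      harmonicMean = hm)
}

#' Harmonic mean of sensitivity and specificity
#'
#' `2 * Sn * Sp / (Sn + Sp)`, the single-number summary used throughout the
#' package's reports.
#'
#' @param sn,sp Sensitivity and specificity, in percent.
#' @return The harmonic mean, in percent.
#' @export
#' @examples
#' harmonicMeanOf(92.09, 97.67)
harmonicMeanOf <- function(sn, sp) 2 * sn * sp / (sn + sp)

#' Evaluate gene calls against truth annotations
#'
#' Convenience wrapper: [matchCalls()] followed by [evalMetrics()].
#'
#' @inheritParams matchCalls
#' @return An [EvalReport-class].
#' @export
evaluateCalls <- function(calls, truth, minOverlap = 60L) {
  m <- matchCalls(calls, truth, minOverlap = minOverlap)
  evalMetrics(m$tp, m$fp, m$fn)
}
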