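## S4 classes for the central objects: GC binning, mRMR selections, Platt
## calibration, the trained ensemble bundle, and evaluation reports.

#' GcBinning: mutually exclusive GC-content intervals
#'
#' Partition of the GC-percent axis `[0, 100]` into left-closed, right-open
#' intervals (the last interval is closed on the right).  With the default
#' nine interior boundaries this yields the ten ranges used to stratify
#' training data and route fragments to bin-specific models.
#'
#' @slot boundaries Numeric vector of strictly increasing interior boundary
#'   values in `(0, 100)`; `length(boundaries) + 1` bins are induced.
#' @seealso [defaultGcBinning()], [assignBin()]
#' @export
setClass("GcBinning", representation(boundaries = "numeric"))

setValidity("GcBinning", function(object) {
  b <- object@boundaries
  if (length(b) < 1L) return("at least one interior boundary is required")
  if (any(!is.finite(b))) return("boundaries must be finite")
  if (any(b <= 0) || any(b >= 100)) return("boundaries must lie in (0, 100)")
  if (any(diff(b) <= 0)) return("boundaries must be strictly increasing")
  TRUE
})

#' Default GC binning
#'
#' The ten standard GC ranges (percent): 0-36.57, 36.57-41.57, 41.57-46,
#' 46-50.14, 50.14-54.28, 54.28-58.14, 58.14-61.85, 61.85-65, 65-68.28,
#' 68.28-100.
#'
#' @return A [GcBinning-class] object with 10 bins.
#' @export
#' @examples
#' nBins(defaultGcBinning())
defaultGcBinning <- function() {
  new("GcBinning",
      boundaries = c(36.57, 41.57, 46, 50.14, 54.28, 58.14, 61.85, 65, 68.28))
}

#' @describeIn GcBinning-class Constructor from interior boundaries.
#' @param boundaries Numeric vector of interior boundaries.
#' @export
GcBinning <- function(boundaries) new("GcBinning", boundaries = as.numeric(boundaries))

#' @rdname GcBinning-class
#' @param object,x A `GcBinning`.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname GcBinning-class
#' @export
setMethod("nBins", "GcBinning", function(x) length(x@boundaries) + 1L)

#' @rdname GcBinning-class
#' @export
setGeneric("gcBoundaries", function(x) standardGeneric("gcBoundaries"))

#' @rdname GcBinning-class
#' @export
setMethod("gcBoundaries", "GcBinning", function(x) x@boundaries)

setMethod("show", "GcBinning", function(object) {
  b <- c(0, object@boundaries, 100)
  cat("GcBinning with", length(b) - 1L, "bins (percent GC):\n")
  cat(paste0(" [", head(b, -1L), ", ", b[-1L],
             c(rep(")", length(b) - 2L), "]")), fill = TRUE)
})

#' PlattModel: sigmoid posterior calibration parameters
#'
#' Parameters of the sigmoid `P(coding | f) = 1 / (1 + exp(A * f + B))`
#' mapping an SVM decision value `f` to a class posterior probability.
#' `A < 0` whenever larger decision values indicate the coding class.
#'
#' @slot A,B Finite numeric scalars.
#' @seealso [fitPlatt()], [plattPosterior()]
#' @export
setClass("PlattModel", representation(A = "numeric", B = "numeric"))

setValidity("PlattModel", function(object) {
  if (length(object@A) != 1L || length(object@B) != 1L)
    return("A and B must be scalars")
  if (!is.finite(object@A) || !is.finite(object@B))
    return("A and B must be finite")
  TRUE
})

setMethod("show", "PlattModel", function(object) {
  cat(sprintf("PlattModel: P(y=1|f) = 1/(1+exp(%.4g * f + %.4g))\n",
              object@A, object@B))
})

#' MrmrSelection: result of greedy mRMR (FCQ) feature selection
#'
#' @slot selected Integer vector of selected feature indices in selection
#'   order (most relevant first).
#' @slot relevance Numeric vector of per-feature F statistics over the full
#'   candidate pool.
#' @slot redundancy Matrix of absolute Pearson correlations among the
#'   selected features, in selection order.
#' @slot k Integer, the requested selection size.
#' @seealso [mrmrSelect()]
#' @export
setClass("MrmrSelection",
         representation(selected = "integer", relevance = "numeric",
                        redundancy = "matrix", k = "integer"))

setValidity("MrmrSelection", function(object) {
  if (anyDuplicated(object@selected)) return("selected indices must be distinct")
  if (length(object@selected) > 0 && any(object@selected < 1L))
    return("selected indices must be positive")
  if (any(object@relevance < 0, na.rm = TRUE))
    return("relevance (F statistics) must be non-negative")
  TRUE
})

#' @rdname MrmrSelection-class
#' @param x An `MrmrSelection`.
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname MrmrSelection-class
#' @export
setMethod("selectedFeatures", "MrmrSelection", function(x) x@selected)

#' @rdname MrmrSelection-class
#' @export
setGeneric("relevance", function(x) standardGeneric("relevance"))

#' @rdname MrmrSelection-class
#' @export
setMethod("relevance", "MrmrSelection", function(x) x@relevance)

setMethod("show", "MrmrSelection", function(object) {
  cat("MrmrSelection:", length(object@selected), "of", length(object@relevance),
      "features selected (k =", object@k, ")\n")
  n <- min(5L, length(object@selected))
  if (n > 0)
    cat(" first picks:", paste(object@selected[seq_len(n)], collapse = ", "), "\n")
})

#' ModelBundle: GC-stratified ensemble of calibrated SVM gene models
#'
#' Everything needed to score candidate ORFs: the GC binning, and per bin the
#' selected feature indices, standardization statistics, a fitted RBF-SVM,
#' its decision-value orientation, and the Platt calibration.  Untrained bins
#' (no training data in that GC range) hold `NULL` and raise an error at
#' prediction time.
#'
#' @slot binning A [GcBinning-class].
#' @slot models List of length `nBins(binning)`; each element is `NULL` or a
#'   list with components `selected`, `center`, `scale`, `svm`, `flip`,
#'   `platt`, `nPos`, `nNeg`, `cost`, `gamma`.
#' @slot featureNames Character vector: the full feature name order the
#'   models were trained against.
#' @slot params List of training parameters (grids, seeds, subsample sizes).
#' @seealso [trainEnsemble()], [predictFragments()]
#' @export
setClass("ModelBundle",
         representation(binning = "GcBinning", models = "list",
                        featureNames = "character", params = "list"))

setValidity("ModelBundle", function(object) {
  if (length(object@models) != nBins(object@binning))
    return("one model slot per GC bin is required")
  for (m in object@models) {
    if (is.null(m)) next
    need <- c("selected", "center", "scale", "svm", "flip", "platt",
              "nPos", "nNeg", "cost", "gamma")
    if (!all(need %in% names(m)))
      return(paste("trained bin is missing components:",
                   paste(setdiff(need, names(m)), collapse = ", ")))
  }
  TRUE
})

#' @rdname ModelBundle-class
#' @param x A `ModelBundle`.
#' @export
setGeneric("binModels", function(x) standardGeneric("binModels"))

#' @rdname ModelBundle-class
#' @export
setMethod("binModels", "ModelBundle", function(x) x@models)

#' @rdname ModelBundle-class
#' @export
setGeneric("gcBinning", function(x) standardGeneric("gcBinning"))

#' @rdname ModelBundle-class
#' @export
setMethod("gcBinning", "ModelBundle", function(x) x@binning)

setMethod("show", "ModelBundle", function(object) {
  trained <- which(!vapply(object@models, is.null, logical(1)))
  cat("ModelBundle:", nBins(object@binning), "GC bins,",
      length(trained), "trained\n")
  for (b in trained) {
    m <- object@models[[b]]
    cat(sprintf("  bin %d: %d features, cost=%g gamma=%g, N+=%d N-=%d\n",
                b, length(m$selected) + 3L, m$cost, m$gamma, m$nPos, m$nNeg))
  }
})

#' EvalReport: gene-level prediction accuracy
#'
#' Counts of true positives, false positives and false negatives under the
#' 60-bp same-strand same-frame matching rule, and the derived percentages
#' sensitivity `100*TP/(TP+FN)`, specificity `100*TP/(TP+FP)` and their
#' harmonic mean `2*Sn*Sp/(Sn+Sp)`.
#'
#' @slot tp,fp,fn Integer counts.
#' @slot sensitivity,specificity,harmonicMean Percent values in `[0, 100]`
#'   (`NaN` when a denominator is zero).
#' @seealso [evalMetrics()], [evaluateCalls()]
#' @export
setClass("EvalReport",
         representation(tp = "integer", fp = "integer", fn = "integer",
                        sensitivity = "numeric", specificity = "numeric",
                        harmonicMean = "numeric"))

setValidity("EvalReport", function(object) {
  cnt <- c(object@tp, object@fp, object@fn)
  if (any(cnt < 0)) return("counts must be non-negative")
  pct <- c(object@sensitivity, object@specificity, object@harmonicMean)
  if (any(pct < -1e-9 | pct > 100 + 1e-9, na.rm = TRUE))
    return("percentages must lie in [0, 100]")
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: TP=%d FP=%d FN=%d\n", object@tp, object@fp, object@fn))
  cat(sprintf("  sensitivity  %6.2f%%\n", object@sensitivity))
  cat(sprintf("  specificity  %6.2f%%\n", object@specificity))
  cat(sprintf("  harmonic mean %5.2f%%\n", object@harmonicMean))
})

#' @rdname EvalReport-class
#' @param x An `EvalReport`.
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))
#' @rdname EvalReport-class
#' @export
setMethod("sensitivity", "EvalReport", function(x) x@sensitivity)
#' @rdname EvalReport-class
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))
#' @rdname EvalReport-class
#' @export
setMethod("specificity", "EvalReport", function(x) x@specificity)
#' @rdname EvalReport-class
#' @export
setGeneric("harmonicMean", function(x) standardGeneric("harmonicMean"))
#' @rdname EvalReport-class
#' @export
setMethod("harmonicMean", "EvalReport", function(x) x@harmonicMean)
#' @rdname EvalReport-class
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname EvalReport-class
#' @export
setMethod("counts", "EvalReport",
          function(x) c(tp = x@tp, fp = x@fp, fn = x@fn))
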