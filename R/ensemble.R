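## GC-stratified ensemble training: partition labelled ORFs by the GC
## content of their parent read, per bin run mRMR on a selection subsample,
## standardize, grid-search RBF-SVM parameters, fit the SVM, and calibrate
## a Platt sigmoid on a held-out split of the bin's data.

#' Assign GC percentages to bins
#'
#' Intervals are left-closed and right-open; the final interval is closed
#' at 100.
#'
#' @param gc Numeric vector of GC percentages in `[0, 100]`.
#' @param binning A [GcBinning-class] (default [defaultGcBinning()]).
#' @return Integer bin indices in `1..nBins(binning)`.
#' @export
#' @examples
#' assignBin(c(0, 36.57, 100))
assignBin <- function(gc, binning = defaultGcBinning()) {
  mgsAssert(all(is.finite(gc)) && all(gc >= 0) && all(gc <= 100),
            "gc values must lie in [0, 100]")
  findInterval(gc, gcBoundaries(binning)) + 1L
}

#' Grid search for RBF-SVM cost and gamma
#'
#' Exhaustive search over a cost/gamma grid by stratified cross-validated
#' accuracy.  Ties are broken toward the smaller cost, then the smaller
#' gamma, so the result is deterministic for a given seed.
#'
#' @param X Numeric matrix (samples x features), already standardized.
#' @param labels Binary label vector.
#' @param costs,gammas Numeric grids.  Defaults span the usual optima for
#'   this problem (cost 100, gamma 1.5-2) and smaller values.
#' @param folds Number of CV folds.
#' @param seed Integer seed for fold assignment.
#' @param classWeights Optional named class weights passed to
#'   [e1071::svm()].
#' @return A list with `cost`, `gamma` and the full `accuracy` grid.
#' @export
gridSearchRbf <- function(X, labels,
                          costs = c(0.1, 1, 10, 100, 1000),
                          gammas = c(0.01, 0.1, 0.5, 1, 1.5, 2),
                          folds = 5L, seed = 1L, classWeights = NULL) {
  mgsAssert(length(costs) >= 1L && length(gammas) >= 1L,
            "grids must be non-empty")
  y <- factor(labels)
  mgsAssert(nlevels(y) == 2L, "labels must contain exactly two classes")
  mgsAssert(folds >= 2L && folds <= min(table(y)),
            "degenerate fold count for the class sizes")
  fold <- stratifiedFolds(labels, folds, substreamSeed(seed, "grid-folds"))
  grid <- expand.grid(gamma = sort(gammas), cost = sort(costs))
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (fd in seq_len(folds)) {
      te <- fold == fd
      fit <- e1071::svm(X[!te, , drop = FALSE], y[!te], type = "C-classification",
                        kernel = "radial", cost = grid$cost[i],
                        gamma = grid$gamma[i], scale = FALSE,
                        class.weights = classWeights)
      pred <- predict(fit, X[te, , drop = FALSE])
      correct <- correct + sum(pred == y[te])
    }
    correct / length(y)
  }, numeric(1))
  best <- order(-acc, grid$cost, grid$gamma)[1L]
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       accuracy = cbind(grid, accuracy = acc))
}

## Fit one bin: mRMR -> standardize -> grid search -> SVM -> Platt.
trainBinModel <- function(X, y, kFeatures, selectionSubsample, gridSubsample,
                          calibFraction, costs, gammas, folds, seed,
                          classWeights) {
  n <- nrow(X)
  selSeed <- substreamSeed(seed, "selection")
  selIdx <- seq_len(n)
  if (is.finite(selectionSubsample) && selectionSubsample < n) {
    set.seed(selSeed)
    selIdx <- sort(sample.int(n, selectionSubsample))
  }
  pool <- seq_len(N_USAGE) # scalar features bypass selection
  sel <- mrmrSelect(X[selIdx, pool, drop = FALSE], y[selIdx],
                    min(kFeatures, length(pool)))
  featCols <- c(selectedFeatures(sel), N_USAGE + 1:3)

  hold <- stratifiedHoldout(y, calibFraction, substreamSeed(seed, "calib"))
  Xtr <- as.matrix(X[!hold, featCols, drop = FALSE])
  ytr <- y[!hold]
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2L, sd)
  scale[scale < 1e-12] <- 1
  Xtr <- scale(Xtr, center, scale)

  gridIdx <- seq_len(nrow(Xtr))
  if (is.finite(gridSubsample) && gridSubsample < nrow(Xtr)) {
    set.seed(substreamSeed(seed, "grid-sub"))
    gridIdx <- sort(sample.int(nrow(Xtr), gridSubsample))
  }
  gs <- gridSearchRbf(Xtr[gridIdx, , drop = FALSE], ytr[gridIdx],
                      costs = costs, gammas = gammas, folds = folds,
                      seed = substreamSeed(seed, "grid"),
                      classWeights = classWeights)
  fit <- e1071::svm(Xtr, factor(ytr), type = "C-classification",
                    kernel = "radial", cost = gs$cost, gamma = gs$gamma,
                    scale = FALSE, class.weights = classWeights)

  Xcal <- scale(as.matrix(X[hold, featCols, drop = FALSE]), center, scale)
  ycal <- y[hold]
  dv <- attr(predict(fit, Xcal, decision.values = TRUE), "decision.values")[, 1L]
  flip <- if (mean(dv[ycal == 1]) >= mean(dv[ycal == 0])) 1 else -1
  platt <- fitPlatt(flip * dv, ycal)

  list(selected = selectedFeatures(sel), center = center, scale = scale,
       svm = fit, flip = flip, platt = platt,
       nPos = sum(ytr == 1), nNeg = sum(ytr == 0),
       cost = gs$cost, gamma = gs$gamma, grid = gs$accuracy, seed = seed)
}

#' Train the GC-stratified SVM ensemble
#'
#' Partitions labelled ORFs into GC bins by the GC content of their parent
#' read and fits one calibrated RBF-SVM per non-empty bin.  Within a bin:
#' mRMR selects `kFeatures` usage features on a subsample (the three scalar
#' features -- GC percent and the two length ratios -- always bypass
#' selection and are appended); features are standardized on the training
#' split; cost and gamma come from a cross-validated grid search; and the
#' Platt sigmoid is calibrated on a held-out split to avoid the optimistic
#' bias of calibrating on training decision values.
#'
#' Bins with no data or a single class are left untrained; scoring a
#' fragment that falls in such a bin raises an error naming it.
#'
#' @param features Feature matrix from [extractFeatures()] (rows = ORFs).
#' @param labels Binary labels (1 = coding) aligned with `features`.
#' @param gc GC percent of each ORF's parent read.
#' @param binning A [GcBinning-class].
#' @param kFeatures Number of usage features selected per bin (default
#'   500).
#' @param selectionSubsample Max ORFs used for mRMR per bin (`Inf` = all).
#' @param trainSubsample Max ORFs used for SVM training per bin.
#' @param gridSubsample Max ORFs used during the grid search.
#' @param calibFraction Fraction of the bin held out for Platt calibration.
#' @param costs,gammas Grid-search grids (see [gridSearchRbf()]).
#' @param folds CV folds for the grid search.
#' @param seed Master seed; all stochastic steps derive named substreams.
#' @param classWeights Optional named class weights (`"0"`, `"1"`).
#' @param minClassCount Minimum number of ORFs of each class a bin needs to
#'   be trained; sparser bins are left untrained.
#' @return A [ModelBundle-class].
#' @export
trainEnsemble <- function(features, labels, gc,
                          binning = defaultGcBinning(),
                          kFeatures = 500L,
                          selectionSubsample = Inf,
                          trainSubsample = Inf,
                          gridSubsample = 2000L,
                          calibFraction = 0.25,
                          costs = c(0.1, 1, 10, 100, 1000),
                          gammas = c(0.01, 0.1, 0.5, 1, 1.5, 2),
                          folds = 5L, seed = 1L, classWeights = NULL,
                          minClassCount = 10L) {
  mgsAssert(nrow(features) == length(labels) && length(labels) == length(gc),
            "features, labels and gc must be aligned")
  labels <- as.integer(labels)
  mgsAssert(all(labels %in% c(0L, 1L)), "labels must be 0/1")
  bins <- assignBin(gc, binning)
  models <- vector("list", nBins(binning))
  for (b in sort(unique(bins))) {
    idx <- which(bins == b)
    if (min(table(factor(labels[idx], levels = 0:1))) < minClassCount) {
      mgsLog("bin ", b, " has too few ORFs of one class; left untrained")
      next
    }
    bseed <- substreamSeed(seed, paste0("bin-", b))
    if (is.finite(trainSubsample) && trainSubsample < length(idx)) {
      set.seed(substreamSeed(bseed, "train-sub"))
      keep <- logical(length(idx))
      for (cl in 0:1) {
        cli <- which(labels[idx] == cl)
        nk <- min(length(cli),
                  max(2L, round(trainSubsample * length(cli) / length(idx))))
        keep[sample(cli, nk)] <- TRUE
      }
      idx <- idx[keep]
    }
    mgsLog("training bin ", b, " on ", length(idx), " ORFs (",
           sum(labels[idx] == 1), " coding)")
    models[[b]] <- trainBinModel(
      features[idx, , drop = FALSE], labels[idx], kFeatures,
      selectionSubsample, gridSubsample, calibFraction, costs, gammas,
      folds, bseed, classWeights)
  }
  new("ModelBundle", binning = binning, models = models,
      featureNames = colnames(features),
      params = list(kFeatures = kFeatures,
                    selectionSubsample = selectionSubsample,
                    trainSubsample = trainSubsample,
                    gridSubsample = gridSubsample,
                    calibFraction = calibFraction,
                    costs = costs, gammas = gammas, folds = folds,
                    seed = seed))
}

#' Save / load a trained model bundle
#'
#' The bundle directory holds a human-readable `metadata.json` (binning
#' boundaries, training parameters, per-bin summaries) and one serialized
#' model file per trained bin.  `loadModelBundle()` restores an object that
#' produces bit-identical predictions.
#'
#' @param bundle A [ModelBundle-class].
#' @param dir Bundle directory (created if needed).
#' @return `dir` (save) or the restored [ModelBundle-class] (load).
#' @export
saveModelBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  trained <- which(!vapply(bundle@models, is.null, logical(1)))
  meta <- list(
    class = "MetaGeneSVM::ModelBundle",
    boundaries = gcBoundaries(bundle@binning),
    n_bins = nBins(bundle@binning),
    trained_bins = as.integer(trained),
    params = bundle@params[setdiff(names(bundle@params),
                                   c("costs", "gammas"))],
    grids = list(costs = bundle@params$costs, gammas = bundle@params$gammas),
    bins = lapply(trained, function(b) {
      m <- bundle@models[[b]]
      list(bin = b, cost = m$cost, gamma = m$gamma, n_pos = m$nPos,
           n_neg = m$nNeg, platt_A = m$platt@A, platt_B = m$platt@B,
           n_selected = length(m$selected))
    }))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(bundle@featureNames, file.path(dir, "feature_names.txt"))
  for (b in trained) {
    saveRDS(bundle@models[[b]], file.path(dir, sprintf("bin_%02d.rds", b)))
  }
  invisible(dir)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(dir) {
  metaPath <- file.path(dir, "metadata.json")
  mgsAssert(file.exists(metaPath), paste0("not a model bundle: ", dir))
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  binning <- GcBinning(meta$boundaries)
  models <- vector("list", nBins(binning))
  for (b in meta$trained_bins) {
    models[[b]] <- readRDS(file.path(dir, sprintf("bin_%02d.rds", b)))
  }
  params <- as.list(meta$params)
  params$costs <- meta$grids$costs
  params$gammas <- meta$grids$gammas
  new("ModelBundle", binning = binning, models = models,
      featureNames = readLines(file.path(dir, "feature_names.txt")),
      params = params)
}
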