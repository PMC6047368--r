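## Minimum-redundancy-maximum-relevance feature selection, FCQ variant:
## relevance is the two-group ANOVA F statistic of a feature against the
## class label, redundancy the mean absolute Pearson correlation with the
## already-selected features, and a candidate's score is the quotient of the
## two.  Selection is greedy forward: the first pick maximizes F alone.
## Also provides the kNN cross-validated error curve used to choose the
## feature-set size.

#' Two-group ANOVA F statistic per feature
#'
#' One-way F statistic (between-group mean square over within-group mean
#' square) of each feature column against a binary label, equal to the
#' square of the pooled two-sample t statistic.  A feature with zero
#' between- and within-group variance has F = 0; zero within-group variance
#' with positive separation gives `Inf`.
#'
#' @param X Numeric matrix or sparse `Matrix` (samples x features).
#' @param labels Binary vector (two distinct values, each with >= 2
#'   samples).
#' @return Numeric vector of F statistics, one per column.
#' @export
#' @examples
#' fStat(cbind(f = c(1, 2, 3, 4)), c(0, 0, 1, 1))
fStat <- function(X, labels) {
  if (is.null(dim(X))) X <- cbind(X)
  lev <- sort(unique(labels))
  mgsAssert(length(lev) == 2L, "labels must contain exactly two classes")
  g1 <- labels == lev[2L]
  n1 <- sum(g1); n0 <- sum(!g1); n <- n1 + n0
  mgsAssert(n1 >= 2L && n0 >= 2L, "each class needs at least two samples")
  s1 <- Matrix::colSums(X[g1, , drop = FALSE])
  s0 <- Matrix::colSums(X[!g1, , drop = FALSE])
  ss <- Matrix::colSums(X^2)
  m1 <- s1 / n1; m0 <- s0 / n0; m <- (s1 + s0) / n
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  sst <- ss - n * m^2
  ssw <- pmax(sst - ssb, 0)
  msw <- ssw / (n - 2L)
  f <- ifelse(ssb <= 1e-12 * pmax(1, abs(sst)), 0,
              ifelse(msw <= 0, Inf, ssb / msw))
  as.numeric(f)
}

#' Greedy mRMR feature selection with the FCQ criterion
#'
#' Forward selection over the feature columns of `X`: the first feature
#' maximizes the F statistic against the labels; each subsequent pick
#' maximizes `F(i) / mean_j |cor(i, j)|` over the already-selected features
#' `j`.  Constant columns (undefined correlation) are excluded from
#' candidacy.  Ties are broken by larger F, then lower column index, so the
#' result is deterministic.
#'
#' @param X Numeric matrix or sparse `Matrix` (samples x features).
#' @param labels Binary label vector.
#' @param k Number of features to select (capped at the number of
#'   non-constant columns, with a warning if fewer are available).
#' @return An [MrmrSelection-class] with the selection order, the relevance
#'   vector and the pairwise absolute-correlation matrix of the selection.
#' @export
mrmrSelect <- function(X, labels, k) {
  mgsAssert(k >= 1, "k must be at least 1")
  if (is.null(dim(X))) X <- cbind(X)
  p <- ncol(X)
  mgsAssert(p >= 1L, "X must have at least one feature")
  n <- nrow(X)
  f <- fStat(X, labels)
  mu <- Matrix::colMeans(X)
  sdv <- sqrt(pmax(Matrix::colSums(X^2) / n - mu^2, 0) * n / (n - 1L))
  candidates <- which(sdv > 1e-12)
  if (k > length(candidates)) {
    warning("k exceeds the number of usable features; selecting all ",
            length(candidates))
    k <- length(candidates)
  }
  selected <- integer(0)
  sumAbs <- numeric(p)
  absMat <- matrix(0, k, k)
  # Exact ties (e.g. duplicated columns) must resolve by larger F then
  # lower index regardless of last-bit noise in the BLAS reductions, so
  # scores within a relative 1e-9 of the maximum are treated as tied.
  pickBest <- function(score, fc, cand) {
    smax <- max(score)
    near <- if (is.infinite(smax)) is.infinite(score) & score > 0
            else (smax - score) <= 1e-9 * max(abs(smax), 1)
    i <- which(near)[order(-fc[near], cand[near])[1L]]
    cand[i]
  }
  for (step in seq_len(k)) {
    if (step == 1L) {
      pick <- pickBest(f[candidates], f[candidates], candidates)
    } else {
      last <- selected[length(selected)]
      xl <- as.numeric(X[, last])
      cp <- as.numeric(Matrix::crossprod(X, xl))
      r <- (cp - n * mu * mu[last]) / ((n - 1L) * sdv * sdv[last])
      r[!is.finite(r)] <- 0
      sumAbs <- sumAbs + abs(r)
      absMat[step - 1L, seq_len(step - 1L)] <-
        absMat[seq_len(step - 1L), step - 1L] <- abs(r[selected])
      meanAbs <- pmax(sumAbs[candidates] / length(selected),
                      .Machine$double.eps)
      score <- f[candidates] / meanAbs
      pick <- pickBest(score, f[candidates], candidates)
    }
    selected <- c(selected, pick)
    candidates <- candidates[candidates != pick]
    if (length(candidates) == 0L && step < k) break
  }
  ns <- length(selected)
  red <- absMat[seq_len(ns), seq_len(ns), drop = FALSE]
  diag(red) <- 1
  selected <- as.integer(unname(selected))
  dimnames(red) <- list(selected, selected)
  new("MrmrSelection", selected = selected, relevance = pmax(f, 0),
      redundancy = red, k = as.integer(k))
}

#' Cross-validated kNN error for nested mRMR feature sets
#'
#' For each requested size `s`, computes the stratified cross-validated
#' k-nearest-neighbour misclassification rate using the first `s` features
#' in mRMR selection order.  Used to locate the plateau of the error curve
#' when choosing how many features to keep.
#'
#' @param X Feature matrix (samples x features).
#' @param labels Binary label vector.
#' @param sizes Integer vector of feature-set sizes to evaluate.
#' @param selection Optional [MrmrSelection-class]; computed with
#'   `k = max(sizes)` when missing.
#' @param nNeighbors Number of neighbours (odd values avoid vote ties).
#' @param folds Number of CV folds.
#' @param seed Integer seed controlling fold assignment.
#' @return A `data.frame` with columns `size` and `error`.
#' @export
knnErrorCurve <- function(X, labels, sizes, selection = NULL,
                          nNeighbors = 5L, folds = 5L, seed = 1L) {
  if (is.null(dim(X))) X <- cbind(X)
  sizes <- sort(unique(as.integer(sizes)))
  mgsAssert(all(sizes >= 1L) && all(sizes <= ncol(X)),
            "sizes must lie in [1, feature count]")
  tab <- table(labels)
  mgsAssert(length(tab) == 2L, "labels must contain exactly two classes")
  mgsAssert(folds <= min(tab), "more folds than samples in a class")
  if (is.null(selection)) selection <- mrmrSelect(X, labels, max(sizes))
  ord <- selectedFeatures(selection)
  mgsAssert(max(sizes) <= length(ord), "sizes exceed the selection length")
  fold <- stratifiedFolds(labels, folds, substreamSeed(seed, "knn-folds"))
  Xd <- as.matrix(X[, ord, drop = FALSE])
  y <- factor(labels)
  err <- vapply(sizes, function(s) {
    wrong <- 0L
    for (fd in seq_len(folds)) {
      te <- fold == fd
      set.seed(substreamSeed(seed, paste0("knn-", s, "-", fd)))
      pred <- class::knn(Xd[!te, seq_len(s), drop = FALSE],
                         Xd[te, seq_len(s), drop = FALSE],
                         y[!te], k = nNeighbors)
      wrong <- wrong + sum(pred != y[te])
    }
    wrong / length(y)
  }, numeric(1))
  data.frame(size = sizes, error = err)
}

#' Choose a feature-set size from an error curve
#'
#' Returns the smallest size after which no larger size improves the error
#' by at least `minGain` -- i.e. the start of the curve's plateau.
#'
#' @param curve A `data.frame` with columns `size` and `error`.
#' @param minGain Minimum improvement considered meaningful (default 0.001,
#'   i.e. 0.1 percentage points of error).
#' @return The chosen size (integer).
#' @export
#' @examples
#' chooseFeatureCount(data.frame(size = c(10, 20, 30),
#'                               error = c(0.2, 0.1, 0.0999)))
chooseFeatureCount <- function(curve, minGain = 0.001) {
  mgsAssert(nrow(curve) >= 1L, "curve must be non-empty")
  o <- order(curve$size)
  sizes <- curve$size[o]
  err <- curve$error[o]
  ns <- length(sizes)
  for (i in seq_len(ns)) {
    later <- if (i < ns) min(err[(i + 1L):ns]) else Inf
    if (err[i] - later < minGain) return(sizes[i])
  }
  sizes[ns]
}
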