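test_that("the F statistic matches hand ANOVA and the two-sample t oracle", {
  # class 0 = {1,2}, class 1 = {3,4}: SSB = 4 on 1 df, MSW = 0.5 on 2 df
  expect_equal(fStat(cbind(c(1, 2, 3, 4)), c(0, 0, 1, 1)), 8)
  expect_equal(fStat(cbind(rep(5, 6)), c(0, 0, 0, 1, 1, 1)), 0)

  set.seed(11)
  y <- rep(0:1, each = 25)
  X <- matrix(rnorm(50 * 50), 50, 50)
  f <- fStat(X, y)
  fOracle <- apply(X, 2, oracleFtest, y = y)
  expect_equal(f, fOracle, tolerance = 1e-10)

  expect_error(fStat(cbind(1:4), c(1, 1, 1, 1)), "two classes")
  expect_error(fStat(cbind(1:3), c(0, 1, 1)), "two samples")
})

test_that("k = 1 selects the single most relevant feature", {
  set.seed(3)
  y <- rep(0:1, each = 30)
  X <- cbind(noise1 = rnorm(60), signal = y + rnorm(60, sd = 0.3),
             noise2 = rnorm(60))
  sel <- mrmrSelect(X, y, 1)
  expect_equal(selectedFeatures(sel), 2L)
})

test_that("an exact duplicate of a selected feature is deferred", {
  set.seed(4)
  y <- rep(0:1, each = 50)
  signal <- y + rnorm(100, sd = 0.4)
  indep <- y + rnorm(100, sd = 0.4) # equally relevant but independent noise
  X <- cbind(signal, dup = signal, indep, noise = rnorm(100))
  sel <- selectedFeatures(mrmrSelect(X, y, 3))
  expect_equal(sel[1], 1L)
  # the duplicate (|cor| = 1 with its twin) must not precede the
  # independent, comparably relevant feature
  expect_true(which(sel == 3L) < which(sel == 2L) || !(2L %in% sel))
})

test_that("greedy selection matches the brute-force rescan oracle", {
  set.seed(12)
  for (i in 1:30) {
    p <- sample(4:12, 1)
    n <- 200
    y <- rep(0:1, each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    informative <- sample(p, sample(2:3, 1))
    for (j in informative) X[, j] <- X[, j] + y * runif(1, 0.5, 2)
    k <- sample(2:p, 1)
    expect_equal(selectedFeatures(mrmrSelect(X, y, k)), oracleMrmr(X, y, k),
                 label = paste("instance", i))
  }
})

test_that("selection is invariant to positive feature scaling", {
  set.seed(21)
  y <- rep(0:1, each = 40)
  X <- matrix(rnorm(80 * 8), 80, 8)
  X[, 2] <- X[, 2] + y; X[, 5] <- X[, 5] + 0.7 * y
  scl <- diag(runif(8, 0.1, 50))
  a <- mrmrSelect(X, y, 4)
  b <- mrmrSelect(X %*% scl, y, 4)
  expect_identical(selectedFeatures(a), selectedFeatures(b))
  expect_equal(relevance(a), relevance(b), tolerance = 1e-9)
})

test_that("permuting feature columns permutes the selection accordingly", {
  set.seed(22)
  y <- rep(0:1, each = 40)
  X <- matrix(rnorm(80 * 6), 80, 6)
  X[, 1] <- X[, 1] + 2 * y; X[, 4] <- X[, 4] + y
  perm <- sample(6)
  a <- selectedFeatures(mrmrSelect(X, y, 3))
  b <- selectedFeatures(mrmrSelect(X[, perm], y, 3))
  expect_identical(perm[b], a)
})

test_that("asking for more features than available warns and selects all", {
  set.seed(8)
  y <- rep(0:1, each = 10)
  X <- matrix(rnorm(20 * 3), 20, 3)
  expect_warning(sel <- mrmrSelect(X, y, 10), "exceeds")
  expect_equal(length(selectedFeatures(sel)), 3L)
})

test_that("the kNN error curve is seeded-deterministic and flat-zero on separable data", {
  set.seed(14)
  y <- rep(0:1, each = 40)
  X <- cbind(sig1 = 5 * y + rnorm(80, sd = 0.1),
             sig2 = -3 * y + rnorm(80, sd = 0.1),
             matrix(rnorm(80 * 4), 80, 4))
  curve1 <- knnErrorCurve(X, y, sizes = c(1, 3, 6), folds = 4, seed = 9)
  curve2 <- knnErrorCurve(X, y, sizes = c(1, 3, 6), folds = 4, seed = 9)
  expect_identical(curve1, curve2)
  expect_equal(curve1$error[curve1$size == 6], 0)
  expect_error(knnErrorCurve(X, y, sizes = 2, folds = 50), "folds")
})

test_that("the plateau rule picks the documented feature-set size", {
  # strictly decreasing by > 0.1% up to 300, by < 0.1% afterwards
  curve <- data.frame(size = c(60, 200, 250, 300, 350, 400, 450, 500),
                      error = c(0.0400, 0.0300, 0.0265, 0.0253,
                                0.02525, 0.0252, 0.02515, 0.0251))
  expect_equal(chooseFeatureCount(curve), 300)
  expect_equal(chooseFeatureCount(data.frame(size = 10, error = 0.5)), 10)
  flat <- data.frame(size = c(5, 10, 20), error = c(0.1, 0.1, 0.1))
  expect_equal(chooseFeatureCount(flat), 5)
})
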