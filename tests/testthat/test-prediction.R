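mkCand <- function(start, end, prob, strand = "+", frag = "f1") {
  data.frame(fragment_id = frag, start = start, end = end, strand = strand,
             frame = start %% 3L, probability = prob, stringsAsFactors = FALSE)
}

test_that("greedy overlap resolution follows the highest-probability-first rule", {
  one <- mkCand(0L, 300L, 0.7)
  expect_equal(nrow(greedySelect(one)), 1L)

  # overlap 100 > 60: only the stronger call survives
  two <- rbind(mkCand(0L, 300L, 0.9), mkCand(200L, 500L, 0.8))
  sel <- greedySelect(two)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$start, 0L)

  # overlap 50 <= 60: both survive
  two2 <- rbind(mkCand(0L, 300L, 0.9), mkCand(250L, 550L, 0.8))
  sel2 <- greedySelect(two2)
  expect_equal(nrow(sel2), 2L)
  expect_equal(sel2$start, c(0L, 250L))

  # overlap is measured across strands
  xs <- rbind(mkCand(0L, 300L, 0.9), mkCand(100L, 400L, 0.8, strand = "-"))
  expect_equal(nrow(greedySelect(xs)), 1L)
})

test_that("greedy selection equals the step-by-step oracle on random candidate sets", {
  set.seed(61)
  for (i in 1:300) {
    n <- sample(1:8, 1)
    starts <- sample(0:600, n, replace = TRUE)
    lens <- sample(60:400, n, replace = TRUE)
    df <- data.frame(fragment_id = "f", start = starts,
                     end = pmin(700, starts + lens),
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     frame = starts %% 3L,
                     probability = round(runif(n, 0.5, 1), 2), # ties likely
                     stringsAsFactors = FALSE)
    got <- greedySelect(df)
    want <- oracleGreedy(df)
    rownames(got) <- NULL
    expect_equal(got, want, label = paste("set", i))
  }
})

test_that("adding a weaker candidate never changes the stronger selections", {
  set.seed(62)
  base <- rbind(mkCand(0L, 300L, 0.95), mkCand(350L, 650L, 0.85))
  weak <- mkCand(100L, 400L, 0.6)
  sel <- greedySelect(rbind(base, weak))
  selBase <- greedySelect(base)
  expect_true(all(paste(selBase$start, selBase$end) %in%
                  paste(sel$start, sel$end)))
})

test_that("every emitted pair of calls overlaps at most o_max", {
  set.seed(63)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    starts <- sample(0:640, n, replace = TRUE)
    df <- data.frame(fragment_id = "f", start = starts,
                     end = pmin(700L, starts + sample(60:500, n, TRUE)),
                     strand = sample(c("+", "-"), n, TRUE),
                     frame = starts %% 3L,
                     probability = runif(n, 0.5, 1), stringsAsFactors = FALSE)
    sel <- greedySelect(df)
    if (nrow(sel) > 1) {
      for (a in 1:(nrow(sel) - 1)) for (b in (a + 1):nrow(sel)) {
        ov <- max(0, min(sel$end[a], sel$end[b]) - max(sel$start[a], sel$start[b]))
        expect_lte(ov, 60)
      }
    }
  }
})

test_that("full prediction respects the threshold and is monotone in it", {
  bundle <- testBundle()
  held <- testHeldOut()
  frags <- held$fragments[1:30]
  lo <- predictFragments(frags, bundle, threshold = 0.5)
  hi <- predictFragments(frags, bundle, threshold = 0.9)
  expect_true(all(lo$probability > 0.5))
  expect_true(all(hi$probability > 0.9))
  keyLo <- paste(lo$fragment_id, lo$start, lo$end, lo$strand)
  keyHi <- paste(hi$fragment_id, hi$start, hi$end, hi$strand)
  # raising the threshold never adds a call: a suppressor always has the
  # higher probability, so a threshold that removes it removes its victims
  expect_true(all(keyHi %in% keyLo))
  expect_lte(nrow(hi), nrow(lo))

  none <- predictFragments(frags, bundle, threshold = 1 - 1e-12)
  expect_equal(nrow(none), 0L)
})
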