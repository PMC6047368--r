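test_that("usage blocks have the fixed dimensions and worked-out values", {
  expect_equal(ncol(monocodonUsage("ATGATG")), 64L)
  expect_equal(ncol(dicodonUsage("ATGATGATG")), 4096L)
  expect_equal(ncol(monoaminoUsage("ATGATG")), 20L)
  expect_equal(ncol(diaminoUsage("ATGAAATAG")), 441L)
  expect_equal(length(featureNames()), 64L + 4096L + 20L + 441L + 3L)

  m <- monocodonUsage("ATGATG")
  expect_equal(unname(m[1, "ATG"]), 1)
  expect_equal(sum(m), 1)
  m2 <- monocodonUsage("ATGAAA")
  expect_equal(unname(m2[1, c("ATG", "AAA")]), c(0.5, 0.5))

  d <- dicodonUsage("ATGAAATAG")
  expect_equal(unname(d[1, c("ATGAAA", "AAATAG")]), c(0.5, 0.5))
  expect_equal(sum(d), 1)
  expect_equal(unname(dicodonUsage("ATGATGATG")[1, "ATGATG"]), 1)

  a <- monoaminoUsage("ATGATG")
  expect_equal(unname(a[1, "M"]), 1)

  # M K * translates to pairs MK and K*
  dd <- diaminoUsage("ATGAAATAG")
  expect_equal(unname(dd[1, c("MK", "K*")]), c(0.5, 0.5))
  expect_equal(sum(dd), 1)
})

test_that("stop codons count in codon blocks but not in monoamino usage", {
  a <- monoaminoUsage("ATGAAATAG") # M K *
  expect_equal(unname(a[1, c("M", "K")]), c(0.5, 0.5))
  expect_equal(sum(a), 1) # stop excluded from denominator
  m <- monocodonUsage("ATGAAATAG")
  expect_equal(unname(m[1, "TAG"]), 1 / 3)
})

test_that("degenerate inputs behave as specified", {
  expect_error(monocodonUsage("AT"), "at least one codon")
  expect_error(dicodonUsage("ATG"), "at least two codons")
  # all-stop translation: empty monoamino block, all zeros
  expect_equal(sum(monoaminoUsage("TAGTAA")), 0)
})

test_that("length ratios are mutually exclusive and correct", {
  expect_equal(unname(lengthRatios(300, 700, TRUE)[1, ]),
               c(300 / 700, 0))
  expect_equal(unname(lengthRatios(699, 700, FALSE)[1, ]),
               c(0, 699 / 700))
  expect_equal(unname(lengthRatios(700, 700, TRUE)[1, ]), c(1, 0))
  expect_error(lengthRatios(800, 700, TRUE), "longer than its read")
})

test_that("the assembled feature vector matches a hand count", {
  frags <- Biostrings::DNAStringSet(c(r1 = "ATGAAAAAATAG"))
  orfs <- extractOrfs(frags, minLen = 3)
  orfs <- orfs[orfs$has_start & orfs$has_stop, ]
  X <- extractFeatures(orfs, frags)
  expect_equal(dim(X), c(1L, 4624L))
  v <- as.matrix(X)[1, ]
  expect_equal(unname(v[c("mc_ATG", "mc_AAA", "mc_TAG")]), c(0.25, 0.5, 0.25))
  expect_equal(unname(v["complete_ratio"]), 1)
  expect_equal(unname(v["incomplete_ratio"]), 0)
  expect_equal(unname(v["gc_percent"]), 100 * 2 / 12)
})

test_that("usage blocks sum to one and GC is shared across a fragment's ORFs", {
  set.seed(31)
  frags <- Biostrings::DNAStringSet(
    setNames(vapply(1:10, function(i) randomFragment(700), character(1)),
             paste0("f", 1:10)))
  orfs <- extractOrfs(frags, minLen = 60)
  X <- as.matrix(extractFeatures(orfs, frags))
  blocks <- list(1:64, 65:4160, 4161:4180, 4181:4621)
  for (b in blocks) {
    s <- rowSums(X[, b, drop = FALSE])
    expect_true(all(abs(s - 1) < 1e-12 | s == 0))
  }
  gcByFrag <- tapply(X[, "gc_percent"], orfs$fragment_id,
                     function(v) diff(range(v)))
  expect_true(all(gcByFrag == 0))
  expect_equal(unname(X[1, "gc_percent"]),
               unname(gcPercent(frags)[orfs$fragment_id[1]]))
})

test_that("a 1-nt frame shift changes the codon blocks", {
  s <- "ATGAAACCCGGGTTTTAG"
  shifted <- substr(paste0("G", s), 1, nchar(s))
  a <- monocodonUsage(s)
  b <- monocodonUsage(shifted)
  expect_false(isTRUE(all.equal(a, b)))
})
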