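test_that("codon profiles hit the GC target with zero stop mass", {
  p <- makeCodonProfile(50, biasStrength = 0, seed = 1)
  expect_equal(sum(p), 1)
  expect_equal(unname(p[STOP_CODONS]), c(0, 0, 0))
  # near-uniform over the 61 sense codons at zero bias (GC tilt only)
  sense <- p[p > 0]
  expect_equal(length(sense), 61L)
  expect_lt(diff(range(sense)), 0.05)

  # empirical GC of sampled codons is close to the target
  for (target in c(35, 50, 70)) {
    pr <- makeCodonProfile(target, biasStrength = 1.5, seed = 9)
    set.seed(4)
    cods <- sample(names(pr), 10000, replace = TRUE, prob = pr)
    gc <- mean(vapply(strsplit(cods, ""),
                      function(x) sum(x %in% c("G", "C")), numeric(1)) / 3)
    expect_lt(abs(100 * gc - target), 1.5)
  }
  expect_error(makeCodonProfile(0, 1, 1), "strictly inside")
  expect_error(makeCodonProfile(100, 1, 1), "strictly inside")
})

test_that("generated genomes honor the construction invariants", {
  gen <- generateGenome(50000, geneDensity = 0.6, gcTarget = 45,
                        codonBiasStrength = 2, seed = 3)
  expect_equal(nchar(gen$sequence), 50000L)
  expect_gt(nrow(gen$genes), 0)
  for (i in seq_len(nrow(gen$genes))) {
    g <- gen$genes[i, ]
    s <- substr(gen$sequence, g$start + 1, g$end)
    if (g$strand == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nchar(s) %% 3, 0)
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_true(cods[1] %in% DEFAULT_START_CODONS)
    expect_true(cods[length(cods)] %in% STOP_CODONS)
    expect_false(any(cods[-length(cods)] %in% STOP_CODONS))
  }
  # planted genes never overlap (well under the 45-bp prokaryotic bound)
  o <- order(gen$genes$start)
  expect_true(all(gen$genes$start[o][-1] >= gen$genes$end[o][-nrow(gen$genes)]))

  # no genes at zero density
  none <- generateGenome(5000, geneDensity = 0, gcTarget = 50, seed = 2)
  expect_equal(nrow(none$genes), 0L)

  # determinism
  again <- generateGenome(50000, geneDensity = 0.6, gcTarget = 45,
                          codonBiasStrength = 2, seed = 3)
  expect_identical(gen$sequence, again$sequence)
  expect_identical(gen$genes, again$genes)

  expect_error(generateGenome(50000, geneDensity = 1.2), "\\[0, 1\\)")
})

test_that("realized coding density tracks the requested density", {
  gen <- generateGenome(200000, geneDensity = 0.7, gcTarget = 50,
                        codonBiasStrength = 1, seed = 8)
  coding <- sum(gen$genes$end - gen$genes$start)
  expect_lt(abs(coding / 200000 - 0.7) / 0.7, 0.1)
})

test_that("fragmentation yields the expected read count and exact truth transfer", {
  gen <- generateGenome(70000, geneDensity = 0.5, gcTarget = 50,
                        codonBiasStrength = 1, seed = 10)
  fr <- fragmentGenome(gen, fragmentLength = 700, coverage = 1, seed = 5)
  expect_equal(length(fr$fragments), 100L) # 1 x 70000 / 700
  fr5 <- fragmentGenome(gen, fragmentLength = 700, coverage = 5, seed = 5)
  expect_equal(length(fr5$fragments), 500L)
  expect_true(all(Biostrings::width(fr$fragments) == 700L))

  # a gene fully inside a read keeps its length, sequence and frame sense
  full <- fr$truth[fr$truth$start > 0 & fr$truth$end < 700, ]
  expect_gt(nrow(full), 0)
  genes <- gen$genes[match(full$gene_id, gen$genes$gene_id), ]
  expect_equal(full$end - full$start, genes$end - genes$start)
  for (i in seq_len(min(10, nrow(full)))) {
    readSeq <- as.character(fr$fragments[[full$fragment_id[i]]])
    sub <- substr(readSeq, full$start[i] + 1, full$end[i])
    s <- if (full$strand[i] == "-") as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(sub))) else sub
    expect_true(substr(s, 1, 3) %in% DEFAULT_START_CODONS)
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% STOP_CODONS)
    # the recorded frame points at the gene's codon grid
    if (full$strand[i] == "+") {
      expect_equal(full$start[i] %% 3L, full$frame[i])
    } else {
      expect_equal((700L - full$end[i]) %% 3L, full$frame[i])
    }
  }

  # determinism
  fr2 <- fragmentGenome(gen, fragmentLength = 700, coverage = 1, seed = 5)
  expect_identical(as.character(fr$fragments), as.character(fr2$fragments))
  expect_identical(fr$truth, fr2$truth)
})

test_that("genomes at GC 40 and 65 land their reads in different default bins", {
  sim <- testSim()
  loBins <- assignBin(gcPercent(sim$lo$fragments))
  hiBins <- assignBin(gcPercent(sim$hi$fragments))
  expect_true(length(intersect(unique(loBins), unique(hiBins))) == 0)
  # low-GC reads sit in the 36.57-46 ranges, high-GC reads in 61.85-100
  expect_true(as.integer(names(which.max(table(loBins)))) %in% 2:3)
  expect_true(as.integer(names(which.max(table(hiBins)))) %in% 8:10)
})

test_that("ORF labelling agrees with the same-frame overlap rule", {
  # no truth: everything non-coding
  set.seed(15)
  frags <- Biostrings::DNAStringSet(setNames(randomFragment(700), "f1"))
  lab <- makeLabelledOrfs(frags, data.frame(
    fragment_id = character(), start = integer(), end = integer(),
    strand = character(), frame = integer(), gene_id = character()))
  expect_true(all(lab$labels == 0L))

  # a designed fragment with one known gene labels exactly the ORFs that
  # cover it in frame
  gene <- paste0("ATG", strrep("GAAACCCTG", 30), "TAA") # 276 nt, stop-free
  pre <- "TTTTTAAGGG" # 10 nt, shifts gene to frame 1
  frag <- paste0(pre, gene, strrep("T", 50))
  frags <- Biostrings::DNAStringSet(setNames(frag, "f1"))
  truth <- data.frame(fragment_id = "f1", start = 10L,
                      end = 10L + nchar(gene), strand = "+",
                      frame = 10L %% 3L, gene_id = "g1")
  lab <- makeLabelledOrfs(frags, truth, minLen = 60)
  coding <- lab$orfs[lab$labels == 1L, ]
  expect_equal(nrow(coding), 1L)
  expect_equal(coding$strand, "+")
  expect_equal(coding$frame, 1L)
  ov <- min(coding$end, 10 + nchar(gene)) - max(coding$start, 10)
  expect_gte(ov, 60)
})
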