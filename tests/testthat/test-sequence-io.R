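test_that("FASTA reading validates records and computes GC with N excluded", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGT", ">r2 some description", "acgn"), fa)
  frags <- readFragments(fa)
  expect_equal(names(frags), c("r1", "r2"))
  expect_equal(as.character(frags), c(r1 = "ACGT", r2 = "ACGN"))
  gc <- gcPercent(frags)
  expect_equal(unname(gc[1]), 50)
  expect_equal(unname(gc[2]), 100 * 2 / 3, tolerance = 1e-12)

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(readFragments(empty), "no records")

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGR"), bad)
  expect_error(readFragments(bad), "illegal character 'R' in record 'r1' at position 4")

  allN <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "NNNN"), allN)
  expect_error(readFragments(allN), "only N")
})

test_that("FASTA write/read round trip preserves ids and sequences", {
  set.seed(42)
  seqs <- Biostrings::DNAStringSet(vapply(1:20, function(i)
    randomFragment(sample(50:200, 1)), character(1)))
  names(seqs) <- paste0("frag", 1:20)
  fa <- tempfile(fileext = ".fasta")
  writeFragments(seqs, fa)
  back <- readFragments(fa)
  expect_identical(names(back), names(seqs))
  expect_identical(as.character(back), as.character(seqs))
})

test_that("GFF3 import shifts to 0-based half-open; BED is passed through", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "frag1\ttest\tgene\t101\t200\t.\t+\t.\tID=g1"), gff)
  ann <- readAnnotations(gff)
  expect_equal(ann$start, 100L)
  expect_equal(ann$end, 200L)
  expect_equal(ann$gene_id, "g1")
  expect_equal(ann$frame, 100L %% 3L)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg1\t0\t+", bed)
  annB <- readAnnotations(bed)
  expect_equal(annB$start, 100L)
  expect_equal(annB$end, 200L)

  badGff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "frag1\ttest\tgene\t200\t101\t.\t+\t.\tID=g1"), badGff)
  expect_error(suppressWarnings(readAnnotations(badGff)))
})

test_that("GFF3 <-> internal <-> BED conversions compose to identity", {
  ann <- data.frame(fragment_id = c("f1", "f1", "f2"),
                    start = c(0L, 120L, 33L), end = c(99L, 300L, 633L),
                    strand = c("+", "-", "+"), frame = c(0L, 1L, 0L),
                    gene_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  gff <- tempfile(fileext = ".gff3")
  writeAnnotations(ann, gff, "gff3")
  annG <- readAnnotations(gff)
  expect_equal(annG[, c("fragment_id", "start", "end", "strand", "frame")],
               ann[, c("fragment_id", "start", "end", "strand", "frame")])
  bed <- tempfile(fileext = ".bed")
  writeAnnotations(annG, bed, "bed")
  annB <- readAnnotations(bed, seqLengths = c(f1 = 700L, f2 = 700L))
  expect_equal(annB[, c("fragment_id", "start", "end", "strand")],
               ann[, c("fragment_id", "start", "end", "strand")])
})

test_that("prediction TSV round trip is lossless and prints >= 4 decimals", {
  calls <- data.frame(
    fragment_id = paste0("f", 1:100),
    start = as.integer(sample(0:500, 100, replace = TRUE)),
    end = as.integer(sample(501:700, 100, replace = TRUE)),
    strand = sample(c("+", "-"), 100, replace = TRUE),
    frame = sample(0:2, 100, replace = TRUE),
    has_start = sample(c(TRUE, FALSE), 100, replace = TRUE),
    has_stop = sample(c(TRUE, FALSE), 100, replace = TRUE),
    probability = runif(100, 0.5, 1),
    bin = sample(1:10, 100, replace = TRUE),
    stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  writePredictions(calls, tsv)
  back <- readPredictions(tsv)
  expect_identical(back, calls)

  one <- calls[1, ]
  one$probability <- 0.5
  writePredictions(one, tsv)
  expect_match(readLines(tsv)[2], "0.5000")

  writePredictions(calls[0, ], tsv)
  expect_equal(length(readLines(tsv)), 1L) # header only
})
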