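## Synthetic prokaryotic genomes and reads.
##
## Genomes alternate non-coding stretches (i.i.d. bases at the target GC)
## with genes whose interiors are sampled from a stop-free, GC-tilted,
## optionally Dirichlet-sharpened codon profile.  Genes never overlap, are
## placed on either strand with probability 1/2, and have lognormal lengths
## (median ~900 nt, floor 120 nt) so that 700-bp reads contain a realistic
## mix of complete and boundary-truncated ORFs.  Fragmentation excises
## fixed-length reads at uniformly random positions to a stated fold
## coverage and re-expresses the truth annotations in read coordinates with
## the reading frame preserved.
##
## All randomness flows from one master seed through named substreams.

## GC count (0..3) per codon
codonGcCount <- function(codons) {
  vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")), integer(1))
}

#' Build a stop-free codon profile with a target GC content
#'
#' Sense-codon probabilities with zero mass on stop codons.  Bias: each
#' sense codon receives a log-weight `biasStrength * z` with `z` standard
#' normal (seeded), so `biasStrength = 0` gives near-uniform usage and
#' larger values concentrate it.  The profile is then exponentially tilted
#' in the codon GC count so that the expected per-base GC of a sampled
#' codon equals `gcTarget` (within numerical tolerance of the root
#' finder).
#'
#' @param gcTarget Target GC percent, strictly inside `(0, 100)`.
#' @param biasStrength Non-negative codon-bias sharpness.
#' @param seed Integer seed for the bias draw.
#' @return Named numeric 64-vector summing to 1, zero on `TAA/TAG/TGA`.
#' @export
#' @examples
#' p <- makeCodonProfile(50, biasStrength = 0, seed = 1)
#' sum(p); p[STOP_CODONS]
makeCodonProfile <- function(gcTarget, biasStrength = 0, seed = 1L) {
  mgsAssert(gcTarget > 0 && gcTarget < 100,
            "gcTarget must lie strictly inside (0, 100)")
  mgsAssert(biasStrength >= 0, "biasStrength must be non-negative")
  cods <- allCodons()
  sense <- setdiff(cods, STOP_CODONS)
  set.seed(substreamSeed(seed, "codon-profile"))
  lw <- biasStrength * rnorm(length(sense))
  gcc <- codonGcCount(sense)
  target <- gcTarget / 100
  meanGc <- function(theta) {
    w <- exp(lw + theta * gcc - max(lw + theta * gcc))
    sum(w * gcc / 3) / sum(w)
  }
  theta <- uniroot(function(t) meanGc(t) - target, c(-60, 60), tol = 1e-12)$root
  w <- exp(lw + theta * gcc - max(lw + theta * gcc))
  p <- numeric(length(cods))
  names(p) <- cods
  p[sense] <- w / sum(w)
  p
}

sampleBases <- function(n, gcTarget) {
  probs <- c(A = (1 - gcTarget / 100) / 2, C = gcTarget / 200,
             G = gcTarget / 200, T = (1 - gcTarget / 100) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic prokaryotic genome with truth annotations
#'
#' @param genomeLength Genome length in nt.
#' @param geneDensity Target fraction of the genome that is coding, in
#'   `[0, 1)`.
#' @param gcTarget Target GC percent for both coding and non-coding parts.
#' @param codonBiasStrength Codon-bias sharpness for gene interiors
#'   ([makeCodonProfile()]).
#' @param seed Integer master seed.
#' @param geneLenMeanlog,geneLenSdlog Lognormal gene-length parameters
#'   (defaults give a median of ~900 nt).
#' @param geneLenFloor Minimum gene length in nt (default 120).
#' @return A list: `sequence` (character genome), `genes` (`data.frame`
#'   with `gene_id`, `start`, `end` 0-based half-open, `strand`),
#'   `profile` (the codon profile used).
#' @export
generateGenome <- function(genomeLength, geneDensity = 0.7, gcTarget = 50,
                           codonBiasStrength = 1, seed = 1L,
                           geneLenMeanlog = log(900), geneLenSdlog = 0.5,
                           geneLenFloor = 120L) {
  mgsAssert(geneDensity >= 0 && geneDensity < 1,
            "geneDensity must lie in [0, 1)")
  mgsAssert(genomeLength >= 1000, "genomeLength must be at least 1 kb")
  profile <- makeCodonProfile(gcTarget, codonBiasStrength, seed)
  sense <- names(profile)[profile > 0]
  psense <- profile[sense]
  set.seed(substreamSeed(seed, "genome"))
  meanGene <- exp(geneLenMeanlog + geneLenSdlog^2 / 2)
  pieces <- character(0)
  genes <- list()
  pos <- 0L
  geneN <- 0L
  repeat {
    gap <- if (geneDensity == 0) genomeLength else {
      round(rexp(1, rate = geneDensity / (meanGene * (1 - geneDensity))))
    }
    gap <- min(gap, genomeLength - pos)
    if (gap > 0L) {
      pieces <- c(pieces, sampleBases(gap, gcTarget))
      pos <- pos + gap
    }
    if (pos >= genomeLength || geneDensity == 0) break
    len <- max(geneLenFloor, round(rlnorm(1, geneLenMeanlog, geneLenSdlog)))
    len <- 3L * as.integer(round(len / 3))
    if (pos + len > genomeLength) {
      # not enough room: fill the tail with non-coding sequence
      tail <- genomeLength - pos
      if (tail > 0L) pieces <- c(pieces, sampleBases(tail, gcTarget))
      pos <- genomeLength
      break
    }
    startCodon <- sample(DEFAULT_START_CODONS, 1L, prob = c(0.8, 0.15, 0.05))
    stopCodon <- sample(STOP_CODONS, 1L)
    interior <- paste(sample(sense, len / 3L - 2L, replace = TRUE,
                             prob = psense), collapse = "")
    gene <- paste0(startCodon, interior, stopCodon)
    strand <- sample(c("+", "-"), 1L)
    pieces <- c(pieces, if (strand == "+") gene else revcompChar(gene))
    geneN <- geneN + 1L
    genes[[geneN]] <- data.frame(
      gene_id = sprintf("g%04d", geneN), start = pos, end = pos + len,
      strand = strand, stringsAsFactors = FALSE)
    pos <- pos + len
    if (pos >= genomeLength) break
  }
  genes <- if (geneN > 0L) do.call(rbind, genes) else {
    data.frame(gene_id = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  }
  list(sequence = paste(pieces, collapse = ""), genes = genes,
       profile = profile)
}

#' Fragment a genome into fixed-length reads with per-read truth
#'
#' Excises `round(coverage * genomeLength / fragmentLength)` reads at
#' uniformly random start positions and intersects the truth genes with
#' each read, re-expressing coordinates in the read and preserving the
#' reading frame: for a plus-strand gene the frame is
#' `(geneStart - fragStart) mod 3`; for a minus-strand gene it is measured
#' from the read's 3' end, `(fragmentLength - (geneEnd - fragStart)) mod 3`.
#'
#' @param genome Character genome sequence (or the list from
#'   [generateGenome()]).
#' @param genes Truth `data.frame` (ignored when `genome` is a list).
#' @param fragmentLength Read length in nt (default 700).
#' @param coverage Fold coverage (default 1).
#' @param seed Integer seed for the excision positions.
#' @param prefix Fragment id prefix.
#' @return A list: `fragments` (named [Biostrings::DNAStringSet]) and
#'   `truth` (`data.frame` with `fragment_id`, `start`, `end`, `strand`,
#'   `frame`, `gene_id` in read coordinates, clipped to the read).
#' @export
fragmentGenome <- function(genome, genes = NULL, fragmentLength = 700L,
                           coverage = 1, seed = 1L, prefix = "frag") {
  if (is.list(genome)) {
    genes <- genome$genes
    genome <- genome$sequence
  }
  L <- nchar(genome)
  mgsAssert(fragmentLength <= L, "fragmentLength must not exceed the genome")
  n <- round(coverage * L / fragmentLength)
  mgsAssert(n >= 1, "coverage too low: zero fragments")
  set.seed(substreamSeed(seed, "fragmentation"))
  starts <- sample.int(L - fragmentLength + 1L, n, replace = TRUE) - 1L
  ids <- sprintf("%s_%05d", prefix, seq_len(n))
  seqs <- substring(genome, starts + 1L, starts + fragmentLength)
  fragments <- Biostrings::DNAStringSet(seqs)
  names(fragments) <- ids
  truth <- list()
  for (i in seq_len(n)) {
    fs <- starts[i]; fe <- fs + fragmentLength
    hit <- which(genes$start < fe & genes$end > fs)
    if (length(hit) == 0L) next
    g <- genes[hit, , drop = FALSE]
    frame <- ifelse(g$strand == "+",
                    (g$start - fs) %% 3L,
                    (fragmentLength - (g$end - fs)) %% 3L)
    truth[[length(truth) + 1L]] <- data.frame(
      fragment_id = ids[i],
      start = as.integer(pmax(0L, g$start - fs)),
      end = as.integer(pmin(fragmentLength, g$end - fs)),
      strand = g$strand, frame = as.integer(frame), gene_id = g$gene_id,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else {
    data.frame(fragment_id = character(), start = integer(), end = integer(),
               strand = character(), frame = integer(), gene_id = character(),
               stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  list(fragments = fragments, truth = truth)
}

#' Extract ORFs from reads and label them against truth
#'
#' Runs [extractOrfs()] on every read and labels a candidate as coding iff
#' it overlaps a truth gene by at least `minOverlap` nt on the same strand
#' and reading frame -- the same rule used at evaluation time, so the
#' training labels and the evaluation agree.
#'
#' @param fragments Named [Biostrings::DNAStringSet].
#' @param truth Truth `data.frame` in read coordinates
#'   ([fragmentGenome()]).
#' @param minLen Minimum ORF length (nt).
#' @param minOverlap Minimum same-frame overlap for the coding label (nt).
#' @return A list: `orfs` ([extractOrfs()] output) and `labels` (integer
#'   0/1 per ORF).
#' @export
makeLabelledOrfs <- function(fragments, truth, minLen = 60L,
                             minOverlap = 60L) {
  orfs <- extractOrfs(fragments, minLen = minLen)
  labels <- integer(nrow(orfs))
  if (nrow(orfs) > 0L && nrow(truth) > 0L) {
    key <- function(d) paste(d$fragment_id, d$strand, d$frame, sep = "\r")
    ok <- key(orfs); tk <- key(truth)
    byKey <- split(seq_len(nrow(truth)), tk)
    for (i in seq_len(nrow(orfs))) {
      ti <- byKey[[ok[i]]]
      if (is.null(ti)) next
      ov <- intervalOverlap(orfs$start[i], orfs$end[i],
                            truth$start[ti], truth$end[ti])
      if (any(ov >= minOverlap)) labels[i] <- 1L
    }
  }
  list(orfs = orfs, labels = labels)
}

#' Simulate a labelled read set in one call
#'
#' Convenience wrapper chaining [generateGenome()] and [fragmentGenome()].
#'
#' @inheritParams generateGenome
#' @inheritParams fragmentGenome
#' @return A list: `fragments`, `truth`, `genome` (the [generateGenome()]
#'   result).
#' @export
simulateReads <- function(genomeLength = 100000L, geneDensity = 0.7,
                          gcTarget = 50, codonBiasStrength = 1,
                          fragmentLength = 700L, coverage = 1, seed = 1L,
                          prefix = "frag") {
  gen <- generateGenome(genomeLength, geneDensity, gcTarget,
                        codonBiasStrength, seed = substreamSeed(seed, "gen"))
  fr <- fragmentGenome(gen, fragmentLength = fragmentLength,
                       coverage = coverage,
                       seed = substreamSeed(seed, "frag"), prefix = prefix)
  list(fragments = fr$fragments, truth = fr$truth, genome = gen)
}
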