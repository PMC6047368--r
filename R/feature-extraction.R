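## Usage featurization of candidate ORFs.
##
## Four usage blocks in a fixed global order -- monocodon (64), dicodon
## (4,096), monoamino (20), diamino (441) -- followed by three scalar
## features: fragment GC percent, complete length ratio, incomplete length
## ratio.  Every usage block is a relative frequency (counts divided by the
## number of counted units) and sums to one whenever its denominator is
## positive; an empty block is all zeros.
##
## "Half-overlapping" pairs step by one unit: dicodons are hexamers starting
## every 3 nt (consecutive pairs share a codon), diamino pairs step by one
## residue.  The diamino alphabet has 21 symbols (20 residues + stop), the
## monoamino block excludes stops entirely.

#' Names of the full feature vector, in the fixed global order
#'
#' @return Character vector of length 4,624: `mc_*` (64 codons), `dc_*`
#'   (4,096 dicodons), `ma_*` (20 amino acids), `da_*` (441 residue pairs
#'   over the 21-symbol alphabet), then `gc_percent`, `complete_ratio`,
#'   `incomplete_ratio`.
#' @export
featureNames <- function() {
  cods <- allCodons()
  dic <- as.vector(t(outer(cods, cods, paste0)))
  dia <- as.vector(t(outer(AA21, AA21, paste0)))
  c(paste0("mc_", cods), paste0("dc_", dic), paste0("ma_", AA20),
    paste0("da_", dia), "gc_percent", "complete_ratio", "incomplete_ratio")
}

## number of usage features (excludes the three scalars)
N_USAGE <- 64L + 4096L + 20L + 441L

## truncate sequences to whole codons
truncateToCodons <- function(seqs) {
  n <- nchar(seqs)
  substring(seqs, 1L, n - n %% 3L)
}

normalizeRows <- function(m) {
  rs <- rowSums(m)
  pos <- rs > 0
  m[pos, ] <- m[pos, , drop = FALSE] / rs[pos]
  m
}

#' Monocodon usage of in-frame ORF sequences
#'
#' Relative frequency of each of the 64 codons, read in frame (a trailing
#' partial codon is ignored).
#'
#' @param seqs Character vector (or `DNAStringSet`) of in-frame DNA.
#' @return Numeric matrix, one row per sequence, 64 columns in lexicographic
#'   codon order; each row sums to 1.
#' @export
#' @examples
#' monocodonUsage("ATGAAA")[, c("ATG", "AAA")]
monocodonUsage <- function(seqs) {
  seqs <- truncateToCodons(as.character(seqs))
  mgsAssert(all(nchar(seqs) >= 3L), "each sequence needs at least one codon")
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 3L, step = 3L)
  normalizeRows(cnt)
}

#' Dicodon usage of in-frame ORF sequences
#'
#' Relative frequency of successive half-overlapping codon pairs: the
#' hexamers starting every 3 nt, so a sequence of `n` codons contributes
#' `n - 1` pairs and consecutive pairs share one codon.
#'
#' @inheritParams monocodonUsage
#' @return Numeric matrix with 4,096 columns (lexicographic hexamer order);
#'   each row sums to 1.
#' @export
dicodonUsage <- function(seqs) {
  seqs <- truncateToCodons(as.character(seqs))
  mgsAssert(all(nchar(seqs) >= 6L), "each sequence needs at least two codons")
  cnt <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 6L, step = 3L)
  normalizeRows(cnt)
}

translateOrfs <- function(seqs) {
  seqs <- truncateToCodons(as.character(seqs))
  mgsAssert(all(nchar(seqs) >= 3L), "each sequence needs at least one codon")
  as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAStringSet(seqs), no.init.codon = TRUE)))
}

#' Monoamino acid usage
#'
#' Relative frequency of the 20 standard amino acids in the translated ORF
#' (standard genetic code; start codons translate as their literal codon).
#' Stop codons are excluded from numerator and denominator; a translation
#' consisting only of stops yields an all-zero row.
#'
#' @inheritParams monocodonUsage
#' @return Numeric matrix with 20 columns (alphabetical one-letter codes).
#' @export
monoaminoUsage <- function(seqs) {
  aa <- translateOrfs(seqs)
  cnt <- Biostrings::letterFrequency(Biostrings::AAStringSet(aa),
                                     letters = AA20)
  colnames(cnt) <- AA20
  if (any(rowSums(cnt) == 0))
    mgsLog(sum(rowSums(cnt) == 0), " ORF(s) with empty monoamino block")
  normalizeRows(cnt)
}

#' Diamino acid usage
#'
#' Relative frequency of successive half-overlapping residue pairs (step of
#' one residue) over the 21-symbol alphabet of the 20 standard amino acids
#' plus the stop symbol `*`, giving 441 pair features.
#'
#' @inheritParams monocodonUsage
#' @return Numeric matrix with 441 columns (row-major over the 21-symbol
#'   alphabet).
#' @export
diaminoUsage <- function(seqs) {
  aa <- translateOrfs(seqs)
  mgsAssert(all(nchar(aa) >= 2L), "each sequence needs at least two codons")
  n <- length(aa)
  lens <- nchar(aa)
  chars <- strsplit(aa, "", fixed = TRUE)
  first <- unlist(lapply(chars, function(x) x[-length(x)]), use.names = FALSE)
  second <- unlist(lapply(chars, function(x) x[-1L]), use.names = FALSE)
  rowIdx <- rep.int(seq_len(n), lens - 1L)
  i1 <- match(first, AA21)
  i2 <- match(second, AA21)
  mgsAssert(!anyNA(i1) && !anyNA(i2), "unexpected residue in translation")
  colIdx <- (i1 - 1L) * 21L + i2
  cnt <- matrix(0, nrow = n, ncol = 441L,
                dimnames = list(NULL, as.vector(t(outer(AA21, AA21, paste0)))))
  tab <- table(factor(rowIdx, levels = seq_len(n)), factor(colIdx, levels = 1:441))
  cnt[] <- as.numeric(tab)
  normalizeRows(cnt)
}

#' ORF length-ratio features
#'
#' Ratio of ORF length to read length, split into two mutually exclusive
#' features: a complete ORF (both start and stop codon present) fills
#' `complete_ratio` and has `incomplete_ratio = 0`; an incomplete ORF the
#' reverse.
#'
#' @param orfLen Integer vector of ORF lengths (nt).
#' @param readLen Integer vector of read lengths (nt).
#' @param complete Logical vector: is the ORF complete?
#' @return A two-column matrix `complete_ratio`, `incomplete_ratio`.
#' @export
#' @examples
#' lengthRatios(300, 700, complete = TRUE)
lengthRatios <- function(orfLen, readLen, complete) {
  mgsAssert(all(readLen > 0), "read lengths must be positive")
  mgsAssert(all(orfLen <= readLen), "ORF cannot be longer than its read")
  r <- orfLen / readLen
  cbind(complete_ratio = ifelse(complete, r, 0),
        incomplete_ratio = ifelse(complete, 0, r))
}

#' Feature matrix for a set of candidate ORFs
#'
#' Computes the full 4,624-dimensional feature vector for every ORF: the
#' four usage blocks in the fixed global order, the GC percent of the
#' parent fragment (shared by all ORFs of a read), and the two length
#' ratios.
#'
#' @param orfs A `data.frame` of candidates from [extractOrfs()].
#' @param fragments The [Biostrings::DNAStringSet] the ORFs came from.
#' @param chunkSize Number of ORFs processed per dense block before sparse
#'   conversion (memory/speed trade-off).
#' @return A sparse `Matrix::dgCMatrix` with one row per ORF and
#'   `featureNames()` as column names.
#' @export
extractFeatures <- function(orfs, fragments, chunkSize = 2000L) {
  fn <- featureNames()
  n <- nrow(orfs)
  if (n == 0L) {
    return(Matrix::Matrix(0, nrow = 0, ncol = length(fn), sparse = TRUE,
                          dimnames = list(NULL, fn)))
  }
  mgsAssert(all(orfs$fragment_id %in% names(fragments)),
            "every ORF must reference a known fragment")
  gc <- gcPercent(fragments)
  readLen <- Biostrings::width(fragments)
  names(readLen) <- names(fragments)
  blocks <- list()
  starts <- seq.int(1L, n, by = chunkSize)
  for (s in starts) {
    idx <- s:min(s + chunkSize - 1L, n)
    sq <- orfs$seq[idx]
    dense <- cbind(monocodonUsage(sq), dicodonUsage(sq),
                   monoaminoUsage(sq), diaminoUsage(sq))
    blocks[[length(blocks) + 1L]] <- methods::as(
      Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
  }
  usage <- do.call(rbind, blocks)
  complete <- orfs$has_start & orfs$has_stop
  scalars <- cbind(
    gc_percent = gc[match(orfs$fragment_id, names(fragments))],
    lengthRatios(orfs$end - orfs$start, readLen[orfs$fragment_id], complete))
  X <- cbind(usage, Matrix::Matrix(scalars, sparse = TRUE))
  colnames(X) <- fn
  rownames(X) <- NULL
  X
}
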