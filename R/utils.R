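## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats cor optim predict rexp rlnorm rnorm runif sd setNames
#'   uniroot plogis rbinom
#' @importFrom utils read.delim write.table head tail
NULL

## Fixed alphabets.  Feature order is a function of these constants only,
## never of any data set.
DNA_BASES <- c("A", "C", "G", "T")

#' Codon-set constants
#'
#' `STOP_CODONS` are the three standard stop codons; `DEFAULT_START_CODONS`
#' the common prokaryotic start codons `ATG/GTG/TTG` used as the default
#' start-codon alphabet for ORF extraction (configurable in
#' [extractOrfs()]).
#'
#' @format Character vectors of codons.
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @rdname STOP_CODONS
#' @export
DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

## 64 codons in lexicographic order (AAA, AAC, ..., TTT); matches the column
## order of Biostrings::oligonucleotideFrequency().
allCodons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

## 20 standard amino acids, alphabetical by one-letter code.
AA20 <- sort(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
## 21-symbol alphabet for residue pairs: 20 residues plus the stop symbol.
AA21 <- c(AA20, "*")

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All stochastic steps in the package draw their seed from a single master
#' seed through named substreams, so that e.g. genome simulation and
#' fragmentation are independently reproducible.  The result is always a
#' valid 32-bit integer seed.
#'
#' @param seed Integer master seed.
#' @param name Character scalar naming the substream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substreamSeed(1L, "genome")
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  p <- 2147483647 # 2^31 - 1
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 131 + c) %% p
  as.integer((abs(seed) %% p * 48271 + h) %% p)
}

mgsVerbose <- function() isTRUE(getOption("MetaGeneSVM.verbose", FALSE))

mgsLog <- function(...) {
  if (mgsVerbose()) message("[MetaGeneSVM] ", ...)
  invisible(NULL)
}

## stopifnot with a readable message
mgsAssert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## reverse complement of a plain character vector of DNA strings
revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## stratified index split: returns logical vector, TRUE = held out
stratifiedHoldout <- function(y, fraction, seed) {
  set.seed(seed)
  hold <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    nh <- floor(length(idx) * fraction)
    if (nh > 0 && nh < length(idx)) hold[sample(idx, nh)] <- TRUE
  }
  hold
}

## stratified fold assignment 1..folds
stratifiedFolds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

## interval overlap on 0-based half-open coordinates, vectorized
intervalOverlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}
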