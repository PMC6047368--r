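## Reading and writing the standard formats the pipeline touches: FASTA
## fragments, GFF3/BED truth annotations, TSV predictions, JSON reports.
##
## Internal coordinate convention: 0-based, half-open, on the forward strand
## of the fragment.  Reverse-strand features are stored in forward
## coordinates with strand "-".  GFF3 (1-based, closed) is shifted on
## import/export; BED already matches.
##
## Frame convention: frame is the reading phase within the strand,
##   "+" : frame = start %% 3
##   "-" : frame = (fragment_length - end) %% 3
## so two features are in the same reading frame iff strand and frame agree.

#' Read metagenomic fragments from a FASTA file
#'
#' Reads a (multi-)FASTA file of DNA fragments.  Lowercase letters are
#' normalized to uppercase; any character outside `A,C,G,T,N` is rejected
#' with an error naming the record and position.  Fragments consisting only
#' of `N` have no defined GC content and are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record, in file
#'   order; `names()` carry the record ids (first whitespace token).
#' @seealso [gcPercent()]
#' @export
readFragments <- function(path) {
  mgsAssert(file.exists(path), paste0("file not found: ", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]),
         call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence in record '", ids[which(!nzchar(seqs))[1L]], "'",
         call. = FALSE)
  }
  allN <- !grepl("[ACGT]", seqs)
  if (any(allN)) {
    stop("record '", ids[which(allN)[1L]],
         "' contains only N bases; GC content is undefined", call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write fragments to FASTA
#'
#' @param fragments A named [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFragments <- function(fragments, path) {
  Biostrings::writeXStringSet(fragments, path)
  invisible(path)
}

#' GC content of fragments, in percent
#'
#' Percentage of `G`+`C` among the non-`N` bases of each sequence.  `N`
#' bases are excluded from both numerator and denominator.
#'
#' @param x A [Biostrings::DNAStringSet] or character vector of DNA strings.
#' @return Numeric vector in `[0, 100]`.
#' @export
#' @examples
#' gcPercent(c("ACGT", "ACGN"))
gcPercent <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  freq <- Biostrings::letterFrequency(x, letters = c("G", "C", "A", "T"))
  denom <- rowSums(freq)
  out <- 100 * (freq[, "G"] + freq[, "C"]) / denom
  names(out) <- names(x)
  out
}

#' Read gene annotations from GFF3 or BED
#'
#' Imports truth annotations and normalizes them to the package's internal
#' 0-based half-open convention (GFF3 starts are decremented by one).  The
#' reading frame is taken from a `frame` attribute/column when present
#' (written by [writeAnnotations()]); otherwise it is derived from the
#' coordinates, which requires `seqLengths` for minus-strand features.
#'
#' @param path Path to a GFF3 or BED file.
#' @param dialect `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param seqLengths Optional named integer vector of fragment lengths, used
#'   to derive minus-strand frames when the file does not record them.
#' @return A `data.frame` with columns `fragment_id`, `start`, `end`
#'   (0-based half-open), `strand`, `frame`, `gene_id`.
#' @export
readAnnotations <- function(path, dialect = c("auto", "gff3", "bed"),
                            seqLengths = NULL) {
  dialect <- match.arg(dialect)
  mgsAssert(file.exists(path), paste0("file not found: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3")
  md <- S4Vectors::mcols(gr)
  n <- length(gr)
  geneId <- rep(NA_character_, n)
  for (col in c("ID", "Name", "name", "gene_id")) {
    if (col %in% colnames(md)) {
      v <- as.character(md[[col]])
      geneId[is.na(geneId) & !is.na(v)] <- v[is.na(geneId) & !is.na(v)]
    }
  }
  if (anyNA(geneId)) geneId[is.na(geneId)] <- paste0("gene_", which(is.na(geneId)))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(end0 <= start0)) {
    stop("annotation with end <= start after normalization (record ",
         which(end0 <= start0)[1L], ")", call. = FALSE)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  mgsAssert(all(strand %in% c("+", "-")),
            "annotations must carry explicit +/- strands")
  frame <- rep(NA_integer_, n)
  if ("frame" %in% colnames(md)) {
    frame <- suppressWarnings(as.integer(as.character(md[["frame"]])))
  }
  ids <- as.character(GenomeInfoDb::seqnames(gr))
  miss <- is.na(frame)
  if (any(miss)) {
    plus <- miss & strand == "+"
    frame[plus] <- start0[plus] %% 3L
    minus <- miss & strand == "-"
    if (any(minus)) {
      mgsAssert(!is.null(seqLengths),
                "seqLengths is required to derive minus-strand frames")
      len <- seqLengths[ids[minus]]
      mgsAssert(!anyNA(len), "seqLengths is missing some fragment ids")
      frame[minus] <- (as.integer(len) - end0[minus]) %% 3L
    }
  }
  data.frame(fragment_id = ids, start = as.integer(start0),
             end = as.integer(end0), strand = strand,
             frame = as.integer(frame), gene_id = geneId,
             stringsAsFactors = FALSE)
}

#' Write gene annotations to GFF3 or BED
#'
#' The inverse of [readAnnotations()]: internal 0-based half-open
#' coordinates are shifted to each dialect's convention.  GFF3 output
#' records the reading frame and gene id as attributes so that a round trip
#' is lossless.
#'
#' @param annotations A `data.frame` as returned by [readAnnotations()].
#' @param path Output path.
#' @param dialect `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(annotations, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$fragment_id,
    ranges = IRanges::IRanges(start = annotations$start + 1L,
                              end = annotations$end),
    strand = annotations$strand)
  if (dialect == "gff3") {
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- annotations$gene_id
    S4Vectors::mcols(gr)$frame <- annotations$frame
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    S4Vectors::mcols(gr)$name <- annotations$gene_id
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

predictionColumns <- c("fragment_id", "start", "end", "strand", "frame",
                       "has_start", "has_stop", "probability", "bin")

#' Write gene calls to a TSV file
#'
#' Writes one row per predicted gene with a header line.  Probabilities are
#' printed with 17 decimal places so that a write/read round trip through
#' [readPredictions()] is lossless.
#'
#' @param calls A `data.frame` of gene calls ([predictFragments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(calls, path) {
  mgsAssert(all(predictionColumns %in% colnames(calls)),
            paste("calls must have columns:",
                  paste(predictionColumns, collapse = ", ")))
  out <- calls[, predictionColumns, drop = FALSE]
  out$probability <- sprintf("%.17f", out$probability)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write predictions to '", path, "': ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read gene calls from a TSV file written by [writePredictions()]
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of gene calls.
#' @export
readPredictions <- function(path) {
  mgsAssert(file.exists(path), paste0("file not found: ", path))
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(fragment_id = "character",
                                  start = "integer", end = "integer",
                                  strand = "character", frame = "integer",
                                  has_start = "logical", has_stop = "logical",
                                  probability = "numeric", bin = "integer"))
  df
}

#' Write an evaluation report (or any list of scalars) as JSON
#'
#' @param report An [EvalReport-class] or a named list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(report, path) {
  if (is(report, "EvalReport")) {
    report <- list(tp = report@tp, fp = report@fp, fn = report@fn,
                   sensitivity = report@sensitivity,
                   specificity = report@specificity,
                   harmonic_mean = report@harmonicMean)
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
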