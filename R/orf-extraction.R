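## Six-frame ORF enumeration.
##
## For each strand and frame the fragment is partitioned by in-frame stop
## codons.  Each stop-to-stop segment yields at most one candidate: the
## maximal ORF from the leftmost in-frame start codon through the stop (the
## "leftmost TIS" convention -- start-site refinement is a downstream step).
## Segments touching a fragment boundary yield boundary-clipped incomplete
## candidates.  The stop codon is included in the ORF span, so complete ORF
## lengths are multiples of three.

## Enumerate candidates in the three frames of one oriented sequence.
## Returns a data.frame in the coordinates of `w` (0-based half-open).
scanFrames <- function(w, minLen, startCodons, stopCodons) {
  L <- nchar(w)
  out <- vector("list", 3L)
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 1L) next
    pos <- f + 3L * (seq_len(ncod) - 1L) # 0-based codon start positions
    codons <- substring(w, pos + 1L, pos + 3L)
    isStop <- codons %in% stopCodons
    isStart <- codons %in% startCodons
    stops <- which(isStop)
    segs <- list()
    addOrf <- function(i1, i2, hasStart, hasStop) {
      # codons i1..i2 inclusive (1-based codon indices)
      segs[[length(segs) + 1L]] <<- c(i1, i2, hasStart, hasStop)
    }
    prev <- 0L
    for (s in stops) {
      a <- prev + 1L
      if (prev == 0L) {
        # fragment boundary on the left: maximal ORF from the boundary
        # through the stop; complete iff the first codon is a start codon
        addOrf(1L, s, isStart[1L], TRUE)
      } else if (a <= s - 1L) {
        # stop-to-stop: complete ORF from the leftmost start codon, if any
        cand <- which(isStart[a:(s - 1L)])
        if (length(cand) > 0L) addOrf(a + cand[1L] - 1L, s, TRUE, TRUE)
      }
      prev <- s
    }
    if (prev < ncod) {
      a <- prev + 1L
      if (prev == 0L) {
        # no in-frame stop at all: clipped at least on the right; the left
        # end is a true start when the first codon is a start codon
        addOrf(1L, ncod, isStart[1L], FALSE)
      } else {
        # stop-to-boundary: needs a start codon, runs to the last full codon
        cand <- which(isStart[a:ncod])
        if (length(cand) > 0L) addOrf(a + cand[1L] - 1L, ncod, TRUE, FALSE)
      }
    }
    if (length(segs) == 0L) next
    m <- do.call(rbind, segs)
    ws <- f + 3L * (m[, 1L] - 1L)
    we <- f + 3L * m[, 2L]
    keep <- (we - ws) >= minLen
    if (!any(keep)) next
    out[[f + 1L]] <- data.frame(
      w_start = ws[keep], w_end = we[keep], frame = f,
      has_start = as.logical(m[keep, 3L]), has_stop = as.logical(m[keep, 4L]))
  }
  do.call(rbind, out)
}

#' Enumerate candidate ORFs in all six frames of each fragment
#'
#' Finds all complete and incomplete open reading frames: a complete ORF
#' runs from the leftmost in-frame start codon to its stop codon
#' (inclusive); an ORF truncated by a fragment boundary on either side is
#' reported as incomplete with the corresponding `has_start`/`has_stop`
#' flag unset.  A stop-to-stop segment without a start codon yields no
#' candidate.  Candidates shorter than `minLen` or containing `N` are
#' dropped.
#'
#' @param fragments A named [Biostrings::DNAStringSet] or character vector.
#' @param minLen Minimum ORF length in nucleotides, stop codon included
#'   (default 60, the conventional minimum gene length).
#' @param startCodons,stopCodons Codon sets; defaults `ATG/GTG/TTG` and
#'   `TAA/TAG/TGA`.
#' @return A `data.frame` with one row per candidate: `fragment_id`,
#'   `start`, `end` (0-based half-open, forward strand), `strand`, `frame`
#'   (reading phase within the strand), `has_start`, `has_stop`, `seq`
#'   (in-frame DNA, reverse-complemented for strand `-`).  Sorted by
#'   fragment, start, end, strand.
#' @export
#' @examples
#' extractOrfs(c(r1 = "ATGAAAAAATAG"), minLen = 3)
extractOrfs <- function(fragments, minLen = 60L,
                        startCodons = DEFAULT_START_CODONS,
                        stopCodons = STOP_CODONS) {
  if (is.character(fragments) && is.null(names(fragments)))
    names(fragments) <- paste0("frag_", seq_along(fragments))
  seqs <- if (is.character(fragments)) toupper(fragments)
          else as.character(fragments)
  ids <- names(seqs)
  mgsAssert(!is.null(ids) && all(nzchar(ids)), "fragments must be named")
  rc <- revcompChar(seqs)
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    fwd <- scanFrames(seqs[i], minLen, startCodons, stopCodons)
    rev <- scanFrames(rc[i], minLen, startCodons, stopCodons)
    rows <- list()
    if (!is.null(fwd) && nrow(fwd)) {
      fwd$start <- fwd$w_start
      fwd$end <- fwd$w_end
      fwd$strand <- "+"
      fwd$seq <- substring(seqs[i], fwd$w_start + 1L, fwd$w_end)
      rows[[1L]] <- fwd
    }
    if (!is.null(rev) && nrow(rev)) {
      rev$start <- L - rev$w_end
      rev$end <- L - rev$w_start
      rev$strand <- "-"
      rev$seq <- substring(rc[i], rev$w_start + 1L, rev$w_end)
      rows[[2L]] <- rev
    }
    if (length(rows) == 0L) next
    df <- do.call(rbind, rows)
    hasN <- grepl("N", df$seq, fixed = TRUE)
    if (any(hasN)) {
      mgsLog("dropping ", sum(hasN), " candidate(s) containing N in ", ids[i])
      df <- df[!hasN, , drop = FALSE]
    }
    if (nrow(df) == 0L) next
    df$fragment_id <- ids[i]
    res[[i]] <- df[, c("fragment_id", "start", "end", "strand", "frame",
                       "has_start", "has_stop", "seq")]
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(fragment_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), has_start = logical(),
                      has_stop = logical(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  # locale-independent ordering (character collation varies with LC_COLLATE)
  out <- out[order(match(out$fragment_id, ids), out$start, out$end,
                   match(out$strand, c("+", "-")), out$frame), ]
  rownames(out) <- NULL
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  out$frame <- as.integer(out$frame)
  out
}
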