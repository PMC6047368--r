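# Independent reference implementations used to cross-check the package.
# Each oracle is written as a direct, unoptimized transcription of the
# intended behaviour and shares no code with the implementation it checks.

# --- six-frame ORF oracle -------------------------------------------------
# For one oriented sequence and frame, enumerate candidates by scanning
# every codon end-position and searching backwards for the leftmost
# admissible begin, using cumulative stop counts for stop-freeness.
oracleScanOneFrame <- function(w, f, minLen, starts, stops) {
  L <- nchar(w)
  ncod <- (L - f) %/% 3
  if (ncod < 1) return(NULL)
  cod <- sapply(seq_len(ncod) - 1, function(k) substr(w, f + 3 * k + 1, f + 3 * k + 3))
  isStop <- cod %in% stops
  isStart <- cod %in% starts
  cum <- cumsum(isStop)
  stopFree <- function(i, j) { # no stop among codons i..j
    if (j < i) return(TRUE)
    (cum[j] - if (i > 1) cum[i - 1] else 0) == 0
  }
  res <- list()
  emit <- function(i, j, hs, he) { # codons i..j inclusive
    if ((j - i + 1) * 3 >= minLen)
      res[[length(res) + 1]] <<- data.frame(
        w_start = f + 3 * (i - 1), w_end = f + 3 * j,
        frame = f, has_start = hs, has_stop = he)
  }
  stopIdx <- which(isStop)
  for (j in stopIdx) {
    prior <- stopIdx[stopIdx < j]
    if (length(prior) == 0) {
      # runs from the fragment boundary through this stop
      emit(1, j, isStart[1], TRUE)
    } else {
      lo <- max(prior) + 1
      cands <- if (lo <= j - 1) which(isStart & seq_len(ncod) >= lo &
                                      seq_len(ncod) <= j - 1) else integer(0)
      cands <- cands[vapply(cands, function(i) stopFree(i, j - 1), logical(1))]
      if (length(cands) > 0) emit(min(cands), j, TRUE, TRUE)
    }
  }
  # tail piece running into the right boundary
  if (length(stopIdx) == 0) {
    emit(1, ncod, isStart[1], FALSE)
  } else if (max(stopIdx) < ncod) {
    lo <- max(stopIdx) + 1
    cands <- which(isStart & seq_len(ncod) >= lo)
    cands <- cands[vapply(cands, function(i) stopFree(i, ncod), logical(1))]
    if (length(cands) > 0) emit(min(cands), ncod, TRUE, FALSE)
  }
  if (length(res) == 0) NULL else do.call(rbind, res)
}

oracleOrfs <- function(seq, minLen = 60,
                       starts = c("ATG", "GTG", "TTG"),
                       stops = c("TAA", "TAG", "TGA")) {
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (f in 0:2) {
    fw <- oracleScanOneFrame(seq, f, minLen, starts, stops)
    if (!is.null(fw)) {
      fw$start <- fw$w_start; fw$end <- fw$w_end; fw$strand <- "+"
      fw$seq <- substring(seq, fw$w_start + 1, fw$w_end)
      out[[length(out) + 1]] <- fw
    }
    rv <- oracleScanOneFrame(rc, f, minLen, starts, stops)
    if (!is.null(rv)) {
      rv$start <- L - rv$w_end; rv$end <- L - rv$w_start; rv$strand <- "-"
      rv$seq <- substring(rc, rv$w_start + 1, rv$w_end)
      out[[length(out) + 1]] <- rv
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(), strand = character(),
                      frame = integer(), has_start = logical(),
                      has_stop = logical(), seq = character()))
  }
  df <- do.call(rbind, out)
  df <- df[!grepl("N", df$seq, fixed = TRUE),
           c("start", "end", "strand", "frame", "has_start", "has_stop", "seq")]
  df[order(df$start, df$end, df$strand), ]
}

# --- brute-force greedy mRMR oracle ---------------------------------------
# Rescans every remaining feature at every step; relevance via t.test,
# redundancy via stats::cor, recomputed from scratch each time.
oracleFtest <- function(x, y) {
  unname(stats::t.test(x[y == 1], x[y == 0], var.equal = TRUE)$statistic^2)
}

oracleMrmr <- function(X, y, k) {
  p <- ncol(X)
  usable <- which(apply(X, 2, function(col) stats::sd(col) > 1e-12))
  fvals <- rep(NA_real_, p)
  for (j in usable) fvals[j] <- oracleFtest(X[, j], y)
  sel <- integer(0)
  for (step in seq_len(min(k, length(usable)))) {
    remaining <- setdiff(usable, sel)
    best <- NA; bestScore <- -Inf; bestF <- -Inf
    for (j in remaining) {
      score <- if (length(sel) == 0) fvals[j] else {
        red <- mean(abs(sapply(sel, function(s) stats::cor(X[, j], X[, s]))))
        fvals[j] / max(red, .Machine$double.eps)
      }
      if (score > bestScore ||
          (score == bestScore && fvals[j] > bestF) ||
          (score == bestScore && fvals[j] == bestF && j < best)) {
        best <- j; bestScore <- score; bestF <- fvals[j]
      }
    }
    sel <- c(sel, best)
  }
  sel
}

# --- step-by-step greedy overlap-resolution oracle ------------------------
# Literal transcription of the selection loop: move the highest-probability
# candidate to the gene list, discard overlaps > oMax, repeat.
oracleGreedy <- function(df, oMax = 60) {
  g <- df[0, , drop = FALSE]
  C <- df
  while (nrow(C) > 0) {
    ord <- order(-C$probability, -(C$end - C$start), C$start,
                 ifelse(C$strand == "+", 0, 1))
    top <- C[ord[1], , drop = FALSE]
    g <- rbind(g, top)
    ov <- pmax(0, pmin(C$end, top$end) - pmax(C$start, top$start))
    keep <- ov <= oMax
    keep[ord[1]] <- FALSE
    C <- C[keep, , drop = FALSE]
  }
  g <- g[order(g$start, g$end), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# random DNA fragment generator for property tests
randomFragment <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# normalize an ORF table for comparison
orfKey <- function(df) {
  df <- df[order(df$start, df$end, df$strand, df$frame), ]
  paste(df$start, df$end, df$strand, df$frame, df$has_start, df$has_stop,
        df$seq, sep = "|")
}
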