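# Six-frame translation into stop-free, codon-aligned candidate ORFs.
#
# Every input sequence is read in six frames (three offsets on each strand).
# Stop codons split each frame into maximal stop-free codon runs; runs long
# enough become candidate ORFs.  A frame with no stop at all yields a
# "strict" ORF spanning the whole codon-trimmed frame; a run covering at
# least `looseFraction` of the original sequence is "loose"; anything else
# is "other".  Strict ORFs seed the self-supervised SVM training set, strict
# plus loose ORFs feed the assembly graph.

FRAME_LABELS <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' The six reading-frame strings of a sequence
#'
#' Frames `+1/+2/+3` are the sequence offset by 0/1/2 bases; `-1/-2/-3` are
#' the reverse complement offset likewise.  Each frame is truncated at the
#' 3' end to a whole number of codons, so frame length is
#' `3 * floor((L - offset) / 3)`.
#'
#' @param seq a single nucleotide string (length >= 3; shorter input yields
#'   an empty result).
#' @return named character vector of up to 6 frame strings (frames shorter
#'   than one codon are dropped).
#' @export
frameSequences <- function(seq) {
  seq <- asCharSeqs(seq)[[1]]
  L <- nchar(seq)
  if (L < 3L) return(stats::setNames(character(), character()))
  rc <- revComp(seq)
  out <- character(6)
  for (i in 0:2) {
    len <- 3L * ((L - i) %/% 3L)
    out[i + 1L] <- substr(seq, i + 1L, i + len)
    out[i + 4L] <- substr(rc, i + 1L, i + len)
  }
  stats::setNames(out, FRAME_LABELS)[nchar(out) > 0L]
}

#' Extract candidate ORFs by six-frame translation
#'
#' @param seqs sequences (`DNAStringSet` or character vector); names become
#'   source ids.
#' @param minLen minimum ORF length in bp; must be a positive multiple of 3.
#'   Default 27, the default graph k, so every retained ORF contributes at
#'   least one graph node.
#' @param looseFraction a stop-free run covering at least this fraction of
#'   the original sequence is labelled `loose` (default 0.8).
#' @return data.frame with one row per ORF: `source_id`, `frame` (one of
#'   `r paste(FRAME_LABELS, collapse = ", ")`), `start` (0-based bp offset of
#'   the run on the oriented frame string, a multiple of 3), `length` (bp),
#'   `seq`, and `kind` (`strict` / `loose` / `other`).  Rows are ordered by
#'   source, then decreasing length.  Codons containing `N` are treated as
#'   non-stop.
#' @export
extractOrfs <- function(seqs, minLen = 27L, looseFraction = 0.8) {
  stopifnot(minLen >= 3L, minLen %% 3L == 0L,
            looseFraction > 0, looseFraction <= 1)
  seqs <- asCharSeqs(seqs)
  if (is.null(names(seqs))) names(seqs) <- makeIds("seq", length(seqs))
  keep <- nchar(seqs) >= 3L
  ids <- names(seqs)[keep]
  fwd <- unname(seqs[keep])
  if (length(fwd) == 0L) return(emptyOrfTable())
  rc <- revComp(fwd)
  stopsF <- stopPositionsSet(fwd)
  stopsR <- stopPositionsSet(rc)

  rows <- vector("list", length(fwd) * 6L)
  ri <- 0L
  for (i in seq_along(fwd)) {
    L <- nchar(fwd[i])
    for (strand in c("+", "-")) {
      oriented <- if (strand == "+") fwd[i] else rc[i]
      stops <- if (strand == "+") stopsF[[i]] else stopsR[[i]]
      for (off in 0:2) {
        frameLen <- 3L * ((L - off) %/% 3L)
        if (frameLen < minLen) next
        nc <- frameLen %/% 3L
        # stop codons landing on this frame's codon grid, fully inside frame
        cs <- stops[(stops - 1L - off) %% 3L == 0L & stops + 2L <= off + frameLen]
        cs <- (cs - 1L - off) %/% 3L   # 0-based codon indices of stops
        bounds <- c(-1L, cs, nc)
        runStart <- head(bounds, -1L) + 1L
        runEnd <- tail(bounds, -1L) - 1L
        lenC <- runEnd - runStart + 1L
        sel <- which(lenC * 3L >= minLen)
        if (!length(sel)) next
        strict <- length(cs) == 0L
        for (j in sel) {
          ri <- ri + 1L
          runBp <- lenC[j] * 3L
          kind <- if (strict) "strict"
                  else if (runBp >= looseFraction * L) "loose"
                  else "other"
          rows[[ri]] <- data.frame(
            source_id = ids[i],
            frame = paste0(strand, off + 1L),
            start = runStart[j] * 3L,
            length = runBp,
            seq = substr(oriented, off + runStart[j] * 3L + 1L,
                         off + (runEnd[j] + 1L) * 3L),
            kind = kind,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (ri == 0L) return(emptyOrfTable())
  out <- do.call(rbind, rows[seq_len(ri)])
  out <- out[order(match(out$source_id, ids), -out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyOrfTable <- function() {
  data.frame(source_id = character(), frame = character(), start = integer(),
             length = integer(), seq = character(), kind = character(),
             stringsAsFactors = FALSE)
}

#' Partition ORFs into the SVM-source set and the graph/test set
#'
#' @param orfs ORF table from [extractOrfs()].
#' @return list with `strict` (strict ORFs only, the source of the
#'   self-supervised training set) and `all` (strict plus loose ORFs, the
#'   set that feeds the assembly graph and the SVM test set).
#' @export
partitionOrfs <- function(orfs) {
  list(
    strict = orfs[orfs$kind == "strict", , drop = FALSE],
    all = orfs[orfs$kind %in% c("strict", "loose"), , drop = FALSE]
  )
}
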