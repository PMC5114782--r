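# Sequence input/output and read-pair merging.
#
# FASTA/FASTQ parsing is delegated to Biostrings; this layer normalises ids
# (verbatim up to the first whitespace), uppercases sequences, and provides
# an internal overlap-based pair merger in place of an external tool.

#' Read sequences from FASTA or FASTQ
#'
#' @param path input file.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (sniffed from the first
#'   non-empty character: `@` means FASTQ).
#' @return a [Biostrings::DNAStringSet] (FASTA) or
#'   [Biostrings::QualityScaledDNAStringSet] (FASTQ, Phred+33).  Names are
#'   record ids truncated at the first whitespace; sequences are uppercased.
#'   An empty file yields an empty set.
#' @export
readSeqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    checkFastq(path)
    # the reader itself warns about dropping its own metadata columns
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
  }
  names(x) <- sub("\\s.*$", "", names(x))
  if (length(x)) {
    up <- Biostrings::DNAStringSet(toupper(as.character(x)))
    S4Vectors::mcols(up) <- NULL
    if (format == "fastq") {
      nm <- names(x)
      q <- Biostrings::quality(x)
      names(up) <- NULL
      x <- Biostrings::QualityScaledDNAStringSet(up, q)
      names(x) <- nm
    } else {
      names(up) <- names(x)
      x <- up
    }
  }
  x
}

# structural FASTQ check so malformed records fail with the record index
checkFastq <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(ln)]
  if (length(ln) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(ln) %/% 4L
  for (i in seq_len(n)) {
    b <- ln[(i - 1L) * 4L + 1:4]
    if (!startsWith(b[1], "@") || !startsWith(b[3], "+"))
      stop(sprintf("malformed FASTQ record %d in %s", i, path))
    if (nchar(b[2]) != nchar(b[4]))
      stop(sprintf(
        "FASTQ record %d in %s: quality length %d != sequence length %d",
        i, path, nchar(b[4]), nchar(b[2])))
  }
  invisible(TRUE)
}

#' Write sequences as FASTA
#'
#' Round-trips with [readSeqs()] on (id, seq).
#'
#' @param records a `DNAStringSet` or named character vector.
#' @param path output file.
#' @param wrap line width for the sequence lines.
#' @return (invisibly) the number of records written.
#' @export
writeFasta <- function(records, path, wrap = 60L) {
  x <- Biostrings::DNAStringSet(asCharSeqs(records))
  if (is.null(names(x))) names(x) <- makeIds("seq", length(x))
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(wrap))
  invisible(length(x))
}

#' Write sequences as FASTQ (Phred+33)
#'
#' @param records `QualityScaledDNAStringSet`, or `DNAStringSet`/character
#'   (a constant quality of "I" is then used).
#' @param path output file.
#' @return (invisibly) the number of records written.
#' @export
writeFastq <- function(records, path) {
  if (!methods::is(records, "QualityScaledDNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(asCharSeqs(records))
    S4Vectors::mcols(seqs) <- NULL
    qual <- Biostrings::PhredQuality(strrep("I", Biostrings::width(seqs)))
    nm <- names(seqs)
    names(seqs) <- NULL
    records <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
    names(records) <- nm
  }
  Biostrings::writeXStringSet(records, filepath = path, format = "fastq",
                              qualities = Biostrings::quality(records))
  invisible(length(records))
}

#' Pair up two mate files by id
#'
#' Strips trailing `/1`, `/2` or space-delimited mate tags and checks that
#' the two files list the same fragments in the same order.
#'
#' @param path1,path2 FASTQ/FASTA files for mate 1 and mate 2.
#' @return list with elements `r1`, `r2` (sequence sets) and `id` (shared
#'   fragment ids).
#' @export
readPairs <- function(path1, path2) {
  r1 <- readSeqs(path1)
  r2 <- readSeqs(path2)
  if (length(r1) != length(r2))
    stop("mate files differ in record count")
  id1 <- stripMate(names(r1))
  id2 <- stripMate(names(r2))
  if (!identical(id1, id2))
    stop("mate ids do not correspond after suffix stripping")
  list(r1 = r1, r2 = r2, id = id1)
}

stripMate <- function(ids) sub("/[12]$", "", sub("\\s.*$", "", ids))

#' Merge overlapping read pairs into long fragments
#'
#' Internal stand-in for an external read merger.  For each pair, mate 2 is
#' reverse-complemented and every candidate overlap of at least `minOverlap`
#' bases between the mate-1 suffix and the reverse-complemented mate-2
#' prefix is scored; `N` never counts as a match.  The best overlap (lowest
#' mismatch fraction, ties to the longer overlap) is accepted when its
#' mismatch fraction is at most `maxMismatchRate`, and the pair is merged to
#' a consensus of length `len(r1) + len(r2) - overlap`: at disagreeing
#' positions the higher-quality base wins, mate 1 winning ties or when
#' qualities are absent.  Pairs with no acceptable overlap are routed to
#' `unmerged`.
#'
#' @param r1,r2 mate sequence sets (`DNAStringSet`,
#'   `QualityScaledDNAStringSet`, or character), parallel by position;
#'   mate 2 as sequenced.
#' @param minOverlap minimum overlap length in bp (default 10).
#' @param maxMismatchRate maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return list with `merged` (a named `DNAStringSet`) and `unmerged`
#'   (list of `r1`, `r2` character vectors).
#' @export
mergePairs <- function(r1, r2, minOverlap = 10L, maxMismatchRate = 0.25) {
  stopifnot(minOverlap >= 1L, maxMismatchRate >= 0, maxMismatchRate < 0.5)
  q1 <- readQuals(r1)
  q2 <- readQuals(r2)
  s1 <- asCharSeqs(r1)
  s2 <- asCharSeqs(r2)
  if (length(s1) != length(s2)) stop("mate vectors differ in length")
  ids <- if (!is.null(names(s1))) stripMate(names(s1)) else
    makeIds("pair", length(s1))

  mergedSeq <- character(0)
  mergedId <- character(0)
  keepUn <- logical(length(s1))
  for (i in seq_along(s1)) {
    a <- s1[[i]]
    b <- revComp(s2[[i]])
    qb <- if (!is.null(q2)) rev(q2[[i]]) else NULL
    qa <- if (!is.null(q1)) q1[[i]] else NULL
    res <- bestOverlap(a, b, minOverlap)
    if (is.null(res) || res$rate > maxMismatchRate) {
      keepUn[i] <- TRUE
      next
    }
    o <- res$overlap
    na <- nchar(a)
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    ovA <- av[(na - o + 1L):na]
    ovB <- bv[1:o]
    cons <- ovA
    dis <- which(ovA != ovB)
    if (length(dis) && !is.null(qa) && !is.null(qb)) {
      qA <- qa[(na - o + 1L):na][dis]
      qB <- qb[1:o][dis]
      useB <- qB > qA
      cons[dis[useB]] <- ovB[useB]
    }
    mergedSeq <- c(mergedSeq, paste0(
      substr(a, 1L, na - o), paste0(cons, collapse = ""),
      substr(b, o + 1L, nchar(b))))
    mergedId <- c(mergedId, ids[i])
  }
  merged <- Biostrings::DNAStringSet(mergedSeq)
  names(merged) <- mergedId
  list(
    merged = merged,
    unmerged = list(r1 = s1[keepUn], r2 = s2[keepUn])
  )
}

# per-read integer quality vectors, or NULL when absent
readQuals <- function(x) {
  if (!methods::is(x, "QualityScaledDNAStringSet")) return(NULL)
  lapply(as.character(Biostrings::quality(x)), function(q)
    as.integer(charToRaw(q)) - 33L)
}

# best suffix(a)/prefix(b) overlap >= minOverlap; N never matches
bestOverlap <- function(a, b, minOverlap) {
  na <- nchar(a)
  nb <- nchar(b)
  maxO <- min(na, nb)
  if (maxO < minOverlap) return(NULL)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  best <- NULL
  for (o in minOverlap:maxO) {
    x <- av[(na - o + 1L):na]
    y <- bv[1:o]
    mm <- sum(x != y | x == "N" | y == "N")
    rate <- mm / o
    if (is.null(best) || rate < best$rate ||
        (rate == best$rate && o > best$overlap)) {
      best <- list(overlap = o, mismatches = mm, rate = rate)
    }
  }
  best
}
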