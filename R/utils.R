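# Shared low-level helpers: alphabet constants, reverse complement, stop
# scanning, coercion between character vectors and Biostrings containers.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# 64 codons in lexicographic order AAA..TTT
ALL_CODONS <- sort(as.vector(outer(
  outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
  c("A", "C", "G", "T"), paste0)))

SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

#' Reverse complement of nucleotide strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' `N` stays `N`.
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revComp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# TRUE when any codon-aligned codon of `seq` (frame +1) is a stop
hasInFrameStop <- function(seq) {
  L <- nchar(seq)
  if (L < 3L) return(FALSE)
  pos <- stopPositions(seq)
  any((pos - 1L) %% 3L == 0L & pos + 2L <= 3L * (L %/% 3L))
}

# 1-based start positions of all stop-codon occurrences (any frame)
stopPositions <- function(seq) {
  s <- Biostrings::DNAString(seq)
  unlist(lapply(STOP_CODONS, function(p) {
    Biostrings::start(Biostrings::matchPattern(p, s))
  }), use.names = FALSE)
}

# Per-sequence stop positions for a whole character vector (one orientation),
# via vectorized pattern matching; returns a list of sorted integer vectors.
stopPositionsSet <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(list())
  ss <- Biostrings::DNAStringSet(seqs)
  hits <- vector("list", n)
  for (p in STOP_CODONS) {
    m <- Biostrings::vmatchPattern(p, ss)
    st <- Biostrings::startIndex(m)
    for (i in seq_len(n)) if (!is.null(st[[i]]))
      hits[[i]] <- c(hits[[i]], st[[i]])
  }
  lapply(hits, function(v) if (is.null(v)) integer() else sort(v))
}

# Accept DNAStringSet / character, return upper-case character with names
asCharSeqs <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- toupper(as.character(x))
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) {
    return(stats::setNames(toupper(x), names(x)))
  }
  stop("expected a character vector or a DNAStringSet")
}

# split a codon-aligned sequence into codons (length %% 3 must be 0)
codonSplit <- function(seq) {
  L <- nchar(seq)
  if (L == 0L) return(character())
  substring(seq, seq(1L, L - 2L, by = 3L), seq(3L, L, by = 3L))
}

# deterministic id strings: prefix_0001 ...
makeIds <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))
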