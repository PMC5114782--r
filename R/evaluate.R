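# Evaluation of predicted CDSs against a reference gene set: alignment
# ingestion (BLAT PSL) or a built-in seeded aligner, the survival filters,
# and the benchmark statistics (redundancy, ROC point, fragment number,
# base error rate, chimera rate, ortholog pair classification).

emptyAlignments <- function() {
  data.frame(
    query_id = character(), target_id = character(),
    identity = numeric(), query_coverage = numeric(),
    target_coverage = numeric(), mismatches = integer(),
    alignment_length = integer(),
    qstart = integer(), qend = integer(),
    tstart = integer(), tend = integer(),
    stringsAsFactors = FALSE)
}

#' Parse BLAT PSL alignments
#'
#' Reads the 21-column tab-separated PSL dialect (a `psLayout` header block,
#' when present, is skipped).  Identity is computed as
#' `matches / (matches + misMatches + qBaseInsert)`, coverages from the
#' aligned spans over the sequence sizes, and the alignment length as
#' `matches + misMatches + qBaseInsert + tBaseInsert`.
#'
#' @param path PSL file.
#' @return alignment record data.frame (`query_id`, `target_id`,
#'   `identity`, `query_coverage`, `target_coverage`, `mismatches`,
#'   `alignment_length`, and 0-based half-open `qstart/qend/tstart/tend`).
#' @export
readPsl <- function(path) {
  ln <- readLines(path)
  # skip header block: keep lines whose first field is an integer
  isAln <- grepl("^[0-9]+\t", ln)
  ln <- ln[isAln]
  if (!length(ln)) return(emptyAlignments())
  fields <- strsplit(ln, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 21L)
  if (length(bad))
    stop("unparseable PSL line (fewer than 21 fields) at alignment line ",
         bad[1])
  g <- function(i, num = TRUE) {
    v <- vapply(fields, `[[`, character(1), i)
    if (num) as.numeric(v) else v
  }
  matches <- g(1); misMatches <- g(2)
  qBaseInsert <- g(6); tBaseInsert <- g(8)
  qName <- g(10, FALSE); qSize <- g(11); qStart <- g(12); qEnd <- g(13)
  tName <- g(14, FALSE); tSize <- g(15); tStart <- g(16); tEnd <- g(17)
  denom <- matches + misMatches + qBaseInsert
  data.frame(
    query_id = qName, target_id = tName,
    identity = ifelse(denom > 0, matches / denom, 0),
    query_coverage = (qEnd - qStart) / qSize,
    target_coverage = (tEnd - tStart) / tSize,
    mismatches = as.integer(misMatches),
    alignment_length = as.integer(matches + misMatches + qBaseInsert +
                                    tBaseInsert),
    qstart = as.integer(qStart), qend = as.integer(qEnd),
    tstart = as.integer(tStart), tend = as.integer(tEnd),
    stringsAsFactors = FALSE)
}

#' Align predicted CDSs to a reference with a seeded aligner
#'
#' A light seed-and-extend aligner for the near-identical comparisons of
#' synthetic benchmarks (real BLAT output should be ingested with
#' [readPsl()] instead).  Query/target pairs sharing at least one exact
#' `seedLen`-mer are locally aligned with [Biostrings::pairwiseAlignment];
#' identity is matches over alignment length (gaps counted).
#'
#' @param query,target sequence sets (`DNAStringSet` or named character).
#' @param seedLen exact seed length (default 15).
#' @return alignment record data.frame as in [readPsl()].
#' @export
alignSeqs <- function(query, target, seedLen = 15L) {
  q <- asCharSeqs(query)
  t <- asCharSeqs(target)
  if (is.null(names(q))) names(q) <- makeIds("query", length(q))
  if (is.null(names(t))) names(t) <- makeIds("target", length(t))
  if (!length(q) || !length(t)) return(emptyAlignments())
  kmersOf <- function(s) {
    if (nchar(s) < seedLen) return(character())
    starts <- seq_len(nchar(s) - seedLen + 1L)
    unique(substring(s, starts, starts + seedLen - 1L))
  }
  tKmers <- lapply(t, kmersOf)
  tIdx <- rep(seq_along(t), lengths(tKmers))
  tAll <- unlist(tKmers, use.names = FALSE)
  rows <- list()
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (i in seq_along(q)) {
    qk <- kmersOf(q[[i]])
    cand <- unique(tIdx[tAll %in% qk])
    for (j in cand) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q[[i]]), Biostrings::DNAString(t[[j]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 4, gapExtension = 1)
      alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (alnLen == 0L) next
      qr <- aln@pattern@range
      tr <- aln@subject@range
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(q)[i], target_id = names(t)[j],
        identity = Biostrings::nmatch(aln) / alnLen,
        query_coverage = IRanges::width(qr) / nchar(q[[i]]),
        target_coverage = IRanges::width(tr) / nchar(t[[j]]),
        mismatches = Biostrings::nmismatch(aln),
        alignment_length = alnLen,
        qstart = IRanges::start(qr) - 1L, qend = IRanges::end(qr),
        tstart = IRanges::start(tr) - 1L, tend = IRanges::end(tr),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyAlignments())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Load alignments from PSL or compute them with the built-in aligner
#'
#' @param predicted,reference sequence sets (used when `psl` is `NULL`).
#' @param psl optional path to a BLAT PSL file.
#' @return alignment record data.frame.
#' @export
alignOrLoad <- function(predicted, reference, psl = NULL) {
  if (!is.null(psl)) readPsl(psl) else alignSeqs(predicted, reference)
}

#' Filter alignments by identity and coverage
#'
#' Strictly-greater comparisons on identity, query coverage and target
#' (reference) coverage; afterwards one best record per (query, target)
#' pair is kept (highest identity, then longest alignment).
#'
#' @param records alignment data.frame.
#' @param minIdentity,minQcov,minTcov thresholds in (0, 1]; defaults 0.90.
#' @return filtered alignment data.frame.
#' @export
filterAlignments <- function(records, minIdentity = 0.90, minQcov = 0.90,
                             minTcov = 0.90) {
  stopifnot(minIdentity > 0, minIdentity <= 1)
  keep <- records$identity > minIdentity &
    records$query_coverage > minQcov &
    records$target_coverage > minTcov
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) return(out)
  ord <- order(out$query_id, out$target_id,
               -out$identity, -out$alignment_length)
  out <- out[ord, , drop = FALSE]
  pair <- paste(out$query_id, out$target_id, sep = "\r")
  out <- out[!duplicated(pair), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Redundancy of a CDS prediction
#'
#' Number of distinct aligned predicted CDSs divided by the number of
#' reference genes.
#'
#' @param records filtered alignment data.frame.
#' @param nReference number of reference genes (>= 1).
#' @return a single number (>= 0).
#' @export
redundancy <- function(records, nReference) {
  stopifnot(nReference >= 1)
  length(unique(records$query_id)) / nReference
}

#' Sensitivity (TPR) and specificity (1 - FPR) of a CDS prediction
#'
#' Sensitivity is the fraction of reference genes with at least one
#' surviving alignment; specificity is the fraction of predicted CDSs with
#' at least one surviving alignment.
#'
#' @param records filtered alignment data.frame.
#' @param predictedIds,referenceIds the full id sets (non-empty).
#' @return named numeric `c(sensitivity = ..., specificity = ...)`.
#' @export
rocPoint <- function(records, predictedIds, referenceIds) {
  if (!length(predictedIds) || !length(referenceIds))
    stop("rocPoint is undefined for empty predicted or reference sets")
  c(sensitivity = mean(referenceIds %in% records$target_id),
    specificity = mean(predictedIds %in% records$query_id))
}

#' Average fragment number per aligned reference gene
#'
#' With `p_i` the fraction of aligned-to reference genes having exactly `i`
#' aligned CDSs, returns `sum(i * p_i)` — the mean number of predicted CDS
#' fragments per covered gene.
#'
#' @param records filtered alignment data.frame with at least one record.
#' @return a single number (>= 1).
#' @export
fragmentNumber <- function(records) {
  if (!nrow(records)) stop("fragmentNumber needs at least one aligned gene")
  perGene <- tapply(records$query_id, records$target_id,
                    function(q) length(unique(q)))
  counts <- table(factor(perGene, levels = seq_len(max(perGene))))
  p <- as.numeric(counts) / sum(counts)
  sum(seq_along(p) * p)
}

#' Mean base error rate of aligned CDSs
#'
#' Per-record mismatches over alignment length, averaged over records;
#' `pooled = TRUE` instead returns total mismatches over total aligned
#' length.
#'
#' @param records alignment data.frame with at least one record.
#' @param pooled pool before dividing (default FALSE).
#' @return a fraction in \[0, 1\].
#' @export
baseErrorRate <- function(records, pooled = FALSE) {
  if (!nrow(records)) stop("baseErrorRate needs at least one record")
  if (pooled) {
    sum(records$mismatches) / sum(records$alignment_length)
  } else {
    mean(records$mismatches / records$alignment_length)
  }
}

#' Chimera rate of a CDS prediction
#'
#' A predicted CDS longer than `minCdsBp` is chimeric when it has two or
#' more alignments to distinct reference genes, each spanning at least
#' `minFrac` of the CDS length, with query spans that are not nested and
#' overlap by less than half of the shorter span.  The rate is chimeras
#' over the number of predicted CDSs longer than `minCdsBp`.  Unfiltered
#' alignments should be supplied: a chimera's parts need not pass the
#' coverage filters.
#'
#' @param records alignment data.frame (unfiltered).
#' @param predictedLengths named integer vector of predicted CDS lengths.
#' @param minCdsBp size gate in bp (default 500).
#' @param minFrac minimum aligned fraction per part (default 0.30).
#' @return list with `rate` and `chimeric` (character vector of ids).
#' @export
chimeraRate <- function(records, predictedLengths, minCdsBp = 500L,
                        minFrac = 0.30) {
  big <- names(predictedLengths)[predictedLengths > minCdsBp]
  if (!length(big)) return(list(rate = 0, chimeric = character()))
  chim <- character()
  for (qid in big) {
    r <- records[records$query_id == qid, , drop = FALSE]
    if (nrow(r) < 2L) next
    qlen <- predictedLengths[[qid]]
    r <- r[(r$qend - r$qstart) >= minFrac * qlen, , drop = FALSE]
    if (length(unique(r$target_id)) < 2L) next
    found <- FALSE
    for (a in seq_len(nrow(r) - 1L)) {
      for (b in (a + 1L):nrow(r)) {
        if (r$target_id[a] == r$target_id[b]) next
        ov <- min(r$qend[a], r$qend[b]) - max(r$qstart[a], r$qstart[b])
        shorter <- min(r$qend[a] - r$qstart[a], r$qend[b] - r$qstart[b])
        if (ov < 0.5 * shorter) { found <- TRUE; break }
      }
      if (found) break
    }
    if (found) chim <- c(chim, qid)
  }
  list(rate = length(chim) / length(big), chimeric = chim)
}

#' Classify ortholog pairs by predicted-CDS multiplicity
#'
#' For each one-to-one reference ortholog pair, the surviving predicted
#' queries aligned to each side are counted after the ortholog filters
#' (identity > `minIdentity`, query coverage > `minQcov`, reference
#' coverage > `minTcov`, aligned length > `minAlnCodons` codons).  Pairs
#' with counts (1,1) are one-to-one, (1,>1) one-to-many, (>1,1)
#' many-to-one, (>1,>1) many-to-many; a pair with a zero side is unaligned.
#'
#' @param alignmentsA,alignmentsB alignment data.frames for species A and B.
#' @param pairs data.frame with columns `refA`, `refB` of reference ids
#'   (unique per side).
#' @param minIdentity,minQcov,minTcov ortholog filters (defaults 0.95,
#'   0.50, 0.50).
#' @param minAlnCodons minimum aligned length in codons (default 250).
#' @return list with `counts` (named integer vector over the four classes
#'   plus `unaligned`) and `perPair` (data.frame with per-side query
#'   counts and class).
#' @export
classifyOrthologPairs <- function(alignmentsA, alignmentsB, pairs,
                                  minIdentity = 0.95, minQcov = 0.50,
                                  minTcov = 0.50, minAlnCodons = 250L) {
  if (anyDuplicated(pairs$refA) || anyDuplicated(pairs$refB))
    stop("duplicate reference ids in ortholog pair list")
  surv <- function(rec) {
    rec <- filterAlignments(rec, minIdentity, minQcov, minTcov)
    rec[rec$alignment_length / 3 > minAlnCodons, , drop = FALSE]
  }
  sA <- surv(alignmentsA)
  sB <- surv(alignmentsB)
  cnt <- function(rec, refIds) {
    vapply(refIds, function(id)
      length(unique(rec$query_id[rec$target_id == id])), integer(1))
  }
  nA <- cnt(sA, pairs$refA)
  nB <- cnt(sB, pairs$refB)
  cls <- ifelse(nA == 0L | nB == 0L, "unaligned",
         ifelse(nA == 1L & nB == 1L, "one-to-one",
         ifelse(nA == 1L, "one-to-many",
         ifelse(nB == 1L, "many-to-one", "many-to-many"))))
  lev <- c("one-to-one", "one-to-many", "many-to-one", "many-to-many",
           "unaligned")
  counts <- table(factor(cls, levels = lev))
  list(
    counts = stats::setNames(as.integer(counts), lev),
    perPair = data.frame(refA = pairs$refA, refB = pairs$refB,
                         nA = nA, nB = nB, class = cls,
                         stringsAsFactors = FALSE))
}

#' Full evaluation report for a CDS prediction
#'
#' Aligns (or loads) predictions against the reference, applies the
#' survival filters, and assembles the benchmark statistics.
#'
#' @param predicted,reference sequence sets.
#' @param psl optional PSL path (skips the built-in aligner).
#' @param minIdentity,minQcov,minTcov survival filters (defaults 0.90).
#' @return list of metrics: `redundancy`, `sensitivity`, `specificity`,
#'   `fragment_number`, `base_error_rate`, `chimera_rate`, `n_predicted`,
#'   `n_reference`, plus the filtered `records`.
#' @export
evaluateCds <- function(predicted, reference, psl = NULL,
                        minIdentity = 0.90, minQcov = 0.90, minTcov = 0.90) {
  p <- asCharSeqs(predicted)
  r <- asCharSeqs(reference)
  if (is.null(names(p))) names(p) <- makeIds("cds", length(p))
  if (is.null(names(r))) names(r) <- makeIds("gene", length(r))
  raw <- alignOrLoad(p, r, psl)
  rec <- filterAlignments(raw, minIdentity, minQcov, minTcov)
  roc <- rocPoint(rec, names(p), names(r))
  ch <- chimeraRate(raw, stats::setNames(nchar(p), names(p)))
  list(
    redundancy = redundancy(rec, length(r)),
    sensitivity = unname(roc["sensitivity"]),
    specificity = unname(roc["specificity"]),
    fragment_number = if (nrow(rec)) fragmentNumber(rec) else NA_real_,
    base_error_rate = if (nrow(rec)) baseErrorRate(rec) else NA_real_,
    chimera_rate = ch$rate,
    n_predicted = length(p),
    n_reference = length(r),
    records = rec)
}
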