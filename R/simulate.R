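# Synthetic-data generation: codon-biased stop-free CDSs, gene models with
# UTRs/introns, and error-bearing short reads.  Everything the test surface
# needs is generated in code, at desk scale.

#' Codon weight presets
#'
#' Weights over the 61 sense codons used by [makeCds()].  `"uniform"` gives
#' every sense codon equal weight (no composition signal).  `"biased"` is a
#' human-like synthetic usage table: the skew matches the order of magnitude
#' of mammalian codon preference, which is what gives reading frames a
#' detectable codon-usage signature.
#'
#' @param preset `"biased"` (default) or `"uniform"`.
#' @return named numeric vector over the 61 sense codons, summing to 1.
#' @export
codonWeights <- function(preset = c("biased", "uniform")) {
  preset <- match.arg(preset)
  if (preset == "uniform") {
    w <- rep(1, length(SENSE_CODONS))
    names(w) <- SENSE_CODONS
    return(w / sum(w))
  }
  # human-like relative usage (per-1000 scale, synthetic approximation)
  w <- c(
    AAA = 24, AAC = 19, AAG = 32, AAT = 17, ACA = 15, ACC = 19, ACG = 6,
    ACT = 13, AGA = 12, AGC = 19, AGG = 12, AGT = 12, ATA = 7, ATC = 21,
    ATG = 22, ATT = 16, CAA = 12, CAC = 15, CAG = 34, CAT = 11, CCA = 17,
    CCC = 20, CCG = 7, CCT = 17, CGA = 6, CGC = 10, CGG = 11, CGT = 5,
    CTA = 7, CTC = 19, CTG = 40, CTT = 13, GAA = 29, GAC = 25, GAG = 40,
    GAT = 22, GCA = 16, GCC = 28, GCG = 7, GCT = 18, GGA = 17, GGC = 22,
    GGG = 16, GGT = 11, GTA = 7, GTC = 14, GTG = 28, GTT = 11, TAC = 15,
    TAT = 12, TCA = 12, TCC = 18, TCG = 4, TCT = 15, TGC = 13, TGG = 13,
    TGT = 11, TTA = 8, TTC = 20, TTG = 13, TTT = 18)
  w <- w[SENSE_CODONS]
  w / sum(w)
}

#' Generate a stop-free CDS by codon sampling
#'
#' Concatenates `length / 3` codons drawn from a weight table over sense
#' codons, so the result has no in-frame stop by construction.
#'
#' @param length CDS length in bp (a positive multiple of 3).
#' @param weights named weights over sense codons (default
#'   `codonWeights("biased")`); stop codons are rejected.
#' @param seed optional integer seed (omit to draw from the current RNG
#'   stream).
#' @return a single nucleotide string.
#' @export
makeCds <- function(length, weights = codonWeights("biased"), seed = NULL) {
  if (length < 3L || length %% 3L != 0L)
    stop("length must be a positive multiple of 3 (got ", length, ")")
  if (any(names(weights) %in% STOP_CODONS))
    stop("codon weight table must not contain stop codons")
  if (!all(names(weights) %in% SENSE_CODONS))
    stop("codon weight names must be sense codons")
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(names(weights), length %/% 3L, replace = TRUE,
                prob = weights), collapse = "")
}

randomBases <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build a synthetic gene model around a CDS
#'
#' Inserts `nIntrons` random-composition introns (with canonical `GT...AG`
#' termini) at random CDS offsets and attaches random UTRs, recording
#' everything needed to splice the CDS back out.
#'
#' @param cds stop-free CDS string.
#' @param nIntrons number of introns (default 3).
#' @param utrLengths lengths of the 5' and 3' UTRs in bp (default
#'   `c(150, 250)`).
#' @param intronLengthRange min/max intron length in bp (default
#'   `c(60, 400)`).
#' @param maxIntronBp hard cap on intron length (default 10000).
#' @param id gene identifier.
#' @param seed optional integer seed.
#' @return a [GeneModel-class].
#' @export
makeGene <- function(cds, nIntrons = 3L, utrLengths = c(150L, 250L),
                     intronLengthRange = c(60L, 400L), maxIntronBp = 10000L,
                     id = "gene_0001", seed = NULL) {
  stopifnot(nIntrons >= 0L, length(utrLengths) == 2L)
  if (intronLengthRange[2] > maxIntronBp)
    stop("intron length exceeds the configured cap")
  if (!is.null(seed)) set.seed(seed)
  cds <- asCharSeqs(cds)[[1]]
  pos <- sort(sample(seq_len(nchar(cds) - 1L), nIntrons))
  introns <- vapply(seq_len(nIntrons), function(i) {
    len <- sample(intronLengthRange[1]:intronLengthRange[2], 1L)
    paste0("GT", randomBases(len - 4L), "AG")
  }, character(1))
  body <- cds
  # insert right-to-left so earlier offsets stay valid
  for (i in rev(seq_len(nIntrons))) {
    body <- paste0(substr(body, 1L, pos[i]), introns[i],
                   substr(body, pos[i] + 1L, nchar(body)))
  }
  utr5 <- randomBases(utrLengths[1])
  utr3 <- randomBases(utrLengths[2])
  methods::new("GeneModel",
    id = id, cds = cds, utr5 = utr5, utr3 = utr3,
    intronPos = as.integer(pos), introns = introns,
    fullGene = paste0(utr5, body, utr3))
}

#' Simulate short reads from a template
#'
#' Two sampling models are available.  `"uniform"` draws plus-strand read
#' start positions uniformly over the template with an expected read count
#' of `depth * length(template) / readLength`.  `"fragmentation"` emulates
#' physical RNA fragmentation: whole template copies are cut at random
#' (geometric fragment lengths around `meanFragment`), and one read is
#' sequenced off a random end of each fragment, on a random strand — this
#' covers the template termini exactly, which uniform start sampling almost
#' never does.  Substitution errors are i.i.d. per base at `errorRate`
#' (uniform over the three alternative bases); there are no indels, so
#' reading-frame semantics are preserved.  Paired mode (uniform model)
#' emits mates from the two ends of uniformly placed fragments of
#' `insertSize`, mate 2 reverse-complemented.
#'
#' @param template nucleotide string.
#' @param readLength read length in bp (default 150; must not exceed the
#'   template).
#' @param depth mean per-base coverage (default 30).
#' @param errorRate per-base substitution probability in \[0, 0.1\]
#'   (default 0).
#' @param paired emit read pairs (uniform model only; default FALSE).
#' @param insertSize fragment size for paired mode (default 250).
#' @param model `"uniform"` (default) or `"fragmentation"`.
#' @param meanFragment mean fragment length for the fragmentation model
#'   (default 250).
#' @param minFragment fragments shorter than this are not sequenced
#'   (default 50).
#' @param idPrefix read id prefix.
#' @param seed optional integer seed.
#' @return unpaired: a named `DNAStringSet` with a `truth` attribute
#'   (data.frame `read_id`, `start` 0-based on the template, `strand`).
#'   Paired: list with `r1`, `r2` (both `DNAStringSet`) and `truth`.
#' @export
simulateReads <- function(template, readLength = 150L, depth = 30,
                          errorRate = 0, paired = FALSE, insertSize = 250L,
                          model = c("uniform", "fragmentation"),
                          meanFragment = 250L, minFragment = 50L,
                          idPrefix = "read", seed = NULL) {
  model <- match.arg(model)
  stopifnot(errorRate >= 0, errorRate <= 0.1, depth > 0)
  template <- asCharSeqs(template)[[1]]
  L <- nchar(template)
  if (readLength > L) stop("readLength exceeds template length")
  if (!is.null(seed)) set.seed(seed)

  if (paired) {
    stopifnot(insertSize >= readLength, insertSize <= L)
    n <- max(1L, round(depth * L / (2 * readLength)))
    starts <- sample.int(L - insertSize + 1L, n, replace = TRUE) - 1L
    frag <- substring(template, starts + 1L, starts + insertSize)
    r1 <- substr(frag, 1L, readLength)
    r2 <- revComp(substr(frag, insertSize - readLength + 1L, insertSize))
    r1 <- injectErrors(r1, errorRate)
    r2 <- injectErrors(r2, errorRate)
    ids <- sprintf("%s_%05d", idPrefix, seq_len(n))
    truth <- data.frame(read_id = ids, start = starts, strand = "+",
                        stringsAsFactors = FALSE)
    out1 <- Biostrings::DNAStringSet(r1)
    out2 <- Biostrings::DNAStringSet(r2)
    names(out1) <- paste0(ids, "/1")
    names(out2) <- paste0(ids, "/2")
    return(list(r1 = out1, r2 = out2, truth = truth))
  }

  if (model == "uniform") {
    n <- max(1L, round(depth * L / readLength))
    starts <- sample.int(L - readLength + 1L, n, replace = TRUE) - 1L
    reads <- substring(template, starts + 1L, starts + readLength)
    strand <- rep("+", n)
  } else {
    copies <- max(1L, round(depth * meanFragment / readLength))
    starts <- integer(0)
    reads <- character(0)
    strand <- character(0)
    for (cp in seq_len(copies)) {
      nCuts <- rbinom(1L, L - 1L, 1 / meanFragment)
      cuts <- sort(sample.int(L - 1L, nCuts))
      bounds <- c(0L, cuts, L)
      fs <- head(bounds, -1L)
      fe <- tail(bounds, -1L)
      keep <- (fe - fs) >= minFragment
      fs <- fs[keep]; fe <- fe[keep]
      if (!length(fs)) next
      sd <- sample(c("+", "-"), length(fs), replace = TRUE)
      for (i in seq_along(fs)) {
        flen <- fe[i] - fs[i]
        rl <- min(readLength, flen)
        if (sd[i] == "+") {
          st <- fs[i]
          reads <- c(reads, substr(template, st + 1L, st + rl))
        } else {
          st <- fe[i] - rl
          reads <- c(reads, revComp(substr(template, st + 1L, st + rl)))
        }
        starts <- c(starts, st)
        strand <- c(strand, sd[i])
      }
    }
    n <- length(reads)
  }
  reads <- injectErrors(reads, errorRate)
  ids <- sprintf("%s_%05d", idPrefix, seq_len(n))
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- ids
  attr(out, "truth") <- data.frame(read_id = ids, start = starts,
                                   strand = strand,
                                   stringsAsFactors = FALSE)
  out
}

# i.i.d. substitutions at `rate`, uniform over the three alternatives
injectErrors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  for (i in seq_along(reads)) {
    len <- nchar(reads[i])
    nMut <- rbinom(1L, len, rate)
    if (nMut == 0L) next
    pos <- sample.int(len, nMut)
    v <- strsplit(reads[i], "")[[1]]
    for (p in pos) {
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    }
    reads[i] <- paste0(v, collapse = "")
  }
  reads
}

#' Generate a complete synthetic benchmark bundle
#'
#' Draws `nGenes` codon-biased stop-free CDSs, simulates reads from each
#' (fragmentation model by default, so transcript termini are sequenced),
#' and returns genes, reads and a per-read origin truth table.  With
#' `outPrefix` set, writes `<prefix>_genes.fa`, `<prefix>_reads.fq` and
#' `<prefix>_truth.tsv`.
#'
#' @param nGenes number of genes (default 20).
#' @param cdsLengthRange min/max CDS length in bp (default
#'   `c(900, 1800)`; lengths are rounded to codons).
#' @param readLength,depth,errorRate read simulation settings (defaults
#'   150 bp, 30x, error-free).
#' @param weights codon weight table (default `codonWeights("biased")`).
#' @param model read sampling model (default `"fragmentation"`).
#' @param seed integer seed (default 1); the bundle is byte-identical per
#'   seed.
#' @param outPrefix optional output path prefix.
#' @return list with `genes` (named `DNAStringSet`), `reads` (named
#'   `DNAStringSet`) and `truth` (data.frame `read_id`, `gene_id`,
#'   `start`, `strand`).
#' @export
makeBenchmark <- function(nGenes = 20L, cdsLengthRange = c(900L, 1800L),
                          readLength = 150L, depth = 30, errorRate = 0,
                          weights = codonWeights("biased"),
                          model = "fragmentation", seed = 1L,
                          outPrefix = NULL) {
  set.seed(seed)
  lens <- 3L * sample((cdsLengthRange[1] %/% 3L):(cdsLengthRange[2] %/% 3L),
                      nGenes, replace = TRUE)
  geneIds <- makeIds("gene", nGenes)
  genes <- vapply(lens, function(L) makeCds(L, weights), character(1))
  names(genes) <- geneIds
  readsL <- vector("list", nGenes)
  truthL <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    rd <- simulateReads(genes[i], readLength = readLength, depth = depth,
                        errorRate = errorRate, model = model,
                        idPrefix = geneIds[i])
    tr <- attr(rd, "truth")
    tr$gene_id <- geneIds[i]
    readsL[[i]] <- asCharSeqs(rd)
    truthL[[i]] <- tr[, c("read_id", "gene_id", "start", "strand")]
  }
  reads <- Biostrings::DNAStringSet(unlist(readsL))
  truth <- do.call(rbind, truthL)
  rownames(truth) <- NULL
  genesSet <- Biostrings::DNAStringSet(genes)
  if (!is.null(outPrefix)) {
    writeFasta(genesSet, paste0(outPrefix, "_genes.fa"))
    writeFastq(reads, paste0(outPrefix, "_reads.fq"))
    write.table(truth, paste0(outPrefix, "_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(genes = genesSet, reads = reads, truth = truth)
}
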