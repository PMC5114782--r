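# Self-supervised SVM filtration of candidate ORFs.
#
# The training set is built from the data themselves: a codon-based de
# Bruijn graph over strictly translated ORFs is spelled into unitig contigs;
# long contigs (default >= 1 kb) are the positive class, and the stop-free
# runs of each long contig's other five reading frames are the negative
# class.  Features are 64-dimensional codon-usage frequency vectors; a
# radial-kernel SVM is fitted and its decision threshold calibrated on a
# held-out split to a target specificity ("strict" filtration).

#' Codon-usage frequency features
#'
#' One 64-dimensional vector per sequence: for each codon AAA..TTT in
#' lexicographic order, its count divided by the number of codons counted.
#' Codons containing `N` (or any non-ACGT base) are excluded from both
#' numerator and denominator; a sequence with no countable codon yields an
#' all-zero row.
#'
#' @param seqs codon-aligned sequences (character or `DNAStringSet`); every
#'   length must be a multiple of 3.
#' @return numeric matrix, `length(seqs)` rows by 64 codon columns.
#' @export
codonUsage <- function(seqs) {
  seqs <- unname(asCharSeqs(seqs))
  if (any(nchar(seqs) %% 3L != 0L))
    stop("codonUsage requires codon-aligned sequences (length %% 3 == 0)")
  m <- matrix(0, nrow = length(seqs), ncol = 64L,
              dimnames = list(NULL, ALL_CODONS))
  for (i in seq_along(seqs)) {
    cod <- codonSplit(seqs[i])
    idx <- match(cod, ALL_CODONS)   # NA for codons containing N etc.
    idx <- idx[!is.na(idx)]
    if (length(idx)) m[i, ] <- tabulate(idx, 64L) / length(idx)
  }
  m
}

#' Build the self-supervised SVM training sets
#'
#' A codon-based de Bruijn graph is built from strict ORFs only and spelled
#' into unitig contigs.  Contigs of at least `minContigBp` become the
#' positive set; for each positive contig, the longest stop-free run of each
#' of its five alternate reading frames (all but `+1`, the contig itself)
#' becomes a negative example, capping negatives at five per positive.
#'
#' @param strictOrfs strict ORF table (or character vector of sequences).
#' @param k graph k-mer size (default 27).
#' @param minContigBp positive-contig length floor in bp (default 1000).
#' @param minOrfLen minimum negative-run length in bp (default 27).
#' @return list with `positives` and `negatives` (character vectors).  When
#'   no contig reaches `minContigBp` a warning is raised and `positives` is
#'   empty, so the caller may lower the threshold.
#' @export
buildTrainingSets <- function(strictOrfs, k = 27L, minContigBp = 1000L,
                              minOrfLen = 27L) {
  stopifnot(minContigBp >= k)
  g <- buildCodonGraph(strictOrfs, k)
  contigs <- unitigs(g)$seqs
  positives <- contigs[nchar(contigs) >= minContigBp]
  if (!length(positives)) {
    warning("no unitig contig reached ", minContigBp,
            " bp; positive set is empty (consider lowering minContigBp)")
    return(list(positives = character(), negatives = character()))
  }
  negatives <- character()
  for (ctg in positives) {
    orfs <- extractOrfs(stats::setNames(ctg, "contig"),
                        minLen = minOrfLen, looseFraction = 0.8)
    alt <- orfs[orfs$frame != "+1", , drop = FALSE]
    if (!nrow(alt)) next
    # longest run per alternate frame, at most five negatives per positive
    best <- do.call(rbind, lapply(split(alt, alt$frame), function(d)
      d[which.max(d$length), , drop = FALSE]))
    negatives <- c(negatives, best$seq)
  }
  list(positives = positives, negatives = unname(negatives))
}

#' Train the codon-usage SVM
#'
#' Radial-kernel SVM (`C = 1`, `gamma = 1/64`, balanced class weights) on
#' codon-usage features.  The data are split 80/20 with a fixed seed; the
#' decision threshold is set to the `targetSpecificity` quantile of the
#' held-out negative scores, so that held-out specificity reaches the
#' target — filtration is deliberately strict, trading sensitivity for
#' specificity.
#'
#' @param positives,negatives training sequences (codon-aligned).
#' @param targetSpecificity specificity targeted by threshold calibration
#'   (default 0.95).
#' @param cost,gamma SVM hyperparameters.
#' @param seed integer seed for the split (the fit itself is
#'   deterministic).
#' @param minClassSize per-class example floor (default 20).
#' @return an [SvmModel-class].
#' @export
trainSvm <- function(positives, negatives, targetSpecificity = 0.95,
                     cost = 1, gamma = 1 / 64, seed = 1L,
                     minClassSize = 20L) {
  positives <- unname(asCharSeqs(positives))
  negatives <- unname(asCharSeqs(negatives))
  if (length(positives) < minClassSize || length(negatives) < minClassSize)
    stop(sprintf(
      "too few training examples (%d positives, %d negatives; floor %d per class)",
      length(positives), length(negatives), minClassSize))
  x <- codonUsage(c(positives, negatives))
  y <- factor(rep(c("pos", "neg"), c(length(positives), length(negatives))),
              levels = c("neg", "pos"))
  set.seed(seed)
  holdIdx <- c(
    sample(which(y == "pos"), max(1L, round(0.2 * sum(y == "pos")))),
    sample(which(y == "neg"), max(1L, round(0.2 * sum(y == "neg")))))
  train <- setdiff(seq_along(y), holdIdx)
  cw <- length(train) / (2 * table(y[train]))
  fit <- e1071::svm(x[train, , drop = FALSE], y[train],
                    kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = cw, scale = FALSE)
  decTrain <- rawDecision(fit, x[train, , drop = FALSE])
  sgn <- if (mean(decTrain[y[train] == "pos"]) >=
             mean(decTrain[y[train] == "neg"])) 1 else -1
  decHold <- sgn * rawDecision(fit, x[holdIdx, , drop = FALSE])
  hp <- decHold[y[holdIdx] == "pos"]
  hn <- decHold[y[holdIdx] == "neg"]
  threshold <- as.numeric(stats::quantile(hn, probs = targetSpecificity,
                                          type = 7, names = FALSE))
  sens <- mean(hp > threshold)
  spec <- mean(hn <= threshold)
  acc <- (sum(hp > threshold) + sum(hn <= threshold)) / length(decHold)
  # no usable signal: held-out accuracy indistinguishable from chance
  separable <- acc >= 0.6
  if (!separable)
    warning(sprintf(
      "threshold calibration reports a non-separable training set (held-out accuracy %.2f)",
      acc))
  methods::new("SvmModel",
    fit = fit, sign = sgn, threshold = threshold,
    nPos = length(positives), nNeg = length(negatives),
    seed = as.integer(seed), targetSpecificity = targetSpecificity,
    holdout = c(accuracy = acc, sensitivity = sens, specificity = spec),
    separable = separable)
}

rawDecision <- function(fit, x) {
  as.numeric(attr(predict(fit, x, decision.values = TRUE),
                  "decision.values"))
}

#' Oriented SVM decision scores for sequences
#'
#' @param model an [SvmModel-class].
#' @param seqs codon-aligned sequences.
#' @return numeric vector; scores above `svmThreshold(model)` are accepted.
#' @export
svmScores <- function(model, seqs) {
  seqs <- unname(asCharSeqs(seqs))
  if (!length(seqs)) return(numeric())
  model@sign * rawDecision(model@fit, codonUsage(seqs))
}

#' Filter candidate ORFs into reliable ORFs (rORFs)
#'
#' Scores every ORF with the codon-usage SVM; ORFs scoring above the
#' calibrated threshold are reliable (rORFs) and will supply traversal
#' landmarks.  The partition is exhaustive and disjoint and preserves
#' input order.
#'
#' @param model an [SvmModel-class].
#' @param orfs ORF table from [extractOrfs()] (or character vector).
#' @return list with `rorfs` and `rejected`, each the same type as `orfs`.
#' @export
filterOrfs <- function(model, orfs) {
  seqs <- if (is.data.frame(orfs)) orfs$seq else unname(asCharSeqs(orfs))
  if (!length(seqs)) {
    empty <- if (is.data.frame(orfs)) orfs[integer(0), , drop = FALSE]
             else orfs[integer(0)]
    return(list(rorfs = empty, rejected = empty))
  }
  acc <- svmScores(model, seqs) > model@threshold
  if (is.data.frame(orfs)) {
    list(rorfs = orfs[acc, , drop = FALSE],
         rejected = orfs[!acc, , drop = FALSE])
  } else {
    list(rorfs = orfs[acc], rejected = orfs[!acc])
  }
}
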