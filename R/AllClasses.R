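#' @import methods
#' @importFrom stats quantile predict rbinom runif setNames
#' @importFrom utils head tail read.table write.table packageVersion
NULL

#' CodonGraph: a de Bruijn graph over codon-aligned (or plain) k-mers
#'
#' Directed de Bruijn graph whose nodes are k-mer strings and whose edges
#' record observed suffix/prefix overlaps of `k - step` bases.  With
#' `step = 3` (the codon-based graph) k-mers are sampled every third base of
#' a codon-aligned ORF, so every node stays in one reading frame and an edge
#' advances the walk by exactly one codon.  With `step = 1` the object holds
#' a traditional de Bruijn graph (overlap `k - 1`), used for comparison.
#'
#' Nodes and edges carry multiplicities (number of times observed across the
#' input ORFs); topological operations ignore multiplicity, traversal uses it
#' to order children deterministically.
#'
#' @slot k k-mer size in bp (multiple of 3 when `step == 3`).
#' @slot step sliding-window step in bp: 3 for the codon-based graph, 1 for
#'   the traditional graph.
#' @slot nodes character vector of distinct k-mer sequences.
#' @slot nodeMult integer vector, observation count per node.
#' @slot edgeFrom,edgeTo integer indices into `nodes` for each distinct
#'   directed edge.
#' @slot edgeMult integer vector, observation count per edge.
#'
#' @exportClass CodonGraph
setClass("CodonGraph",
  representation(
    k = "integer",
    step = "integer",
    nodes = "character",
    nodeMult = "integer",
    edgeFrom = "integer",
    edgeTo = "integer",
    edgeMult = "integer"
  )
)

setValidity("CodonGraph", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 2L)
    msg <- c(msg, "k must be a single integer >= 2")
  if (!object@step %in% c(1L, 3L))
    msg <- c(msg, "step must be 1 or 3")
  if (object@step == 3L && object@k %% 3L != 0L)
    msg <- c(msg, "codon graphs need k to be a multiple of 3")
  n <- length(object@nodes)
  if (length(object@nodeMult) != n)
    msg <- c(msg, "nodeMult length must equal number of nodes")
  if (n > 0L && any(nchar(object@nodes) != object@k))
    msg <- c(msg, "every node must have length k")
  ne <- length(object@edgeFrom)
  if (length(object@edgeTo) != ne || length(object@edgeMult) != ne)
    msg <- c(msg, "edgeFrom/edgeTo/edgeMult lengths differ")
  if (ne > 0L) {
    if (min(object@edgeFrom, object@edgeTo) < 1L ||
        max(object@edgeFrom, object@edgeTo) > n)
      msg <- c(msg, "edge endpoints out of node range")
    # overlap contract: suffix(u, k - step) == prefix(v, k - step);
    # checked on a bounded sample so validity stays cheap on large graphs
    idx <- if (ne > 5000L) seq(1L, ne, length.out = 5000L) else seq_len(ne)
    idx <- as.integer(idx)
    ov <- object@k - object@step
    suf <- substr(object@nodes[object@edgeFrom[idx]], object@step + 1L, object@k)
    pre <- substr(object@nodes[object@edgeTo[idx]], 1L, ov)
    if (any(suf != pre))
      msg <- c(msg, "edge with suffix/prefix overlap mismatch")
  }
  if (any(object@nodeMult < 1L) || (ne > 0L && any(object@edgeMult < 1L)))
    msg <- c(msg, "multiplicities must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CodonGraph compact summary
#' @param object a `CodonGraph`
#' @export
setMethod("show", "CodonGraph", function(object) {
  kind <- if (object@step == 3L) "codon-based" else "traditional"
  cat(sprintf("CodonGraph (%s): k=%d step=%d | %d nodes, %d edges\n",
              kind, object@k, object@step,
              length(object@nodes), length(object@edgeFrom)))
  if (length(object@nodes))
    cat(sprintf("  node multiplicity: min %d / median %s / max %d\n",
                min(object@nodeMult),
                format(stats::median(object@nodeMult)),
                max(object@nodeMult)))
})

#' SvmModel: codon-usage SVM with a specificity-calibrated threshold
#'
#' Wraps a fitted radial-kernel SVM over 64-dimensional codon-usage
#' frequency vectors together with the oriented decision threshold above
#' which a sequence is called coding.  The threshold is calibrated on a
#' held-out split so that held-out specificity reaches a target (strict
#' filtration: false ORFs are preferentially rejected, at some cost in
#' sensitivity).
#'
#' @slot fit the underlying [e1071::svm] fit.
#' @slot sign +1 or -1; multiplies raw decision values so that larger
#'   oriented scores mean "coding".
#' @slot threshold oriented decision-value cutoff (score > threshold is
#'   accepted).
#' @slot nPos,nNeg training-class sizes.
#' @slot seed integer seed used for the train/calibration split.
#' @slot targetSpecificity specificity targeted during calibration.
#' @slot holdout named numeric: accuracy/sensitivity/specificity measured on
#'   the held-out split at the calibrated threshold.
#' @slot separable FALSE when the held-out split shows no usable signal.
#'
#' @exportClass SvmModel
setClass("SvmModel",
  representation(
    fit = "ANY",
    sign = "numeric",
    threshold = "numeric",
    nPos = "integer",
    nNeg = "integer",
    seed = "integer",
    targetSpecificity = "numeric",
    holdout = "numeric",
    separable = "logical"
  )
)

setValidity("SvmModel", function(object) {
  msg <- character()
  if (!is.finite(object@threshold)) msg <- c(msg, "threshold must be finite")
  if (!object@sign %in% c(-1, 1)) msg <- c(msg, "sign must be +/-1")
  if (object@nPos < 1L || object@nNeg < 1L)
    msg <- c(msg, "training metadata incomplete")
  if (length(msg)) msg else TRUE
})

#' @describeIn SvmModel compact summary
#' @param object an `SvmModel`
#' @export
setMethod("show", "SvmModel", function(object) {
  cat(sprintf(
    "SvmModel: RBF codon-usage classifier | %d pos / %d neg | threshold %.4f\n",
    object@nPos, object@nNeg, object@threshold))
  cat(sprintf("  held-out: accuracy %.3f, sensitivity %.3f, specificity %.3f%s\n",
              object@holdout[["accuracy"]], object@holdout[["sensitivity"]],
              object@holdout[["specificity"]],
              if (object@separable) "" else "  [non-separable]"))
})

#' GeneModel: a synthetic gene with UTRs and introns around a CDS
#'
#' Holds a stop-free CDS plus the synthetic gene structure built around it:
#' 5'/3' UTRs and introns (with canonical GT...AG termini) inserted at
#' recorded CDS positions.  `fullGene` is the unspliced genomic string;
#' removing introns and UTRs reconstructs the CDS exactly.
#'
#' @slot id gene identifier.
#' @slot cds stop-free coding sequence (length a multiple of 3).
#' @slot utr5,utr3 untranslated regions.
#' @slot intronPos 0-based CDS offsets at which introns are inserted.
#' @slot introns intron sequences, parallel to `intronPos`.
#' @slot fullGene spliced-in genomic sequence.
#'
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    id = "character",
    cds = "character",
    utr5 = "character",
    utr3 = "character",
    intronPos = "integer",
    introns = "character",
    fullGene = "character"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (nchar(object@cds) %% 3L != 0L)
    msg <- c(msg, "cds length must be a multiple of 3")
  if (hasInFrameStop(object@cds))
    msg <- c(msg, "cds must be stop-free in frame +1")
  if (length(object@introns) != length(object@intronPos))
    msg <- c(msg, "introns and intronPos lengths differ")
  if (!identical(spliceGene(object), object@cds))
    msg <- c(msg, "fullGene does not reconstruct the cds")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneModel compact summary
#' @param object a `GeneModel`
#' @export
setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s: CDS %d bp, UTR5 %d bp, UTR3 %d bp, %d intron(s), gene %d bp\n",
              object@id, nchar(object@cds), nchar(object@utr5),
              nchar(object@utr3), length(object@introns),
              nchar(object@fullGene)))
})

#' @describeIn CodonGraph k-mer size
#' @param x a `CodonGraph`
#' @export
graphK <- function(x) x@k

#' @describeIn CodonGraph window step (3 = codon-based, 1 = traditional)
#' @export
graphStep <- function(x) x@step

#' @describeIn CodonGraph distinct k-mer node sequences
#' @export
nodeSeqs <- function(x) x@nodes

#' @describeIn CodonGraph node observation counts
#' @export
nodeMult <- function(x) x@nodeMult

#' @describeIn CodonGraph edges as a data.frame of from/to indices, the node
#'   sequences they join and the edge multiplicity
#' @export
edgeTable <- function(x) {
  data.frame(
    from = x@edgeFrom, to = x@edgeTo,
    fromSeq = x@nodes[x@edgeFrom], toSeq = x@nodes[x@edgeTo],
    mult = x@edgeMult, stringsAsFactors = FALSE
  )
}

#' @describeIn SvmModel oriented decision threshold
#' @param x an `SvmModel`
#' @export
svmThreshold <- function(x) x@threshold

#' @describeIn SvmModel held-out accuracy/sensitivity/specificity at the
#'   calibrated threshold
#' @export
svmHoldout <- function(x) x@holdout

#' @describeIn GeneModel coding sequence of a gene model
#' @param x a `GeneModel`
#' @export
geneCds <- function(x) x@cds

#' @describeIn GeneModel unspliced genomic sequence
#' @export
geneFull <- function(x) x@fullGene

#' @describeIn GeneModel remove introns and UTRs, returning the CDS encoded
#'   by `fullGene`
#' @export
spliceGene <- function(x) {
  g <- x@fullGene
  body <- substr(g, nchar(x@utr5) + 1L, nchar(g) - nchar(x@utr3))
  if (length(x@introns) == 0L) return(body)
  # introns were inserted left-to-right at 0-based CDS offsets
  out <- character(length(x@introns) + 1L)
  cur <- 1L
  prev <- 0L
  for (i in seq_along(x@introns)) {
    seg <- x@intronPos[i] - prev
    out[i] <- substr(body, cur, cur + seg - 1L)
    cur <- cur + seg + nchar(x@introns[i])
    prev <- x@intronPos[i]
  }
  out[length(out)] <- substr(body, cur, nchar(body))
  paste0(out, collapse = "")
}
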