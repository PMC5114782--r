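# Construction of codon-based (step 3) and traditional (step 1) de Bruijn
# graphs, with node/edge accounting.

newCodonGraph <- function(k, step, nodes, nodeMult, edgeFrom, edgeTo, edgeMult) {
  methods::new("CodonGraph",
    k = as.integer(k), step = as.integer(step),
    nodes = as.character(nodes), nodeMult = as.integer(nodeMult),
    edgeFrom = as.integer(edgeFrom), edgeTo = as.integer(edgeTo),
    edgeMult = as.integer(edgeMult))
}

# shared k-mer accounting: window of k, given step, edges only from
# adjacency observed within one input sequence
buildGraph <- function(seqs, k, step) {
  seqs <- unname(asCharSeqs(seqs))
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L)
    return(newCodonGraph(k, step, character(), integer(),
                         integer(), integer(), integer()))
  kl <- lapply(seqs, function(s) {
    starts <- seq.int(1L, nchar(s) - k + 1L, by = step)
    substring(s, starts, starts + k - 1L)
  })
  nk <- lengths(kl)
  all <- unlist(kl, use.names = FALSE)
  nodes <- unique(all)
  idx <- match(all, nodes)
  nmult <- tabulate(idx, length(nodes))
  # consecutive k-mers within one sequence form one directed edge occurrence
  last <- cumsum(nk)
  first <- last - nk + 1L
  fromPos <- unlist(mapply(function(a, b) if (b > a) a:(b - 1L) else integer(),
                           first, last, SIMPLIFY = FALSE), use.names = FALSE)
  if (length(fromPos) == 0L)
    return(newCodonGraph(k, step, nodes, nmult, integer(), integer(), integer()))
  ef <- idx[fromPos]
  et <- idx[fromPos + 1L]
  key <- (as.double(ef) - 1) * length(nodes) + as.double(et)
  ukey <- unique(key)
  eidx <- match(key, ukey)
  emult <- tabulate(eidx, length(ukey))
  uf <- ef[!duplicated(key)]
  ut <- et[!duplicated(key)]
  newCodonGraph(k, step, nodes, nmult, uf, ut, emult)
}

#' Build a codon-based de Bruijn graph from ORFs
#'
#' k-mers are taken from each codon-aligned ORF with a sliding window of `k`
#' and a step of 3 bp, so every node stays in the ORF's reading frame.
#' Consecutive k-mers within one ORF create one directed edge occurrence
#' (overlap `k - 3` bp); multiplicities accumulate across ORFs.  ORFs
#' shorter than `k` contribute nothing.
#'
#' @param orfs ORF table from [extractOrfs()] (its `seq` column is used), or
#'   a character vector / `DNAStringSet` of codon-aligned sequences.
#' @param k k-mer size in bp; must be a multiple of 3 between 6 and 63.
#'   Default 27.
#' @return a [CodonGraph-class] with `step = 3`.
#' @export
buildCodonGraph <- function(orfs, k = 27L) {
  k <- as.integer(k)
  if (k %% 3L != 0L)
    stop("k must be a multiple of 3 for a codon-based graph (got ", k, ")")
  if (k < 6L || k > 63L) stop("k must be between 6 and 63")
  seqs <- if (is.data.frame(orfs)) orfs$seq else orfs
  buildGraph(seqs, k, 3L)
}

#' Build a traditional (step 1) de Bruijn graph
#'
#' k-mers at every offset; edges join k-mers overlapping by `k - 1` bp, as
#' observed within each input sequence.  Used as the comparison baseline for
#' the codon-based graph.
#'
#' @param seqs character vector / `DNAStringSet` of sequences.
#' @param k k-mer size in bp (>= 2).  Default 27.
#' @return a [CodonGraph-class] with `step = 1`.
#' @export
buildTraditionalGraph <- function(seqs, k = 27L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  buildGraph(seqs, k, 1L)
}

#' Count distinct nodes and edges of a graph
#'
#' Multiplicity is ignored: the count is over distinct k-mers and distinct
#' directed edges.
#'
#' @param graph a [CodonGraph-class].
#' @return named integer vector `c(nodes = ..., edges = ...)`.
#' @export
countNodesEdges <- function(graph) {
  c(nodes = length(graph@nodes), edges = length(graph@edgeFrom))
}

#' Node-plus-edge reduction of the codon-based graph over the traditional
#'
#' Builds both graphs from the same sequences at the same `k` and returns
#' `(nodes + edges)` of the codon-based graph divided by `(nodes + edges)`
#' of the traditional graph.  On long stop-free CDSs with distinct k-mers
#' this ratio approaches 1/3.
#'
#' @param seqs codon-aligned CDS sequences.
#' @param k k-mer size (multiple of 3).  Default 27.
#' @return list with `ratio`, `codon` and `traditional` count vectors.
#' @export
graphReduction <- function(seqs, k = 27L) {
  cg <- countNodesEdges(buildCodonGraph(seqs, k))
  tg <- countNodesEdges(buildTraditionalGraph(seqs, k))
  list(ratio = sum(cg) / sum(tg), codon = cg, traditional = tg)
}

# ---- internal adjacency helpers shared by simplification and traversal ----

outAdjacency <- function(g) {
  n <- length(g@nodes)
  adj <- vector("list", n)
  if (length(g@edgeFrom)) {
    sp <- split(g@edgeTo, g@edgeFrom)
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

inAdjacency <- function(g) {
  n <- length(g@nodes)
  adj <- vector("list", n)
  if (length(g@edgeTo)) {
    sp <- split(g@edgeFrom, g@edgeTo)
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

nodeDegrees <- function(g) {
  n <- length(g@nodes)
  list(
    indeg = tabulate(g@edgeTo, n),
    outdeg = tabulate(g@edgeFrom, n)
  )
}

# subset a graph to the nodes flagged in `keep` (logical), dropping incident
# edges and remapping indices
subsetGraph <- function(g, keep) {
  newIdx <- cumsum(keep)
  ke <- keep[g@edgeFrom] & keep[g@edgeTo]
  newCodonGraph(g@k, g@step,
    g@nodes[keep], g@nodeMult[keep],
    newIdx[g@edgeFrom[ke]], newIdx[g@edgeTo[ke]], g@edgeMult[ke])
}

# spell a node-index path into its sequence: first k-mer plus the trailing
# `step` bases of every subsequent node
spellPath <- function(g, path) {
  if (length(path) == 0L) return("")
  nodes <- g@nodes[path]
  if (length(nodes) == 1L) return(nodes)
  paste0(nodes[1L],
         paste0(substring(nodes[-1L], g@k - g@step + 1L, g@k), collapse = ""))
}

spelledLength <- function(g, nNodes) g@k + g@step * (nNodes - 1L)
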