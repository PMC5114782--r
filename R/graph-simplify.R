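# Graph simplification: tip trimming and bubble merging, plus the
# component-level classification (simple / tips / bubbles) used to describe
# graph topology before and after simplification.

# ---- tips -----------------------------------------------------------------

# A tip is a chain of nodes disconnected on one end that attaches to the
# rest of the graph at a branching node.  Returns a list of
# list(chain = <node indices>, attach = <node index or NA>); chains whose
# far end never attaches (bare isolated paths) carry attach = NA and are
# not removable.
detectTipChains <- function(g) {
  deg <- nodeDegrees(g)
  outAdj <- outAdjacency(g)
  inAdj <- inAdjacency(g)
  tips <- list()
  walk <- function(start, nextAdj, fwdDeg, revDeg) {
    # generic walk: from a degree-0 end, follow unique links until the
    # chain attaches (next node branches) or dies
    chain <- start
    cur <- start
    repeat {
      if (fwdDeg[cur] != 1L) return(list(chain = chain, attach = NA_integer_))
      nxt <- nextAdj[[cur]][1L]
      if (revDeg[nxt] > 1L || fwdDeg[nxt] > 1L)
        return(list(chain = chain, attach = nxt))
      chain <- c(chain, nxt)
      cur <- nxt
    }
  }
  srcs <- which(deg$indeg == 0L & deg$outdeg >= 1L)
  for (s in srcs)
    tips[[length(tips) + 1L]] <- walk(s, outAdj, deg$outdeg, deg$indeg)
  snks <- which(deg$outdeg == 0L & deg$indeg >= 1L)
  for (s in snks)
    tips[[length(tips) + 1L]] <- walk(s, inAdj, deg$indeg, deg$outdeg)
  tips
}

#' Trim short tips from a graph
#'
#' A tip — a chain of nodes disconnected on one end that hangs off the rest
#' of the graph at a branching node — is removed when its spelled length
#' (`k + step * (chain nodes - 1)` bp) is strictly shorter than `maxTipBp`.
#' Removal is iterated to a fixpoint, since trimming can expose new tips.
#' Isolated simple paths are not tips and are never removed.
#'
#' @param graph a [CodonGraph-class].
#' @param maxTipBp spelled-length cutoff in bp; default `2 * k`.
#' @return list with `graph` (trimmed) and `removed` (number of tip chains
#'   removed).
#' @export
trimTips <- function(graph, maxTipBp = 2L * graphK(graph)) {
  stopifnot(maxTipBp >= graphK(graph))
  removed <- 0L
  repeat {
    tips <- detectTipChains(graph)
    if (!length(tips)) break
    drop <- logical(length(graph@nodes))
    nRemoved <- 0L
    for (tp in tips) {
      if (is.na(tp$attach)) next
      if (spelledLength(graph, length(tp$chain)) < maxTipBp &&
          !any(drop[tp$chain])) {
        drop[tp$chain] <- TRUE
        nRemoved <- nRemoved + 1L
      }
    }
    if (nRemoved == 0L) break
    graph <- subsetGraph(graph, !drop)
    removed <- removed + nRemoved
  }
  list(graph = graph, removed = removed)
}

# ---- bubbles --------------------------------------------------------------

# Simple-bubble detection: from each node with out-degree >= 2, each branch
# is walked along in-degree-1/out-degree-1 interior nodes (bounded by
# maxBubbleNodes) until it reaches a node with in-degree >= 2 (candidate
# reconvergence).  Two or more branches of one source reconverging at the
# same node form a bubble.  Returns list of
# list(from, to, paths = list(interior node index vectors)).
detectBubbles <- function(g, maxBubbleNodes = 200L) {
  deg <- nodeDegrees(g)
  outAdj <- outAdjacency(g)
  bubbles <- list()
  forks <- which(deg$outdeg >= 2L)
  for (u in forks) {
    ends <- integer(0)
    paths <- list()
    for (s in outAdj[[u]]) {
      interior <- integer(0)
      cur <- s
      ok <- FALSE
      for (step in seq_len(maxBubbleNodes)) {
        if (deg$indeg[cur] >= 2L) { ok <- TRUE; break }
        if (deg$outdeg[cur] != 1L) break      # dead end or fork: no bubble
        interior <- c(interior, cur)
        cur <- outAdj[[cur]][1L]
        if (cur == u) break                   # cycled back
      }
      if (ok && cur != u) {
        ends <- c(ends, cur)
        paths[[length(paths) + 1L]] <- interior
      }
    }
    for (w in unique(ends[duplicated(ends)])) {
      sel <- which(ends == w)
      bubbles[[length(bubbles) + 1L]] <-
        list(from = u, to = w, paths = paths[sel])
    }
  }
  bubbles
}

# global alignment identity = matches / alignment length (gaps count)
alignmentIdentity <- function(a, b) {
  if (identical(a, b)) return(1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global")
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alnLen
}

#' Merge near-identical bubble paths
#'
#' A bubble is a set of alternative simple paths sharing start and end
#' nodes.  For each bubble the spelled path sequences are compared by
#' global-alignment identity (matches over alignment length, gaps counted);
#' paths whose identity to the longest path reaches `minIdentity` are
#' deleted, keeping the longest spelled path (ties broken by higher summed
#' node multiplicity, then by lexicographically smaller spelled sequence).
#' Merging is iterated to a fixpoint.
#'
#' @param graph a [CodonGraph-class].
#' @param minIdentity identity cutoff (default 0.95).
#' @param maxBubbleNodes bound on the per-branch search (default 200 nodes).
#' @return list with `graph` (merged) and `merged` (number of bubble sites
#'   at which at least one path was deleted).
#' @export
mergeBubbles <- function(graph, minIdentity = 0.95, maxBubbleNodes = 200L) {
  stopifnot(minIdentity > 0, minIdentity <= 1)
  mergedTotal <- 0L
  repeat {
    bubbles <- detectBubbles(graph, maxBubbleNodes)
    if (!length(bubbles)) break
    drop <- logical(length(graph@nodes))
    nMerged <- 0L
    for (bb in bubbles) {
      fullPaths <- lapply(bb$paths, function(p) c(bb$from, p, bb$to))
      if (any(vapply(fullPaths, function(p) any(drop[p]), logical(1)))) next
      spelled <- vapply(fullPaths, function(p) spellPath(graph, p), character(1))
      len <- nchar(spelled)
      mult <- vapply(bb$paths, function(p)
        if (length(p)) sum(graph@nodeMult[p]) else 0L, numeric(1))
      keep <- order(-len, -mult, spelled)[1L]
      del <- FALSE
      for (j in seq_along(fullPaths)) {
        if (j == keep) next
        if (alignmentIdentity(spelled[keep], spelled[j]) >= minIdentity &&
            length(bb$paths[[j]])) {
          drop[bb$paths[[j]]] <- TRUE
          del <- TRUE
        }
      }
      if (del) nMerged <- nMerged + 1L
    }
    if (nMerged == 0L) break
    graph <- subsetGraph(graph, !drop)
    mergedTotal <- mergedTotal + nMerged
  }
  list(graph = graph, merged = mergedTotal)
}

#' Simplify a graph: trim tips and merge bubbles to a joint fixpoint
#'
#' Alternates [trimTips()] and [mergeBubbles()] until a full pass removes
#' nothing, so re-running simplification on the result is a no-op.
#'
#' @inheritParams trimTips
#' @inheritParams mergeBubbles
#' @return list with `graph`, `tipsRemoved`, `bubblesMerged`.
#' @export
simplifyGraph <- function(graph, maxTipBp = 2L * graphK(graph),
                          minIdentity = 0.95, maxBubbleNodes = 200L) {
  tipsRemoved <- 0L
  bubblesMerged <- 0L
  repeat {
    tt <- trimTips(graph, maxTipBp)
    bb <- mergeBubbles(tt$graph, minIdentity, maxBubbleNodes)
    graph <- bb$graph
    tipsRemoved <- tipsRemoved + tt$removed
    bubblesMerged <- bubblesMerged + bb$merged
    if (tt$removed == 0L && bb$merged == 0L) break
  }
  list(graph = graph, tipsRemoved = tipsRemoved, bubblesMerged = bubblesMerged)
}

# ---- component classification --------------------------------------------

#' Classify weakly connected components as simple / tips / bubbles
#'
#' Components are classed mutually exclusively: `simple` means no node has
#' in-degree or out-degree above 1; `bubbles` means the component contains
#' at least one detected bubble (whether or not it also has tips — the
#' bubble class absorbs mixed cases); `tips` means it contains at least one
#' tip and no bubble.  Branching components in which the bounded detectors
#' find neither structure (rare tangles) are reported as `bubbles`.
#'
#' @param graph a [CodonGraph-class].
#' @param maxBubbleNodes bound for the bubble detector.
#' @return data.frame with one row per component (`component_id`,
#'   `n_nodes`, `n_edges`, `class`); the per-class component counts are
#'   attached as `attr(, "summary")`.
#' @export
classifyComponents <- function(graph, maxBubbleNodes = 200L) {
  n <- length(graph@nodes)
  if (n == 0L) {
    out <- data.frame(component_id = integer(), n_nodes = integer(),
                      n_edges = integer(), class = character(),
                      stringsAsFactors = FALSE)
    attr(out, "summary") <- c(simple = 0L, tips = 0L, bubbles = 0L)
    return(out)
  }
  ig <- igraph::make_empty_graph(n = n, directed = TRUE)
  if (length(graph@edgeFrom))
    ig <- igraph::add_edges(ig, rbind(graph@edgeFrom, graph@edgeTo))
  memb <- igraph::components(ig, mode = "weak")$membership
  deg <- nodeDegrees(graph)
  branching <- deg$indeg > 1L | deg$outdeg > 1L

  tipComp <- integer(0)
  for (tp in detectTipChains(graph))
    if (!is.na(tp$attach)) tipComp <- c(tipComp, memb[tp$chain[1L]])
  bubComp <- integer(0)
  for (bb in detectBubbles(graph, maxBubbleNodes))
    bubComp <- c(bubComp, memb[bb$from])

  nComp <- max(memb)
  nNodes <- tabulate(memb, nComp)
  nEdges <- tabulate(memb[graph@edgeFrom], nComp)
  hasBranch <- tabulate(memb[branching], nComp) > 0L
  cls <- ifelse(!hasBranch, "simple",
         ifelse(seq_len(nComp) %in% bubComp, "bubbles",
         ifelse(seq_len(nComp) %in% tipComp, "tips", "bubbles")))
  out <- data.frame(component_id = seq_len(nComp), n_nodes = nNodes,
                    n_edges = nEdges, class = cls, stringsAsFactors = FALSE)
  attr(out, "summary") <- c(
    simple = sum(cls == "simple"),
    tips = sum(cls == "tips"),
    bubbles = sum(cls == "bubbles"))
  out
}
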