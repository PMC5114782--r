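# Unitigs: maximal non-branching paths, spelled into contigs.

#' Extract unitig contigs from a graph
#'
#' A unitig is a maximal path in which every traversed edge `u -> v` has
#' `outdeg(u) == 1` and `indeg(v) == 1`, so the walk never crosses a
#' branch.  Every node (including isolated ones) appears in exactly one
#' unitig; self-loops and cycles terminate extension, with pure cycles
#' opened at their lexicographically smallest node.
#'
#' @param graph a [CodonGraph-class].
#' @return list with `seqs` (character vector of spelled contigs, first
#'   k-mer plus `step` bp per subsequent node) and `paths` (list of node
#'   index vectors, parallel to `seqs`).
#' @export
unitigs <- function(graph) {
  n <- length(graph@nodes)
  if (n == 0L) return(list(seqs = character(), paths = list()))
  deg <- nodeDegrees(graph)
  outAdj <- outAdjacency(graph)
  inAdj <- inAdjacency(graph)
  extendableBack <- deg$indeg == 1L &
    vapply(seq_len(n), function(v)
      if (deg$indeg[v] == 1L) deg$outdeg[inAdj[[v]][1L]] == 1L else FALSE,
      logical(1))
  visited <- logical(n)
  paths <- list()
  walkFrom <- function(s) {
    path <- s
    visited[s] <<- TRUE
    cur <- s
    repeat {
      if (deg$outdeg[cur] != 1L) break
      nxt <- outAdj[[cur]][1L]
      if (deg$indeg[nxt] != 1L || visited[nxt]) break
      path <- c(path, nxt)
      visited[nxt] <<- TRUE
      cur <- nxt
    }
    path
  }
  starts <- which(!extendableBack)
  # deterministic order
  for (s in starts[order(graph@nodes[starts])]) {
    paths[[length(paths) + 1L]] <- walkFrom(s)
  }
  # remaining unvisited nodes lie on pure cycles
  repeat {
    left <- which(!visited)
    if (!length(left)) break
    s <- left[order(graph@nodes[left])][1L]
    paths[[length(paths) + 1L]] <- walkFrom(s)
  }
  seqs <- vapply(paths, function(p) spellPath(graph, p), character(1))
  list(seqs = seqs, paths = paths)
}
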