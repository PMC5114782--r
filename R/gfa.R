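# GFA1 import/export for assembly graphs.  Segment lines carry the k-mer
# sequence and its multiplicity (RC tag); link lines carry the fixed
# (k - step)M overlap.

#' Export a graph as GFA1
#'
#' Writes one `S` line per node (sequence plus `RC:i:` multiplicity) and
#' one `L` line per directed edge with a `(k-step)M` overlap CIGAR.
#'
#' @param graph a [CodonGraph-class].
#' @param path output file.
#' @return (invisibly) the path.
#' @export
exportGFA <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tkm:i:%d\tsp:i:%d", graph@k, graph@step), con)
  n <- length(graph@nodes)
  if (n) {
    writeLines(sprintf("S\tn%d\t%s\tRC:i:%d",
                       seq_len(n), graph@nodes, graph@nodeMult), con)
  }
  if (length(graph@edgeFrom)) {
    ov <- graph@k - graph@step
    writeLines(sprintf("L\tn%d\t+\tn%d\t+\t%dM\tRC:i:%d",
                       graph@edgeFrom, graph@edgeTo, ov, graph@edgeMult), con)
  }
  invisible(path)
}

#' Import a GFA1 file written by [exportGFA()]
#'
#' @param path GFA file.
#' @return a [CodonGraph-class] reproducing the exported nodes and edges.
#' @export
importGFA <- function(path) {
  ln <- readLines(path)
  if (!length(ln)) stop("empty GFA file: ", path)
  tag <- substr(ln, 1L, 1L)
  hdr <- strsplit(ln[tag == "H"][1L], "\t", fixed = TRUE)[[1]]
  getInt <- function(key, default) {
    hit <- grep(paste0("^", key, ":i:"), hdr, value = TRUE)
    if (length(hit)) as.integer(sub(".*:", "", hit[1])) else default
  }
  sLines <- strsplit(ln[tag == "S"], "\t", fixed = TRUE)
  nodesNm <- vapply(sLines, `[[`, character(1), 2L)
  nodes <- vapply(sLines, `[[`, character(1), 3L)
  nodeMult <- vapply(sLines, function(f) {
    rc <- grep("^RC:i:", f, value = TRUE)
    if (length(rc)) as.integer(sub(".*:", "", rc[1])) else 1L
  }, integer(1))
  k <- getInt("km", if (length(nodes)) nchar(nodes[1]) else 0L)
  step <- getInt("sp", 3L)
  lLines <- strsplit(ln[tag == "L"], "\t", fixed = TRUE)
  ef <- match(vapply(lLines, `[[`, character(1), 2L), nodesNm)
  et <- match(vapply(lLines, `[[`, character(1), 4L), nodesNm)
  if (length(lLines) && anyNA(c(ef, et)))
    stop("GFA link references an unknown segment")
  em <- vapply(lLines, function(f) {
    rc <- grep("^RC:i:", f, value = TRUE)
    if (length(rc)) as.integer(sub(".*:", "", rc[1])) else 1L
  }, integer(1))
  newCodonGraph(k, step, nodes, nodeMult, ef, et, em)
}
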