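# Landmark-guided traversal: rORF k-mers are mapped onto the simplified
# graph as landmarks; a depth-first search connects landmark to landmark,
# segments are chained into maximal paths, and paths are spelled into CDSs.

#' Map rORF k-mers onto a graph as landmarks
#'
#' The landmark set is the set of graph nodes that occur among the step-3
#' k-mers of the reliable ORFs; rORF k-mers absent from the graph are
#' ignored.  Mapping is by exact k-mer match.
#'
#' @param graph a simplified [CodonGraph-class].
#' @param rorfs reliable ORFs (table from [filterOrfs()], or character
#'   vector of sequences).
#' @return integer vector of landmark node indices (each node once); the
#'   ids of the supporting rORFs per landmark are attached as
#'   `attr(, "orfIds")` (a list parallel to the landmark vector) when ids
#'   are available.
#' @export
mapLandmarks <- function(graph, rorfs) {
  if (is.data.frame(rorfs)) {
    seqs <- rorfs$seq
    oids <- if ("source_id" %in% names(rorfs)) rorfs$source_id
            else as.character(seq_along(seqs))
  } else {
    seqs <- asCharSeqs(rorfs)
    oids <- if (!is.null(names(seqs))) names(seqs)
            else as.character(seq_along(seqs))
    seqs <- unname(seqs)
  }
  k <- graph@k
  keep <- nchar(seqs) >= k
  seqs <- seqs[keep]
  oids <- oids[keep]
  if (!length(seqs)) {
    lm <- integer(0)
    attr(lm, "orfIds") <- list()
    return(lm)
  }
  kl <- lapply(seqs, function(s) {
    starts <- seq.int(1L, nchar(s) - k + 1L, by = 3L)
    substring(s, starts, starts + k - 1L)
  })
  all <- unlist(kl, use.names = FALSE)
  who <- rep(seq_along(seqs), lengths(kl))
  hit <- match(all, graph@nodes)
  ok <- !is.na(hit)
  lm <- sort(unique(hit[ok]))
  ids <- lapply(split(oids[who[ok]], hit[ok]), unique)
  attr(lm, "orfIds") <- unname(ids[as.character(lm)])
  lm
}

#' Connect landmarks by depth-first search and chain the segments
#'
#' From each landmark, a depth-first search follows out-edges — children
#' ordered by descending edge multiplicity, ties broken lexicographically —
#' never revisiting a node within one search, and halts a branch at another
#' landmark (success), at `maxDepth`, or at a dead end.  In `strict` mode
#' every node on a successful path must itself be a landmark.  Successful
#' landmark-to-landmark segments are then chained greedily (longest first,
#' each landmark serving as the start of at most one chained segment and
#' the end of at most one) into maximal paths; segments that cannot be
#' chained are kept as paths of their own.  Each path is finally extended
#' at both termini along strictly unbranching edges (the rest of its
#' containing unitig): the graph is built from all candidate ORFs
#' precisely so that stretches whose ORFs the SVM rejected still support
#' the walk, and an unbranching terminal stretch is unambiguous even
#' without a landmark.  Strict mode keeps the DFS landmark-only and adds
#' a corroboration requirement: when per-landmark rORF support is
#' available (the `orfIds` attribute of [mapLandmarks()]), a strict path
#' must be supported by at least two distinct rORFs — a lone SVM false
#' positive maps all of its own k-mers and would otherwise resurface
#' verbatim as a "CDS".
#'
#' @param graph a simplified [CodonGraph-class].
#' @param landmarks integer node indices from [mapLandmarks()].
#' @param maxDepth search depth bound in nodes (default 5000, roughly a
#'   15 kb CDS at k = 27).
#' @param mode `"default"` or `"strict"`.
#' @return list of integer node-index paths.
#' @export
connectLandmarks <- function(graph, landmarks, maxDepth = 5000L,
                             mode = c("default", "strict")) {
  mode <- match.arg(mode)
  stopifnot(maxDepth >= 1L)
  n <- length(graph@nodes)
  if (!length(landmarks)) return(list())
  isLm <- logical(n)
  isLm[landmarks] <- TRUE

  # out-adjacency with deterministic child order: multiplicity desc, k-mer asc
  adj <- vector("list", n)
  if (length(graph@edgeFrom)) {
    ord <- order(graph@edgeFrom, -graph@edgeMult, graph@nodes[graph@edgeTo])
    adj[] <- list(integer(0))
    sp <- split(graph@edgeTo[ord], graph@edgeFrom[ord])
    adj[as.integer(names(sp))] <- sp
  } else {
    adj[] <- list(integer(0))
  }

  segStart <- integer(0)
  segEnd <- integer(0)
  segs <- list()
  stamp <- integer(n)
  ctr <- 0L
  path <- integer(maxDepth + 1L)
  iter <- integer(maxDepth + 1L)
  for (s in landmarks) {
    ctr <- ctr + 1L
    depth <- 1L
    path[1L] <- s
    iter[1L] <- 0L
    stamp[s] <- ctr
    while (depth > 0L) {
      children <- adj[[path[depth]]]
      iter[depth] <- iter[depth] + 1L
      if (iter[depth] > length(children)) {
        depth <- depth - 1L
        next
      }
      v <- children[iter[depth]]
      if (stamp[v] == ctr) next
      if (isLm[v]) {
        stamp[v] <- ctr
        segs[[length(segs) + 1L]] <- c(path[seq_len(depth)], v)
        segStart <- c(segStart, s)
        segEnd <- c(segEnd, v)
        next   # do not search past a landmark
      }
      if (mode == "strict") next
      stamp[v] <- ctr
      if (depth >= maxDepth) next
      depth <- depth + 1L
      path[depth] <- v
      iter[depth] <- 0L
    }
  }
  if (!length(segs)) return(list())
  paths <- chainSegments(segs, segStart, segEnd)
  orfIds <- attr(landmarks, "orfIds")
  if (mode == "strict" && !is.null(orfIds)) {
    support <- vector("list", n)
    support[as.integer(landmarks)] <- orfIds
    nSupp <- vapply(paths, function(p)
      length(unique(unlist(support[p], use.names = FALSE))), integer(1))
    paths <- paths[nSupp >= 2L]
  }
  deg <- nodeDegrees(graph)
  inAdj <- inAdjacency(graph)
  lapply(paths, extendPathEnds, deg = deg, inAdj = inAdj,
         outAdj = adj, maxExtra = maxDepth)
}

# extend a path through strictly unbranching terminal stretches:
# backward while the head has in-degree 1 from a node with out-degree 1,
# forward while the tail has out-degree 1 to a node with in-degree 1
extendPathEnds <- function(path, deg, inAdj, outAdj, maxExtra = 5000L) {
  onPath <- new.env(hash = TRUE)
  for (v in path) onPath[[as.character(v)]] <- TRUE
  pre <- integer(0)
  v <- path[1L]
  while (length(pre) < maxExtra && deg$indeg[v] == 1L) {
    u <- inAdj[[v]][1L]
    if (deg$outdeg[u] != 1L || !is.null(onPath[[as.character(u)]])) break
    pre <- c(u, pre)
    onPath[[as.character(u)]] <- TRUE
    v <- u
  }
  post <- integer(0)
  v <- path[length(path)]
  while (length(post) < maxExtra && deg$outdeg[v] == 1L) {
    w <- outAdj[[v]][1L]
    if (deg$indeg[w] != 1L || !is.null(onPath[[as.character(w)]])) break
    post <- c(post, w)
    onPath[[as.character(w)]] <- TRUE
    v <- w
  }
  c(pre, path, post)
}

# Greedy chaining: longest segments first, each landmark at most one chained
# outgoing and one incoming segment; chains follow successor links; leftover
# segments are emitted as their own paths.
chainSegments <- function(segs, segStart, segEnd) {
  len <- lengths(segs)
  ord <- order(-len, segStart, segEnd)
  outUsed <- new.env(hash = TRUE)
  inUsed <- new.env(hash = TRUE)
  succ <- new.env(hash = TRUE)
  chained <- logical(length(segs))
  for (i in ord) {
    skey <- as.character(segStart[i])
    ekey <- as.character(segEnd[i])
    if (!is.null(outUsed[[skey]]) || !is.null(inUsed[[ekey]])) next
    outUsed[[skey]] <- i
    inUsed[[ekey]] <- i
    succ[[skey]] <- i
    chained[i] <- TRUE
  }
  consumed <- logical(length(segs))
  paths <- list()
  # chain starts: chained segments whose start landmark has no chained
  # incoming segment
  startIdx <- which(chained &
    vapply(segStart, function(s) is.null(inUsed[[as.character(s)]]),
           logical(1)))
  emitChain <- function(i0) {
    p <- segs[[i0]]
    consumed[i0] <<- TRUE
    cur <- segEnd[i0]
    repeat {
      nxt <- succ[[as.character(cur)]]
      if (is.null(nxt) || consumed[nxt]) break
      p <- c(p, segs[[nxt]][-1L])
      consumed[nxt] <<- TRUE
      cur <- segEnd[nxt]
    }
    p
  }
  for (i0 in startIdx) {
    if (consumed[i0]) next
    paths[[length(paths) + 1L]] <- emitChain(i0)
  }
  # chained segments still unconsumed lie on chain cycles; open each
  for (i0 in which(chained & !consumed)) {
    if (consumed[i0]) next
    paths[[length(paths) + 1L]] <- emitChain(i0)
  }
  # unchained segments stand alone
  for (i0 in which(!chained)) {
    paths[[length(paths) + 1L]] <- segs[[i0]]
  }
  paths
}

#' Spell node paths into CDSs and dereplicate
#'
#' Each path is spelled as its first k-mer plus 3 bp per subsequent node.
#' Exact-substring duplicates are removed, keeping the longest container;
#' output is sorted by length (descending) with stable ids.
#'
#' @param graph the [CodonGraph-class] the paths live in.
#' @param paths list of integer node-index paths.
#' @param mode traversal mode recorded in the output metadata.
#' @return a [Biostrings::DNAStringSet] of CDSs with metadata columns
#'   `path_len` (nodes) and `mode`.
#' @export
emitCds <- function(graph, paths, mode = "default") {
  if (!length(paths)) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      path_len = integer(), mode = character())
    return(out)
  }
  spelled <- vapply(paths, function(p) spellPath(graph, p), character(1))
  plen <- lengths(paths)
  ord <- order(-nchar(spelled), spelled)
  spelled <- spelled[ord]
  plen <- plen[ord]
  # drop exact duplicates, then any sequence contained in a longer one
  dup <- duplicated(spelled)
  spelled <- spelled[!dup]
  plen <- plen[!dup]
  keep <- rep(TRUE, length(spelled))
  for (i in seq_along(spelled)) {
    if (i == 1L) next
    longer <- which(keep[seq_len(i - 1L)])
    for (j in longer) {
      if (grepl(spelled[i], spelled[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- Biostrings::DNAStringSet(spelled[keep])
  names(out) <- makeIds("cds", sum(keep))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    path_len = plen[keep], mode = rep(mode, sum(keep)))
  out
}

#' Assemble full-length CDSs from reads end to end
#'
#' Runs the whole pipeline: six-frame translation into candidate ORFs;
#' self-supervised SVM training (positives: unitig contigs of the
#' strict-ORF codon graph at least `minContigBp` long; negatives: their
#' alternate-frame runs) and filtration into rORFs; construction of a
#' codon-based de Bruijn graph from all candidate (strict + loose) ORFs;
#' tip trimming and bubble merging; landmark mapping and depth-first
#' landmark-to-landmark traversal; spelling and dereplication.
#'
#' @param reads input sequences (`DNAStringSet`, character, or a FASTA/FASTQ
#'   path).
#' @param k graph k-mer size in bp (multiple of 3; default 27).
#' @param minOrf minimum ORF length in bp (default `k`).
#' @param looseFraction loose-ORF coverage fraction (default 0.8).
#' @param minContigBp positive-contig floor for SVM training (default 1000).
#' @param tipBp tip-trimming cutoff (default `2 * k`).
#' @param bubbleIdentity bubble-merging identity cutoff (default 0.95).
#' @param maxBubbleNodes bubble search bound (default 200).
#' @param targetSpecificity SVM threshold calibration target (default 0.95).
#' @param maxDepth traversal depth bound (default 5000).
#' @param mode `"default"` or `"strict"` traversal.
#' @param seed seed for the SVM split.
#' @param minClassSize SVM per-class floor (default 10; small inputs yield
#'   few long contigs).
#' @return list with `cds` (a `DNAStringSet`, see [emitCds()]), `model`
#'   (the [SvmModel-class]), `graph` (the simplified graph), and `stats`
#'   (per-stage counts).
#' @export
assembleCds <- function(reads, k = 27L, minOrf = k, looseFraction = 0.8,
                        minContigBp = 1000L, tipBp = 2L * k,
                        bubbleIdentity = 0.95, maxBubbleNodes = 200L,
                        targetSpecificity = 0.95, maxDepth = 5000L,
                        mode = c("default", "strict"), seed = 1L,
                        minClassSize = 10L) {
  mode <- match.arg(mode)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readSeqs(reads)
  orfs <- extractOrfs(reads, minLen = minOrf, looseFraction = looseFraction)
  parts <- partitionOrfs(orfs)
  ts <- buildTrainingSets(parts$strict, k = k, minContigBp = minContigBp,
                          minOrfLen = minOrf)
  model <- trainSvm(ts$positives, ts$negatives,
                    targetSpecificity = targetSpecificity, seed = seed,
                    minClassSize = minClassSize)
  filt <- filterOrfs(model, parts$all)
  g <- buildCodonGraph(parts$all, k)
  simp <- simplifyGraph(g, maxTipBp = tipBp, minIdentity = bubbleIdentity,
                        maxBubbleNodes = maxBubbleNodes)
  lms <- mapLandmarks(simp$graph, filt$rorfs)
  paths <- connectLandmarks(simp$graph, lms, maxDepth = maxDepth, mode = mode)
  cds <- emitCds(simp$graph, paths, mode = mode)
  list(
    cds = cds, model = model, graph = simp$graph,
    rorfs = filt$rorfs,
    stats = c(
      n_input = length(asCharSeqs(reads)),
      n_orfs = nrow(orfs),
      n_strict = nrow(parts$strict),
      n_graph_orfs = nrow(parts$all),
      n_rorfs = nrow(filt$rorfs),
      n_pos = length(ts$positives),
      n_neg = length(ts$negatives),
      tips_removed = simp$tipsRemoved,
      bubbles_merged = simp$bubblesMerged,
      n_nodes = length(simp$graph@nodes),
      n_edges = length(simp$graph@edgeFrom),
      n_landmarks = length(lms),
      n_cds = length(cds))
  )
}
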