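# Landmark mapping, DFS connection, chaining, spelling and the assembly
# end-to-end contract.

linearFixture <- function() {
  # a 10-node codon path at k = 6 (ORF of 6 + 3*9 = 33 bp)
  orf <- makeCds(33, seed = 201)
  list(orf = orf, graph = buildCodonGraph(orf, 6))
}

test_that("landmarks are the rORF k-mers present in the graph", {
  fx <- linearFixture()
  g <- fx$graph
  # an rORF matching nodes 3..6 contributes those four landmarks
  ror <- substr(fx$orf, 7, 21)          # 15 bp: k-mers at nodes 3,4,5,6
  lm <- mapLandmarks(g, c(r1 = ror))
  expect_equal(sort(lm), 3:6)
  # k-mers absent from the graph are ignored
  lm2 <- mapLandmarks(g, c(r1 = paste0(substr(fx$orf, 7, 15), "AAACCC")))
  expect_true(all(lm2 %in% seq_along(nodeSeqs(g))))
  # an rORF shorter than k maps nothing
  expect_length(mapLandmarks(g, c(r1 = "ATG")), 0L)
  # shared k-mers count once, both supporters recorded
  lmS <- mapLandmarks(g, c(a = ror, b = ror))
  expect_equal(sort(lmS), 3:6)
  expect_setequal(attr(lmS, "orfIds")[[1]], c("a", "b"))
})

test_that("DFS connects two landmarks along the unique simple path", {
  fx <- linearFixture()
  g <- fx$graph
  lm <- c(1L, 10L)
  paths <- connectLandmarks(g, lm, maxDepth = 50, mode = "default")
  expect_length(paths, 1L)
  expect_equal(paths[[1]], 1:10)
  # oracle: igraph's exhaustive simple-path enumeration agrees
  ig <- igraph::graph_from_edgelist(as.matrix(edgeTable(g)[, c("from", "to")]))
  allPaths <- igraph::all_simple_paths(ig, 1, 10, mode = "out")
  expect_length(allPaths, 1L)
  expect_equal(as.integer(allPaths[[1]]), paths[[1]])
})

test_that("strict mode refuses paths through non-landmark interior nodes", {
  fx <- linearFixture()
  paths <- connectLandmarks(fx$graph, c(1L, 10L), maxDepth = 50,
                            mode = "strict")
  expect_length(paths, 0L)
  # with every node a landmark the full strict path is found
  pathsAll <- connectLandmarks(fx$graph, 1:10, maxDepth = 50, mode = "strict")
  expect_equal(pathsAll[[1]], 1:10)
})

test_that("a fork with landmarks on both tips yields one path per branch", {
  stem <- makeCds(60, seed = 202)
  brA <- paste0(substr(stem, 34, 60), makeCds(30, seed = 203))
  brB <- paste0(substr(stem, 34, 60), makeCds(30, seed = 204))
  g <- buildCodonGraph(c(stem, brA, brB), 27)
  n <- length(nodeSeqs(g))
  tipA <- match(substring(brA, nchar(brA) - 26, nchar(brA)), nodeSeqs(g))
  tipB <- match(substring(brB, nchar(brB) - 26, nchar(brB)), nodeSeqs(g))
  lm <- c(1L, tipA, tipB)
  paths <- connectLandmarks(g, lm, maxDepth = 50, mode = "default")
  expect_length(paths, 2L)
  spelled <- vapply(paths, function(p) codonCDS:::spellPath(g, p),
                    character(1))
  expect_setequal(spelled, c(paste0(stem, substr(brA, 28, nchar(brA))),
                             paste0(stem, substr(brB, 28, nchar(brB)))))
})

test_that("paths spell to the documented length and dereplicate", {
  fx <- linearFixture()
  cds <- emitCds(fx$graph, list(1:10), mode = "default")
  expect_equal(unname(Biostrings::width(cds)), 6 + 3 * 9)
  expect_equal(as.character(cds)[[1]], fx$orf)
  # a sub-path is absorbed by its container
  both <- emitCds(fx$graph, list(1:10, 3:6))
  expect_length(both, 1L)
  expect_equal(S4Vectors::mcols(both)$path_len, 10L)
  expect_length(emitCds(fx$graph, list()), 0L)
})

test_that("k = 27 spelling arithmetic: a 10-node path is 54 bp", {
  orf <- makeCds(27 + 3 * 9, seed = 205)
  g <- buildCodonGraph(orf, 27)
  cds <- emitCds(g, list(1:10))
  expect_equal(unname(Biostrings::width(cds)), 54L)
})

test_that("coverage gaps fragment the output into exact substrings", {
  cds <- makeCds(1200, seed = 206)
  # tile reads over [1, 600] and [631, 1200], leaving a 30 bp gap
  s1 <- seq(1, 451, by = 15)
  s2 <- seq(631, 1051, by = 15)
  reads <- c(substring(cds, s1, s1 + 149), substring(cds, s2, s2 + 149))
  names(reads) <- paste0("r", seq_along(reads))
  orfs <- partitionOrfs(extractOrfs(reads))$all
  g <- buildCodonGraph(orfs, 27)
  lm <- mapLandmarks(g, orfs[orfs$frame == "+1", ])
  paths <- connectLandmarks(g, lm, maxDepth = 1000)
  out <- as.character(emitCds(g, paths))
  expect_gt(length(out), 1L)    # fragmented, not joined across the gap
  for (s in out) expect_true(grepl(s, cds, fixed = TRUE))
})

test_that("assembly output spells real walks with no in-frame stops", {
  asm <- benchAssembly("default")
  g <- asm$graph
  cds <- as.character(asm$cds)
  expect_gt(length(cds), 0L)
  idx <- stats::setNames(seq_along(nodeSeqs(g)), nodeSeqs(g))
  et <- edgeTable(g)
  edgeKey <- paste(et$from, et$to)
  for (s in cds[seq_len(min(25, length(cds)))]) {
    expect_equal(nchar(s) %% 3, 0)
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    starts <- seq(1, nchar(s) - 26, by = 3)
    nodes <- idx[substring(s, starts, starts + 26)]
    expect_false(anyNA(nodes))
    if (length(nodes) > 1)
      expect_true(all(paste(nodes[-length(nodes)], nodes[-1]) %in% edgeKey))
  }
  # dereplication: no output is a substring of another
  for (i in seq_len(min(20, length(cds)))) {
    others <- cds[-i][nchar(cds[-i]) >= nchar(cds[i])]
    expect_false(any(vapply(others, function(o)
      grepl(cds[i], o, fixed = TRUE), logical(1))))
  }
})
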