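# Codon-based and traditional de Bruijn graphs: construction, counts,
# simplification, unitigs, components and GFA round trip.

test_that("a 12 bp ORF at k=6 gives the hand-derived 3-node path", {
  g <- buildCodonGraph("ATGGCCGCAAAA", k = 6)
  expect_equal(nodeSeqs(g), c("ATGGCC", "GCCGCA", "GCAAAA"))
  et <- edgeTable(g)
  expect_equal(et$fromSeq, c("ATGGCC", "GCCGCA"))
  expect_equal(et$toSeq, c("GCCGCA", "GCAAAA"))
  expect_equal(unname(countNodesEdges(g)), c(3L, 2L))
})

test_that("node/edge count formulas hold for distinct-k-mer CDSs", {
  for (L in c(300L, 901L * 3L %/% 3L, 1500L)) {
    s <- makeCds(3L * (L %/% 3L), seed = L)
    cg <- countNodesEdges(buildCodonGraph(s, 27))
    tg <- countNodesEdges(buildTraditionalGraph(s, 27))
    Ls <- nchar(s)
    expect_equal(unname(cg), c((Ls - 27L) / 3L + 1L, (Ls - 27L) / 3L))
    expect_equal(unname(tg), c(Ls - 27L + 1L, Ls - 27L))
  }
  # the worked 300 bp example: (92 + 91) / (274 + 273)
  r <- graphReduction(makeCds(300, seed = 300), 27)
  expect_equal(r$ratio, 183 / 547, tolerance = 1e-12)
})

test_that("multiplicities accumulate and counts ignore them", {
  one <- buildCodonGraph("ATGGCCGCAAAA", k = 6)
  two <- buildCodonGraph(c("ATGGCCGCAAAA", "ATGGCCGCAAAA"), k = 6)
  expect_equal(nodeSeqs(two), nodeSeqs(one))
  expect_equal(nodeMult(two), 2L * nodeMult(one))
  expect_equal(countNodesEdges(two), countNodesEdges(one))
})

test_that("degenerate and invalid inputs behave as specified", {
  ga <- buildTraditionalGraph(strrep("A", 50), 5)
  expect_equal(unname(countNodesEdges(ga)), c(1L, 1L))  # self-loop
  expect_equal(unname(countNodesEdges(buildCodonGraph(character(), 27))),
               c(0L, 0L))
  expect_error(buildCodonGraph("ATGGCC", k = 28), "multiple of 3")
  # node-disjoint inputs add their counts
  a <- makeCds(300, seed = 21)
  b <- makeCds(300, seed = 22)
  expect_equal(countNodesEdges(buildCodonGraph(c(a, b), 27)),
               countNodesEdges(buildCodonGraph(a, 27)) +
                 countNodesEdges(buildCodonGraph(b, 27)))
})

test_that("codon graphs shrink to about one-third of traditional graphs", {
  set.seed(31)
  lens <- 3L * sample(300:1000, 30, replace = TRUE)
  seqs <- vapply(lens, function(L) makeCds(L), character(1))
  r <- graphReduction(seqs, 27)
  expect_lt(abs(r$ratio - 1 / 3), 0.02)
})

test_that("unitigs spell losslessly and cover every node once", {
  s <- makeCds(300, seed = 41)
  g <- buildCodonGraph(s, 27)
  u <- unitigs(g)
  expect_equal(u$seqs, s)           # single ORF spells back to itself
  m <- length(u$paths[[1]])
  expect_equal(nchar(u$seqs[1]), 27 + 3 * (m - 1))
  # Y-shaped graph: one fork, three unitigs; branches share the stem's
  # last k-mer so the fork is a real node
  stem <- makeCds(60, seed = 42)
  brA <- paste0(substr(stem, 34, 60), makeCds(30, seed = 43))
  brB <- paste0(substr(stem, 34, 60), makeCds(30, seed = 44))
  gy <- buildCodonGraph(c(stem, brA, brB), 27)
  uy <- unitigs(gy)
  expect_length(uy$seqs, 3L)
  expect_equal(sort(unlist(uy$paths)), seq_along(nodeSeqs(gy)))
  # rebuilding from unitig contigs reproduces the node set
  g2 <- buildCodonGraph(uy$seqs, 27)
  expect_setequal(nodeSeqs(g2), nodeSeqs(gy))
})

test_that("short side branches are trimmed; bare paths never are", {
  path <- makeCds(6 + 3 * 19, seed = 2)          # 20-node path at k=6
  g <- buildCodonGraph(path, 6)
  n5 <- nodeSeqs(g)[5]
  gb <- buildCodonGraph(c(path, paste0(n5, "AGTCAT")), 6)  # 2-node tip
  expect_equal(unname(countNodesEdges(gb))[1], 22L)
  tr <- trimTips(gb, maxTipBp = 12)              # tip spells 9 < 12
  expect_equal(tr$removed, 1L)
  expect_equal(countNodesEdges(tr$graph), countNodesEdges(g))
  again <- trimTips(tr$graph, maxTipBp = 12)
  expect_equal(again$removed, 0L)                # idempotent at fixpoint
  plain <- trimTips(g, maxTipBp = 12)
  expect_equal(plain$removed, 0L)                # a bare path is not a tip
})

test_that("a tip spelling exactly 2k bp is retained (strictly-shorter rule)", {
  path <- makeCds(6 + 3 * 19, seed = 2)
  g <- buildCodonGraph(path, 6)
  n5 <- nodeSeqs(g)[5]
  # 3-node branch spells 6 + 3*2 = 12 = 2k exactly
  gb <- buildCodonGraph(c(path, paste0(n5, "AGTCATCGA")), 6)
  tr <- trimTips(gb, maxTipBp = 12)
  expect_equal(tr$removed, 0L)
  expect_equal(unname(countNodesEdges(tr$graph))[1], 23L)
})

test_that("near-identical bubble paths merge, divergent ones are kept", {
  a <- makeCds(60, seed = 3)
  b <- a
  substr(b, 31, 31) <- if (substr(a, 31, 31) == "A") "C" else "A"
  g <- buildCodonGraph(c(a, b), 9)
  mb <- mergeBubbles(g, minIdentity = 0.95)
  expect_equal(mb$merged, 1L)
  surv <- unitigs(mb$graph)$seqs
  expect_length(surv, 1L)                   # one 60 bp path survives
  expect_true(surv %in% c(a, b))
  expect_equal(mergeBubbles(mb$graph, 0.95)$merged, 0L)
  # paths sharing only their flanks (identity << 0.95) both survive
  pre <- makeCds(30, seed = 51)
  post <- makeCds(30, seed = 52)
  g2 <- buildCodonGraph(c(paste0(pre, makeCds(30, seed = 53), post),
                          paste0(pre, makeCds(30, seed = 54), post)), 9)
  mb2 <- mergeBubbles(g2, minIdentity = 0.95)
  expect_equal(mb2$merged, 0L)
  expect_equal(countNodesEdges(mb2$graph), countNodesEdges(g2))
})

test_that("components classify as simple, tips or bubbles", {
  path <- makeCds(120, seed = 61)
  expect_equal(classifyComponents(buildCodonGraph(path, 27))$class, "simple")
  g <- buildCodonGraph(path, 6)
  n5 <- nodeSeqs(g)[5]
  withTip <- buildCodonGraph(c(path, paste0(n5, "AGTCAT")), 6)
  expect_equal(classifyComponents(withTip)$class, "tips")
  a <- makeCds(60, seed = 3)
  b <- a
  substr(b, 31, 31) <- if (substr(a, 31, 31) == "A") "C" else "A"
  diamond <- buildCodonGraph(c(a, b), 9)
  expect_equal(classifyComponents(diamond)$class, "bubbles")
  # one component per class when all three fixtures coexist
  all3 <- buildCodonGraph(c(makeCds(120, seed = 62), a, b), 9)
  cc <- classifyComponents(all3)
  expect_equal(sort(cc$class), c("bubbles", "simple"))
})

test_that("GFA export/import round-trips nodes and edges", {
  f <- withr::local_tempfile(fileext = ".gfa")
  g <- buildCodonGraph(makeCds(120, seed = 71), 27)
  exportGFA(g, f)
  ln <- readLines(f)
  expect_equal(sum(startsWith(ln, "S")), length(nodeSeqs(g)))
  expect_equal(sum(startsWith(ln, "L")), nrow(edgeTable(g)))
  g2 <- importGFA(f)
  expect_equal(nodeSeqs(g2), nodeSeqs(g))
  expect_equal(nodeMult(g2), nodeMult(g))
  expect_equal(edgeTable(g2), edgeTable(g))
  expect_equal(graphK(g2), graphK(g))
  # empty graph: header only
  f2 <- withr::local_tempfile(fileext = ".gfa")
  exportGFA(buildCodonGraph(character(), 27), f2)
  expect_equal(length(readLines(f2)), 1L)
})
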