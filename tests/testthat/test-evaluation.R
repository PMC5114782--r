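# Alignment ingestion and the CDS benchmark statistics.

test_that("PSL fields convert to identity, coverage and spans", {
  f <- withr::local_tempfile(fileext = ".psl")
  hdr <- c("psLayout version 3", "", "match\tmis-", "---------------")
  aln <- paste(c(950, 50, 0, 0, 0, 0, 0, 0, "+", "q1", 1000, 0, 1000,
                 "t1", 1000, 0, 1000, 1, 1000, 0, 1000), collapse = "\t")
  writeLines(c(hdr, aln), f)
  r <- readPsl(f)
  expect_equal(nrow(r), 1L)
  expect_equal(r$identity, 0.95)
  expect_equal(r$query_coverage, 1)
  expect_equal(r$target_coverage, 1)
  expect_equal(r$mismatches, 50L)
  expect_equal(r$alignment_length, 1000L)
})

test_that("malformed PSL lines fail with the line number", {
  f <- withr::local_tempfile(fileext = ".psl")
  writeLines(paste(c(950, 50, 0, 0, 0), collapse = "\t"), f)
  expect_error(readPsl(f), "line 1")
})

test_that("the built-in aligner recovers identical and absent homology", {
  ref <- Biostrings::DNAStringSet(c(g1 = makeCds(600, seed = 301)))
  r <- alignSeqs(ref, ref)
  expect_equal(nrow(r), 1L)
  expect_equal(r$identity, 1)
  expect_equal(r$query_coverage, 1)
  expect_equal(r$target_coverage, 1)
  none <- alignSeqs(Biostrings::DNAStringSet(c(q = makeCds(600, seed = 302))),
                    ref)
  expect_equal(nrow(none), 0L)
})

test_that("survival filters use strict inequalities and keep best per pair", {
  r <- rbind(rec("q1", "t1", identity = 0.92, qcov = 0.95, tcov = 0.85),
             rec("q2", "t1", identity = 0.95, qcov = 0.95, tcov = 0.95),
             rec("q3", "t1", identity = 0.90, qcov = 0.95, tcov = 0.95),
             rec("q2", "t1", identity = 0.93, qcov = 0.95, tcov = 0.95))
  out <- filterAlignments(r)
  expect_equal(out$query_id, "q2")
  expect_equal(out$identity, 0.95)   # best record per (query, target)
})

test_that("redundancy divides aligned queries by reference count", {
  r10 <- do.call(rbind, lapply(1:10, function(i)
    rec(sprintf("q%d", i), sprintf("t%d", (i - 1) %% 5 + 1)))
  )
  expect_equal(redundancy(r10, 5), 2)
  expect_equal(redundancy(r10[0, ], 5), 0)
  r5 <- do.call(rbind, lapply(1:5, function(i)
    rec(sprintf("q%d", i), sprintf("t%d", i))))
  expect_equal(redundancy(r5, 5), 1)
})

test_that("the ROC point counts covered references and aligned queries", {
  r <- rbind(rec("q1", "t1"), rec("q2", "t2"), rec("q3", "t3"))
  roc <- rocPoint(r, paste0("q", 1:3), paste0("t", 1:4))
  expect_equal(unname(roc["sensitivity"]), 0.75)
  expect_equal(unname(roc["specificity"]), 1)
  roc0 <- rocPoint(r[0, ], "q1", "t1")
  expect_equal(unname(roc0), c(0, 0))
  expect_error(rocPoint(r, character(), "t1"), "empty")
})

test_that("fragment number is the support-weighted mean over covered genes", {
  # 20 genes: 18 hit once, 1 twice, 1 three times -> 1.15
  r <- rbind(
    do.call(rbind, lapply(1:18, function(i) rec(sprintf("q%d", i),
                                                sprintf("t%d", i)))),
    rec("q19", "t19"), rec("q20", "t19"),
    rec("q21", "t20"), rec("q22", "t20"), rec("q23", "t20"))
  expect_equal(fragmentNumber(r), 1.15)
  one <- do.call(rbind, lapply(1:5, function(i) rec(sprintf("q%d", i),
                                                    sprintf("t%d", i))))
  expect_equal(fragmentNumber(one), 1)
  two <- rbind(rec("q1", "tA"), rec("q2", "tB"), rec("q3", "tB"),
               rec("q4", "tB"))
  expect_equal(fragmentNumber(two), 2)     # (1 + 3) / 2
  expect_error(fragmentNumber(two[0, ]), "at least one")
})

test_that("the p_i formula equals the direct per-gene mean on random data", {
  for (s in 1:100) {
    r <- randomRecords(nGenes = sample(3:12, 1), nQueries = sample(5:40, 1),
                       seed = s)
    direct <- mean(tapply(r$query_id, r$target_id,
                          function(q) length(unique(q))))
    expect_equal(fragmentNumber(r), unname(direct))
  }
})

test_that("redundancy factors into fragment number times coverage", {
  for (s in 1:20) {
    nGenes <- 10
    r <- randomRecords(nGenes, sample(5:40, 1), seed = 1000 + s)
    covered <- length(unique(r$target_id))
    expect_equal(redundancy(r, nGenes),
                 fragmentNumber(r) * covered / nGenes)
  }
})

test_that("relaxing the filters never lowers sensitivity", {
  for (s in 1:10) {
    r <- randomRecords(8, 30, seed = 2000 + s)
    refs <- sprintf("g%02d", 1:8)
    strictRec <- filterAlignments(r, 0.95, 0.95, 0.95)
    looseRec <- filterAlignments(r, 0.90, 0.90, 0.90)
    expect_gte(rocPoint(looseRec, unique(r$query_id), refs)["sensitivity"],
               rocPoint(strictRec, unique(r$query_id), refs)["sensitivity"])
  }
})

test_that("base error rate averages mismatch fractions", {
  expect_equal(baseErrorRate(rec("q", "t", mismatches = 5L, alnLen = 500L)),
               0.01)
  expect_equal(baseErrorRate(rec("q", "t", mismatches = 0L)), 0)
  two <- rbind(rec("q1", "t", mismatches = 5L, alnLen = 500L),
               rec("q2", "t", mismatches = 15L, alnLen = 500L))
  expect_equal(baseErrorRate(two), 0.02)
  expect_equal(baseErrorRate(two, pooled = TRUE), 20 / 1000)
})

test_that("the chimera rule needs two sizeable non-nested foreign parts", {
  lens <- c(c1 = 600L, c2 = 600L, c3 = 400L)
  # c1: 40% to geneA and 35% to geneB, disjoint spans -> chimeric
  r <- rbind(
    rec("c1", "geneA", qstart = 0L, qend = 240L),
    rec("c1", "geneB", qstart = 300L, qend = 510L),
    # c2: second part below 30% -> clean
    rec("c2", "geneA", qstart = 0L, qend = 240L),
    rec("c2", "geneB", qstart = 400L, qend = 520L),
    # c3: under the size gate, never counted
    rec("c3", "geneA", qstart = 0L, qend = 200L),
    rec("c3", "geneB", qstart = 200L, qend = 400L))
  ch <- chimeraRate(r, lens)
  expect_equal(ch$chimeric, "c1")
  expect_equal(ch$rate, 0.5)        # 1 chimera of 2 CDSs > 500 bp
  # nested/overlapping spans to two genes do not count
  rNest <- rbind(rec("c1", "geneA", qstart = 0L, qend = 240L),
                 rec("c1", "geneB", qstart = 0L, qend = 210L))
  expect_equal(chimeraRate(rNest, lens["c1"])$rate, 0)
  expect_equal(chimeraRate(r[0, ], c(x = 400L))$rate, 0)
})

test_that("ortholog pairs classify by per-side query multiplicity", {
  mkRec <- function(qs, t) do.call(rbind, lapply(qs, function(q)
    rec(q, t, identity = 0.99, qcov = 0.9, tcov = 0.9, alnLen = 900L)))
  alnA <- rbind(mkRec("a1", "hsA"), mkRec(c("a2", "a3", "a4"), "hsB"),
                mkRec("a5", "hsC"))
  alnB <- rbind(mkRec("b1", "mmA"), mkRec("b2", "mmB"))
  # hsC's only alignment is 240 codons: dropped by the codon-length rule
  alnA$alignment_length[alnA$target_id == "hsC"] <- 720L
  pairs <- data.frame(refA = c("hsA", "hsB", "hsC"),
                      refB = c("mmA", "mmB", "mmC"),
                      stringsAsFactors = FALSE)
  res <- classifyOrthologPairs(alnA, alnB, pairs)
  expect_equal(res$perPair$class, c("one-to-one", "many-to-one", "unaligned"))
  expect_equal(unname(res$counts[c("one-to-one", "many-to-one", "unaligned")]),
               c(1L, 1L, 1L))
  dup <- data.frame(refA = c("hsA", "hsA"), refB = c("mmA", "mmB"))
  expect_error(classifyOrthologPairs(alnA, alnB, dup), "duplicate")
})
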