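# Codon-usage features, self-supervised training sets, and SVM filtration.

test_that("codon usage frequencies are counted and normalised correctly", {
  m <- codonUsage(c("ATGGCCATG", "ATGATG", "ATGNNNGCC"))
  expect_equal(unname(m[1, "ATG"]), 2 / 3)
  expect_equal(unname(m[1, "GCC"]), 1 / 3)
  expect_equal(sum(m[1, ]), 1)
  expect_equal(unname(m[2, "ATG"]), 1)
  expect_equal(unname(m[3, "ATG"]), 0.5)  # N codon excluded from both sides
  expect_equal(unname(m[3, "GCC"]), 0.5)
  expect_error(codonUsage("ATGC"), "codon-aligned")
  # invariant under id/order of other sequences
  m2 <- codonUsage(c("ATGATG", "ATGGCCATG"))
  expect_equal(m2[2, ], m[1, ])
})

test_that("an all-ambiguous sequence yields an all-zero feature row", {
  m <- codonUsage("NNNNNN")
  expect_equal(sum(m), 0)
})

test_that("training sets come from long strict-ORF contigs and their frames", {
  cds <- makeCds(1200, seed = 81)
  # strict ORFs tiling the CDS with >= k+3 overlaps reassemble it
  starts <- seq(1, 1051, by = 30)
  tiles <- substring(cds, starts, starts + 149)
  ts <- buildTrainingSets(tiles, k = 27, minContigBp = 1000)
  expect_equal(ts$positives, cds)
  expect_lte(length(ts$negatives), 5L)
  expect_gt(length(ts$negatives), 0L)
  # negatives live on the contig (either strand) but none is the contig
  onEither <- vapply(ts$negatives, function(s)
    grepl(s, cds, fixed = TRUE) || grepl(s, revComp(cds), fixed = TRUE),
    logical(1))
  expect_true(all(onEither))
  expect_false(cds %in% ts$negatives)
  # duplicated ORFs change multiplicity only, not the contigs
  ts2 <- buildTrainingSets(c(tiles, tiles), k = 27, minContigBp = 1000)
  expect_equal(ts2$positives, ts$positives)
})

test_that("short contigs leave the positive set empty with a warning", {
  tiles <- c(substring(makeCds(600, seed = 82), seq(1, 451, 50),
                       pmin(seq(1, 451, 50) + 149, 600)),
             substring(makeCds(600, seed = 83), seq(1, 451, 50),
                       pmin(seq(1, 451, 50) + 149, 600)))
  expect_warning(ts <- buildTrainingSets(tiles, k = 27, minContigBp = 1000),
                 "positive set is empty")
  expect_length(ts$positives, 0L)
})

test_that("biased-vs-uniform training separates with high held-out accuracy", {
  fx <- svmFixture()
  ho <- svmHoldout(fx$model)
  expect_gte(ho[["accuracy"]], 0.9)
  expect_gte(ho[["specificity"]], 0.9)
})

test_that("training is deterministic given data and seed", {
  set.seed(101)
  pos <- vapply(rep(150, 30), makeCds, character(1),
                weights = codonWeights("biased"))
  neg <- vapply(rep(150, 30), makeCds, character(1),
                weights = codonWeights("uniform"))
  m1 <- trainSvm(pos, neg, seed = 5, minClassSize = 20)
  m2 <- trainSvm(pos, neg, seed = 5, minClassSize = 20)
  expect_identical(svmThreshold(m1), svmThreshold(m2))
  probe <- vapply(rep(150, 10), makeCds, character(1))
  expect_identical(svmScores(m1, probe), svmScores(m2, probe))
})

test_that("identical positive and negative sets are flagged non-separable", {
  set.seed(102)
  same <- vapply(rep(150, 40), makeCds, character(1))
  expect_warning(m <- trainSvm(same, same, seed = 1, minClassSize = 20),
                 "non-separable")
  expect_false(m@separable)
  expect_lt(abs(svmHoldout(m)[["accuracy"]] - 0.5), 0.2)
})

test_that("the class-size floor is enforced with counts in the message", {
  expect_error(trainSvm(c("ATGATG"), c("GCCGCC"), minClassSize = 20),
               "1 positives, 1 negatives")
})

test_that("filtration accepts training-like ORFs and rejects uniform ones", {
  fx <- svmFixture()
  res <- filterOrfs(fx$model, fx$pos)
  expect_gte(length(res$rorfs) / length(fx$pos), 0.9)
  expect_equal(sort(c(res$rorfs, res$rejected)), sort(fx$pos))
  set.seed(103)
  freshPos <- vapply(rep(300, 200), makeCds, character(1),
                     weights = codonWeights("biased"))
  freshNeg <- vapply(rep(300, 200), makeCds, character(1),
                     weights = codonWeights("uniform"))
  sens <- length(filterOrfs(fx$model, freshPos)$rorfs) / 200
  spec <- length(filterOrfs(fx$model, freshNeg)$rejected) / 200
  expect_gte(sens, 0.85)
  expect_gte(spec, 0.9)
  # empty input, and determinism of the partition
  e <- filterOrfs(fx$model, character())
  expect_length(e$rorfs, 0L)
  expect_length(e$rejected, 0L)
  expect_identical(filterOrfs(fx$model, freshPos)$rorfs,
                   filterOrfs(fx$model, freshPos)$rorfs)
})

test_that("held-out accuracy grows with codon-usage divergence", {
  wb <- codonWeights("biased")
  wu <- codonWeights("uniform")
  acc <- vapply(c(0.3, 0.6, 1), function(a) {
    w <- a * wb + (1 - a) * wu
    w <- w / sum(w)
    set.seed(104)
    pos <- vapply(rep(300, 200), makeCds, character(1), weights = w)
    neg <- vapply(rep(300, 200), makeCds, character(1), weights = wu)
    m <- suppressWarnings(trainSvm(pos, neg, seed = 104))
    svmHoldout(m)[["accuracy"]]
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("longer test sequences classify with no worse sensitivity", {
  fx <- svmFixture()
  set.seed(105)
  sens <- vapply(c(99, 300, 498, 798), function(len) {
    ts <- vapply(rep(len, 300), makeCds, character(1),
                 weights = codonWeights("biased"))
    mean(svmScores(fx$model, ts) > svmThreshold(fx$model))
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
})
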