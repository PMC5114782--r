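# Shared fixtures, memoised so expensive simulations run once per session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# the main error-free benchmark: 20 codon-biased CDSs, 150 bp reads at 30x
benchFixture <- function() {
  memo("bench", makeBenchmark(nGenes = 20, seed = 7))
}

benchAssembly <- function(mode = "default") {
  memo(paste0("asm_", mode), {
    assembleCds(benchFixture()$reads, seed = 7, mode = mode)
  })
}

benchEval <- function(mode = "default") {
  memo(paste0("eval_", mode), {
    evaluateCds(benchAssembly(mode)$cds, benchFixture()$genes)
  })
}

# a noisy graph: reads at 1% substitution error from 10 genes
noisyGraphFixture <- function() {
  memo("noisy", {
    bench <- makeBenchmark(nGenes = 10, cdsLengthRange = c(900, 1500),
                           errorRate = 0.01, seed = 11)
    orfs <- extractOrfs(bench$reads)
    buildCodonGraph(partitionOrfs(orfs)$all, 27)
  })
}

noisySimplified <- function() {
  memo("noisy_simplified", simplifyGraph(noisyGraphFixture()))
}

# SVM separability experiment: biased positives vs uniform negatives
svmFixture <- function() {
  memo("svm", {
    set.seed(42)
    pos <- vapply(rep(300, 500), makeCds, character(1),
                  weights = codonWeights("biased"))
    neg <- vapply(rep(300, 500), makeCds, character(1),
                  weights = codonWeights("uniform"))
    list(pos = pos, neg = neg, model = trainSvm(pos, neg, seed = 42))
  })
}

# random alignment-record fixtures for the evaluation metric oracles
randomRecords <- function(nGenes, nQueries, seed) {
  set.seed(seed)
  gene <- sample(sprintf("g%02d", seq_len(nGenes)), nQueries, replace = TRUE)
  data.frame(
    query_id = sprintf("q%03d", seq_len(nQueries)),
    target_id = gene,
    identity = runif(nQueries, 0.9, 1),
    query_coverage = runif(nQueries, 0.9, 1),
    target_coverage = runif(nQueries, 0.9, 1),
    mismatches = sample(0:20, nQueries, replace = TRUE),
    alignment_length = sample(500:2000, nQueries, replace = TRUE),
    qstart = 0L, qend = 100L, tstart = 0L, tend = 100L,
    stringsAsFactors = FALSE)
}

# minimal alignment record constructor for metric unit tests
rec <- function(query, target, identity = 1, qcov = 1, tcov = 1,
                mismatches = 0L, alnLen = 1000L,
                qstart = 0L, qend = 1000L, tstart = 0L, tend = 1000L) {
  data.frame(query_id = query, target_id = target, identity = identity,
             query_coverage = qcov, target_coverage = tcov,
             mismatches = mismatches, alignment_length = alnLen,
             qstart = qstart, qend = qend, tstart = tstart, tend = tend,
             stringsAsFactors = FALSE)
}
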