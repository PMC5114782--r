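---
title: "Assembling coding sequences on a codon-based de Bruijn graph"
author: "codonCDS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling coding sequences on a codon-based de Bruijn graph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonCDS)
```

# The problem

De novo transcriptome assembly followed by coding-region prediction is the
standard route to gene sets for species without a reference genome. It is
also a lossy one: assemblers built for arbitrary transcripts emit
fragmented, redundant and occasionally chimeric contigs, and every defect
propagates into the predicted coding sequences (CDSs), corrupting
downstream ortholog detection and phylogenomic inference. `codonCDS`
reconstructs CDSs directly from unassembled reads by exploiting two pieces
of structure that generic assemblers ignore: a true CDS is stop-free in
its reading frame, and coding sequence carries a strong codon-usage
signature that its five other reading frames do not.

# The model

## Candidate ORFs from six frames

Each input sequence of length $L$ is read in six frames (offsets 0/1/2 on
each strand), each frame truncated to whole codons
($3\lfloor(L-o)/3\rfloor$ bases). Stop codons (TAA, TAG, TGA) split a
frame into maximal stop-free codon runs. A frame with no stop at all
yields a *strict* ORF spanning the whole codon-trimmed frame; a run
covering at least `looseFraction` (default 0.8) of the source is *loose*;
shorter runs are kept only as `other` and take no further part. For a read
lying inside a real CDS, exactly one frame is stop-free over its whole
length essentially always, so strict ORFs are enriched for true coding
windows — but wrong frames of short reads are stop-free often enough that
most candidates are still false, which is why a classifier follows.

Two deliberate readings: "strict" is defined per frame (the offset frames
of a sequence can never literally equal it in length), and maximal runs
are used without trimming. Codons containing `N` never count as stops and
are excluded from codon-usage counts.

## Self-supervised SVM filtration

No curated training data exist for a novel transcriptome, so the package
builds its own. Strict ORFs alone are assembled into a codon-based de
Bruijn graph; its unitig contigs of at least `minContigBp` (default
1000 bp) are taken as positives — long stop-free contigs assembled from
agreeing strict ORFs are overwhelmingly genuine coding sequence. For each
positive contig, the longest stop-free run of each of its five other
reading frames (at most five per contig) forms the negative class: the
exact impostors the filter must reject, drawn from the same nucleotide
composition.

Features are 64-dimensional codon-usage frequency vectors (counts over
codons, normalised; no further scaling — the entries are already
commensurable frequencies). The classifier is a radial-kernel SVM
(`e1071`, $C = 1$, $\gamma = 1/64$, balanced class weights). Rather than
using the default decision boundary, the threshold is calibrated on a
held-out 20 % split to a target specificity (default 0.95): filtration is
deliberately strict, accepting a sensitivity cost, because false ORFs that
survive become false landmarks and ultimately false CDSs, while true ORFs
that are lost can still be traversed through (see below). Survivors are
reliable ORFs (rORFs).

## The codon-based de Bruijn graph

From every candidate (strict + loose) ORF, k-mers are taken with window
$k$ (default 27 bp, a multiple of 3) and step 3 bp, so nodes are
codon-aligned and an edge — two k-mers overlapping by $k-3$ bp observed
adjacently within one ORF — advances a walk by exactly one codon. Compared
with the conventional step-1 graph, a length-$L$ sequence contributes
$(L-k)/3 + 1$ nodes and $(L-k)/3$ edges instead of $L-k+1$ and $L-k$:
asymptotically one third the graph. Just as importantly, frame-shifted
false ORFs share no codon-aligned k-mers with the true frame, so they land
in separate components instead of tangling the true path. Because strand
and frame are resolved by translation, k-mers are used as-is, with no
reverse-complement canonicalisation.

Two simplifications run to a joint fixpoint:

* **Tip trimming** — a chain dangling off a branching node and
  disconnected on its other end is removed when it spells strictly less
  than `tipBp` (default $2k$) bases. Isolated simple paths are not tips.
* **Bubble merging** — alternative simple paths sharing start and end
  nodes are compared by global-alignment identity (matches over alignment
  length, gaps counted, via `Biostrings::pairwiseAlignment`); at identity
  ≥ 0.95 only the longest spelled path survives (ties: higher summed node
  multiplicity, then lexicographically smaller spelling). The per-branch
  search is bounded by `maxBubbleNodes` (default 200).

`classifyComponents` labels weak components *simple* (no node with
in- or out-degree above 1), *bubbles* (contains a detected bubble,
whether or not tips are also present), or *tips* (tips only). On clean
data almost everything is simple; substitution errors create tips (error
near a read end) and bubbles (error mid-read), and simplification
restores the simple majority.

## Landmark-guided traversal

The graph is built from *all* candidate ORFs — the SVM inevitably discards
some true ones, and a graph of rORFs alone would fragment — and the rORFs
are then mapped back: every rORF k-mer that exists as a node becomes a
landmark. A depth-first search starts at each landmark (children ordered
by descending edge multiplicity, ties lexicographic, so traversal is
deterministic and prefers well-supported paths), never revisits a node
within one search, and ends a branch at another landmark, at `maxDepth`
(default 5000 nodes), or at a dead end. Landmark-to-landmark segments are
chained greedily — longest first, each landmark heading at most one
chained segment and tailing at most one — into maximal paths; segments
that cannot chain stand alone.

Each path is then completed at both termini through strictly unbranching
edges (the remainder of its containing unitig). This is the package's
answer to a systematic artefact: SVM rejection is driven by local codon
composition, so it is correlated along the sequence, and the terminal
stretch of a gene can lose every covering rORF at once. Interior cold
stretches are bridged by the DFS, but nothing would otherwise extend a
path beyond its outermost landmark; an unbranching continuation is
unambiguous in the graph and requires no landmark evidence.

Paths are spelled (first k-mer, then 3 bp per node), exact-substring
duplicates removed keeping the longest container, and the result returned
as a `DNAStringSet` ordered by length. By construction every emitted CDS
is codon-aligned, stop-free and re-walkable in the graph.

**Strict mode** targets longer, less redundant output at a sensitivity
cost. The DFS accepts only landmark nodes, and a path must be supported by
at least two distinct rORFs. The corroboration rule exists because a lone
false-positive rORF maps all of its own k-mers and would otherwise be
re-emitted verbatim as a "CDS"; demanding independent support suppresses
exactly that class of output.

# Evaluation statistics

Predicted CDSs are scored against a reference gene set from alignments —
ingested from BLAT PSL (identity = matches/(matches + mismatches + query
gap bases)) or computed by a built-in seeded aligner (exact 15-mer seeds,
local `pairwiseAlignment` extension) that is adequate for the
near-identical comparisons of synthetic benchmarks and is not a BLAT
replacement. Alignments survive at identity, query coverage and reference
coverage all strictly above 0.90 (best record per query–target pair).
Then:

* **redundancy** — aligned predicted CDSs / reference genes;
* **ROC point** — sensitivity = fraction of reference genes covered;
  specificity = fraction of predictions aligned;
* **fragment number** — $\sum_i i\,p_i$ with $p_i$ the fraction of
  covered genes having exactly $i$ aligned CDSs (equivalently the mean
  per-covered-gene count, and tested as such);
* **base error rate** — mean per-record mismatches/alignment-length
  (pooled variant available);
* **chimera rate** — among predictions > 500 bp, those with ≥ 2
  alignments to different genes, each ≥ 30 % of the CDS and with query
  spans overlapping < 50 % of the shorter span;
* **ortholog-pair classification** — per one-to-one reference pair, the
  surviving queries on each side (filters: identity > 0.95, coverages
  > 0.5, aligned length > 250 codons) classify the pair one-to-one /
  one-to-many / many-to-one / many-to-many / unaligned.

# The synthetic-data generator

`makeCds` samples codons from a weight table over the 61 sense codons —
stop-free in frame by construction. The `"biased"` preset is a synthetic
human-like usage table; the skew is what gives reading frames a detectable
signature, and interpolating toward the `"uniform"` preset dials the
class separation for the SVM tests. `makeGene` wraps a CDS with random
UTRs and GT…AG introns and splices back losslessly. `simulateReads`
adds i.i.d. substitutions (no indels — the tool's frame semantics assume
substitution-dominated errors, as short-read data are) at 0–10 % and
supports two sampling models:

* `"uniform"` — plus-strand starts uniform over the template, expected
  count `depth·L/readLength`; simple, and every read is an exact
  substring oracle at error 0;
* `"fragmentation"` — whole template copies are cut at geometric spacing
  (`meanFragment`, default 250 bp) and one read is sequenced off a random
  end of each fragment on a random strand. This emulates physical RNA
  fragmentation, whose first and last fragments abut the transcript
  termini. It is the benchmark default because terminus coverage is what
  makes full-length recovery possible at all: under uniform starts the
  probability that any read begins exactly at base 0 of a 1.3 kb gene at
  30× is only ≈ 0.2, so exact full-length reconstruction would fail for
  most genes regardless of assembler quality.

`makeBenchmark` bundles genes, reads and a per-read truth table,
byte-identical per seed.

What the benchmarks do **not** emulate: expression heterogeneity (depth is
uniform per gene), indels, quality-score error profiles, alternative
isoforms, and genuinely shared k-mers between paralogous genes. Passing
them shows the machinery is correct under its stated assumptions, not that
real-library performance matches; real data add error structure and
inter-gene k-mer sharing that reduce recovery and sharpen the role of the
SVM's specificity calibration.

# Numerical and design choices

* **k = 27, step 3.** Balances specificity of node identity against
  sensitivity to coverage gaps; must be a multiple of 3 to preserve
  frame.
* **minOrf = k** (27 bp): shorter ORFs cannot contribute a node.
* **Tip bound 2k, strict "<".** A boundary tip spelling exactly $2k$ is
  retained.
* **Bubble identity denominator** is global alignment length, gaps
  included; bounded search (200 nodes/branch).
* **SVM floor.** `trainSvm` requires 20 examples per class by default;
  `assembleCds` lowers its floor to 10 because small runs (≈ 20 genes)
  legitimately yield ~15–18 positive contigs.
* **Threshold calibration quantile** (type 7) of held-out negative
  scores at the target specificity; orientation of decision values is
  fixed against the training means, so the model is sign-stable.
* **Determinism.** Child ordering, chaining order, tie-breaks and
  dereplication are all total orders; `seed` controls the SVM split and
  all simulation.
* **Degenerate inputs.** Empty files parse to empty sets; an input with
  no usable ORF completes the pipeline with zero CDSs and a warning;
  self-loops and cycles are permitted in the graph, terminate unitig
  extension, and are opened deterministically.

Problem sizes used by the test suite and acceptance script — 200 CDSs for
the graph-size comparison, 20 genes at 30× for assembly, 10 genes at 1 %
error for simplification, 500 + 500 sequences for the SVM — are desk-scale
choices that keep the full suite in a few minutes while leaving every
measured effect far from its decision boundary.

# Known limitations

* Landmark mapping is exact; a single substitution in an rORF k-mer
  unmaps it (coverage redundancy compensates in practice).
* Chaining is greedy; inputs with many genuinely shared k-mers between
  genes (recent paralogs, long repeats) can mis-chain at forks that
  multiplicity does not resolve.
* Coverage-weighted traversal and paired-end linkage are not used.
* The built-in aligner is for synthetic/near-identical comparisons only;
  real evaluations should ingest BLAT PSL.
* Expression-level variation, indel errors and isoforms are out of scope
  for both the generator and the assembler's guarantees.

# A compact demonstration

```{r demo, eval = FALSE}
bench <- makeBenchmark(nGenes = 20, seed = 7)
asm <- assembleCds(bench$reads, seed = 7)
sum(as.character(bench$genes) %in% as.character(asm$cds))  # 20 of 20
evaluateCds(asm$cds, bench$genes)[c("redundancy", "chimera_rate")]
```

The same computations, at the same scales, are what
`tests/testthat/test-acceptance.R` asserts and `scripts/acceptance.R`
re-measures.
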