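---
title: "Methods: circRNA detection with backsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA detection with backsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind the package, in the order the pipeline applies them.
It is the place where genuinely open design decisions are recorded.

## Problem and assumptions

Back-splicing joins an exon's 3' end (donor) to an upstream exon's 5' end
(acceptor) of the same gene, producing a covalently closed circRNA. The
only sequence-level evidence in short-read RNA-seq is the back-splicing
junction (BSJ): reads that span it cannot be explained by any linear
transcript. The package assumes:

* circRNAs are **exonic** and their boundaries coincide with annotated
  exon starts/ends (annotation-driven detection; intronic and unannotated
  circles are out of scope);
* the library is **paired-end**; mate pairs provide the information the
  tandem-RNA filter needs;
* alignments are **ungapped**: against transcript and junction references
  the dominant error mode is substitution, and an ungapped Hamming model
  keeps the mapper exactly verifiable against a brute-force oracle.

## BSJ reference

For each gene the distinct exon starts and ends (union over transcripts)
form all pairs (s, e) with e > s. The junction sequence joins the last
L − 1 spliced bases before the donor boundary to the first L − 1 spliced
bases after the acceptor (L = read length; L = 150 gives the familiar
149 + 149 construction). Junctions whose flanking intronic dinucleotides
are not GT‑AG, GC‑AG or AT‑AC (strand-adjusted) are discarded; junctions
at contig edges are rejected with a distinct reason code.

Two open points were decided as follows:

* **Flanks follow spliced sequence.** Reads come from spliced molecules,
  so flanks walk the exon chain of an annotated transcript rather than
  genomic sequence. Per boundary, the transcript carrying that boundary
  with the longest available flank is used; ties break lexicographically
  by transcript id. When the circle is shorter than L − 1 both flanks
  truncate to the circle length.
* **Duplicate junction sequences are kept** under distinct ids; the
  read-level uniqueness filter resolves them (a read hitting two
  junction records equally well is discarded).

## Read mapping

The mapper is a k-mer seeded, ungapped, end-to-end aligner over a hash
index (compiled via Rcpp). Defaults: k = 15, seeds at every read
position, mismatch budget floor(0.01 × read length) — the "at most 1
mismatch per 100 bases" rule with floor chosen for lengths not divisible
by 100. With m mismatches a qualifying placement contains an exact run of
at least ceil((len − m)/(m + 1)) bases (≥ 49 for 100-base reads at 1%),
so every-base seeding guarantees the hit set equals a brute-force Hamming
scan; the test suite asserts this equivalence directly. Only hits tied at
the minimum mismatch count are reported, sorted by (target, offset,
strand) for determinism. `N` never matches anything, including another
`N` (conservative handling of ambiguous bases).

Pair concordance requires both mates end-to-end on one target, FR
orientation, and an implied fragment length within [2 × anchor_min, 1000]
by default — a deliberately wide band so wild-type removal does not
discard genuine linear pairs over fragment-length quirks.

## Candidate detection

Pairs concordant on the linear transcriptome are wild-type and dropped.
"Unmapped" is interpreted permissively: a pair with one mappable mate but
no concordant placement is retained, maximising junction sensitivity.
Each retained mate is mapped single-end to the BSJ reference and kept
when it (i) passes the mismatch budget, (ii) touches exactly one junction
in its best stratum, and (iii) spans the junction with anchor ≥ 10 bases.
If the two mates of a pair support different junctions the pair is
ambiguous and dropped. Duplicate reads are not collapsed. Candidates are
junctions with at least one surviving supporting read.

## Tandem-RNA filter

Tandem RNAs — linear molecules whose exonic region is duplicated in
tandem (exon repetition, genomic duplication, trans-splicing, RT
template-switching) — reproduce the BSJ signature at their duplication
seam. For each candidate the package builds:

* **circle pseudo-sequences**: for every transcript carrying both
  boundaries, the spliced sequence between them with its last L − 1 bases
  prepended (circles shorter than L − 1 wrap); when no transcript carries
  both boundaries, the union of the gene's exons inside the region is the
  fallback variant;
* a **tandem pseudo-sequence**: upstream flank + circle + circle +
  downstream flank, flanks following the host transcript's spliced
  sequence, truncated to (L − 1) + max fragment length.

A supporting read is kept if its mate maps end-to-end to *any* circle
variant (permissive use of alternative splicing). A mate failing every
circle variant but mapping to the tandem construct is classified as
tandem evidence when its placement is not fully inside the duplicated
region. The duplicated region itself is the circle-equivalent interval:
its interior is sequence-identical to the circle, so any mate that fails
the circle pseudo-sequences yet maps to the tandem construct necessarily
extends into the host flanks — adding slack around the interval would
re-admit exactly those mates and disable the filter, which is why no
slack is used. Mates mapping to neither construct are unresolved: the
read is dropped but not counted as tandem evidence.

Candidates are excluded when tandem-attributed reads exceed 1/3 of their
total supporting reads (kept + tandem-attributed; the total-pool
denominator matches the reported 20–35% prevalence of duplication-derived
BSJs that motivates a one-third cutoff). Candidates with zero kept reads
are removed. The filter is idempotent and order-independent.

A geometric consequence worth knowing: with fragment lengths around
250 ± 25 and L = 100, a mate can only protrude from the duplicated region
when the duplication is shorter than roughly fragment − L + (L − anchor)
≈ 300 nt. Longer tandem RNAs are indistinguishable from circles by mate
position — the motivation for the statistical ranking that follows.

## Two-dimensional local false discovery rate

Each candidate contributes z = (log₂ supporting reads, log₂ length),
with length the median over isoform variant lengths (mean of the two
middle values for even counts). Given a null pool of (count, length)
statistics — in practice depleted circRNAs from independent RNase R
experiments, supplied as a two-column TSV — the package draws M = 100
samples of size n with replacement, labels ensemble points successes and
observed points failures, and smooths the success proportion r(z) with a
k-nearest-neighbour classifier:

* axes are standardised by the pooled standard deviation;
* k = ceil(sqrt((M + 1) · n)) by default — a bandwidth-free rule that
  grows with the pool;
* all points tied with the k-th nearest distance are included, keeping
  the estimate deterministic and free of label-order bias (counts are
  discrete, so ties are common);
* the success count gets add-one smoothing, keeping r strictly inside
  (0, 1).

Then fdr2d = π₀ · r / (M (1 − r)), clamped to [0, 1] (the ratio exceeds 1
when r > M/(M + 1), but a local fdr is a probability-scale quantity and
π₀ = 1 is its maximum, kept fixed rather than estimated — the
conservative choice). At the equal-density point r = M/(M + 1) the
formula returns exactly π₀. Ranking is by ascending fdr2d with ties
broken by read count (descending), length (descending), then junction id.
The analytic identity — plugging r = M f₀/(f + M f₀) for known densities
recovers π₀ f₀/f to machine precision — is covered by a dedicated test,
isolating the smoother as the only approximate component.

Expression-based depletion calls (`classify_depletion`) use counts per
million as the library-size normalisation; a circRNA is non-depleted when
its untreated-sample expression does not exceed the RNase R-treated one
(inclusive rule), and the five-fold enrichment count is likewise
inclusive (≥ 5×).

## Simulator

The simulator emulates the data regime the detection method targets:

* fixture genomes with non-overlapping genes of 1–10 exons (exons
  100–400 nt, introns 100–400 nt), canonical GT-AG dinucleotides planted
  strand-aware at every exon boundary, and up to three exon-subset
  isoforms per gene;
* linear molecules = spliced transcripts; circRNA molecules emit their
  pseudo-sequence (so fragments straddle the junction); tandem molecules
  emit flank + circle + circle + flank;
* expression: log-normal FPKM (meanlog 1, sdlog 2) for linear
  transcripts; circRNA and tandem expression resampled from the linear
  distribution; both truncated to [0.2, 99th percentile];
* fragments: expected count per molecule = FPKM × length/1000 ×
  total/10⁶ realised by randomised rounding; starts uniform; lengths
  N(250, 25) rounded and clipped to [read length, molecule length];
  mate 2 reverse-complemented; substitution errors at 0.005 per base;
  constant quality strings (qualities are unused downstream);
  negative-binomial overdispersion of counts is deliberately not
  modelled.

Every pair gets a truth row (molecule, class, fragment coordinates,
junction-straddle anchors per mate), which the evaluation harness and the
tests use as the oracle.

Scale defaults model the study conditions the package's acceptance runs
reproduce: 200 circRNAs at ≈ 159 fragments per circle, tandem RNAs at the
6256 : 1008 circ : tandem ratio (≈ 1611 fragments each), and a 1.8 M-pair
linear background on a 2 Mb / 300-gene fixture — a proportional
scale-down of the reference dataset sizes, with per-molecule depths
preserved. Where the reference library sizes are ambiguous between read
and fragment counts, depths are interpreted as fragments per molecule.
Circle lengths are sampled from 200–2000 nt (common circRNA sizes);
tandem duplicated regions from 150–1000 nt, reflecting that
duplication-seam artefacts are enriched for short spans and that
mate-position evidence is only observable for short duplications under
the fragment model above.

What the simulator does **not** emulate — and passing tests therefore do
not certify on real data: positional/GC bias, quality-dependent errors,
indels, intronic or unannotated circRNAs, rolling-circle concatemers,
incomplete annotation, and genome-scale repeat structure (fixture
sequence is i.i.d. random, so cross-gene multi-mapping is rarer than in
real genomes).

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive internally (GTF convention); BED
  export converts to 0-based half-open at the boundary.
* Mismatch budget uses floor(); anchor and tandem-fraction rules use
  inclusive comparisons at their stated boundaries (anchor ≥ 10,
  tandem ≤ 1/3 of total).
* Empty inputs propagate as empty tables with stable schemas; an empty
  FASTQ yields an empty candidate table with the full column contract.
* Reads with symbols outside A/C/G/T/N are rejected with an error; N is
  a mismatch against everything.
* All randomness flows through R's RNG; a seed makes fixtures, reads and
  fdr2d scores byte-reproducible. External pointers behind k-mer indexes
  are rebuilt transparently if an index object is restored from disk.

## Known limitations

* Annotation-bound: junctions not at annotated exon boundaries are
  invisible, and circRNA length estimates inherit annotation errors.
* Ungapped mapping: reads with indels near a junction are lost to the
  mismatch budget.
* Long circRNAs cannot be separated from long tandem RNAs by mate
  position; the fdr2d ranking mitigates but does not resolve this.
* The kNN smoother is a pragmatic stand-in for the success/failure
  smoothing; it is isolated behind `estimate_r()` so an alternative
  smoother can be swapped in without touching the rest of the pipeline.
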