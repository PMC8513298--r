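# backsplice

Detection of circular RNAs (circRNAs) from paired-end RNA-seq data, for
transcriptomics researchers who need junction-level circRNA calls with a
statistically grounded ranking rather than a raw read-count ordering.

## The method

circRNAs arise when a downstream splice donor joins back to an upstream
splice acceptor, producing a back-splicing junction (BSJ) whose sequence
exists in no linear transcript. `backsplice` detects exonic circRNAs in
four stages:

1. **BSJ pseudo-reference.** For every gene, all combinations of annotated
   exon starts *s* and exon ends *e* with *e* > *s* are enumerated; each
   junction sequence joins the last *L* − 1 spliced bases preceding the
   donor to the first *L* − 1 bases following the acceptor (*L* = read
   length), so a junction-spanning read aligns contiguously. Junctions are
   kept only with canonical splice signals (GT‑AG, GC‑AG, AT‑AC).
2. **Candidate detection.** Read pairs concordantly explained by the linear
   transcriptome are discarded as wild-type; leftover mates are mapped
   single-end to the BSJ reference with a k-mer seeded, ungapped aligner. A
   supporting read must have at most 1 mismatch per 100 bases, map uniquely
   to a single junction, and span the back-splice with at least 10 bases on
   its shorter side (the anchor).
3. **Tandem-RNA elimination.** Linear molecules with tandemly duplicated
   exons carry the same junction signature and are the dominant source of
   false positives. Each supporting read's mate is re-mapped against
   circRNA and tandem pseudo-sequences; mates falling outside the putative
   circle attribute the read to a tandem RNA, and candidates whose
   tandem-attributed reads exceed 1/3 of their supporting reads are
   excluded.
4. **fdr2d ranking.** Each candidate contributes a bivariate statistic
   z = (z₁, z₂) = (log₂ supporting reads, log₂ circRNA length). With a null
   pool of (count, length) statistics from known artefactual circRNAs
   (e.g. RNase R-depleted calls), the local false discovery rate

   fdr2d(z) = π₀ · f₀(z) / f(z)

   is estimated via the stabilised ratio r(z) = M·f₀ / (f + M·f₀): M = 100
   Monte-Carlo null samples of size n are pooled with the observed
   statistics, r is the smoothed success (null) proportion from a
   k-nearest-neighbour classifier, and fdr2d = π₀ · r / (M(1 − r)) with the
   conservative π₀ = 1. Candidates are ranked by ascending fdr2d.

A built-in simulator generates synthetic genomes with planted canonical
splice sites and paired-end reads from circRNA, tandem-RNA and linear
molecules (read length 100, substitution rate 0.005, fragment length
N(250, 25), expression truncated to [0.2, 99th percentile] FPKM), together
with a per-pair ground-truth table, so the entire pipeline can be validated
without external data.

## Worked example

```r
library(backsplice)

# synthetic genome: 40 genes on a 500 kb contig
fx <- simulate_genome(n_genes = 40, genome_size = 5e5, seed = 7)

# paired-end reads: 12 circRNAs over ~1900 fragments, 30k linear pairs
sim <- simulate_experiment(fx, n_circles = 12, circ_fragments = 1900,
                           linear_fragments = 30000, seed = 8)

idx <- circ_index(fx$genome, fx$annotation, read_length = 100)
#> <circ_index> 821 BSJ records, 62 transcripts, L = 100

null_pool <- tibble::tibble(count = pmax(1, rpois(500, 2)),
                            length_nt = rlnorm(500, log(300), 0.4))
cands <- detect_circrnas(sim$reads, idx, null_pool = null_pool, seed = 9)
cands[, c("bsj_id", "n_support_reads", "circ_length_nt", "fdr2d", "rank")]
#> # A tibble: 12 × 5
#>   bsj_id            n_support_reads circ_length_nt  fdr2d  rank
#>   <chr>                       <int>          <dbl>  <dbl> <int>
#> 1 g0031:76350:77906              86           1007 0.0217     1
#> 2 g0006:14427:14798              42            372 0.027      2
#> 3 g0003:7861:8637                24            522 0.028      3
#> 4 g0032:80861:81128              36            268 0.0356     4
#> 5 g0036:93494:93730              29            237 0.04       5
#> # ℹ 7 more rows

evaluate_candidates(cands, sim$circles)
#> <circ_eval> detected 12 (TP 12, FP 0 of 12 true)
#>   sensitivity 100.00%, precision 100.00%, F1 1.0000
```

Each candidate row gives the junction identity
(`gene:acceptor_start:donor_end`, 1-based inclusive genomic coordinates),
the number of junction-spanning supporting reads that survived all
filters, the circRNA length (median over isoform variants), and its fdr2d
score — here all 12 simulated circles are recovered with no false
positives, ranked with the strongest evidence first. `autoplot()` on the
evaluation draws the true-discovery curve;
`attr(cands, "stage_counts")` reports how many pairs each filtering stage
consumed.

A thin command-line front-end (`exec/backsplice`) exposes the same
pipeline as `index` / `detect` / `simulate` / `evaluate` / `fdr`
subcommands for shell use.

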