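test_that("circle sequences follow transcript exon chains", {
  set.seed(71)
  # six 30-base exons with 20-base introns, as in the duplicated-region
  # illustration: the circle spans exons 2-4
  exon_seqs <- vapply(rep(30, 6), rand_seq, character(1))
  introns <- vapply(rep(20, 6), rand_seq, character(1))
  gseq <- "TT"
  starts <- integer(6)
  for (i in 1:6) {
    starts[i] <- nchar(gseq) + 1L
    gseq <- paste0(gseq, exon_seqs[i], introns[i])
  }
  ends <- starts + 29L
  g <- genome_sequence(c(chr1 = gseq))
  ge <- toy_annotation(starts, ends)
  v <- circ_sequences(ge, g, "g1", starts[2], ends[4])
  expect_equal(nrow(v), 1L)
  expect_equal(v$seq, paste0(exon_seqs[2], exon_seqs[3], exon_seqs[4]))
  expect_equal(v$length_nt, 90L)

  # single-exon circle is a genomic substring
  v1 <- circ_sequences(ge, g, "g1", starts[3], ends[3])
  expect_equal(v1$seq, exon_seqs[3])

  # two isoforms sharing boundaries but differing in a middle exon give
  # two variants
  ge2 <- annotation(dplyr::bind_rows(
    toy_annotation(starts[c(2, 3, 4)], ends[c(2, 3, 4)],
                   transcript_id = "g1.t1"),
    toy_annotation(starts[c(2, 4)], ends[c(2, 4)],
                   transcript_id = "g1.t2")
  ))
  v2 <- circ_sequences(ge2, g, "g1", starts[2], ends[4])
  expect_equal(nrow(v2), 2L)
  expect_setequal(v2$length_nt, c(90L, 60L))

  expect_error(circ_sequences(ge, g, "g1", starts[2] + 1L, ends[4]),
               "exon boundaries")
})

test_that("circle pseudo-sequence prepends the last L-1 bases", {
  expect_equal(build_circ_pseudo("ACGTACGT", 4L), paste0("CGT", "ACGTACGT"))
  expect_equal(build_circ_pseudo("ACGTACGT", 2L), paste0("T", "ACGTACGT"))
  # circles shorter than L-1 wrap: the last 5 bases of the cyclic
  # sequence ...ACGACG are CGACG
  expect_equal(build_circ_pseudo("ACG", 6L), paste0("CGACG", "ACG"))
  expect_error(build_circ_pseudo("", 4L), "empty")

  # a read straddling the back-splice aligns end-to-end with 0 mismatches
  set.seed(72)
  circ <- rand_seq(300)
  pseudo <- build_circ_pseudo(circ, 100L)
  read <- substring(pseudo, 50, 149)  # 50 bases either side of the seam
  idx <- kmer_index(c(p = pseudo))
  h <- map_reads(read, idx)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$offset, 49L)
})

test_that("tandem pseudo-sequence carries the junction motif at its seam", {
  set.seed(73)
  circ <- rand_seq(200)
  up <- rand_seq(400)
  down <- rand_seq(350)
  td <- build_tandem_pseudo(circ, up, down, read_length = 100L,
                            max_fragment = 250L)
  expect_equal(td$circ_len, 200L)
  expect_equal(td$upstream_len, 349L)  # truncated to (L-1) + max_fragment
  expect_equal(td$seam, 349L + 200L)
  # the junction signature (suffix + prefix of the circle) sits at the seam
  motif <- paste0(substring(circ, 102, 200), substring(circ, 1, 99))
  expect_equal(substring(td$seq, td$seam - 98L, td$seam + 99L), motif)
  expect_equal(length(gregexpr(motif, td$seq, fixed = TRUE)[[1]]), 1L)

  # circle spanning the whole transcript: tandem is just circ + circ
  td0 <- build_tandem_pseudo(circ, "", "", read_length = 100L)
  expect_equal(td0$seq, paste0(circ, circ))

  # a BSJ-straddling read matches circle pseudo and tandem seam equally
  pseudo <- build_circ_pseudo(circ, 100L)
  read <- substring(pseudo, 60, 159)
  idx <- kmer_index(c(circ = pseudo, tandem = td$seq))
  h <- map_reads(read, idx)
  expect_setequal(h$target_id, c("circ", "tandem"))
  expect_true(all(h$mismatches == 0L))
})

test_that("mate classification separates circle, tandem and unresolved", {
  set.seed(74)
  circ <- rand_seq(250)
  up <- rand_seq(500)
  down <- rand_seq(500)
  td <- build_tandem_pseudo(circ, up, down, read_length = 100L,
                            max_fragment = 400L)
  variants <- tibble::tibble(variant_id = "t1", seq = circ,
                             length_nt = 250L)
  # mate wholly inside the circle region
  inside <- substring(circ, 51, 150)
  # mate crossing from the duplication into the downstream flank
  crossing <- substring(td$seq, td$seam + 250L - 60L,
                        td$seam + 250L - 60L + 99L)
  # mate unmappable anywhere
  garbage <- rand_seq(100)
  cand <- tibble::tibble(
    bsj_id = "g:1:250", n_support = 3L,
    reads = list(tibble::tibble(
      read_id = c("in", "cross", "none"), mate = 1L, bsj_id = "g:1:250",
      offset = 0L, strand = "+", mismatches = 0L, anchor_length = 20L,
      mate_seq = c(inside, crossing, garbage)
    ))
  )
  cls <- classify_mates(cand, variants, td,
                        mapper_config(read_length = 100L))
  verdicts <- stats::setNames(cls$verdicts$verdict, cls$verdicts$read_id)
  expect_equal(unname(verdicts["in"]), "in_circle")
  expect_equal(unname(verdicts["cross"]), "tandem_evidence")
  expect_equal(unname(verdicts["none"]), "unresolved")
  expect_equal(cls$tandem_read_count, 1L)
  expect_equal(cls$kept$read_id, "in")
})

test_that("the one-third tandem rule keeps and excludes at the boundary", {
  cands <- tibble::tibble(
    bsj_id = c("a", "b", "c", "d"),
    n_support = c(6L, 5L, 1L, 0L),
    n_tandem = c(3L, 4L, 0L, 2L)
  )
  kept <- tandem_fraction_filter(cands)
  # 3 <= 9/3 kept; 4 > 9/3 excluded; 1 kept with no tandem reads;
  # zero kept reads always removed
  expect_equal(kept$bsj_id, c("a", "c"))
  # idempotent and order-independent
  expect_equal(tandem_fraction_filter(kept), kept)
  shuffled <- cands[c(3, 1, 4, 2), ]
  expect_setequal(tandem_fraction_filter(shuffled)$bsj_id, kept$bsj_id)
})

test_that("fragments confined to genuine circles yield no tandem reads", {
  fx <- simulate_genome(n_genes = 20L, genome_size = 3e5, seed = 75)
  idx <- circ_index(fx$genome, fx$annotation, read_length = 100L)
  sim <- simulate_experiment(
    fx, n_circles = 6L, n_tandems = 0L, circ_fragments = 900L,
    linear_fragments = 6000L, config = sim_config(error_rate = 0),
    seed = 76
  )
  cands <- detect_circrnas(sim$reads, idx)
  expect_true(all(cands$n_tandem_reads == 0L))
  # every kept supporting read had an in-circle mate by construction
  expect_gt(nrow(cands), 0L)
})
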