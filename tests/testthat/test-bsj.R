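test_that("junction pair enumeration covers the start/end matrix", {
  ex <- tibble::tibble(exon_start = c(10L, 30L), exon_end = c(20L, 40L))
  p <- enumerate_bsj_pairs(ex)
  expect_equal(
    dplyr::arrange(p, acceptor_start, donor_end),
    tibble::tibble(acceptor_start = c(10L, 10L, 30L),
                   donor_end = c(20L, 40L, 40L))
  )

  single <- tibble::tibble(exon_start = 5L, exon_end = 9L)
  expect_equal(enumerate_bsj_pairs(single),
               tibble::tibble(acceptor_start = 5L, donor_end = 9L))

  # shared start coordinates across exons yield no duplicate pairs
  shared <- tibble::tibble(exon_start = c(10L, 10L, 30L),
                           exon_end = c(20L, 25L, 40L))
  ps <- enumerate_bsj_pairs(shared)
  expect_false(anyDuplicated(paste(ps$acceptor_start, ps$donor_end)) > 0)
  expect_true(all(ps$donor_end > ps$acceptor_start))

  expect_equal(nrow(enumerate_bsj_pairs(ex[0, ])), 0L)
})

test_that("junction sequence joins flanks around the back-splice", {
  # single 12-base exon, circle = whole exon, L = 5
  set.seed(21)
  exon_seq <- rand_seq(12)
  g <- genome_sequence(c(chr1 = paste0("AG", exon_seq, "GT", rand_seq(6))))
  ge <- toy_annotation(3, 14)
  js <- build_junction_sequence(g, ge, 3L, 14L, read_length = 5L)
  expect_equal(js$junction_seq,
               paste0(substring(exon_seq, 9, 12), substring(exon_seq, 1, 4)))
  expect_equal(js$junction_offset, 4L)

  # circle shorter than L - 1: both flanks truncate to the circle length
  js2 <- build_junction_sequence(g, ge, 3L, 14L, read_length = 100L)
  expect_equal(nchar(js2$junction_seq), 2L * 12L)
  expect_equal(js2$junction_offset, 12L)
  expect_equal(js2$junction_seq, paste0(exon_seq, exon_seq))

  expect_error(build_junction_sequence(g, ge, 4L, 14L, read_length = 5L),
               "boundaries")
})

test_that("L = 150 reproduces the 149-base flank sizing", {
  set.seed(22)
  exon_seq <- rand_seq(400)
  g <- genome_sequence(c(chr1 = paste0("AG", exon_seq, "GT", rand_seq(4))))
  ge <- toy_annotation(3, 402)
  js <- build_junction_sequence(g, ge, 3L, 402L, read_length = 150L)
  expect_equal(js$junction_offset, 149L)
  expect_equal(nchar(js$junction_seq), 298L)
  expect_equal(js$junction_seq,
               paste0(substring(exon_seq, 400 - 148, 400),
                      substring(exon_seq, 1, 149)))
})

test_that("canonical splice classification is strand-aware", {
  # plus strand: GT after the donor end, AG before the acceptor start
  g <- genome_sequence(c(chr1 = paste0("AAAG", "CCCCC", "GTAAA")))
  # acceptor_start = 5, donor_end = 9; genome[3:4] = AG, genome[10:11] = GT
  expect_equal(canonical_splice_filter(g, "chr1", "+", 5L, 9L), "GT-AG")

  # minus strand: genomic AC before the start, CT after the end
  gm <- genome_sequence(c(chr1 = paste0("AAAC", "CCCCC", "CTAAA")))
  expect_equal(canonical_splice_filter(gm, "chr1", "-", 5L, 9L), "GT-AG")
  # the same genomic context is rejected on the plus strand
  expect_true(is.na(canonical_splice_filter(gm, "chr1", "+", 5L, 9L)))

  # CT/AG on the plus strand is rejected as non-canonical
  gr <- genome_sequence(c(chr1 = paste0("AAAG", "CCCCC", "CTAAA")))
  rej <- canonical_splice_filter(gr, "chr1", "+", 5L, 9L)
  expect_true(is.na(rej))
  expect_equal(attr(rej, "reason"), "noncanonical")

  # GC-AG and AT-AC classes
  ggc <- genome_sequence(c(chr1 = paste0("AAAG", "CCCCC", "GCAAA")))
  expect_equal(canonical_splice_filter(ggc, "chr1", "+", 5L, 9L), "GC-AG")
  gat <- genome_sequence(c(chr1 = paste0("AAAC", "CCCCC", "ATAAA")))
  expect_equal(canonical_splice_filter(gat, "chr1", "+", 5L, 9L), "AT-AC")

  # junctions at the contig edge are rejected with a distinct reason
  edge <- canonical_splice_filter(g, "chr1", "+", 2L, 9L)
  expect_true(is.na(edge))
  expect_equal(attr(edge, "reason"), "contig_edge")
})

test_that("reference construction filters junctions by splice class", {
  # two exons: starts {s1, s2}, ends {e1, e2} enumerate 3 pairs; plant
  # canonical signals only around (s1, e1)
  set.seed(23)
  e1s <- rand_seq(30)
  e2s <- rand_seq(30)
  g <- genome_sequence(c(chr1 = paste0(
    "TTTT", "AG", e1s, "GT", rand_seq(20), "TT", e2s, "CC", rand_seq(10)
  )))
  # exon1 = [7, 36], exon2 = [61, 90]
  ge <- toy_annotation(c(7, 61), c(36, 90))
  ref <- build_bsj_reference(ge, g, read_length = 10L)
  expect_equal(nrow(ref), 1L)
  expect_equal(ref$acceptor_start, 7L)
  expect_equal(ref$donor_end, 36L)
  expect_equal(ref$splice_class, "GT-AG")
  # monotone: canonical filtering never adds junctions
  expect_lte(nrow(ref), nrow(enumerate_bsj_pairs(ge)))

  # empty annotation gives an empty reference
  empty <- build_bsj_reference(ge[0, ], g, read_length = 10L)
  expect_equal(nrow(empty), 0L)
})

test_that("every emitted record is canonical with donor > acceptor, and
           junction sequences match a brute-force extractor", {
  fx <- simulate_genome(n_genes = 6L, genome_size = 1.2e5, max_isoforms = 1L,
                        seed = 31)
  L <- 20L
  ref <- build_bsj_reference(fx$annotation, fx$genome, read_length = L)
  expect_gt(nrow(ref), 0L)
  expect_true(all(ref$donor_end > ref$acceptor_start))
  expect_true(all(ref$splice_class %in% c("GT-AG", "GC-AG", "AT-AC")))
  expect_false(anyDuplicated(ref$bsj_id) > 0)

  # single-isoform genes: the junction sequence must equal suffix + prefix
  # of the circle's spliced sequence, assembled by hand
  for (i in sample(nrow(ref), min(25, nrow(ref)))) {
    ge <- fx$annotation[fx$annotation$gene_id == ref$gene_id[i], ]
    keep <- ge$exon_start >= ref$acceptor_start[i] &
      ge$exon_end <= ref$donor_end[i]
    circ <- spliced_sequence(fx$genome, ge[keep, ], ge$strand[[1]])
    f <- min(L - 1L, nchar(circ))
    expected <- paste0(substring(circ, nchar(circ) - f + 1L, nchar(circ)),
                       substring(circ, 1L, f))
    expect_equal(ref$junction_seq[i], expected)
    expect_equal(ref$junction_offset[i], f)
  }
})

test_that("splice-class proportions recover planted classes", {
  # plant 60 junction contexts with known classes in fixed proportions
  set.seed(41)
  classes <- c(rep("GT-AG", 40), rep("GC-AG", 15), rep("AT-AC", 5))
  donor <- c("GT-AG" = "GT", "GC-AG" = "GC", "AT-AC" = "AT")
  acceptor <- c("GT-AG" = "AG", "GC-AG" = "AG", "AT-AC" = "AC")
  pieces <- character(0)
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L
  for (cl in classes) {
    exon <- rand_seq(50)
    block <- paste0(acceptor[[cl]], exon, donor[[cl]], rand_seq(6))
    starts <- c(starts, pos + 2L)
    ends <- c(ends, pos + 51L)
    pieces <- c(pieces, block)
    pos <- pos + nchar(block)
  }
  g <- genome_sequence(c(chr1 = paste0("TT", paste(pieces, collapse = ""))))
  res <- classify_splice_sites(g, tibble::tibble(
    contig = "chr1", strand = "+",
    acceptor_start = starts + 2L, donor_end = ends + 2L
  ))
  expect_equal(res$splice_class, classes)
})
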