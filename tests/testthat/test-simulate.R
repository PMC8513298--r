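test_that("fixtures are byte-deterministic under a seed", {
  fx1 <- simulate_genome(n_genes = 5L, genome_size = 1e5, seed = 91)
  fx2 <- simulate_genome(n_genes = 5L, genome_size = 1e5, seed = 91)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  gt1 <- withr::local_tempfile(fileext = ".gtf")
  gt2 <- withr::local_tempfile(fileext = ".gtf")
  write_genome_fasta(fx1$genome, fa1)
  write_genome_fasta(fx2$genome, fa2)
  write_gtf(fx1$annotation, gt1)
  write_gtf(fx2$annotation, gt2)
  expect_identical(readLines(fa1), readLines(fa2))
  expect_identical(readLines(gt1), readLines(gt2))
})

test_that("planted splice sites are all canonical GT-AG", {
  fx <- simulate_genome(n_genes = 8L, genome_size = 1.5e5, seed = 92)
  per_gene <- split(fx$annotation, fx$annotation$gene_id)
  for (ge in per_gene) {
    pairs <- enumerate_bsj_pairs(ge)
    res <- classify_splice_sites(fx$genome, dplyr::mutate(
      pairs, contig = ge$contig[[1]], strand = ge$strand[[1]]
    ))
    expect_true(all(res$splice_class == "GT-AG"))
  }
})

test_that("fixture packing failures are reported", {
  expect_error(simulate_genome(n_genes = 100L, genome_size = 5e4),
               "infeasible packing")
})

test_that("expression sampling respects floor and ceiling", {
  cfg <- sim_config()
  x <- sample_expression(2000, config = cfg, seed = 93)
  expect_true(all(x >= cfg$fpkm_floor))
  expect_true(all(x <= stats::qlnorm(0.99, 1, 2)))

  src <- stats::rlnorm(5000, 2, 1)
  y <- sample_expression(1000, source = src, config = cfg, seed = 94)
  expect_true(all(y >= 0.2))
  expect_true(all(y <= stats::quantile(src, 0.99)))

  expect_equal(sample_expression(10, source = rep(5, 50)), rep(5, 10))
})

test_that("molecule emissions delegate to the pseudo-sequence builders", {
  fx <- simulate_genome(n_genes = 10L, genome_size = 2e5, seed = 95)
  ann <- fx$annotation
  set.seed(96)
  circles <- backsplice:::.sample_junction_molecules(
    ann, fx$genome, 3L, "circ", c(150L, 1500L)
  )
  mol <- build_molecule_sequences(ann, fx$genome, circles = circles,
                                  read_length = 100L)
  # linear emissions equal the spliced transcript sequences
  tx <- transcript_sequences(ann, fx$genome)
  lin <- mol[mol$class == "linear", ]
  expect_equal(stats::setNames(lin$seq, lin$molecule_id), tx[lin$molecule_id])
  # circle emission length is circ length + L - 1
  circ <- mol[mol$class == "circ", ]
  expect_equal(nchar(circ$seq), circles$length_nt + 99L)
  expect_equal(circ$seq,
               vapply(circles$circ_seq, build_circ_pseudo, character(1),
                      read_length = 100L),
               ignore_attr = TRUE)
})

test_that("error-free reads are exact substrings of their molecules", {
  fx <- simulate_genome(n_genes = 8L, genome_size = 1.5e5, seed = 97)
  sim <- simulate_experiment(fx, n_circles = 3L, circ_fragments = 100L,
                             linear_fragments = 500L,
                             config = sim_config(error_rate = 0), seed = 98)
  mol <- build_molecule_sequences(
    fx$annotation, fx$genome, circles = NULL, read_length = 100L
  )
  # check the linear reads against their molecule sequences
  seqs <- stats::setNames(mol$seq, mol$molecule_id)
  lin <- sim$truth$class == "linear"
  found1 <- mapply(function(rs, m, st) {
    substring(seqs[[m]], st, st + 99L) == rs
  }, sim$reads$seq1[lin], sim$truth$molecule_id[lin],
     sim$truth$fragment_start[lin])
  expect_true(all(found1))
  ends <- sim$truth$fragment_start[lin] + sim$truth$fragment_length[lin] - 1L
  found2 <- mapply(function(rs, m, en) {
    revcomp(substring(seqs[[m]], en - 99L, en)) == rs
  }, sim$reads$seq2[lin], sim$truth$molecule_id[lin], ends)
  expect_true(all(found2))
})

test_that("fragment lengths and error rates match the configured model", {
  fx <- simulate_genome(n_genes = 10L, genome_size = 2e5, seed = 99)
  # long transcripts only, so Normal(250, 25) is rarely clipped
  cfg <- sim_config()
  sim <- simulate_experiment(fx, n_circles = 0L, circ_fragments = 0L,
                             linear_fragments = 10000L, config = cfg,
                             seed = 100)
  mol <- build_molecule_sequences(fx$annotation, fx$genome,
                                  read_length = 100L)
  seqs <- stats::setNames(mol$seq, mol$molecule_id)
  # restrict to molecules long enough that clipping is negligible
  keep <- nchar(seqs)[sim$truth$molecule_id] >= 400L
  n <- sum(keep)
  expect_gt(n, 1000)
  se <- cfg$fragment_sd / sqrt(n)
  expect_lt(abs(mean(sim$truth$fragment_length[keep]) - 250), 3 * se + 1)
  idx <- sample(nrow(sim$reads), 2000)
  mism <- mapply(function(rs, m, st) {
    truth_read <- substring(seqs[[m]], st, st + 99L)
    sum(strsplit(rs, "")[[1]] != strsplit(truth_read, "")[[1]])
  }, sim$reads$seq1[idx], sim$truth$molecule_id[idx],
     sim$truth$fragment_start[idx])
  n_bases <- 2000 * 100
  rate <- sum(mism) / n_bases
  se_rate <- sqrt(0.005 * 0.995 / n_bases)
  expect_lt(abs(rate - 0.005), 3 * se_rate)
})

test_that("truth rows are conserved and output is seed-deterministic", {
  fx <- simulate_genome(n_genes = 6L, genome_size = 1.2e5, seed = 101)
  s1 <- simulate_experiment(fx, n_circles = 2L, circ_fragments = 50L,
                            linear_fragments = 300L, seed = 102)
  s2 <- simulate_experiment(fx, n_circles = 2L, circ_fragments = 50L,
                            linear_fragments = 300L, seed = 102)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$reads), nrow(s1$truth))
  expect_setequal(s1$reads$read_id, s1$truth$read_id)

  # molecules shorter than the read length are skipped with a warning
  mol <- tibble::tibble(molecule_id = "tiny", class = "linear",
                        seq = "ACGTACGT", seam = NA_real_, length_nt = 8L)
  expect_warning(simulate_reads(mol, expected_fragments = 5),
                 "shorter than the read length")
})
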