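# Shared fixtures and independent oracles.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A minimal annotation tibble for hand-built gene models.
toy_annotation <- function(starts, ends, strand = "+", gene_id = "g1",
                           transcript_id = "g1.t1", contig = "chr1") {
  annotation(tibble::tibble(
    gene_id = gene_id, transcript_id = transcript_id,
    contig = contig, strand = strand,
    exon_start = as.integer(starts), exon_end = as.integer(ends)
  ))
}

# Brute-force end-to-end Hamming mapper: scans every offset of every
# reference on both strands, counts mismatches (non-ACGT never matches),
# keeps hits within floor(rate * len) and returns the best stratum sorted
# like map_reads().
oracle_map_read <- function(read, refs, rate = 0.01) {
  len <- nchar(read)
  cap <- floor(rate * len)
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (s in c("+", "-")) {
    q <- if (s == "+") read else revcomp(read)
    qv <- strsplit(q, "")[[1]]
    q_ok <- qv %in% acgt
    for (t in seq_along(refs)) {
      rv <- strsplit(refs[[t]], "")[[1]]
      r_ok <- rv %in% acgt
      if (length(rv) < len) next
      for (off in 0:(length(rv) - len)) {
        seg <- rv[(off + 1):(off + len)]
        mm <- sum(seg != qv | !q_ok | !r_ok[(off + 1):(off + len)])
        if (mm <= cap) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            target_id = names(refs)[[t]], offset = off, strand = s,
            mismatches = mm
          )
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(target_id = character(0), offset = integer(0),
                          strand = character(0), mismatches = integer(0)))
  }
  h <- dplyr::bind_rows(rows)
  h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
  h[order(h$target_id, h$offset, h$strand), ]
}

# Oracle pairing decision built on oracle_map_read(): concordant iff some
# shared target carries the mates on opposite strands in FR orientation
# with fragment length within bounds.
oracle_pair_class <- function(read1, read2, refs, rate = 0.01,
                              frag_min = 20, frag_max = 1000) {
  h1 <- oracle_map_read(read1, refs, rate)
  h2 <- oracle_map_read(read2, refs, rate)
  if (nrow(h1) == 0 && nrow(h2) == 0) return("unmapped")
  l1 <- nchar(read1)
  l2 <- nchar(read2)
  for (i in seq_len(nrow(h1))) {
    for (j in seq_len(nrow(h2))) {
      if (h1$target_id[i] != h2$target_id[j]) next
      if (h1$strand[i] == h2$strand[j]) next
      fwd_off <- if (h1$strand[i] == "+") h1$offset[i] else h2$offset[j]
      rev_off <- if (h1$strand[i] == "+") h2$offset[j] else h1$offset[i]
      fwd_len <- if (h1$strand[i] == "+") l1 else l2
      rev_len <- if (h1$strand[i] == "+") l2 else l1
      if (fwd_off > rev_off) next
      frag <- rev_off + rev_len - fwd_off
      if (frag >= max(frag_min, max(fwd_len, rev_len)) && frag <= frag_max) {
        return("concordant")
      }
    }
  }
  "discordant"
}
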