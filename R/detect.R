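# Stage 1 of the pipeline: remove read pairs explained by linear
# transcripts, map leftover mates to the BSJ reference, apply the
# junction-read filters, and group surviving reads into candidates.

#' Read a pair of FASTQ files
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @return Tibble with `read_id`, `seq1`, `seq2`.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) {
    stop("FASTQ mate files differ in read count (", length(r1), " vs ",
         length(r2), ")", call. = FALSE)
  }
  ids <- vapply(strsplit(names(r1), "\\s+"), `[[`, character(1), 1L)
  ids <- sub("/[12]$", "", ids)
  tibble::tibble(read_id = ids,
                 seq1 = as.character(r1),
                 seq2 = as.character(r2))
}

#' Write paired reads as FASTQ
#'
#' @param reads Tibble with `read_id`, `seq1`, `seq2` (see
#'   [read_fastq_pair()]).
#' @param path1,path2 Output FASTQ paths.
#' @param quality Constant per-base quality character.
#' @return Invisibly, `c(path1, path2)`.
#' @export
write_fastq_pair <- function(reads, path1, path2, quality = "I") {
  write_one <- function(ids, seqs, path) {
    qual <- vapply(nchar(seqs), function(n) strrep(quality, n), character(1))
    lines <- as.vector(rbind(paste0("@", ids), seqs, "+", qual))
    writeLines(lines, path)
  }
  write_one(paste0(reads$read_id, "/1"), reads$seq1, path1)
  write_one(paste0(reads$read_id, "/2"), reads$seq2, path2)
  invisible(c(path1, path2))
}

#' Partition read pairs into wild-type and retained
#'
#' Maps every pair against the linear transcriptome; pairs concordantly
#' explained by an annotated transcript are wild-type and discarded, all
#' other pairs (orphan, discordant or fully unmapped) are retained for the
#' BSJ search.
#'
#' @param reads Tibble with `read_id`, `seq1`, `seq2`.
#' @param tx_index [kmer_index()] over the spliced transcript sequences.
#' @param config A [mapper_config()].
#' @param chunk_size Pairs mapped per batch (memory control).
#' @return List with `retained` (tibble subset of `reads`) and `counts`
#'   (named integer vector over pair classes).
#' @export
partition_wildtype <- function(reads, tx_index, config = mapper_config(),
                               chunk_size = 500000L) {
  n <- nrow(reads)
  status <- character(n)
  for (from in seq(1L, max(n, 1L), by = chunk_size)) {
    if (n == 0L) break
    to <- min(from + chunk_size - 1L, n)
    status[from:to] <- as.character(
      classify_pairs(reads$seq1[from:to], reads$seq2[from:to],
                     tx_index, config)
    )
  }
  wild <- status == "concordant"
  counts <- c(
    total = n,
    wildtype = sum(wild),
    retained = sum(!wild)
  )
  list(retained = reads[!wild, , drop = FALSE], counts = counts)
}

#' Detect BSJ supporting-reads among retained pairs
#'
#' Maps each mate of the retained pairs single-end against the BSJ
#' reference and keeps a mate as a supporting read when (i) its mismatch
#' count is within `floor(max_mismatch_rate * length)`, (ii) its
#' best-stratum hits touch exactly one junction, and (iii) the placement
#' spans the back-splice boundary with at least `anchor_min` bases on the
#' shorter side. Pairs whose two mates support different junctions are
#' dropped as ambiguous. The sequence of the other mate is carried along
#' for the tandem-RNA stage.
#'
#' @param reads Tibble of retained pairs (`read_id`, `seq1`, `seq2`).
#' @param bsj_ref A [build_bsj_reference()] table.
#' @param bsj_index Optional pre-built [kmer_index()] over
#'   `bsj_ref$junction_seq` (built on the fly when NULL).
#' @param config A [mapper_config()].
#' @return Tibble of supporting reads: `read_id`, `mate`, `bsj_id`,
#'   `offset`, `strand`, `mismatches`, `anchor_length`, `mate_seq`.
#' @export
detect_bsj_reads <- function(reads, bsj_ref, bsj_index = NULL,
                             config = mapper_config()) {
  empty <- tibble::tibble(
    read_id = character(0), mate = integer(0), bsj_id = character(0),
    offset = integer(0), strand = character(0), mismatches = integer(0),
    anchor_length = integer(0), mate_seq = character(0)
  )
  if (nrow(reads) == 0L || nrow(bsj_ref) == 0L) return(empty)
  if (is.null(bsj_index)) {
    bsj_index <- kmer_index(
      stats::setNames(bsj_ref$junction_seq, bsj_ref$bsj_id), config = config
    )
  }
  offsets <- stats::setNames(bsj_ref$junction_offset, bsj_ref$bsj_id)

  mate_hits <- function(seqs) {
    h <- map_reads(seqs, bsj_index, config)
    if (nrow(h) == 0L) {
      return(dplyr::mutate(h, read_len = integer(0),
                           junction_offset = integer(0),
                           anchor_length = integer(0)))
    }
    h$read_len <- nchar(seqs)[h$read]
    h$junction_offset <- unname(offsets[h$target_id])
    # uniqueness first: best-stratum hits must touch exactly one junction
    h <- h %>%
      dplyr::group_by(.data$read) %>%
      dplyr::filter(dplyr::n_distinct(.data$target_id) == 1L) %>%
      dplyr::ungroup()
    # junction-spanning with minimum anchor
    up <- h$junction_offset - h$offset
    down <- h$offset + h$read_len - h$junction_offset
    h$anchor_length <- pmin(up, down)
    h <- h[h$anchor_length >= config$anchor_min, , drop = FALSE]
    # one row per read (duplicate placements on the same junction are rare
    # repeats; keep the leftmost)
    h %>%
      dplyr::arrange(.data$read, .data$offset, .data$strand) %>%
      dplyr::distinct(.data$read, .keep_all = TRUE)
  }

  h1 <- mate_hits(reads$seq1)
  h2 <- mate_hits(reads$seq2)
  bsj1 <- rep(NA_character_, nrow(reads))
  bsj2 <- rep(NA_character_, nrow(reads))
  bsj1[h1$read] <- h1$target_id
  bsj2[h2$read] <- h2$target_id
  ambiguous <- !is.na(bsj1) & !is.na(bsj2) & bsj1 != bsj2

  sup1 <- h1[!ambiguous[h1$read], , drop = FALSE]
  sup2 <- h2[!ambiguous[h2$read], , drop = FALSE]
  out <- dplyr::bind_rows(
    tibble::tibble(
      read_id = reads$read_id[sup1$read], mate = 1L,
      bsj_id = sup1$target_id, offset = sup1$offset, strand = sup1$strand,
      mismatches = sup1$mismatches, anchor_length = sup1$anchor_length,
      mate_seq = reads$seq2[sup1$read]
    ),
    tibble::tibble(
      read_id = reads$read_id[sup2$read], mate = 2L,
      bsj_id = sup2$target_id, offset = sup2$offset, strand = sup2$strand,
      mismatches = sup2$mismatches, anchor_length = sup2$anchor_length,
      mate_seq = reads$seq1[sup2$read]
    )
  )
  dplyr::arrange(out, .data$bsj_id, .data$read_id, .data$mate)
}

#' Group supporting reads into circRNA candidates
#'
#' @param supporting Tibble from [detect_bsj_reads()].
#' @return Tibble with one row per junction: `bsj_id`, `n_support`, and a
#'   nested `reads` list-column of the supporting reads.
#' @export
assemble_candidates <- function(supporting) {
  if (nrow(supporting) == 0L) {
    return(tibble::tibble(bsj_id = character(0), n_support = integer(0),
                          reads = list()))
  }
  supporting %>%
    tidyr::nest(reads = -"bsj_id") %>%
    dplyr::mutate(n_support = vapply(.data$reads, nrow, integer(1)),
                  .after = "bsj_id") %>%
    dplyr::arrange(dplyr::desc(.data$n_support), .data$bsj_id)
}
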