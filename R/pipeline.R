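# Pipeline orchestration: index construction, end-to-end detection and
# run manifests.

#' Build the detection index (transcriptome + BSJ reference)
#'
#' @param genome A `genome_seq` (or path to a FASTA file).
#' @param ann Annotation tibble (or path to a GTF file).
#' @param read_length Read length `L` the BSJ reference is sized for.
#' @param config A [mapper_config()] (its `read_length` is synced to
#'   `read_length`).
#' @return List of class `circ_index`: `bsj_ref`, `bsj_index`,
#'   `tx_index`, `genome`, `annotation`, `config`.
#' @export
circ_index <- function(genome, ann, read_length = 100L,
                       config = mapper_config(read_length = read_length)) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  if (is.character(ann) && length(ann) == 1L) {
    ann <- read_gtf(ann)
  }
  config$read_length <- as.integer(read_length)
  tx <- transcript_sequences(ann, genome)
  bsj_ref <- build_bsj_reference(ann, genome, read_length = read_length)
  structure(list(
    bsj_ref = bsj_ref,
    bsj_index = if (nrow(bsj_ref)) {
      kmer_index(stats::setNames(bsj_ref$junction_seq, bsj_ref$bsj_id),
                 config = config)
    },
    tx_index = kmer_index(tx, config = config),
    genome = genome, annotation = ann, config = config
  ), class = "circ_index")
}

#' @export
print.circ_index <- function(x, ...) {
  cat("<circ_index> ", nrow(x$bsj_ref), " BSJ records, ",
      length(x$tx_index$names), " transcripts, L = ",
      x$config$read_length, "\n", sep = "")
  invisible(x)
}

# Empty final candidate table (column contract of detect_circrnas()).
.empty_candidates <- function() {
  tibble::tibble(
    bsj_id = character(0), contig = character(0),
    acceptor_start = integer(0), donor_end = integer(0),
    strand = character(0), gene_id = character(0),
    n_support_reads = integer(0), n_tandem_reads = integer(0),
    circ_length_nt = numeric(0), fdr2d = numeric(0), rank = integer(0)
  )
}

#' Run the full circRNA detection pipeline
#'
#' Stages: (1) drop read pairs concordantly explained by linear
#' transcripts; (2) map leftover mates to the BSJ reference and apply the
#' junction-read filters (mismatch rate, unique junction, minimum
#' anchor); (3) eliminate tandem-RNA false positives via mate
#' classification on circle/tandem pseudo-sequences and the one-third
#' rule; (4, optional) score and rank by fdr2d when a null-statistic pool
#' is given.
#'
#' @param reads Tibble with `read_id`, `seq1`, `seq2` (see
#'   [read_fastq_pair()]), or a length-2 character vector of FASTQ paths.
#' @param index A [circ_index()].
#' @param null_pool Optional null statistics for fdr2d scoring (see
#'   [fdr2d_fit()]); without it `fdr2d`/`rank` order by read count.
#' @param config A [mapper_config()] (defaults to the index's).
#' @param chunk_size Read pairs mapped per batch.
#' @param seed Seed for the fdr2d Monte-Carlo draw.
#' @param M,pi0 fdr2d parameters.
#' @return Candidate tibble (class `circ_candidates`) with columns
#'   `bsj_id`, `contig`, `acceptor_start`, `donor_end`, `strand`,
#'   `gene_id`, `n_support_reads`, `n_tandem_reads`, `circ_length_nt`,
#'   `fdr2d`, `rank`, sorted by rank. Stage read counts are in attribute
#'   `stage_counts`.
#' @export
detect_circrnas <- function(reads, index, null_pool = NULL,
                            config = index$config, chunk_size = 500000L,
                            seed = NULL, M = 100L, pi0 = 1) {
  if (is.character(reads)) {
    stopifnot(length(reads) == 2L)
    reads <- read_fastq_pair(reads[[1L]], reads[[2L]])
  }
  part <- partition_wildtype(reads, index$tx_index, config, chunk_size)
  supporting <- detect_bsj_reads(part$retained, index$bsj_ref,
                                 index$bsj_index, config)
  cands <- assemble_candidates(supporting)
  cands <- apply_tandem_filter(cands, index$bsj_ref, index$annotation,
                               index$genome, config)
  prefilter <- attr(cands, "prefilter")
  stage_counts <- c(
    part$counts,
    bsj_supporting_reads = nrow(supporting),
    candidates_pre_tandem_filter = if (is.null(prefilter)) nrow(cands)
                                   else nrow(prefilter),
    tandem_attributed_reads = if (is.null(prefilter)) 0L
                              else sum(prefilter$n_tandem)
  )
  if (nrow(cands) == 0L) {
    out <- .empty_candidates()
    attr(out, "stage_counts") <- stage_counts
    class(out) <- c("circ_candidates", class(out))
    return(out)
  }
  ref <- index$bsj_ref[match(cands$bsj_id, index$bsj_ref$bsj_id), ,
                       drop = FALSE]
  out <- tibble::tibble(
    bsj_id = cands$bsj_id, contig = ref$contig,
    acceptor_start = ref$acceptor_start, donor_end = ref$donor_end,
    strand = ref$strand, gene_id = ref$gene_id,
    n_support = cands$n_support, n_tandem = cands$n_tandem,
    circ_length_nt = cands$circ_length_nt
  )
  if (!is.null(null_pool)) {
    out <- score_candidates(out, null_pool, M = M, pi0 = pi0, seed = seed)
  } else {
    out <- dplyr::mutate(out, fdr2d = NA_real_)
    out <- dplyr::arrange(out, dplyr::desc(.data$n_support),
                          .data$bsj_id)
    out <- dplyr::mutate(out, rank = dplyr::row_number())
  }
  out <- dplyr::rename(out, n_support_reads = "n_support",
                       n_tandem_reads = "n_tandem")
  stage_counts <- c(stage_counts, candidates_final = nrow(out))
  attr(out, "stage_counts") <- stage_counts
  class(out) <- c("circ_candidates", class(tibble::tibble()))
  out
}

#' Write the final candidate table as TSV (optionally BED6)
#'
#' The BED export converts the 1-based inclusive junction coordinates to
#' 0-based half-open.
#'
#' @param candidates Output of [detect_circrnas()].
#' @param tsv_path Output TSV path.
#' @param bed_path Optional BED6 path.
#' @return `tsv_path`, invisibly.
#' @export
write_candidates <- function(candidates, tsv_path, bed_path = NULL) {
  utils::write.table(as.data.frame(candidates), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = candidates$contig,
      chromStart = candidates$acceptor_start - 1L,
      chromEnd = candidates$donor_end,
      name = candidates$bsj_id,
      score = candidates$n_support_reads,
      strand = candidates$strand
    )
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}

#' Read a candidate table written by [write_candidates()]
#'
#' @param path TSV path.
#' @return Candidate tibble.
#' @export
read_candidates <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE))
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records input paths with checksums, all parameters, the seed and the
#' package version, sufficient to re-run the pipeline byte-for-byte.
#'
#' @param path Output JSON path.
#' @param inputs Named character vector of input file paths (checksummed
#'   when they exist).
#' @param parameters Named list of parameters (configs included).
#' @param seed The RNG seed of the run.
#' @param stage_counts Optional named numeric vector of per-stage read
#'   counts.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs = character(0),
                           parameters = list(), seed = NULL,
                           stage_counts = NULL) {
  checksums <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1))
  manifest <- list(
    package = "backsplice",
    version = as.character(utils::packageVersion("backsplice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = as.list(inputs),
    input_md5 = as.list(checksums),
    parameters = parameters,
    stage_counts = as.list(stage_counts)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
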