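#' Read a genome FASTA file
#'
#' Reads a (multi-)FASTA file into a named character vector of uppercase
#' contig sequences, the genome representation used throughout the package.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return A named character vector of contig sequences (alphabet A/C/G/T/N),
#'   of class `genome_seq`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(seqs) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  # headers may carry descriptions after whitespace; contig name is field 1
  nm <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  genome_sequence(stats::setNames(toupper(as.character(seqs)), nm))
}

#' Construct a genome object from named sequences
#'
#' @param contigs Named character vector (or named list) of nucleotide
#'   strings; names are contig names.
#' @return A `genome_seq` object (named uppercase character vector).
#' @export
genome_sequence <- function(contigs) {
  contigs <- unlist(contigs)
  if (is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("all contigs must be named", call. = FALSE)
  }
  if (anyDuplicated(names(contigs))) {
    stop("contig names must be unique", call. = FALSE)
  }
  contigs <- toupper(contigs)
  if (any(nchar(contigs) == 0L)) {
    stop("contig sequences must be non-empty", call. = FALSE)
  }
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    stop("contig '", names(contigs)[bad][1L],
         "' contains characters outside A/C/G/T/N", call. = FALSE)
  }
  structure(contigs, class = c("genome_seq", "character"))
}

#' Write a genome object to FASTA
#'
#' @param genome A `genome_seq` object or named character vector.
#' @param path Output file path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Reverse-complement nucleotide strings
#'
#' @param x Character vector of A/C/G/T/N strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read exon annotation from a GTF file
#'
#' Parses the `exon` features of a GTF file into the flat exon table used by
#' the package (one row per exon). Coordinates stay 1-based inclusive as in
#' the GTF. Attribute parsing (quoted values, trailing semicolons) is
#' delegated to rtracklayer.
#'
#' @param path Path to a GTF file with `exon` features carrying `gene_id`
#'   and `transcript_id` attributes.
#' @return An annotation tibble, see [annotation()].
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) {
    stop("GTF file not found: ", path, call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) {
      stop("malformed GTF in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    stop("GTF file '", path, "' contains no exon features", call. = FALSE)
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("exon feature missing transcript_id attribute", call. = FALSE)
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
    stop("exon feature missing gene_id attribute", call. = FALSE)
  }
  annotation(tibble::tibble(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_start = GenomicRanges::start(gr),
    exon_end = GenomicRanges::end(gr)
  ))
}

#' Construct / validate an exon annotation table
#'
#' The annotation is a tibble with one row per exon and columns `gene_id`,
#' `transcript_id`, `contig`, `strand`, `exon_start`, `exon_end`
#' (1-based inclusive genomic coordinates).
#'
#' Invariants enforced: `exon_start <= exon_end`; strand is `+` or `-`;
#' all exons of a gene share contig and strand; exons of a transcript do
#' not overlap.
#'
#' @param exons A data frame with the columns above.
#' @return A validated annotation tibble of class `circ_annotation`.
#' @export
annotation <- function(exons) {
  req <- c("gene_id", "transcript_id", "contig", "strand",
           "exon_start", "exon_end")
  missing_cols <- setdiff(req, names(exons))
  if (length(missing_cols)) {
    stop("annotation is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  exons <- tibble::as_tibble(exons)[req]
  if (any(exons$exon_start > exons$exon_end)) {
    stop("exon with start > end in annotation", call. = FALSE)
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every exon", call. = FALSE)
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(exons, .data$gene_id),
    n_contig = dplyr::n_distinct(.data$contig),
    n_strand = dplyr::n_distinct(.data$strand)
  )
  if (any(per_gene$n_contig > 1L) || any(per_gene$n_strand > 1L)) {
    stop("all exons of a gene must share contig and strand", call. = FALSE)
  }
  # exons of one transcript must be disjoint
  check <- exons %>%
    dplyr::arrange(.data$transcript_id, .data$exon_start) %>%
    dplyr::group_by(.data$transcript_id) %>%
    dplyr::mutate(prev_end = dplyr::lag(.data$exon_end)) %>%
    dplyr::ungroup()
  if (any(!is.na(check$prev_end) & check$exon_start <= check$prev_end)) {
    stop("overlapping exons within a transcript", call. = FALSE)
  }
  class(exons) <- c("circ_annotation", class(tibble::tibble()))
  exons
}

#' Extract the spliced sequence of a transcript
#'
#' Concatenates the exon substrings in genomic order and reverse-complements
#' the result for minus-strand transcripts, yielding the mature (spliced)
#' sequence in transcription orientation.
#'
#' @param genome A `genome_seq` object.
#' @param exons Data frame of exons with `contig`, `exon_start`, `exon_end`
#'   columns (a single transcript's exons).
#' @param strand `"+"` or `"-"`.
#' @return A single nucleotide string.
#' @export
spliced_sequence <- function(genome, exons, strand = "+") {
  stopifnot(nrow(exons) >= 1L)
  contig <- unique(exons$contig)
  if (length(contig) != 1L) {
    stop("exons of one transcript must share a contig", call. = FALSE)
  }
  if (!contig %in% names(genome)) {
    stop("contig not in genome: ", contig, call. = FALSE)
  }
  seq <- genome[[contig]]
  if (any(exons$exon_start < 1L) || any(exons$exon_end > nchar(seq))) {
    stop("exon outside contig bounds on ", contig, call. = FALSE)
  }
  ord <- order(exons$exon_start)
  pieces <- substring(seq, exons$exon_start[ord], exons$exon_end[ord])
  out <- paste(pieces, collapse = "")
  if (identical(strand, "-")) out <- revcomp(out) else out
}

#' Spliced sequences of all annotated transcripts
#'
#' @param ann Annotation tibble ([annotation()]).
#' @param genome A `genome_seq` object.
#' @return Named character vector, one spliced sequence per transcript.
#' @export
transcript_sequences <- function(ann, genome) {
  tx <- split(ann, ann$transcript_id)
  out <- vapply(tx, function(e) {
    spliced_sequence(genome, e, e$strand[[1L]])
  }, character(1))
  out
}
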