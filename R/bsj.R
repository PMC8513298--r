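# BSJ reference construction: enumerate candidate back-splice junctions per
# gene, size their junction sequences from spliced exonic context, and keep
# only junctions flanked by canonical splice-site dinucleotides.

#' Enumerate candidate back-splice junction pairs for one gene
#'
#' Takes the distinct exon start and end coordinates of a gene (union over
#' its transcripts) and forms all combinations with end > start.
#'
#' @param gene_exons Data frame of one gene's exons (`exon_start`,
#'   `exon_end`).
#' @return Tibble with columns `acceptor_start`, `donor_end` (genomic
#'   coordinates; `donor_end > acceptor_start`), deduplicated.
#' @export
enumerate_bsj_pairs <- function(gene_exons) {
  if (nrow(gene_exons) == 0L) {
    return(tibble::tibble(acceptor_start = integer(0),
                          donor_end = integer(0)))
  }
  starts <- sort(unique(gene_exons$exon_start))
  ends <- sort(unique(gene_exons$exon_end))
  grid <- expand.grid(acceptor_start = starts, donor_end = ends,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$donor_end > grid$acceptor_start, , drop = FALSE]
  tibble::as_tibble(grid[order(grid$acceptor_start, grid$donor_end), ])
}

# Strand-adjusted boundary roles of a circle [s, e]:
# the transcription 5' boundary needs an annotated exon start (+) / end (-),
# the transcription 3' boundary an annotated exon end (+) / start (-).
.tx_boundaries <- function(strand, s, e) {
  if (strand == "+") list(tx5 = s, tx3 = e) else list(tx5 = e, tx3 = s)
}

# Exons of one transcript overlapping [s, e], clipped to the region,
# as a two-column matrix in genomic order. NULL if no overlap.
.clip_chain <- function(starts, ends, s, e) {
  keep <- ends >= s & starts <= e
  if (!any(keep)) return(NULL)
  cbind(pmax(starts[keep], s), pmin(ends[keep], e))
}

.chain_seq <- function(contig_seq, chain, strand) {
  pieces <- substring(contig_seq, chain[, 1L], chain[, 2L])
  out <- paste(pieces, collapse = "")
  if (strand == "-") revcomp(out) else out
}

# Per-gene exon structures reused across junctions of the gene.
.gene_structure <- function(gene_exons) {
  tx <- split(gene_exons[c("exon_start", "exon_end")],
              gene_exons$transcript_id)
  tx <- lapply(tx, function(d) {
    o <- order(d$exon_start)
    list(starts = d$exon_start[o], ends = d$exon_end[o])
  })
  tx[order(names(tx))]
}

#' Build the junction sequence of one back-splice junction
#'
#' Joins the last `L - 1` spliced exonic bases preceding the circle's
#' transcription 3' boundary to the first `L - 1` spliced bases following
#' its transcription 5' boundary, so that a read of length `L` spanning the
#' back-splice aligns contiguously. Flanks are confined to the circle
#' region; circles shorter than `L - 1` yield proportionally shorter
#' flanks. For each boundary the annotated transcript carrying that
#' boundary with the longest available flank is used (ties broken by
#' transcript id).
#'
#' @param genome A `genome_seq` object.
#' @param gene_exons Data frame of the gene's exons (one gene).
#' @param acceptor_start,donor_end Genomic circle boundaries
#'   (`donor_end > acceptor_start`), both annotated exon boundaries.
#' @param read_length Read length `L` (>= 2) used to size the flanks.
#' @return List with `junction_seq` and `junction_offset` (number of bases
#'   before the back-splice boundary within `junction_seq`).
#' @export
build_junction_sequence <- function(genome, gene_exons, acceptor_start,
                                    donor_end, read_length) {
  stopifnot(read_length >= 2, donor_end > acceptor_start)
  strand <- gene_exons$strand[[1L]]
  contig <- gene_exons$contig[[1L]]
  gs <- .gene_structure(gene_exons)
  out <- .junction_seq_core(genome[[contig]], gs, strand,
                            acceptor_start, donor_end, read_length)
  if (is.null(out)) {
    stop("coordinates (", acceptor_start, ", ", donor_end,
         ") are not annotated exon boundaries of this gene", call. = FALSE)
  }
  out
}

# Core junction-sequence builder on precomputed gene structures.
# Returns NULL when no transcript carries a boundary.
.junction_seq_core <- function(contig_seq, gs, strand, s, e, L) {
  b <- .tx_boundaries(strand, s, e)
  flank_max <- L - 1L

  pick <- function(role) {
    # role "tx3": flank = suffix of oriented chain; needs the 3' boundary.
    # role "tx5": flank = prefix; needs the 5' boundary.
    best <- NULL
    best_len <- -1L
    for (tid in names(gs)) {
      t <- gs[[tid]]
      has <- if (strand == "+") {
        if (role == "tx3") any(t$ends == e) else any(t$starts == s)
      } else {
        if (role == "tx3") any(t$starts == s) else any(t$ends == e)
      }
      if (!has) next
      chain <- .clip_chain(t$starts, t$ends, s, e)
      if (is.null(chain)) next
      len <- min(sum(chain[, 2L] - chain[, 1L] + 1L), flank_max)
      if (len > best_len) {
        best <- chain
        best_len <- len
      }
    }
    if (is.null(best)) NULL else best
  }

  chain3 <- pick("tx3")
  chain5 <- pick("tx5")
  if (is.null(chain3) || is.null(chain5)) return(NULL)
  seq3 <- .chain_seq(contig_seq, chain3, strand)
  seq5 <- .chain_seq(contig_seq, chain5, strand)
  up <- substring(seq3, max(1L, nchar(seq3) - flank_max + 1L), nchar(seq3))
  down <- substring(seq5, 1L, min(flank_max, nchar(seq5)))
  list(junction_seq = paste0(up, down), junction_offset = nchar(up))
}

#' Classify the splice-site dinucleotides flanking a back-splice junction
#'
#' Reads the two intronic bases immediately downstream (in transcription
#' direction) of the donor boundary and immediately upstream of the
#' acceptor boundary, strand-adjusted, and classifies the junction as
#' `GT-AG`, `GC-AG` or `AT-AC`. Other dinucleotides are rejected, as are
#' junctions whose flanking bases fall outside the contig.
#'
#' @inheritParams build_junction_sequence
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @return The splice class as a string, or `NA_character_` with attribute
#'   `reason` (`"noncanonical"` or `"contig_edge"`) when rejected.
#' @export
canonical_splice_filter <- function(genome, contig, strand, acceptor_start,
                                    donor_end) {
  res <- classify_splice_sites(
    genome,
    tibble::tibble(contig = contig, strand = strand,
                   acceptor_start = acceptor_start, donor_end = donor_end)
  )
  out <- res$splice_class[[1L]]
  if (is.na(out)) attr(out, "reason") <- res$reject_reason[[1L]]
  out
}

#' Vectorised splice-site classification
#'
#' @param genome A `genome_seq` object.
#' @param junctions Tibble with `contig`, `strand`, `acceptor_start`,
#'   `donor_end`.
#' @return `junctions` with `splice_class` (NA when rejected) and
#'   `reject_reason` columns appended.
#' @export
classify_splice_sites <- function(genome, junctions) {
  canonical <- c("GT-AG", "GC-AG", "AT-AC")
  n <- nrow(junctions)
  donor <- rep(NA_character_, n)
  acceptor <- rep(NA_character_, n)
  edge <- logical(n)
  for (ct in unique(junctions$contig)) {
    i <- which(junctions$contig == ct)
    seq <- genome[[ct]]
    clen <- nchar(seq)
    s <- junctions$acceptor_start[i]
    e <- junctions$donor_end[i]
    edge[i] <- (s - 2L) < 1L | (e + 2L) > clen
    ok <- !edge[i]
    left <- substring(seq, s - 2L, s - 1L)   # genomic bases before start
    right <- substring(seq, e + 1L, e + 2L)  # genomic bases after end
    plus <- junctions$strand[i] == "+"
    donor[i][ok & plus] <- right[ok & plus]
    acceptor[i][ok & plus] <- left[ok & plus]
    if (any(ok & !plus)) {
      donor[i][ok & !plus] <- revcomp(left[ok & !plus])
      acceptor[i][ok & !plus] <- revcomp(right[ok & !plus])
    }
  }
  cls <- dplyr::case_when(
    donor == "GT" & acceptor == "AG" ~ "GT-AG",
    donor == "GC" & acceptor == "AG" ~ "GC-AG",
    donor == "AT" & acceptor == "AC" ~ "AT-AC",
    TRUE ~ NA_character_
  )
  cls[edge] <- NA_character_
  reason <- dplyr::case_when(
    edge ~ "contig_edge",
    is.na(cls) ~ "noncanonical",
    TRUE ~ NA_character_
  )
  stopifnot(all(cls[!is.na(cls)] %in% canonical))
  dplyr::mutate(junctions, splice_class = cls, reject_reason = reason)
}

#' Build the back-splice junction reference for a genome and annotation
#'
#' For every gene, enumerates all exon-boundary combinations with
#' end > start, keeps those with canonical splice signals (GT-AG, GC-AG,
#' AT-AC), and constructs their junction sequences sized for reads of
#' length `read_length`.
#'
#' @param ann Annotation tibble ([annotation()]).
#' @param genome A `genome_seq` object.
#' @param read_length Read length `L` the reference is sized for.
#' @return A `bsj_reference` tibble with columns `bsj_id`
#'   (`gene_id:acceptor_start:donor_end`), `gene_id`, `contig`, `strand`,
#'   `acceptor_start`, `donor_end`, `junction_seq`, `junction_offset`,
#'   `splice_class`; read length stored in attribute `read_length`.
#' @export
build_bsj_reference <- function(ann, genome, read_length = 100L) {
  genes <- split(ann, ann$gene_id)
  recs <- lapply(genes, function(ge) {
    pairs <- enumerate_bsj_pairs(ge)
    if (nrow(pairs) == 0L) return(NULL)
    strand <- ge$strand[[1L]]
    contig <- ge$contig[[1L]]
    pairs$contig <- contig
    pairs$strand <- strand
    pairs <- classify_splice_sites(genome, pairs)
    pairs <- pairs[!is.na(pairs$splice_class), , drop = FALSE]
    if (nrow(pairs) == 0L) return(NULL)
    gs <- .gene_structure(ge)
    contig_seq <- genome[[contig]]
    seqs <- vector("list", nrow(pairs))
    for (j in seq_len(nrow(pairs))) {
      seqs[[j]] <- .junction_seq_core(contig_seq, gs, strand,
                                      pairs$acceptor_start[[j]],
                                      pairs$donor_end[[j]], read_length)
    }
    keep <- !vapply(seqs, is.null, logical(1))
    pairs <- pairs[keep, , drop = FALSE]
    seqs <- seqs[keep]
    if (nrow(pairs) == 0L) return(NULL)
    tibble::tibble(
      gene_id = ge$gene_id[[1L]],
      contig = contig,
      strand = strand,
      acceptor_start = pairs$acceptor_start,
      donor_end = pairs$donor_end,
      junction_seq = vapply(seqs, `[[`, character(1), "junction_seq"),
      junction_offset = vapply(seqs, `[[`, integer(1), "junction_offset"),
      splice_class = pairs$splice_class
    )
  })
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      gene_id = character(0), contig = character(0), strand = character(0),
      acceptor_start = integer(0), donor_end = integer(0),
      junction_seq = character(0), junction_offset = integer(0),
      splice_class = character(0)
    )
  }
  out <- dplyr::mutate(
    out,
    bsj_id = paste(.data$gene_id, .data$acceptor_start, .data$donor_end,
                   sep = ":"),
    .before = 1L
  )
  stopifnot(!anyDuplicated(out$bsj_id))
  attr(out, "read_length") <- as.integer(read_length)
  class(out) <- c("bsj_reference", class(tibble::tibble()))
  out
}

#' Write a BSJ reference as FASTA (+ sidecar TSV)
#'
#' FASTA headers encode the junction id and offset as
#' `bsj_id|offset=<n>`; the sidecar TSV carries the full record table.
#'
#' @param ref A `bsj_reference` tibble.
#' @param fasta_path Output FASTA path.
#' @param tsv_path Optional sidecar TSV path.
#' @return `fasta_path`, invisibly.
#' @export
write_bsj_reference <- function(ref, fasta_path, tsv_path = NULL) {
  seqs <- Biostrings::DNAStringSet(ref$junction_seq)
  names(seqs) <- paste0(ref$bsj_id, "|offset=", ref$junction_offset)
  Biostrings::writeXStringSet(seqs, filepath = fasta_path)
  if (!is.null(tsv_path)) {
    utils::write.table(
      ref[setdiff(names(ref), "junction_seq")], tsv_path,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(fasta_path)
}
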