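# Stage 2: tandem-RNA false-positive elimination. Re-maps the mates of
# BSJ supporting-reads against circRNA and tandem pseudo-sequences,
# discards reads whose mates fall outside the putative circle, and
# excludes candidates dominated by tandem evidence.

#' Candidate circRNA sequences for a back-splice junction
#'
#' Applies the alternative-splicing information of the annotated linear
#' transcripts: for every transcript of the gene carrying both circle
#' boundaries, the circRNA sequence follows that transcript's exon chain
#' between the boundaries. When no transcript carries both boundaries, the
#' union of the gene's exons inside the circle region (in genomic order)
#' is used as a single fallback variant.
#'
#' @param ann Annotation tibble.
#' @param genome A `genome_seq` object.
#' @param gene_id Gene identifier.
#' @param acceptor_start,donor_end Genomic circle boundaries.
#' @return Tibble with `variant_id`, `seq` (transcription orientation) and
#'   `length_nt`, one row per variant.
#' @export
circ_sequences <- function(ann, genome, gene_id, acceptor_start, donor_end) {
  ge <- ann[ann$gene_id == gene_id, , drop = FALSE]
  if (nrow(ge) == 0L) stop("unknown gene: ", gene_id, call. = FALSE)
  strand <- ge$strand[[1L]]
  contig_seq <- genome[[ge$contig[[1L]]]]
  s <- acceptor_start
  e <- donor_end
  gs <- .gene_structure(ge)

  has_boundary <- function(t) {
    if (strand == "+") any(t$starts == s) && any(t$ends == e)
    else any(t$starts == s) && any(t$ends == e)
  }
  carriers <- names(gs)[vapply(gs, has_boundary, logical(1))]
  if (length(carriers)) {
    seqs <- vapply(carriers, function(tid) {
      t <- gs[[tid]]
      chain <- .clip_chain(t$starts, t$ends, s, e)
      .chain_seq(contig_seq, chain, strand)
    }, character(1))
    return(tibble::tibble(variant_id = carriers, seq = unname(seqs),
                          length_nt = nchar(unname(seqs))))
  }
  # fallback: union of all gene exons inside the region
  keep <- ge$exon_end >= s & ge$exon_start <= e
  if (!any(keep) ||
      !(s %in% ge$exon_start) ||
      !(e %in% ge$exon_end)) {
    stop("circle boundaries (", s, ", ", e,
         ") are not exon boundaries of gene ", gene_id, call. = FALSE)
  }
  iv <- cbind(pmax(ge$exon_start[keep], s), pmin(ge$exon_end[keep], e))
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  merged <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(merged)
    if (iv[i, 1L] <= merged[last, 2L] + 1L) {
      merged[last, 2L] <- max(merged[last, 2L], iv[i, 2L])
    } else {
      merged <- rbind(merged, iv[i, , drop = FALSE])
    }
  }
  sq <- .chain_seq(contig_seq, merged, strand)
  tibble::tibble(variant_id = "exon_union", seq = sq, length_nt = nchar(sq))
}

#' Build the circRNA pseudo-sequence
#'
#' Prepends the last `L - 1` bases of the circRNA sequence to its
#' beginning, so a read of length `L` spanning the back-splice aligns
#' contiguously. Circles shorter than `L - 1` wrap around as often as
#' needed.
#'
#' @param circ_seq The circRNA sequence (one string).
#' @param read_length Read length `L` (>= 2).
#' @return The pseudo-sequence string; the back-splice boundary sits after
#'   position `L - 1`.
#' @export
build_circ_pseudo <- function(circ_seq, read_length) {
  stopifnot(read_length >= 2)
  n <- nchar(circ_seq)
  if (n == 0L) stop("empty circRNA sequence", call. = FALSE)
  flank <- read_length - 1L
  rep_seq <- strrep(circ_seq, ceiling(flank / n) + 1L)
  suffix <- substring(rep_seq, nchar(rep_seq) - flank + 1L, nchar(rep_seq))
  paste0(suffix, circ_seq)
}

#' Build a tandem-RNA pseudo-sequence
#'
#' Models a linear molecule whose circle region is duplicated in tandem:
#' `upstream flank + circle + circle + downstream flank`, where the flanks
#' follow the host transcript's spliced sequence and are truncated to
#' `(L - 1) + max_fragment` bases. The duplication seam carries the same
#' sequence signature as the back-splice junction.
#'
#' @param circ_seq Circle sequence (transcription orientation).
#' @param upstream,downstream Host-transcript spliced context before and
#'   after the circle region (transcription orientation; may be empty).
#' @param read_length Read length `L`.
#' @param max_fragment Largest fragment length to allow for (flank sizing).
#' @return List with `seq`, `upstream_len`, `circ_len` and `seam` (the
#'   1-based position of the last base before the duplication seam).
#' @export
build_tandem_pseudo <- function(circ_seq, upstream = "", downstream = "",
                                read_length = 100L, max_fragment = 1000L) {
  flank <- read_length - 1L + max_fragment
  up <- substring(upstream, max(1L, nchar(upstream) - flank + 1L),
                  nchar(upstream))
  down <- substring(downstream, 1L, min(flank, nchar(downstream)))
  u <- nchar(up)
  c_len <- nchar(circ_seq)
  list(
    seq = paste0(up, circ_seq, circ_seq, down),
    upstream_len = u,
    circ_len = c_len,
    seam = u + c_len
  )
}

# Host-transcript context of a circle: spliced sequence before and after
# the circle region along a transcript carrying both boundaries (longest
# transcript preferred; empty context when none exists).
.host_context <- function(ann, genome, gene_id, s, e) {
  ge <- ann[ann$gene_id == gene_id, , drop = FALSE]
  strand <- ge$strand[[1L]]
  contig_seq <- genome[[ge$contig[[1L]]]]
  gs <- .gene_structure(ge)
  carriers <- names(gs)[vapply(gs, function(t) {
    any(t$starts == s) && any(t$ends == e)
  }, logical(1))]
  if (!length(carriers)) return(list(upstream = "", downstream = ""))
  lens <- vapply(carriers, function(tid) {
    t <- gs[[tid]]
    sum(t$ends - t$starts + 1L)
  }, integer(1))
  t <- gs[[carriers[which.max(lens)]]]
  left <- .clip_chain(t$starts, t$ends, 1L, s - 1L)
  right <- .clip_chain(t$starts, t$ends, e + 1L, .Machine$integer.max)
  left_seq <- if (is.null(left)) "" else .chain_seq(contig_seq, left, "+")
  right_seq <- if (is.null(right)) "" else .chain_seq(contig_seq, right, "+")
  if (strand == "+") {
    list(upstream = left_seq, downstream = right_seq)
  } else {
    list(upstream = revcomp(right_seq), downstream = revcomp(left_seq))
  }
}

#' Classify the mates of a candidate's supporting reads
#'
#' A supporting read is kept when its mate maps end-to-end (within the
#' mismatch threshold) to any circRNA pseudo-sequence variant of the
#' candidate (`in_circle`). A mate that fails every circle variant but
#' maps to the tandem pseudo-sequence at a placement extending beyond the
#' circle-equivalent interval (the duplicated region, whose interior is
#' sequence-identical to the circle) is tandem evidence: the read is
#' dropped and counted. All other mates are unresolved (dropped, not
#' counted). Every placement fully inside the duplicated region is also a
#' circle placement, so tandem-only placements are exactly those
#' extending into the host flanks.
#'
#' @param candidate One row of [assemble_candidates()] output (with nested
#'   `reads`).
#' @param circ_variants Tibble from [circ_sequences()].
#' @param tandem List from [build_tandem_pseudo()].
#' @param config A [mapper_config()].
#' @return List with `kept` (tibble of kept supporting reads, with a
#'   `mate_verdict` column), `tandem_read_count`, and `verdicts` (tibble
#'   of `read_id`, `verdict`).
#' @export
classify_mates <- function(candidate, circ_variants, tandem,
                           config = mapper_config()) {
  reads <- candidate$reads[[1L]]
  L <- config$read_length
  circ_pseudos <- vapply(circ_variants$seq, build_circ_pseudo,
                         character(1), read_length = L)
  refs <- c(stats::setNames(circ_pseudos,
                            paste0("circ|", circ_variants$variant_id)),
            stats::setNames(tandem$seq, "tandem"))
  idx <- kmer_index(refs, config = config)
  hits <- map_reads(reads$mate_seq, idx, config)
  verdict <- rep("unresolved", nrow(reads))
  in_circle <- unique(hits$read[startsWith(hits$target_id, "circ|")])
  verdict[in_circle] <- "in_circle"

  th <- hits[hits$target_id == "tandem" & !(hits$read %in% in_circle), ,
             drop = FALSE]
  if (nrow(th)) {
    lo <- tandem$upstream_len + 1L
    hi <- tandem$upstream_len + 2L * tandem$circ_len
    read_len <- nchar(reads$mate_seq)[th$read]
    inside <- (th$offset + 1L) >= lo & (th$offset + read_len) <= hi
    per_read <- tapply(inside, th$read, function(x) {
      if (any(x)) "unresolved" else "tandem_evidence"
    })
    verdict[as.integer(names(per_read))] <- as.character(per_read)
  }
  kept <- reads[verdict == "in_circle", , drop = FALSE]
  kept$mate_verdict <- "in_circle"
  list(
    kept = kept,
    tandem_read_count = sum(verdict == "tandem_evidence"),
    verdicts = tibble::tibble(read_id = reads$read_id, verdict = verdict)
  )
}

#' Exclude candidates dominated by tandem evidence
#'
#' Keeps a candidate only when its tandem-attributed read count does not
#' exceed one third of its total BSJ supporting-reads (kept plus
#' tandem-attributed); candidates left with zero kept reads are removed.
#'
#' @param candidates Tibble with `n_support` (kept reads) and
#'   `n_tandem` columns.
#' @return The filtered tibble.
#' @export
tandem_fraction_filter <- function(candidates) {
  total <- candidates$n_support + candidates$n_tandem
  keep <- candidates$n_support >= 1L & candidates$n_tandem <= total / 3
  candidates[keep, , drop = FALSE]
}

#' Apply the tandem-RNA stage to all candidates
#'
#' For every candidate: derive the circle sequence variants, build circle
#' and tandem pseudo-sequences, classify the supporting reads' mates, and
#' apply the one-third tandem-fraction exclusion. Also attaches the
#' candidate's circRNA length (median over variant lengths).
#'
#' @param candidates Output of [assemble_candidates()].
#' @param bsj_ref The [build_bsj_reference()] table (resolves `bsj_id`).
#' @param ann Annotation tibble.
#' @param genome A `genome_seq` object.
#' @param config A [mapper_config()].
#' @return Candidate tibble with `n_support` (kept reads), `n_tandem`,
#'   `circ_length_nt`, nested `reads`, filtered by the one-third rule;
#'   the unfiltered table is kept in attribute `prefilter`.
#' @export
apply_tandem_filter <- function(candidates, bsj_ref, ann, genome,
                                config = mapper_config()) {
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, n_tandem = integer(0),
                         circ_length_nt = numeric(0)))
  }
  ref <- bsj_ref[match(candidates$bsj_id, bsj_ref$bsj_id), , drop = FALSE]
  L <- config$read_length
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    variants <- circ_sequences(ann, genome, ref$gene_id[[i]],
                               ref$acceptor_start[[i]], ref$donor_end[[i]])
    ctx <- .host_context(ann, genome, ref$gene_id[[i]],
                         ref$acceptor_start[[i]], ref$donor_end[[i]])
    tandem <- build_tandem_pseudo(
      variants$seq[[which.max(variants$length_nt)]],
      upstream = ctx$upstream, downstream = ctx$downstream,
      read_length = L, max_fragment = config$frag_max
    )
    cls <- classify_mates(candidates[i, ], variants, tandem, config)
    out[[i]] <- tibble::tibble(
      bsj_id = candidates$bsj_id[[i]],
      n_support = nrow(cls$kept),
      n_tandem = cls$tandem_read_count,
      circ_length_nt = circ_length(variants$length_nt),
      reads = list(cls$kept)
    )
  }
  prefilter <- dplyr::bind_rows(out)
  res <- tandem_fraction_filter(prefilter)
  attr(res, "prefilter") <- prefilter
  res
}
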