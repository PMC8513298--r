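# Synthetic data: a genome/annotation fixture generator (stands in for a
# real reference) and a paired-end read simulator emitting circRNA,
# tandem-RNA and linear reads with a ground-truth table.

#' Simulation configuration
#'
#' @param read_length Read length in bases (default 100).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param fragment_mean,fragment_sd Fragment-length distribution,
#'   Normal(250, 25) by default; drawn lengths are rounded and clipped to
#'   `[read_length, molecule length]`.
#' @param fpkm_floor Lower truncation of sampled expression (default 0.2).
#' @param fpkm_ceiling_quantile Upper truncation quantile (default 0.99).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(read_length = 100L, error_rate = 0.005,
                       fragment_mean = 250, fragment_sd = 25,
                       fpkm_floor = 0.2, fpkm_ceiling_quantile = 0.99) {
  stopifnot(read_length >= 2, error_rate >= 0, error_rate < 1,
            fragment_mean > 0, fragment_sd >= 0,
            fpkm_floor > 0, fpkm_ceiling_quantile > 0,
            fpkm_ceiling_quantile <= 1)
  structure(list(read_length = as.integer(read_length),
                 error_rate = error_rate,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 fpkm_floor = fpkm_floor,
                 fpkm_ceiling_quantile = fpkm_ceiling_quantile),
            class = "sim_config")
}

#' Generate a synthetic genome and annotation fixture
#'
#' Random contig sequence with non-overlapping multi-exon genes; canonical
#' GT-AG dinucleotides are planted in the introns and the flanking
#' intergenic sequence (strand-aware), so every enumerated back-splice
#' junction passes the canonical splice filter. Each gene gets one
#' transcript with all exons plus up to two random exon-subset isoforms.
#'
#' @param n_genes Number of genes.
#' @param genome_size Contig length in bases.
#' @param exon_count_range,exon_length_range,intron_length_range,
#'   intergenic_range Integer ranges for the gene model.
#' @param max_isoforms Maximum transcripts per gene.
#' @param contig Contig name.
#' @param seed Optional RNG seed (fixture is byte-deterministic given the
#'   seed).
#' @return List of class `genome_fixture` with `genome` (a `genome_seq`)
#'   and `annotation` (an [annotation()] tibble).
#' @export
simulate_genome <- function(n_genes = 300L, genome_size = 2e6,
                            exon_count_range = c(1L, 10L),
                            exon_length_range = c(100L, 400L),
                            intron_length_range = c(100L, 400L),
                            intergenic_range = c(200L, 500L),
                            max_isoforms = 3L, contig = "chr1",
                            seed = NULL) {
  stopifnot(n_genes >= 1, genome_size > 1000)
  if (!is.null(seed)) set.seed(seed)
  base <- sample(c("A", "C", "G", "T"), genome_size, replace = TRUE)
  rows <- list()
  cursor <- 10L
  for (g in seq_len(n_genes)) {
    gene_id <- sprintf("g%04d", g)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq(exon_count_range[1L], exon_count_range[2L]), 1L)
    ex_len <- sample(seq(exon_length_range[1L], exon_length_range[2L]),
                     n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) {
      sample(seq(intron_length_range[1L], intron_length_range[2L]),
             n_ex - 1L, replace = TRUE)
    } else integer(0)
    gap <- sample(seq(intergenic_range[1L], intergenic_range[2L]), 1L)
    start <- cursor + gap
    ends <- start + cumsum(ex_len) + c(0L, cumsum(in_len))[seq_len(n_ex)] - 1L
    starts <- ends - ex_len + 1L
    if (ends[n_ex] + 2L > genome_size) {
      stop("infeasible packing: ", n_genes, " genes do not fit in ",
           genome_size, " bases", call. = FALSE)
    }
    # canonical splice dinucleotides around every exon boundary
    if (strand == "+") {
      before <- c("A", "G")   # acceptor AG upstream of each exon start
      after <- c("G", "T")    # donor GT downstream of each exon end
    } else {
      before <- c("A", "C")   # revcomp(GT)
      after <- c("C", "T")    # revcomp(AG)
    }
    for (i in seq_len(n_ex)) {
      base[(starts[i] - 2L):(starts[i] - 1L)] <- before
      base[(ends[i] + 1L):(ends[i] + 2L)] <- after
    }
    # isoforms: transcript 1 has all exons, further isoforms random subsets
    n_iso <- sample(seq_len(max_isoforms), 1L)
    subsets <- list(seq_len(n_ex))
    while (length(subsets) < n_iso) {
      keep <- which(stats::runif(n_ex) < 0.8)
      if (length(keep) == 0L) next
      if (any(vapply(subsets, identical, logical(1), keep))) {
        n_iso <- n_iso - 1L
        next
      }
      subsets <- c(subsets, list(keep))
    }
    for (t in seq_along(subsets)) {
      idx <- subsets[[t]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = gene_id,
        transcript_id = sprintf("%s.t%d", gene_id, t),
        contig = contig, strand = strand,
        exon_start = starts[idx], exon_end = ends[idx]
      )
    }
    cursor <- ends[n_ex] + 2L
  }
  genome <- genome_sequence(stats::setNames(
    paste(base, collapse = ""), contig
  ))
  structure(list(genome = genome,
                 annotation = annotation(dplyr::bind_rows(rows))),
            class = "genome_fixture")
}

#' Write an annotation tibble as GTF
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   ann$gene_id, ann$transcript_id)
  lines <- paste(ann$contig, "backsplice", "exon", ann$exon_start,
                 ann$exon_end, ".", ann$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Sample expression values (FPKM)
#'
#' Draws from the empirical distribution of `source` when given (the
#' paper-style case: circRNA/tandem expression sampled from the linear
#' transcripts' expression), otherwise from a log-normal; either way the
#' range is truncated to `[fpkm_floor, 99th percentile]`.
#'
#' @param n Number of values.
#' @param source Optional numeric vector to resample from.
#' @param config A [sim_config()] (for floor and ceiling quantile).
#' @param meanlog,sdlog Log-normal parameters for the default
#'   distribution.
#' @param seed Optional RNG seed.
#' @return Numeric vector of length `n` within the truncation range.
#' @export
sample_expression <- function(n, source = NULL, config = sim_config(),
                              meanlog = 1, sdlog = 2, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lo <- config$fpkm_floor
  if (!is.null(source)) {
    hi <- stats::quantile(source, config$fpkm_ceiling_quantile, names = FALSE)
    pool <- source[source >= lo & source <= hi]
    if (length(pool) == 0L) pool <- pmin(pmax(source, lo), hi)
    return(sample(pool, n, replace = TRUE))
  }
  hi <- stats::qlnorm(config$fpkm_ceiling_quantile, meanlog, sdlog)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Sample circle (or tandem) specifications from the annotated exon
# structure: pick a transcript and an exon sub-chain whose spliced length
# falls in the requested range.
.sample_junction_molecules <- function(ann, genome, n, prefix,
                                       length_range = c(200L, 2000L),
                                       exclude_genes = character(0),
                                       max_tries = 50L * n) {
  genes <- setdiff(unique(ann$gene_id), exclude_genes)
  out <- list()
  seen <- character(0)
  tries <- 0L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    gid <- sample(genes, 1L)
    ge <- ann[ann$gene_id == gid, , drop = FALSE]
    tid <- sample(unique(ge$transcript_id), 1L)
    te <- ge[ge$transcript_id == tid, , drop = FALSE]
    te <- te[order(te$exon_start), , drop = FALSE]
    i <- sample.int(nrow(te), 1L)
    j <- i + sample.int(nrow(te) - i + 1L, 1L) - 1L
    s <- te$exon_start[[i]]
    e <- te$exon_end[[j]]
    key <- paste(gid, s, e, sep = ":")
    if (key %in% seen) next
    len <- sum(te$exon_end[i:j] - te$exon_start[i:j] + 1L)
    if (len < length_range[1L] || len > length_range[2L]) next
    seen <- c(seen, key)
    variants <- circ_sequences(ann, genome, gid, s, e)
    out[[length(out) + 1L]] <- tibble::tibble(
      molecule_id = sprintf("%s%04d", prefix, length(out) + 1L),
      gene_id = gid, contig = ge$contig[[1L]], strand = ge$strand[[1L]],
      acceptor_start = s, donor_end = e,
      circ_seq = variants$seq[variants$variant_id == tid][1L],
      length_nt = nchar(variants$seq[variants$variant_id == tid][1L])
    )
  }
  if (length(out) < n) {
    stop("could not sample ", n, " junction molecules from the annotation",
         call. = FALSE)
  }
  dplyr::bind_rows(out)
}

#' Build emission sequences for simulation molecules
#'
#' Linear molecules emit their spliced transcript sequence; circRNAs emit
#' their pseudo-sequence (last `L - 1` bases prepended, so fragments can
#' straddle the back-splice); tandem RNAs emit the duplicated-region
#' construct with host-transcript flanks.
#'
#' @param ann Annotation tibble.
#' @param genome A `genome_seq`.
#' @param circles,tandems Spec tibbles from the internal junction sampler
#'   (columns `molecule_id`, `gene_id`, `acceptor_start`, `donor_end`,
#'   `circ_seq`); may be empty.
#' @param transcripts Character vector of transcript ids to emit as linear
#'   molecules (default: all).
#' @param read_length Read length `L`.
#' @param max_fragment Flank sizing for tandem constructs.
#' @return Tibble with `molecule_id`, `class`, `seq`, `seam` (1-based
#'   position of the last base before the back-splice/duplication seam; NA
#'   for linear), `length_nt` (circRNA length for circles, emission length
#'   otherwise).
#' @export
build_molecule_sequences <- function(ann, genome, circles = NULL,
                                     tandems = NULL, transcripts = NULL,
                                     read_length = 100L,
                                     max_fragment = 1000L) {
  out <- list()
  if (!is.null(circles) && nrow(circles)) {
    out$circ <- tibble::tibble(
      molecule_id = circles$molecule_id, class = "circ",
      seq = vapply(circles$circ_seq, build_circ_pseudo, character(1),
                   read_length = read_length, USE.NAMES = FALSE),
      seam = read_length - 1L,
      length_nt = nchar(circles$circ_seq)
    )
  }
  if (!is.null(tandems) && nrow(tandems)) {
    td <- lapply(seq_len(nrow(tandems)), function(i) {
      ctx <- .host_context(ann, genome, tandems$gene_id[[i]],
                           tandems$acceptor_start[[i]],
                           tandems$donor_end[[i]])
      build_tandem_pseudo(tandems$circ_seq[[i]], ctx$upstream,
                          ctx$downstream, read_length, max_fragment)
    })
    out$tandem <- tibble::tibble(
      molecule_id = tandems$molecule_id, class = "tandem",
      seq = vapply(td, `[[`, character(1), "seq"),
      seam = vapply(td, `[[`, numeric(1), "seam"),
      length_nt = nchar(vapply(td, `[[`, character(1), "seq"))
    )
  }
  tx_seqs <- transcript_sequences(ann, genome)
  if (!is.null(transcripts)) tx_seqs <- tx_seqs[transcripts]
  out$linear <- tibble::tibble(
    molecule_id = names(tx_seqs), class = "linear",
    seq = unname(tx_seqs), seam = NA_real_, length_nt = nchar(tx_seqs)
  )
  dplyr::bind_rows(out)
}

#' Simulate paired-end reads from emission sequences
#'
#' Fragment counts follow `FPKM x length/1000 x total/1e6` (realised by
#' randomised rounding); fragment starts are uniform, lengths Normal with
#' rounding and clipping to `[read_length, molecule length]`; mate 1 is
#' the first `read_length` bases of the fragment, mate 2 the
#' reverse-complemented last `read_length` bases; substitution errors are
#' applied per base at `error_rate`. Every pair gets one truth row.
#'
#' @param molecules Tibble from [build_molecule_sequences()].
#' @param fpkm Expression values aligned with `molecules` (ignored when
#'   `expected_fragments` is given).
#' @param total_fragments Total fragment budget; `fpkm` is rescaled so the
#'   expected totals match.
#' @param expected_fragments Optional vector of expected fragment counts
#'   per molecule, overriding the FPKM formula.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed (byte-deterministic output given the
#'   seed).
#' @return List of class `sim_reads` with `reads` (tibble `read_id`,
#'   `seq1`, `seq2`) and `truth` (one row per pair: `read_id`,
#'   `molecule_id`, `class`, `fragment_start`, `fragment_length`,
#'   `straddles_bsj`, `straddle_anchor`, and the per-mate anchors
#'   `straddle_anchor1`/`straddle_anchor2`).
#' @export
simulate_reads <- function(molecules, fpkm = NULL, total_fragments = NULL,
                           expected_fragments = NULL,
                           config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- config$read_length
  mol <- molecules
  short <- nchar(mol$seq) < L
  if (any(short)) {
    warning(sum(short), " molecule(s) shorter than the read length skipped")
    mol <- mol[!short, , drop = FALSE]
    if (!is.null(fpkm)) fpkm <- fpkm[!short]
    if (!is.null(expected_fragments)) {
      expected_fragments <- expected_fragments[!short]
    }
  }
  len <- nchar(mol$seq)
  if (is.null(expected_fragments)) {
    stopifnot(!is.null(fpkm), length(fpkm) == nrow(mol))
    mu <- fpkm * (len / 1000)
    if (is.null(total_fragments)) {
      stop("provide total_fragments (or expected_fragments)", call. = FALSE)
    }
    mu <- mu / sum(mu) * total_fragments
  } else {
    stopifnot(length(expected_fragments) == nrow(mol))
    mu <- expected_fragments
  }
  n_frag <- floor(mu) + (stats::runif(length(mu)) < (mu - floor(mu)))
  n_frag <- as.integer(n_frag)

  ids <- vector("list", nrow(mol))
  s1 <- vector("list", nrow(mol))
  s2 <- vector("list", nrow(mol))
  tr <- vector("list", nrow(mol))
  for (i in seq_len(nrow(mol))) {
    n <- n_frag[[i]]
    if (n == 0L) next
    li <- len[[i]]
    flen <- as.integer(pmin(pmax(round(
      stats::rnorm(n, config$fragment_mean, config$fragment_sd)
    ), L), li))
    start <- 1L + as.integer(floor(stats::runif(n) * (li - flen + 1L)))
    m1s <- start
    m2s <- start + flen - L
    s1[[i]] <- substring(mol$seq[[i]], m1s, m1s + L - 1L)
    s2[[i]] <- substring(mol$seq[[i]], m2s, m2s + L - 1L)
    ids[[i]] <- paste0(mol$molecule_id[[i]], "_", seq_len(n))
    seam <- mol$seam[[i]]
    anchor <- function(st) {
      if (is.na(seam)) return(rep(0L, n))
      a <- pmin(seam - st + 1L, st + L - 1L - seam)
      pmax(as.integer(a), 0L)
    }
    a1 <- anchor(m1s)
    a2 <- anchor(m2s)
    tr[[i]] <- tibble::tibble(
      read_id = ids[[i]], molecule_id = mol$molecule_id[[i]],
      class = mol$class[[i]], fragment_start = start,
      fragment_length = flen,
      straddles_bsj = pmax(a1, a2) >= 1L,
      straddle_anchor = pmax(a1, a2),
      straddle_anchor1 = a1, straddle_anchor2 = a2
    )
  }
  seq1 <- unlist(s1, use.names = FALSE)
  seq2 <- if (length(s2)) revcomp(unlist(s2, use.names = FALSE)) else character(0)
  if (config$error_rate > 0 && length(seq1)) {
    seq1 <- .mx_mutate(seq1, config$error_rate)
    seq2 <- .mx_mutate(seq2, config$error_rate)
  }
  reads <- tibble::tibble(read_id = unlist(ids, use.names = FALSE),
                          seq1 = seq1, seq2 = seq2)
  truth <- dplyr::bind_rows(tr)
  if (is.null(truth)) truth <- tibble::tibble()
  stopifnot(nrow(reads) == nrow(truth))
  structure(list(reads = reads, truth = truth, config = config),
            class = "sim_reads")
}

#' Simulate a full circRNA RNA-seq experiment
#'
#' Composes the fixture annotation into circRNA, tandem-RNA and linear
#' molecules, samples expression (circRNA and tandem expression is drawn
#' from the linear transcripts' distribution, truncated to the configured
#' floor/ceiling), and emits reads class by class against fixed fragment
#' budgets. The default budgets reproduce, scaled to 200 circles, the
#' per-molecule depths of the study conditions this package's defaults
#' model: about 159 fragments per circRNA, about 1611 per tandem RNA, and
#' a proportional linear background.
#'
#' @param fixture A [simulate_genome()] fixture (or a list with `genome`
#'   and `annotation`).
#' @param n_circles,n_tandems Number of circRNA / tandem molecules.
#' @param circ_fragments,tandem_fragments,linear_fragments Fragment
#'   budgets per class (defaults scale with the molecule counts).
#' @param circ_length_range Spliced-length range circles are sampled
#'   from.
#' @param tandem_length_range Spliced-length range of tandem duplicated
#'   regions; shorter than circles by default, modelling the short
#'   duplication seams (exon repetition, trans-splicing, RT
#'   template-switching) that dominate false-positive back-splice
#'   junctions.
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return List of class `circ_sim`: `reads`, `truth` (per pair),
#'   `circles` and `tandems` (molecule tables with junction coordinates),
#'   `fpkm`, `config`.
#' @export
simulate_experiment <- function(fixture, n_circles = 200L, n_tandems = 0L,
                                circ_fragments = round(n_circles * 997486 / 6256),
                                tandem_fragments = round(n_tandems * 1623654 / 1008),
                                linear_fragments = 1800000L,
                                circ_length_range = c(200L, 2000L),
                                tandem_length_range = c(150L, 1000L),
                                config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ann <- fixture$annotation
  genome <- fixture$genome
  circles <- if (n_circles > 0L) {
    .sample_junction_molecules(ann, genome, n_circles, "circ",
                               circ_length_range)
  }
  tandems <- if (n_tandems > 0L) {
    .sample_junction_molecules(
      ann, genome, n_tandems, "tand", tandem_length_range,
      exclude_genes = if (is.null(circles)) character(0)
                      else unique(circles$gene_id)
    )
  }
  mol <- build_molecule_sequences(ann, genome, circles, tandems,
                                  read_length = config$read_length)
  is_lin <- mol$class == "linear"
  fpkm <- numeric(nrow(mol))
  fpkm[is_lin] <- sample_expression(sum(is_lin), config = config)
  if (any(!is_lin)) {
    fpkm[!is_lin] <- sample_expression(sum(!is_lin), source = fpkm[is_lin],
                                       config = config)
  }
  # fixed per-class budgets: rescale expected counts within each class
  mu <- fpkm * (nchar(mol$seq) / 1000)
  budget <- c(circ = circ_fragments, tandem = tandem_fragments,
              linear = linear_fragments)
  for (cl in names(budget)) {
    sel <- mol$class == cl
    if (any(sel) && budget[[cl]] > 0) {
      mu[sel] <- mu[sel] / sum(mu[sel]) * budget[[cl]]
    } else {
      mu[sel] <- 0
    }
  }
  sim <- simulate_reads(mol, expected_fragments = mu, config = config)
  structure(list(reads = sim$reads, truth = sim$truth, circles = circles,
                 tandems = tandems, fpkm = tibble::tibble(
                   molecule_id = mol$molecule_id, class = mol$class,
                   fpkm = fpkm, expected_fragments = mu
                 ),
                 config = config),
            class = "circ_sim")
}
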