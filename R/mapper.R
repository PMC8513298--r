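# R surface over the compiled k-mer mapper.

#' Mapper configuration
#'
#' @param k Seed length in bases (default 15). Seeds are taken at every
#'   read position, which guarantees that no placement at or below the
#'   mismatch threshold is missed for reads of length >= 2k.
#' @param max_mismatch_rate Maximum allowed mismatch fraction per read
#'   (default 0.01, i.e. at most 1 mismatch per 100 bases; the threshold is
#'   `floor(rate * read_length)`).
#' @param read_length Nominal read length L in bases.
#' @param anchor_min Minimum anchor: the shorter piece of a
#'   junction-spanning read on either side of the back-splice (default 10).
#' @param frag_min,frag_max Implied fragment-length bounds for calling a
#'   read pair concordant (defaults `2 * anchor_min` and 1000).
#' @return A list of class `mapper_config`.
#' @export
mapper_config <- function(k = 15L, max_mismatch_rate = 0.01,
                          read_length = 100L, anchor_min = 10L,
                          frag_min = NULL, frag_max = 1000L) {
  if (is.null(frag_min)) frag_min <- 2L * anchor_min
  stopifnot(k >= 1, k <= read_length,
            max_mismatch_rate >= 0, max_mismatch_rate < 1,
            anchor_min >= 1, frag_min >= 1, frag_max >= frag_min)
  structure(list(k = as.integer(k),
                 max_mismatch_rate = max_mismatch_rate,
                 read_length = as.integer(read_length),
                 anchor_min = as.integer(anchor_min),
                 frag_min = as.integer(frag_min),
                 frag_max = as.integer(frag_max)),
            class = "mapper_config")
}

#' Build a k-mer index over a reference sequence set
#'
#' @param refs Named character vector of reference sequences.
#' @param k Seed length (defaults to `config$k`).
#' @param config A [mapper_config()].
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(refs, k = config$k, config = mapper_config()) {
  stopifnot(length(refs) > 0, !is.null(names(refs)))
  if (any(nchar(refs) == 0L)) stop("reference sequences must be non-empty",
                                   call. = FALSE)
  idx <- list(names = names(refs), seqs = unname(as.character(refs)),
              k = as.integer(k), ptr = new.env(parent = emptyenv()))
  class(idx) <- "kmer_index"
  idx$ptr$xp <- .mx_index_build(idx$names, idx$seqs, idx$k)
  idx
}

# External pointers do not survive serialisation; rebuild on demand.
.index_ptr <- function(index) {
  xp <- index$ptr$xp
  if (is.null(xp) || !.mx_ptr_ok(xp)) {
    xp <- .mx_index_build(index$names, index$seqs, index$k)
    index$ptr$xp <- xp
  }
  xp
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> ", length(x$names), " references, k = ", x$k, "\n",
      sep = "")
  invisible(x)
}

#' Map reads against an indexed reference set
#'
#' Performs k-mer seeded, ungapped, end-to-end placement of each read on
#' both strands, discards placements above the mismatch threshold
#' `floor(max_mismatch_rate * nchar(read))`, and returns only the hits tied
#' at the minimum mismatch count (the best stratum), sorted by
#' (target, offset, strand).
#'
#' @param reads Character vector of reads (A/C/G/T/N).
#' @param index A [kmer_index()].
#' @param config A [mapper_config()].
#' @return Tibble with columns `read` (index into `reads`), `target_id`,
#'   `offset` (0-based start on target), `strand`, `mismatches`.
#' @export
map_reads <- function(reads, index, config = mapper_config()) {
  hits <- .mx_map(.index_ptr(index), as.character(reads),
                  config$max_mismatch_rate)
  tibble::tibble(
    read = hits$read,
    target_id = index$names[hits$target],
    offset = hits$offset,
    strand = hits$strand,
    mismatches = hits$mismatches
  )
}

#' Classify read pairs as concordant / orphan / unmapped
#'
#' A pair is concordant when both mates place end-to-end on the same
#' target in FR orientation (opposite strands, forward mate leftmost) with
#' an implied fragment length within `[frag_min, frag_max]`.
#'
#' @param reads1,reads2 Mate sequences (same length vectors).
#' @inheritParams map_reads
#' @return Factor vector with levels `unmapped`, `concordant`, `discordant`.
#' @export
classify_pairs <- function(reads1, reads2, index, config = mapper_config()) {
  if (length(reads1) != length(reads2)) {
    stop("mate vectors differ in length", call. = FALSE)
  }
  codes <- .mx_pair_class(.index_ptr(index), as.character(reads1),
                          as.character(reads2), config$max_mismatch_rate,
                          config$frag_min, config$frag_max)
  factor(c("unmapped", "concordant", "discordant")[codes + 1L],
         levels = c("unmapped", "concordant", "discordant"))
}

#' Map a single read pair
#'
#' @param read1,read2 Mate sequences (single strings).
#' @inheritParams map_reads
#' @return List with `status` (`concordant`, `discordant` or `unmapped`)
#'   and the per-mate best-stratum hit tibbles.
#' @export
map_pair <- function(read1, read2, index, config = mapper_config()) {
  status <- classify_pairs(read1, read2, index, config)
  list(status = as.character(status),
       hits1 = map_reads(read1, index, config),
       hits2 = map_reads(read2, index, config))
}

#' Look up the seed postings of one k-mer
#'
#' Mainly for verifying the index against a brute-force k-mer scan.
#'
#' @param index A [kmer_index()].
#' @param kmer A string of length `index$k`.
#' @return Tibble with `target_id` and 0-based `pos`.
#' @export
seed_postings <- function(index, kmer) {
  df <- .mx_seed_postings(.index_ptr(index), kmer)
  tibble::tibble(target_id = index$names[df$target], pos = df$pos)
}
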