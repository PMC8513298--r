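# Two-dimensional local false discovery rate on
# z = (log2 supporting-read count, log2 circRNA length).
#
# The density ratio is estimated indirectly: the M Monte-Carlo null
# samples are labelled successes, the observed statistics failures, and
# r(z) -- the smoothed success proportion -- plugs into
# fdr2d(z) = pi0 * r / (M * (1 - r)).

#' Median circRNA length over isoform variants
#'
#' With several annotated transcripts supporting a junction the circRNA
#' length is the median of the variant lengths (mean of the two middle
#' values for an even count).
#'
#' @param lengths Numeric vector of variant lengths (>= 1 value).
#' @return The median length.
#' @export
circ_length <- function(lengths) {
  if (length(lengths) == 0L) {
    stop("no circRNA sequence variant available", call. = FALSE)
  }
  stats::median(lengths)
}

#' Depletion status from paired RNase R libraries
#'
#' A circRNA is non-depleted when its library-size-normalised expression
#' in the untreated (RNase R-) sample does not exceed that in the treated
#' (RNase R+) sample; otherwise it is depleted. Depleted circRNAs serve as
#' the empirical null of the fdr2d method.
#'
#' @param expr_minus,expr_plus Normalised expression in the RNase R- and
#'   RNase R+ samples (same length, non-negative).
#' @return Character vector, `"non_depleted"` or `"depleted"`.
#' @export
classify_depletion <- function(expr_minus, expr_plus) {
  if (any(expr_minus < 0) || any(expr_plus < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  ifelse(expr_minus <= expr_plus, "non_depleted", "depleted")
}

#' Normalise raw counts to counts per million
#'
#' @param counts Raw read counts.
#' @param library_size Total mapped reads of the library (defaults to
#'   `sum(counts)`).
#' @return Counts per million.
#' @export
cpm_normalise <- function(counts, library_size = sum(counts)) {
  counts / library_size * 1e6
}

#' Log2 statistics for the fdr2d method
#'
#' @param count BSJ supporting-read counts (>= 1).
#' @param length_nt circRNA lengths in nucleotides.
#' @return Tibble with `z1 = log2(count)` and `z2 = log2(length_nt)`.
#' @export
circ_statistics <- function(count, length_nt) {
  stopifnot(all(count >= 1), all(length_nt > 0))
  tibble::tibble(z1 = log2(count), z2 = log2(length_nt))
}

#' Read a null-statistic table
#'
#' Two tab-separated columns with header: `bsj_read_count`,
#' `circ_length_nt` — typically the depleted circRNAs of independent
#' RNase R- datasets.
#'
#' @param path TSV path.
#' @return Tibble with `count` and `length_nt`.
#' @export
read_null_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  req <- c("bsj_read_count", "circ_length_nt")
  if (!all(req %in% names(df))) {
    stop("null table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(count = df$bsj_read_count, length_nt = df$circ_length_nt)
}

#' Draw the Monte-Carlo null ensemble
#'
#' Takes `M` samples of size `n`, with replacement, from the null
#' statistic pool.
#'
#' @param null_pool Tibble with `z1`, `z2` (see [circ_statistics()]).
#' @param n Number of observed candidates.
#' @param M Number of Monte-Carlo samples.
#' @param seed Optional RNG seed for reproducibility.
#' @return Tibble with columns `sample` (1..M), `z1`, `z2`
#'   (`M * n` rows).
#' @export
sample_null <- function(null_pool, n, M = 100L, seed = NULL) {
  if (nrow(null_pool) == 0L) stop("empty null pool", call. = FALSE)
  stopifnot(M >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(null_pool), n * M, replace = TRUE)
  tibble::tibble(
    sample = rep(seq_len(M), each = n),
    z1 = null_pool$z1[idx],
    z2 = null_pool$z2[idx]
  )
}

#' Smoothed success proportion r(z) at the observed points
#'
#' Pools the null ensemble (successes) with the observed statistics
#' (failures), standardises each axis by the pooled standard deviation,
#' and evaluates, at every observed point, the success proportion among
#' its `k_nn` nearest pooled neighbours with add-one smoothing, so that
#' `r` never reaches 0 or 1. All points tied with the k-th nearest
#' distance are included, which keeps the estimate deterministic and free
#' of label-order bias when the statistics are heavily tied (counts are
#' discrete).
#'
#' @param observed Tibble with `z1`, `z2` for the candidates.
#' @param ensemble Output of [sample_null()].
#' @param k_nn Neighbourhood size (default `ceiling(sqrt(total points))`).
#' @return Numeric vector of `r` values in (0, 1), one per observed point.
#' @export
estimate_r <- function(observed, ensemble, k_nn = NULL) {
  n <- nrow(observed)
  if (n == 0L) stop("no observed statistics", call. = FALSE)
  pool_z1 <- c(ensemble$z1, observed$z1)
  pool_z2 <- c(ensemble$z2, observed$z2)
  success <- c(rep(TRUE, nrow(ensemble)), rep(FALSE, n))
  total <- length(pool_z1)
  if (is.null(k_nn)) k_nn <- ceiling(sqrt(total))
  if (total < 2L || k_nn < 1L) {
    stop("too few points for smoothing", call. = FALSE)
  }
  k_nn <- min(k_nn, total)
  s1 <- stats::sd(pool_z1)
  s2 <- stats::sd(pool_z2)
  if (!isTRUE(s1 > 0)) s1 <- 1
  if (!isTRUE(s2 > 0)) s2 <- 1
  p1 <- pool_z1 / s1
  p2 <- pool_z2 / s2
  o1 <- observed$z1 / s1
  o2 <- observed$z2 / s2
  r <- numeric(n)
  for (i in seq_len(n)) {
    d <- (p1 - o1[i])^2 + (p2 - o2[i])^2
    dk <- sort(d, partial = k_nn)[k_nn]
    nb <- d <= dk  # inclusive of ties at the k-th distance
    r[i] <- (sum(success[nb]) + 1) / (sum(nb) + 2)
  }
  r
}

#' Convert the success proportion into fdr2d values
#'
#' `fdr2d = pi0 * r / (M * (1 - r))`, clamped to `[0, 1]` (the local fdr
#' is a probability-scale quantity and `pi0` is its maximum).
#'
#' @param r Success proportions in (0, 1).
#' @param M Number of Monte-Carlo null samples used to build `r`.
#' @param pi0 Null proportion (default 1, the conservative maximum).
#' @return fdr2d values in `[0, 1]`.
#' @export
compute_fdr2d <- function(r, M = 100L, pi0 = 1) {
  stopifnot(M >= 1, pi0 > 0, pi0 <= 1)
  if (any(r <= 0 | r >= 1)) {
    stop("r must lie strictly inside (0, 1)", call. = FALSE)
  }
  pmin(pmax(pi0 * r / (M * (1 - r)), 0), 1)
}

#' Fit the fdr2d model to observed candidate statistics
#'
#' @param observed Tibble with `count` and `length_nt` columns (one row
#'   per candidate), or `z1`/`z2` directly.
#' @param null_pool Tibble with `count`/`length_nt` (or `z1`/`z2`) for the
#'   null circRNAs, e.g. from [read_null_table()].
#' @param M Number of Monte-Carlo null samples (default 100).
#' @param pi0 Null proportion (default 1).
#' @param k_nn Neighbourhood size for the smoother (default
#'   `ceiling(sqrt((M + 1) * n))`).
#' @param seed Optional RNG seed for the Monte-Carlo draw.
#' @return An object of class `fdr2d_fit` with the per-candidate `r` and
#'   `fdr2d` values; see [tidy.fdr2d_fit()] and [glance.fdr2d_fit()].
#' @export
fdr2d_fit <- function(observed, null_pool, M = 100L, pi0 = 1,
                      k_nn = NULL, seed = NULL) {
  as_z <- function(d) {
    if (all(c("z1", "z2") %in% names(d))) {
      tibble::tibble(z1 = d$z1, z2 = d$z2)
    } else {
      circ_statistics(d$count, d$length_nt)
    }
  }
  obs <- as_z(observed)
  null_z <- as_z(null_pool)
  ens <- sample_null(null_z, n = nrow(obs), M = M, seed = seed)
  r <- estimate_r(obs, ens, k_nn = k_nn)
  structure(
    list(observed = obs, r = r, fdr2d = compute_fdr2d(r, M = M, pi0 = pi0),
         M = as.integer(M), pi0 = pi0,
         k_nn = if (is.null(k_nn)) ceiling(sqrt((M + 1) * nrow(obs)))
                else as.integer(k_nn),
         n = nrow(obs), null_size = nrow(null_z), seed = seed),
    class = "fdr2d_fit"
  )
}

#' @export
print.fdr2d_fit <- function(x, ...) {
  cat("<fdr2d_fit> n = ", x$n, ", M = ", x$M, ", pi0 = ", x$pi0,
      ", k_nn = ", x$k_nn, "\n", sep = "")
  invisible(x)
}

#' Tidy an fdr2d fit
#'
#' @param x An `fdr2d_fit`.
#' @param ... Unused.
#' @return Tibble with `z1`, `z2`, `r`, `fdr2d` per candidate.
#' @export
tidy.fdr2d_fit <- function(x, ...) {
  dplyr::mutate(x$observed, r = x$r, fdr2d = x$fdr2d)
}

#' One-row summary of an fdr2d fit
#'
#' @param x An `fdr2d_fit`.
#' @param ... Unused.
#' @return One-row tibble with the fit dimensions and the median fdr2d.
#' @export
glance.fdr2d_fit <- function(x, ...) {
  tibble::tibble(n = x$n, M = x$M, pi0 = x$pi0, k_nn = x$k_nn,
                 null_size = x$null_size,
                 median_fdr2d = stats::median(x$fdr2d))
}

#' Score and rank circRNA candidates by fdr2d
#'
#' Attaches fdr2d values to a candidate table (using `n_support` as the
#' count statistic and `circ_length_nt` as the length statistic) and ranks
#' ascending by fdr2d, breaking ties by read count (descending), length
#' (descending), then `bsj_id`.
#'
#' @param candidates Candidate tibble with `n_support` and
#'   `circ_length_nt`.
#' @param null_pool Null statistics (see [fdr2d_fit()]).
#' @inheritParams fdr2d_fit
#' @return `candidates` with `fdr2d` and `rank` columns, sorted by rank;
#'   the fit is attached as attribute `fdr2d_fit`.
#' @export
score_candidates <- function(candidates, null_pool, M = 100L, pi0 = 1,
                             k_nn = NULL, seed = NULL) {
  if (nrow(candidates) == 0L) {
    return(dplyr::mutate(candidates, fdr2d = numeric(0), rank = integer(0)))
  }
  fit <- fdr2d_fit(
    tibble::tibble(count = candidates$n_support,
                   length_nt = candidates$circ_length_nt),
    null_pool, M = M, pi0 = pi0, k_nn = k_nn, seed = seed
  )
  out <- dplyr::mutate(candidates, fdr2d = fit$fdr2d)
  out <- rank_candidates(out)
  attr(out, "fdr2d_fit") <- fit
  out
}

#' Rank candidates by fdr2d
#'
#' @param candidates Tibble with `fdr2d`, `n_support`, `circ_length_nt`,
#'   `bsj_id`.
#' @return The tibble sorted by ascending fdr2d (ties: count desc, length
#'   desc, bsj_id), with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  out <- dplyr::arrange(candidates, .data$fdr2d,
                        dplyr::desc(.data$n_support),
                        dplyr::desc(.data$circ_length_nt), .data$bsj_id)
  dplyr::mutate(out, rank = dplyr::row_number())
}
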