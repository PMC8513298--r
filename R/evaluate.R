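# Evaluation against ground truth: precision, sensitivity, F1,
# true-discovery curves and RNase R enrichment counting.

#' F1 score from precision and sensitivity percentages
#'
#' `F1 = 2 * P * S / (P + S)` on the fractional scale; inputs are
#' percentages, the result is unitless in `[0, 1]`.
#'
#' @param precision_pct,sensitivity_pct Percentages in `[0, 100]`.
#' @return The F1 score.
#' @export
f1_score <- function(precision_pct, sensitivity_pct) {
  p <- precision_pct / 100
  s <- sensitivity_pct / 100
  ifelse(p + s == 0, 0, 2 * p * s / (p + s))
}

#' Score ranked candidates against a truth set
#'
#' A detected candidate is a true positive when its
#' (contig, acceptor_start, donor_end) triple matches a truth circle
#' exactly. Sensitivity is TP over the number of true circles, precision
#' TP over the number of detections (both in percent); the discovery
#' curve accumulates true positives along the ranking.
#'
#' @param candidates Ranked candidate tibble with `contig`,
#'   `acceptor_start`, `donor_end` (and optionally `rank`; row order is
#'   used otherwise).
#' @param truth Tibble of true circles with the same three columns.
#' @return An object of class `circ_eval`; see [glance.circ_eval()],
#'   [tidy.circ_eval()] and [autoplot.circ_eval()].
#' @export
evaluate_candidates <- function(candidates, truth) {
  if (nrow(truth) == 0L) stop("empty truth set", call. = FALSE)
  key <- function(d) paste(d$contig, d$acceptor_start, d$donor_end,
                           sep = ":")
  truth_keys <- unique(key(truth))
  cand <- candidates
  if ("rank" %in% names(cand)) cand <- dplyr::arrange(cand, .data$rank)
  is_tp <- key(cand) %in% truth_keys
  n_det <- nrow(cand)
  n_tp <- sum(is_tp)
  precision <- if (n_det == 0L) NA_real_ else 100 * n_tp / n_det
  sensitivity <- 100 * n_tp / length(truth_keys)
  curve <- tibble::tibble(rank = seq_len(n_det),
                          true_discoveries = cumsum(is_tp))
  structure(
    list(n_detected = n_det, n_true_positive = n_tp,
         n_false_positive = n_det - n_tp,
         n_truth = length(truth_keys),
         sensitivity = sensitivity, precision = precision,
         f1 = if (is.na(precision)) NA_real_
              else f1_score(precision, sensitivity),
         discovery_curve = curve, is_tp = is_tp),
    class = "circ_eval"
  )
}

#' @export
print.circ_eval <- function(x, ...) {
  cat("<circ_eval> detected ", x$n_detected, " (TP ", x$n_true_positive,
      ", FP ", x$n_false_positive, " of ", x$n_truth, " true)\n",
      "  sensitivity ", sprintf("%.2f%%", x$sensitivity),
      ", precision ", sprintf("%.2f%%", x$precision),
      ", F1 ", sprintf("%.4f", x$f1), "\n", sep = "")
  invisible(x)
}

#' One-row summary of an evaluation
#'
#' @param x A `circ_eval`.
#' @param ... Unused.
#' @return One-row tibble with counts, sensitivity/precision (percent)
#'   and F1.
#' @export
glance.circ_eval <- function(x, ...) {
  tibble::tibble(n_detected = x$n_detected,
                 n_true_positive = x$n_true_positive,
                 n_false_positive = x$n_false_positive,
                 n_truth = x$n_truth,
                 sensitivity = x$sensitivity, precision = x$precision,
                 f1 = x$f1)
}

#' True-discovery curve of an evaluation
#'
#' @param x A `circ_eval`.
#' @param ... Unused.
#' @return Tibble with `rank` and cumulative `true_discoveries`.
#' @export
tidy.circ_eval <- function(x, ...) {
  x$discovery_curve
}

#' Plot the true-discovery curve
#'
#' Rank of the candidate on the x axis, cumulative true discoveries on
#' the y axis; the grey diagonal marks a 100% true-discovery rate.
#'
#' @param object A `circ_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circ_eval <- function(object, ...) {
  plot_discovery_curves(list(candidates = object))
}

#' Compare true-discovery curves of several evaluations
#'
#' @param evals Named list of `circ_eval` objects.
#' @return A ggplot object.
#' @export
plot_discovery_curves <- function(evals) {
  curves <- dplyr::bind_rows(
    purrr::imap(evals, ~ dplyr::mutate(tidy(.x), method = .y))
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$rank, y = .data$true_discoveries,
                               colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "top-ranked candidates", y = "true discoveries",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Count RNase R-enriched circRNAs among the top candidates
#'
#' A candidate is significantly enriched when its library-size-normalised
#' expression in the RNase R+ sample is at least five-fold that in the
#' RNase R- sample (inclusive bound).
#'
#' @param candidates Ranked candidate tibble with `expr_minus` and
#'   `expr_plus` columns (normalised expression).
#' @param top_k How many top candidates to consider; values beyond the
#'   candidate count evaluate over all (noted in the attribute
#'   `evaluated_over`).
#' @param fold Enrichment threshold (default 5).
#' @return Integer count with attribute `evaluated_over`.
#' @export
enrichment_count <- function(candidates, top_k = 100L, fold = 5) {
  cand <- candidates
  if ("rank" %in% names(cand)) cand <- dplyr::arrange(cand, .data$rank)
  k <- min(top_k, nrow(cand))
  top <- cand[seq_len(k), , drop = FALSE]
  out <- sum(top$expr_plus >= fold * top$expr_minus)
  attr(out, "evaluated_over") <- k
  out
}
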