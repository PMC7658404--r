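#' Plot an FD-cutoff scan
#'
#' Training F-score and panel size across the scanned frequency-difference
#' cutoffs; the dashed line marks the winning cutoff.
#'
#' @param object An `reo_scan` tibble (the `scan` element of
#'   [fd_cutoff_scan()], also stored on trained signatures).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_scan <- function(object, ...) {
  best <- object$fd_cutoff[which.max(object$best_f_score)]
  long <- object |>
    dplyr::select("fd_cutoff", `F-score` = "best_f_score",
                  `panel size` = "panel_size") |>
    tidyr::pivot_longer(-"fd_cutoff", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fd_cutoff, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed") +
    ggplot2::facet_wrap(~quantity, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "FD cutoff", y = NULL,
                  title = "Vote-classifier performance across FD-cutoff panels") +
    ggplot2::theme_minimal()
}

#' Plot a gene-pair signature
#'
#' Frequency difference of each oriented pair, with the group-wise ordering
#' frequencies when available.
#'
#' @param object An `reo_signature`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_signature <- function(object, ...) {
  p <- object$pairs
  p$pair <- factor(paste(p$g_up, ">", p$g_down),
                   levels = paste(p$g_up, ">", p$g_down)[order(p$fd)])
  ggplot2::ggplot(p, ggplot2::aes(x = .data$fd, y = .data$pair)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::labs(
      x = "frequency difference (p1 - p2)", y = NULL,
      title = sprintf("%d-pair signature, positive call at >= %d votes",
                      nrow(p), object$k)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `reo_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reo_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "ROC of the vote-count classifier") +
    ggplot2::theme_minimal()
}

#' Plot vote-count distributions by class
#'
#' Histogram of signature votes per sample, split by the reference group, with
#' the decision threshold marked. A well-separated signature shows two
#' non-overlapping vote distributions.
#'
#' @param calls Output of [classify_samples()].
#' @param labels Reference labels (`sample_id`, `group`).
#' @param sig The signature used (for the threshold line); optional.
#' @return A ggplot object.
#' @export
plot_vote_distribution <- function(calls, labels, sig = NULL) {
  labels <- as_phenotype_labels(labels)
  x <- dplyr::inner_join(calls, labels, by = "sample_id")
  x$class <- factor(ifelse(x$group == 1L, "positive", "negative"),
                    levels = c("positive", "negative"))
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$votes, fill = .data$class)) +
    ggplot2::geom_histogram(binwidth = 1, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "votes for the positive class", y = "samples") +
    ggplot2::theme_minimal()
  if (!is.null(sig)) {
    p <- p + ggplot2::geom_vline(xintercept = sig$k - 0.5, linetype = "dashed")
  }
  p
}
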