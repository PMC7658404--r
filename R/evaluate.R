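#' Confusion counts of a two-group prediction
#'
#' Group 1 is the positive class. Inputs may be label tibbles
#' (`sample_id`, `group`/`predicted`) matched by sample, or two plain vectors
#' of equal length coded 1/2.
#'
#' @param pred Predicted labels: a tibble from [classify_samples()] (or with a
#'   `group` column), or a vector of 1/2.
#' @param truth Reference labels in the same form.
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  grab <- function(x, cols) {
    if (is.data.frame(x)) {
      col <- intersect(cols, names(x))[1L]
      if (is.na(col) || !"sample_id" %in% names(x)) {
        abort_data("Label tables need `sample_id` plus a group/predicted column.")
      }
      tibble(sample_id = as.character(x$sample_id), group = as.integer(x[[col]]))
    } else {
      tibble(sample_id = NA_character_, group = as.integer(x))
    }
  }
  p <- grab(pred, c("predicted", "group"))
  t <- grab(truth, c("group", "predicted"))
  if (is.data.frame(pred) && is.data.frame(truth)) {
    if (!setequal(p$sample_id, t$sample_id)) {
      abort_data("Predicted and reference labels must cover the same samples.")
    }
    t <- t[match(p$sample_id, t$sample_id), ]
  } else if (length(p$group) != length(t$group)) {
    abort_data("Predicted and reference labels must have the same length.")
  }
  if (!all(p$group %in% c(1L, 2L)) || !all(t$group %in% c(1L, 2L))) {
    abort_data("Labels must be coded 1 (positive) / 2 (negative).")
  }
  tibble(
    tp = sum(p$group == 1L & t$group == 1L),
    fp = sum(p$group == 1L & t$group == 2L),
    fn = sum(p$group == 2L & t$group == 1L),
    tn = sum(p$group == 2L & t$group == 2L)
  )
}

#' Sensitivity, specificity and their harmonic mean from confusion counts
#'
#' @param counts A one-row tibble or list with `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble `sensitivity`, `specificity`, `f`.
#' @examples
#' metrics_from_confusion(tibble::tibble(tp = 58, fp = 12, fn = 6, tn = 105))
#' @export
metrics_from_confusion <- function(counts) {
  need <- c("tp", "fp", "fn", "tn")
  if (!all(need %in% names(counts))) {
    abort_data("Confusion counts need tp, fp, fn, tn.")
  }
  tp <- counts$tp[1L]; fp <- counts$fp[1L]; fn <- counts$fn[1L]; tn <- counts$tn[1L]
  vals <- c(tp, fp, fn, tn)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    abort_data("Confusion counts must be non-negative integers.")
  }
  if (tp + fn == 0 || tn + fp == 0) {
    abort_data("Both classes must be present to compute sensitivity and specificity.")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble(sensitivity = sens, specificity = spec, f = f_score(sens, spec))
}

auc_stat <- function(scores, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  r <- rank(scores) # average ranks implement the half-credit tie convention
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC area under the curve with a stratified bootstrap interval
#'
#' AUC is the probability that a random positive sample outscores a random
#' negative one, with ties credited one half — computed by the rank
#' (Mann-Whitney) identity, which sweeps all thresholds at once. Vote counts
#' are small integers, so ties are common and the half-credit convention
#' matters. The confidence interval is percentile-based over stratified
#' bootstrap resamples (positives and negatives resampled separately).
#'
#' @param scores Numeric scores (e.g. vote counts), or a tibble with
#'   `sample_id` and a `votes` column.
#' @param truth Reference labels: vector of 1/2 aligned with `scores`, or a
#'   labels tibble matched by `sample_id`.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf_level Interval coverage (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return A one-row tibble `auc`, `ci_lower`, `ci_upper`, `n_boot`.
#' @export
roc_auc <- function(scores, truth, n_boot = 2000L, conf_level = 0.95, seed = 1L) {
  if (is.data.frame(scores)) {
    truth <- as_phenotype_labels(truth)
    x <- dplyr::inner_join(scores, truth, by = "sample_id")
    s <- x$votes
    g <- x$group
  } else {
    s <- as.numeric(scores)
    g <- if (is.data.frame(truth)) as_phenotype_labels(truth)$group else as.integer(truth)
  }
  if (length(s) != length(g)) {
    abort_data("Scores and labels must cover the same samples.")
  }
  is_pos <- g == 1L
  if (!any(is_pos) || all(is_pos)) {
    abort_data("Both classes must be present to compute an AUC.")
  }
  auc <- auc_stat(s, is_pos)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    sp <- s[is_pos]
    sn <- s[!is_pos]
    boots <- with_rng(seed, {
      vapply(seq_len(n_boot), function(i) {
        bs <- c(sample(sp, length(sp), replace = TRUE),
                sample(sn, length(sn), replace = TRUE))
        auc_stat(bs, c(rep(TRUE, length(sp)), rep(FALSE, length(sn))))
      }, numeric(1L))
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  tibble(auc = auc, ci_lower = ci[1L], ci_upper = ci[2L], n_boot = as.integer(n_boot))
}

#' ROC curve points for a score-based classifier
#'
#' One row per distinct threshold of the rule "positive iff score >= t",
#' including the degenerate all-positive and all-negative rules.
#'
#' @inheritParams roc_auc
#' @return A tibble `threshold`, `tpr`, `fpr` with class `reo_roc`, ordered by
#'   decreasing threshold (fpr increasing).
#' @export
roc_curve <- function(scores, truth) {
  if (is.data.frame(scores)) {
    truth <- as_phenotype_labels(truth)
    x <- dplyr::inner_join(scores, truth, by = "sample_id")
    s <- x$votes
    g <- x$group
  } else {
    s <- as.numeric(scores)
    g <- if (is.data.frame(truth)) as_phenotype_labels(truth)$group else as.integer(truth)
  }
  is_pos <- g == 1L
  if (!any(is_pos) || all(is_pos)) {
    abort_data("Both classes must be present to compute a ROC curve.")
  }
  th <- c(sort(unique(s), decreasing = TRUE), -Inf)
  out <- tibble(
    threshold = c(Inf, th),
    tpr = c(0, vapply(th, function(t) mean(s[is_pos] >= t), numeric(1L))),
    fpr = c(0, vapply(th, function(t) mean(s[!is_pos] >= t), numeric(1L)))
  )
  class(out) <- c("reo_roc", class(out))
  out
}

#' Concordance between unsupervised clustering and signature calls
#'
#' Selects the `top_n` most differential genes between two reference sample
#' sets (Welch test p-value, ascending), clusters **all** samples by
#' complete-linkage hierarchical clustering on Euclidean distances, cuts the
#' tree into two clusters, maps each cluster to a class by the majority of
#' the reference samples it contains, and reports the fraction of
#' non-reference (disputed) samples that land in the cluster of their
#' predicted class.
#'
#' @param expr Expression tibble covering reference and disputed samples.
#' @param labels Predicted class per sample (`sample_id`, `group`).
#' @param ref_pos,ref_neg Disjoint, non-empty reference sample id sets
#'   (e.g. the signature-confirmed positives and negatives).
#' @param top_n Number of differential genes used for the distance
#'   (default 100).
#' @return A list with `assignments` (tibble `sample_id`, `cluster`,
#'   `cluster_class`, `group`, `is_reference`), `agreement` (fraction of
#'   disputed samples in their predicted class's cluster; `NaN` when there are
#'   none) and `ambiguous` (`TRUE` when a cluster had no reference majority,
#'   in which case `agreement` is `NA`).
#' @export
cluster_concordance <- function(expr, labels, ref_pos, ref_neg, top_n = 100L) {
  m <- expr_matrix(expr)
  labels <- check_labels(m, labels)
  ref_pos <- as.character(ref_pos)
  ref_neg <- as.character(ref_neg)
  if (length(intersect(ref_pos, ref_neg))) {
    abort_data("Reference sets must be disjoint.")
  }
  if (!length(ref_pos) || !length(ref_neg)) {
    abort_data("Both reference sets must be non-empty.")
  }
  missing <- setdiff(c(ref_pos, ref_neg), colnames(m))
  if (length(missing)) {
    abort_data(sprintf("Reference samples absent from the expression table: %s", fmt_ids(missing)))
  }
  if (top_n > nrow(m)) {
    abort_data("`top_n` exceeds the number of genes.")
  }
  i1 <- match(ref_pos, colnames(m))
  i2 <- match(ref_neg, colnames(m))
  if (length(i1) >= 2L && length(i2) >= 2L) {
    res <- row_welch_t(m, i1, i2)
    top <- res |>
      dplyr::arrange(.data$p_value, .data$gene_id) |>
      dplyr::slice_head(n = as.integer(top_n))
    sub <- m[top$gene_id, , drop = FALSE]
  } else {
    # too few reference samples for a test: use all genes
    sub <- m
  }
  hc <- stats::hclust(stats::dist(t(sub), method = "euclidean"), method = "complete")
  cl <- stats::cutree(hc, k = min(2L, ncol(sub)))

  ref_class <- setNames(rep(NA_integer_, ncol(m)), colnames(m))
  ref_class[ref_pos] <- 1L
  ref_class[ref_neg] <- 2L
  cluster_class <- vapply(sort(unique(cl)), function(k) {
    members <- ref_class[names(cl)[cl == k]]
    n1 <- sum(members == 1L, na.rm = TRUE)
    n2 <- sum(members == 2L, na.rm = TRUE)
    if (n1 == n2) NA_integer_ else if (n1 > n2) 1L else 2L
  }, integer(1L))
  ambiguous <- anyNA(cluster_class) ||
    length(unique(cluster_class)) < length(cluster_class)
  if (ambiguous) {
    rlang::warn("Cluster-to-class mapping is ambiguous (no clear reference majority).")
  }
  assignments <- tibble(
    sample_id = names(cl),
    cluster = unname(cl),
    cluster_class = unname(cluster_class[cl]),
    group = labels$group[match(names(cl), labels$sample_id)],
    is_reference = names(cl) %in% c(ref_pos, ref_neg)
  )
  disputed <- assignments[!assignments$is_reference & !is.na(assignments$group), ]
  agreement <- if (ambiguous) {
    NA_real_
  } else if (nrow(disputed) == 0L) {
    NaN
  } else {
    mean(disputed$cluster_class == disputed$group)
  }
  list(assignments = assignments, agreement = agreement, ambiguous = ambiguous)
}

#' Differential methylation screen on beta values
#'
#' Per-site Welch test on the beta values between the two groups, at an
#' unadjusted p-value threshold (promoter-hypermethylation screens are
#' conventionally reported at raw `P < 0.05`; pass [bh_adjust()]ed output
#' through your own threshold if FDR control is wanted). Sites below the
#' threshold are split by sign: `hyper` = higher mean beta in group 1.
#'
#' @param meth A [methylation_data()] object or a site-by-sample beta matrix.
#' @param labels Phenotype labels (>= 2 samples per group).
#' @param p_threshold Unadjusted p-value threshold (default 0.05).
#' @return A tibble `site_id`, `mean_pos`, `mean_neg`, `delta`, `p_value`,
#'   `direction` (`"hyper"`, `"hypo"` or `"ns"`).
#' @export
diff_methylation <- function(meth, labels, p_threshold = 0.05) {
  beta <- if (inherits(meth, "methylation_data")) meth$beta else as.matrix(meth)
  if (is.null(rownames(beta))) {
    abort_data("Beta matrix needs site identifiers as rownames.")
  }
  labels <- check_labels(matrix_expr(beta), labels, min_per_group = 2L)
  i1 <- match(labels$sample_id[labels$group == 1L], colnames(beta))
  i2 <- match(labels$sample_id[labels$group == 2L], colnames(beta))
  res <- row_welch_t(beta, i1, i2)
  tibble(
    site_id = res$gene_id,
    mean_pos = res$mean_1,
    mean_neg = res$mean_2,
    delta = res$mean_1 - res$mean_2,
    p_value = res$p_value,
    direction = dplyr::case_when(
      res$p_value < p_threshold & res$mean_1 > res$mean_2 ~ "hyper",
      res$p_value < p_threshold & res$mean_1 < res$mean_2 ~ "hypo",
      TRUE ~ "ns"
    )
  )
}

#' Hypergeometric overlap enrichment test
#'
#' Upper-tail probability `P(X >= |A intersect B|)` of drawing at least the
#' observed overlap when `|A|` items are drawn without replacement from a
#' universe of size `N` containing `|B|` successes.
#'
#' @param set_a,set_b Identifier vectors, subsets of `universe`.
#' @param universe Identifier vector defining the sampling frame.
#' @return The enrichment p-value.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    abort_data("Both sets must be subsets of the universe.")
  }
  k <- length(intersect(set_a, set_b))
  stats::phyper(k - 1, length(set_b), length(universe) - length(set_b),
                length(set_a), lower.tail = FALSE)
}
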