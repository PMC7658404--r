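#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, capped
#' at 1 and mapped back to the input order (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03)) # all 0.03
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) {
    abort_data("p-values must be numeric.")
  }
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort_data("p-values must lie in [0, 1] with no missing values.")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Vectorised Welch two-sample t-test across matrix rows.
row_welch_t <- function(m, idx1, idx2) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # zero variance in both groups: p = 1 for zero difference, ~0 otherwise
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  tibble(gene_id = rownames(m), statistic = unname(tt), df = unname(df),
         p_value = unname(p), mean_1 = unname(m1), mean_2 = unname(m2))
}

# Pooled-variance t with the per-gene variance shrunk toward the mean variance
# using a fixed prior weight d0 (degrees of freedom d0 + d).
row_moderated_t <- function(m, idx1, idx2, d0 = 4) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  x1 <- m[, idx1, drop = FALSE]
  x2 <- m[, idx2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  d <- n1 + n2 - 2
  v_pool <- (rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)) / d
  v_bar <- mean(v_pool)
  v_mod <- (d0 * v_bar + d * v_pool) / (d0 + d)
  se <- sqrt(v_mod * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  df <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  tibble(gene_id = rownames(m), statistic = unname(tt), df = df,
         p_value = unname(p), mean_1 = unname(m1), mean_2 = unname(m2))
}

row_test <- function(m, idx1, idx2, method = c("welch_t", "moderated_t"), d0 = 4) {
  method <- match.arg(method)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    abort_data("Each group needs at least 2 samples for a differential test.")
  }
  switch(method,
    welch_t = row_welch_t(m, idx1, idx2),
    moderated_t = row_moderated_t(m, idx1, idx2, d0 = d0)
  )
}

#' Screen for differentially expressed genes between two groups
#'
#' Per-gene two-sample test (Welch's t by default, or a pooled-variance
#' moderated variant that shrinks each gene's variance toward the mean
#' variance with prior weight `d0 = 4`), followed by Benjamini-Hochberg
#' adjustment. The screen only gates the gene-pair search space; downstream
#' ordering statistics do not depend on the expression scale.
#'
#' @param expr Expression tibble.
#' @param labels Phenotype labels (`sample_id`, `group`), both groups with at
#'   least 2 samples.
#' @param alpha FDR threshold; genes with adjusted p below it are returned.
#' @param method `"welch_t"` (default) or `"moderated_t"`.
#' @param log2 Apply `log2()` to the values before testing (default `TRUE`;
#'   set to `FALSE` for data already on a log scale). No autodetection is
#'   attempted; values must be strictly positive when `log2 = TRUE`.
#' @param d0 Prior degrees of freedom for the moderated variant.
#' @return A tibble `gene_id`, `p_value`, `fdr` of genes passing `alpha`,
#'   sorted by p ascending with ties broken by gene id.
#' @export
de_screen <- function(expr, labels, alpha = 0.01,
                      method = c("welch_t", "moderated_t"), log2 = TRUE, d0 = 4) {
  method <- match.arg(method)
  m <- expr_matrix(expr)
  labels <- check_labels(m, labels, min_per_group = 2L)
  if (isTRUE(log2)) {
    if (any(m <= 0)) {
      abort_data("log2 = TRUE requires strictly positive values; set log2 = FALSE for data already on a log scale.")
    }
    m <- log2(m)
  }
  idx1 <- match(labels$sample_id[labels$group == 1L], colnames(m))
  idx2 <- match(labels$sample_id[labels$group == 2L], colnames(m))
  res <- row_test(m, idx1, idx2, method = method, d0 = d0)
  res$fdr <- bh_adjust(res$p_value)
  res |>
    dplyr::filter(.data$fdr < alpha) |>
    dplyr::arrange(.data$p_value, .data$gene_id) |>
    dplyr::select("gene_id", "p_value", "fdr")
}
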