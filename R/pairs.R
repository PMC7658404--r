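#' Relative-expression-ordering frequencies of a gene pair
#'
#' For genes i and j, computes `p_c = P(E_i > E_j | group c)` as the fraction
#' of samples in each group where gene i exceeds gene j. Ties (`E_i == E_j`)
#' count against the pattern — the ordering event is defined by strict
#' inequality. Also returns the 2x2 group-by-ordering count table used by the
#' exact test.
#'
#' @param expr Expression tibble.
#' @param gene_i,gene_j Gene identifiers (pattern tested: `E_i > E_j`).
#' @param labels Phenotype labels.
#' @return A list with `p1`, `p2` and `table`, the 2x2 integer matrix
#'   `rbind(c(a, n1 - a), c(b, n2 - b))` where `a`, `b` count samples with
#'   `E_i > E_j` per group.
#' @export
reo_frequencies <- function(expr, gene_i, gene_j, labels) {
  m <- expr_matrix(expr)
  labels <- check_labels(m, labels)
  for (g in c(gene_i, gene_j)) {
    if (!g %in% rownames(m)) {
      abort_data(sprintf("Gene '%s' is absent from the expression table.", g))
    }
  }
  xi <- m[gene_i, labels$sample_id]
  xj <- m[gene_j, labels$sample_id]
  gt <- xi > xj
  n1 <- sum(labels$group == 1L)
  n2 <- sum(labels$group == 2L)
  a <- sum(gt[labels$group == 1L])
  b <- sum(gt[labels$group == 2L])
  tab <- matrix(as.integer(c(a, n1 - a, b, n2 - b)), nrow = 2L, byrow = TRUE,
                dimnames = list(c("group1", "group2"), c("i_gt_j", "not")))
  list(p1 = a / n1, p2 = b / n2, table = tab)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (the convention of [stats::fisher.test()], to which this
#' delegates).
#'
#' @param table 2x2 matrix of non-negative integer counts; both row sums must
#'   be positive.
#' @return The two-sided p-value.
#' @examples
#' fisher_pair_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)) # 2 / choose(20, 10)
#' @export
fisher_pair_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) {
    abort_data("`table` must be a 2x2 matrix of counts.")
  }
  if (anyNA(table) || any(table < 0) || any(table != round(table))) {
    abort_data("Counts must be non-negative integers.")
  }
  if (any(rowSums(table) == 0)) {
    abort_data("Both groups must contain at least one sample (positive row sums).")
  }
  min(stats::fisher.test(table)$p.value, 1) # tail summation can overshoot 1 by eps
}

# Fisher p-values for count pairs (a, b) at fixed group sizes, memoised over
# the distinct (a, b) actually observed.
fisher_p_lookup <- function(a, b, n1, n2) {
  key <- a * (n2 + 1) + b
  uk <- unique(key)
  ua <- uk %/% (n2 + 1)
  ub <- uk %% (n2 + 1)
  up <- vapply(seq_along(uk), function(r) {
    min(stats::fisher.test(matrix(c(ua[r], n1 - ua[r], ub[r], n2 - ub[r]),
                                  nrow = 2L, byrow = TRUE))$p.value, 1)
  }, numeric(1L))
  up[match(key, uk)]
}

# Ordering counts for many pairs at once: for row indices ii, jj of m, counts
# of E_i > E_j and of ties within the given sample columns, chunked to bound
# memory.
pair_order_counts <- function(m, ii, jj, cols, chunk_size = 100000L) {
  n <- length(ii)
  gt <- integer(n)
  eq <- integer(n)
  start <- 1L
  while (start <= n) {
    end <- min(start + chunk_size - 1L, n)
    idx <- start:end
    d <- m[ii[idx], cols, drop = FALSE] - m[jj[idx], cols, drop = FALSE]
    gt[idx] <- as.integer(rowSums(d > 0))
    eq[idx] <- as.integer(rowSums(d == 0))
    start <- end + 1L
  }
  list(gt = gt, eq = eq)
}

#' Screen gene pairs for phenotype-associated ordering reversals
#'
#' Enumerates candidate pairs (by default every pair with at least one member
#' in `de_genes`), computes the group-wise ordering frequencies
#' `p_c = P(E_up > E_down | c)`, tests each 2x2 ordering-by-group table with
#' a two-sided Fisher's exact test, adjusts across **all** tested pairs by
#' Benjamini-Hochberg, and keeps pairs with FDR below `alpha`. Each retained
#' pair is oriented so that the pattern `E_up > E_down` is the one more
#' frequent in the positive group, hence `fd = p1 - p2 > 0`.
#'
#' The whole screen depends on the data only through within-sample orderings,
#' so it is invariant to any strictly increasing per-sample transform.
#'
#' @param expr Expression tibble.
#' @param labels Phenotype labels.
#' @param de_genes Character vector anchoring the pair space (typically from
#'   [de_screen()]); must be non-empty and a subset of the expression genes.
#' @param alpha FDR threshold for retaining pairs (default 0.01).
#' @param pair_space `"de_by_all"` (default; at least one member differential)
#'   or `"de_by_de"` (both members differential).
#' @param chunk_size Pairs per block when computing ordering counts.
#' @return A tibble `g_up`, `g_down`, `p1`, `p2`, `fd`, `p_value`, `fdr`
#'   sorted by `fd` descending, then p ascending, then pair ids.
#' @export
screen_pairs <- function(expr, labels, de_genes, alpha = 0.01,
                         pair_space = c("de_by_all", "de_by_de"),
                         chunk_size = 100000L) {
  pair_space <- match.arg(pair_space)
  m <- expr_matrix(expr)
  labels <- check_labels(m, labels)
  genes <- rownames(m)
  de_genes <- unique(as.character(de_genes))
  if (length(de_genes) == 0L) {
    abort_data("`de_genes` is empty: no pair space to screen. Loosen the differential-expression threshold.")
  }
  missing <- setdiff(de_genes, genes)
  if (length(missing)) {
    abort_data(sprintf("de_genes absent from the expression table: %s", fmt_ids(missing)))
  }

  # candidate pair index sets; enumeration order is immaterial (final sort is
  # deterministic), membership is not
  de_idx <- sort(match(de_genes, genes))
  ii <- integer(0)
  jj <- integer(0)
  if (length(de_idx) >= 2L) {
    d <- length(de_idx)
    ii <- rep(de_idx[-d], times = (d - 1L):1L)
    jj <- de_idx[unlist(lapply(2:d, function(k) k:d), use.names = FALSE)]
  }
  if (pair_space == "de_by_all") {
    other <- setdiff(seq_along(genes), de_idx)
    if (length(other)) {
      ii <- c(ii, rep(de_idx, each = length(other)))
      jj <- c(jj, rep(other, times = length(de_idx)))
    }
  }
  if (length(ii) == 0L) {
    abort_data("The pair space is empty; need at least two genes.")
  }

  pos <- match(labels$sample_id[labels$group == 1L], colnames(m))
  neg <- match(labels$sample_id[labels$group == 2L], colnames(m))
  n1 <- length(pos)
  n2 <- length(neg)

  cp <- pair_order_counts(m, ii, jj, pos, chunk_size)
  cn <- pair_order_counts(m, ii, jj, neg, chunk_size)
  p <- fisher_p_lookup(cp$gt, cn$gt, n1, n2)
  fdr <- bh_adjust(p)

  keep <- fdr < alpha
  if (!any(keep)) {
    return(tibble(g_up = character(), g_down = character(), p1 = double(),
                  p2 = double(), fd = double(), p_value = double(), fdr = double()))
  }
  ii <- ii[keep]; jj <- jj[keep]
  a <- cp$gt[keep]; b <- cn$gt[keep]
  t1 <- cp$eq[keep]; t2 <- cn$eq[keep]
  p <- p[keep]; fdr <- fdr[keep]

  p1 <- a / n1
  p2 <- b / n2
  flip <- p1 < p2
  # reversed pattern E_j > E_i: ties count against it too
  p1_f <- (n1 - a - t1) / n1
  p2_f <- (n2 - b - t2) / n2
  out <- tibble(
    g_up = ifelse(flip, genes[jj], genes[ii]),
    g_down = ifelse(flip, genes[ii], genes[jj]),
    p1 = ifelse(flip, p1_f, p1),
    p2 = ifelse(flip, p2_f, p2),
    p_value = p,
    fdr = fdr
  )
  out$fd <- out$p1 - out$p2
  out |>
    dplyr::filter(.data$fd > 0) |>
    dplyr::arrange(dplyr::desc(.data$fd), .data$p_value, .data$g_up, .data$g_down) |>
    dplyr::select("g_up", "g_down", "p1", "p2", "fd", "p_value", "fdr")
}
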