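test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))

  set.seed(42)
  for (i in 1:10) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }

  # order equivariance
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])

  expect_error(bh_adjust(c(0.5, 1.2)), class = "reopairs_data_error")
  expect_error(bh_adjust(c(0.5, NA)), class = "reopairs_data_error")
})

test_that("differential screen controls false positives and detects shifted genes", {
  # null cohorts: both groups from the same distribution
  false_hits <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    m <- matrix(rnorm(2000 * 20), nrow = 2000,
                dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:20)))
    labels <- make_labels(colnames(m), rep(1:2, each = 10))
    nrow(de_screen(tiny_expr(m), labels, alpha = 0.01, log2 = FALSE))
  })
  expect_lte(mean(false_hits), 1)

  # 50 genes shifted by 3 SD, n = 30 + 30: all detected by both tests
  set.seed(5)
  m <- matrix(rnorm(500 * 60), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:60)))
  m[1:50, 1:30] <- m[1:50, 1:30] + 3
  expr <- tiny_expr(m)
  labels <- make_labels(colnames(m), rep(1:2, each = 30))
  for (method in c("welch_t", "moderated_t")) {
    de <- de_screen(expr, labels, alpha = 0.01, method = method, log2 = FALSE)
    expect_true(all(sprintf("g%03d", 1:50) %in% de$gene_id))
    expect_true(all(de$fdr < 0.01))
    expect_equal(de$p_value, sort(de$p_value))
  }

  # zero effect is never selected
  flat <- tiny_expr(matrix(5, nrow = 1, ncol = 8))
  flat_labels <- make_labels(colnames(flat)[-1], rep(1:2, each = 4))
  expect_identical(nrow(de_screen(flat, flat_labels, log2 = FALSE)), 0L)

  expect_error(de_screen(expr, make_labels(colnames(m)[1:3], c(1, 2, 2)), log2 = FALSE),
               class = "reopairs_data_error")
  expect_error(de_screen(tiny_expr(matrix(c(-1, 1, 2, 3), 2)),
                         make_labels(c("s01", "s02"), 1:2), log2 = TRUE),
               class = "reopairs_data_error")
})

test_that("differential screens agree with reference implementations", {
  set.seed(9)
  m <- matrix(rnorm(200 * 24), nrow = 200,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:24)))
  m[1:20, 1:12] <- m[1:20, 1:12] + 3
  expr <- tiny_expr(m)
  labels <- make_labels(colnames(m), rep(1:2, each = 12))

  # Welch p-values equal stats::t.test gene by gene (alpha above 1 keeps all)
  de <- de_screen(expr, labels, alpha = 1.1, log2 = FALSE)
  for (g in sample(rownames(m), 20)) {
    ref <- t.test(m[g, 1:12], m[g, 13:24])$p.value
    expect_equal(de$p_value[de$gene_id == g], ref)
  }

  # the moderated variant and limma find exactly the planted genes
  de_mod <- de_screen(expr, labels, alpha = 0.01, method = "moderated_t", log2 = FALSE)
  design <- cbind(1, rep(c(1, 0), each = 12))
  fit <- limma::eBayes(limma::lmFit(m, design))
  lp <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  limma_hits <- rownames(lp)[p.adjust(lp$P.Value, "BH") < 0.01]
  planted <- sprintf("g%03d", 1:20)
  expect_setequal(de_mod$gene_id, planted)
  expect_setequal(limma_hits, planted)
})

test_that("ordering frequencies count strict inequalities per group", {
  # group 1 orderings (>, >, <); group 2 (<, <, <, >)
  gi <- c(2, 3, 1, 0, 0, 0, 5)
  gj <- c(1, 1, 4, 2, 2, 2, 3)
  expr <- tiny_expr(rbind(gi, gj), genes = c("gi", "gj"))
  labels <- make_labels(colnames(expr)[-1], c(1, 1, 1, 2, 2, 2, 2))
  fr <- reo_frequencies(expr, "gi", "gj", labels)
  expect_equal(fr$p1, 2 / 3)
  expect_equal(fr$p2, 1 / 4)
  expect_identical(fr$table, matrix(c(2L, 1L, 1L, 3L), nrow = 2, byrow = TRUE,
                                    dimnames = dimnames(fr$table)))

  # ties count against the pattern
  tied <- tiny_expr(rbind(rep(1, 6), rep(1, 6)), genes = c("a", "b"))
  tl <- make_labels(colnames(tied)[-1], rep(1:2, each = 3))
  tf <- reo_frequencies(tied, "a", "b", tl)
  expect_equal(tf$p1, 0)
  expect_equal(tf$p2, 0)

  # loop oracle on a random 40-sample cohort
  set.seed(21)
  m <- matrix(rnorm(10 * 40), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:40)))
  labels40 <- make_labels(colnames(m), rep(1:2, times = c(15, 25)))
  for (i in 1:5) {
    pick <- sample(rownames(m), 2)
    fr <- reo_frequencies(tiny_expr(m), pick[1], pick[2], labels40)
    won <- sapply(labels40$sample_id, function(s) m[pick[1], s] > m[pick[2], s])
    expect_equal(fr$p1, mean(won[labels40$group == 1L]))
    expect_equal(fr$p2, mean(won[labels40$group == 2L]))
  }

  expect_error(reo_frequencies(tied, "a", "zz", tl), "zz",
               class = "reopairs_data_error")
})

test_that("the pair exact test matches hypergeometric enumeration", {
  expect_equal(fisher_pair_test(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)),
               2 / choose(20, 10))
  expect_equal(fisher_pair_test(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)), 1)

  set.seed(13)
  for (i in 1:30) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0)) next
    expect_equal(fisher_pair_test(tab),
                 oracle_fisher_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
  }

  expect_error(fisher_pair_test(matrix(c(-1, 2, 3, 4), 2)), class = "reopairs_data_error")
  expect_error(fisher_pair_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "reopairs_data_error")
  expect_error(fisher_pair_test(matrix(c(0.5, 1, 3, 4), 2)), class = "reopairs_data_error")
})

test_that("pair screening retains planted reversals, oriented positively", {
  cfg <- synthetic_config(seed = 1L)
  coh <- generate_cohort(cfg)
  de <- de_screen(coh$expr, coh$labels, alpha = 0.01, log2 = FALSE)
  cand <- screen_pairs(coh$expr, coh$labels, de$gene_id, alpha = 0.01)

  expect_true(all(cand$fd > 0))
  expect_true(all(cand$p1 > cand$p2))
  expect_true(all(cand$fdr < 0.01))
  # sorted by fd desc, then p, then ids
  expect_equal(order(-cand$fd, cand$p_value, cand$g_up, cand$g_down), seq_len(nrow(cand)))

  truth <- coh$truth$planted_pairs
  hit <- dplyr::inner_join(cand, truth, by = c("g_up", "g_down"))
  expect_gte(nrow(hit), 27)
  # per-pair fd is binomial around the planted 0.90
  expect_lte(abs(mean(hit$fd) - 0.90), 0.08)
  expect_true(all(abs(hit$fd - 0.90) <= 0.15))

  expect_error(screen_pairs(coh$expr, coh$labels, character(0)),
               "threshold", class = "reopairs_data_error")
})

test_that("a pair ordered identically in both groups is never retained", {
  # gA > gB in every sample of both groups: fd = 0, p = 1
  m <- rbind(gA = seq(2, 3, length.out = 12), gB = seq(1, 1.5, length.out = 12))
  expr <- tiny_expr(m, genes = c("gA", "gB"))
  labels <- make_labels(colnames(expr)[-1], rep(1:2, each = 6))
  out <- screen_pairs(expr, labels, de_genes = "gA", alpha = 0.5)
  expect_identical(nrow(out), 0L)
})

test_that("pair screening is invariant to row/column order and label swap", {
  cfg <- small_config(seed = 3L)
  coh <- generate_cohort(cfg)
  de_genes <- unique(c(coh$truth$planted_pairs$g_up, coh$truth$planted_pairs$g_down))
  base <- screen_pairs(coh$expr, coh$labels, de_genes, alpha = 0.01)
  expect_gt(nrow(base), 0)

  set.seed(8)
  shuf <- coh$expr[sample(nrow(coh$expr)), c(1, 1 + sample(ncol(coh$expr) - 1))]
  expect_equal(screen_pairs(shuf, coh$labels[sample(nrow(coh$labels)), ],
                            de_genes, alpha = 0.01), base)

  swapped <- coh$labels
  swapped$group <- 3L - swapped$group
  flipped <- screen_pairs(coh$expr, swapped, de_genes, alpha = 0.01)
  # same unordered pair set, flipped orientation, same fd and p-value
  expect_setequal(paste(flipped$g_up, flipped$g_down),
                  paste(base$g_down, base$g_up))
  merged <- dplyr::inner_join(base, flipped,
                              by = c(g_up = "g_down", g_down = "g_up"))
  expect_equal(merged$fd.x, merged$fd.y)
  expect_equal(merged$p_value.x, merged$p_value.y)
})

test_that("per-sample monotone transforms leave the screen unchanged", {
  cfg <- small_config(seed = 4L)
  coh <- generate_cohort(cfg)
  de_genes <- unique(c(coh$truth$planted_pairs$g_up, coh$truth$planted_pairs$g_down))
  base <- screen_pairs(coh$expr, coh$labels, de_genes, alpha = 0.01)
  for (family in c("affine_pos", "exp", "rank")) {
    corrupted <- corrupt_monotone(coh$expr, family = family, seed = 99L)
    expect_identical(screen_pairs(corrupted, coh$labels, de_genes, alpha = 0.01),
                     base)
  }
})
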