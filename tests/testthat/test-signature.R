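test_that("redundancy removal keeps the best pair per gene", {
  pairs <- tibble::tibble(
    g_up = c("A", "A", "D"), g_down = c("B", "C", "E"),
    fd = c(0.9, 0.8, 0.7)
  )
  out <- remove_redundant_pairs(pairs)
  expect_identical(paste(out$g_up, out$g_down), c("A B", "D E"))

  chain <- tibble::tibble(
    g_up = c("A", "B", "C"), g_down = c("B", "C", "D"),
    fd = c(0.9, 0.85, 0.8)
  )
  out <- remove_redundant_pairs(chain)
  expect_identical(paste(out$g_up, out$g_down), c("A B", "C D"))

  expect_identical(nrow(remove_redundant_pairs(pairs[0, ])), 0L)
})

test_that("redundancy removal matches an independent greedy oracle", {
  set.seed(17)
  genes <- sprintf("G%02d", 1:50)
  for (i in 1:5) {
    up <- sample(genes, 200, replace = TRUE)
    down <- sample(genes, 200, replace = TRUE)
    keep <- up != down
    pairs <- tibble::tibble(g_up = up[keep], g_down = down[keep],
                            fd = round(runif(sum(keep)), 2),
                            p_value = runif(sum(keep))) |>
      dplyr::distinct(g_up, g_down, .keep_all = TRUE)
    out <- remove_redundant_pairs(pairs)
    oracle <- oracle_greedy_removal(pairs)
    expect_equal(out, oracle)
    expect_false(anyDuplicated(c(out$g_up, out$g_down)) > 0)
    # result is a function of the set, not the row order
    expect_equal(remove_redundant_pairs(pairs[sample(nrow(pairs)), ]), out)
  }
})

test_that("vote counting is a strict-inequality tally", {
  pairs <- tibble::tibble(g_up = c("a", "c"), g_down = c("b", "d"))
  all_win <- tiny_expr(matrix(c(2, 1, 5, 4), ncol = 1),
                       genes = c("a", "b", "c", "d"), samples = "s1")
  expect_identical(count_votes(all_win, pairs)$votes, 2L)

  all_tie <- tiny_expr(matrix(c(3, 3, 7, 7), ncol = 1),
                       genes = c("a", "b", "c", "d"), samples = "s1")
  expect_identical(count_votes(all_tie, pairs)$votes, 0L)

  set.seed(2)
  m <- matrix(rnorm(8 * 12), nrow = 8,
              dimnames = list(letters[1:8], sprintf("s%02d", 1:12)))
  rp <- tibble::tibble(g_up = c("a", "c", "e"), g_down = c("b", "d", "f"))
  got <- count_votes(tiny_expr(m), rp)
  naive <- sapply(colnames(m), function(s) {
    sum(sapply(seq_len(nrow(rp)), function(r) m[rp$g_up[r], s] > m[rp$g_down[r], s]))
  })
  expect_equal(got$votes, unname(naive))

  missing <- tiny_expr(matrix(1:2, ncol = 1), genes = c("a", "b"))
  err <- expect_error(count_votes(missing, pairs), class = "reopairs_data_error")
  expect_match(conditionMessage(err), "adapt_to_platform")
})

test_that("the F-score is the harmonic mean of sensitivity and specificity", {
  expect_equal(round(f_score(1, 8 / 13), 2), 0.76)
  expect_equal(round(f_score(5 / 6, 6 / 7), 2), 0.85)
  s <- seq(0, 1, by = 0.1)
  expect_equal(f_score(s, s), s) # harmonic mean of equal values
  expect_equal(f_score(0, 0), 0)
  expect_error(f_score(1.2, 0.5), class = "reopairs_data_error")
  expect_error(f_score(-0.1, 0.5), class = "reopairs_data_error")
})

test_that("vote-threshold optimisation maximises F with ties toward larger k", {
  m <- 10L
  votes <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                          votes = rep(c(10L, 0L), c(12, 18)))
  labels <- make_labels(votes$sample_id, rep(c(1L, 2L), c(12, 18)))
  opt <- optimize_vote_rule(votes, labels, m)
  expect_equal(opt$f_score, 1)
  expect_identical(opt$k, 10L) # every k separates; ties go to the strictest

  # identical votes: every k <= v predicts all positive
  const <- tibble::tibble(sample_id = votes$sample_id, votes = 4L)
  copt <- optimize_vote_rule(const, labels, m)
  sens <- 1
  spec <- 0
  expect_equal(copt$f_score, f_score(sens, spec))

  set.seed(33)
  for (i in 1:10) {
    v <- sample(0:m, 40, replace = TRUE)
    g <- sample(1:2, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(g)) < 2) next
    vt <- tibble::tibble(sample_id = sprintf("x%02d", 1:40), votes = v)
    lt <- make_labels(vt$sample_id, g)
    got <- optimize_vote_rule(vt, lt, m)
    ref <- oracle_best_k(v, g, m)
    expect_identical(got$k, as.integer(ref$k))
    expect_equal(got$f_score, ref$f)
    expect_equal(got$sensitivity, ref$sens)
    expect_equal(got$specificity, ref$spec)
  }

  expect_error(optimize_vote_rule(votes, make_labels(votes$sample_id, rep(1L, 30)), m),
               class = "reopairs_data_error")
})

# A hand-built cohort in which pair i of (a_i, b_i) satisfies a_i > b_i in
# exactly pos_wins[i] of the positive and neg_wins[i] of the negative samples.
crafted_cohort <- function(pos_wins, neg_wins, n_pos = 10L, n_neg = 10L) {
  np <- length(pos_wins)
  genes <- as.vector(rbind(sprintf("up%02d", 1:np), sprintf("dn%02d", 1:np)))
  m <- matrix(0, nrow = 2 * np, ncol = n_pos + n_neg,
              dimnames = list(genes, sprintf("s%02d", seq_len(n_pos + n_neg))))
  for (i in seq_len(np)) {
    win <- c(seq_len(n_pos) <= pos_wins[i], seq_len(n_neg) <= neg_wins[i])
    m[2 * i - 1, ] <- ifelse(win, 2, 1) + (i - 1) * 10
    m[2 * i, ] <- 1.5 + (i - 1) * 10
  }
  list(expr = tiny_expr(m, genes = genes),
       labels = make_labels(colnames(m), rep(1:2, c(n_pos, n_neg))),
       pairs = tibble::tibble(g_up = sprintf("up%02d", 1:np),
                              g_down = sprintf("dn%02d", 1:np),
                              p1 = pos_wins / n_pos, p2 = neg_wins / n_neg,
                              fd = pos_wins / n_pos - neg_wins / n_neg,
                              p_value = seq_len(np) * 1e-6))
}

test_that("the FD-cutoff scan uses a spacing-anchored grid and picks the max", {
  # fd values 0.6, 0.7, 0.8, 0.9 -> grid must span 0.60..0.90 = 31 cutoffs
  cc <- crafted_cohort(pos_wins = c(9, 9, 9, 10), neg_wins = c(3, 2, 1, 1))
  expect_equal(sort(unique(cc$pairs$fd)), c(0.6, 0.7, 0.8, 0.9))
  fit <- fd_cutoff_scan(cc$pairs, cc$expr, cc$labels, spacing = 0.01)
  expect_identical(nrow(fit$scan), 31L)
  expect_equal(max(fit$scan$best_f_score), fit$signature$training$f_score)
  # panel size is non-increasing in the cutoff
  ordered <- fit$scan[order(fit$scan$fd_cutoff), ]
  expect_true(all(diff(ordered$panel_size) <= 0))
  # every signature pair clears the chosen cutoff
  expect_true(all(fit$signature$pairs$fd >= fit$signature$fd_cutoff - 1e-9))

  single <- fd_cutoff_scan(cc$pairs[1, ], cc$expr, cc$labels)
  expect_identical(nrow(single$signature$pairs), 1L)
  expect_identical(single$signature$k, 1L)

  glob <- fd_cutoff_scan(cc$pairs, cc$expr, cc$labels, removal_stage = "global")
  expect_s3_class(glob$signature, "reo_signature")

  expect_error(fd_cutoff_scan(cc$pairs[0, ], cc$expr, cc$labels),
               class = "reopairs_data_error")
})

test_that("classification applies the vote threshold at the boundary", {
  cc <- crafted_cohort(pos_wins = rep(10, 5), neg_wins = rep(0, 5))
  sig <- reo_signature(cc$pairs, k = 3)

  calls <- classify_samples(cc$expr, sig)
  expect_true(all(calls$predicted[1:10] == 1L))
  expect_true(all(calls$predicted[11:20] == 2L))

  # a sample satisfying exactly k-1 pairs is negative; k pairs, positive
  probe <- tiny_expr(
    matrix(c(2, 1, 2, 1, 1, 2, 1, 2, 1, 2,   # votes: up01, up02 only
             2, 1, 2, 1, 2, 1, 1, 2, 1, 2), ncol = 2),
    genes = as.vector(rbind(sprintf("up%02d", 1:5), sprintf("dn%02d", 1:5))),
    samples = c("two_votes", "three_votes")
  )
  got <- classify_samples(probe, sig)
  expect_identical(got$votes, c(2L, 3L))
  expect_identical(got$predicted, c(2L, 1L))
})

test_that("training confusion equals the one recorded during optimisation", {
  cfg <- small_config(seed = 5L)
  coh <- generate_cohort(cfg)
  sig <- train_signature(coh$expr, coh$labels, log2 = FALSE)
  calls <- classify_samples(coh$expr, sig)
  met <- metrics_from_confusion(confusion_counts(calls, coh$labels))
  expect_equal(met$sensitivity, sig$training$sensitivity)
  expect_equal(met$specificity, sig$training$specificity)
  expect_equal(met$f, sig$training$f_score)
})

test_that("classification ignores non-signature genes and monotone distortion", {
  cfg <- small_config(seed = 6L)
  coh <- generate_cohort(cfg)
  sig <- train_signature(coh$expr, coh$labels, log2 = FALSE)
  base <- classify_samples(coh$expr, sig)

  sig_genes <- unique(c(sig$pairs$g_up, sig$pairs$g_down))
  slim <- coh$expr[coh$expr$gene_id %in% sig_genes, ]
  expect_equal(classify_samples(slim, sig), base)

  for (family in c("affine_pos", "exp", "rank")) {
    corrupted <- corrupt_monotone(coh$expr, family = family, seed = 123L)
    expect_identical(classify_samples(corrupted, sig), base)
  }
})

test_that("platform adaptation re-optimises the threshold on training data", {
  cc <- crafted_cohort(pos_wins = c(10, 9, 9, 8, 8, 7, 9, 10, 8, 9),
                       neg_wins = c(0, 1, 2, 1, 3, 2, 2, 1, 0, 2))
  sig <- reo_signature(cc$pairs, k = 6, fd_cutoff = min(cc$pairs$fd))

  # every gene available: the signature is unchanged
  all_genes <- cc$expr$gene_id
  expect_identical(adapt_to_platform(sig, all_genes, cc$expr, cc$labels), sig)

  # drop the genes of three pairs: k re-derived by exhaustive scan over 1..7
  lost <- c("up02", "up05", "dn09")
  avail <- setdiff(all_genes, lost)
  ad <- adapt_to_platform(sig, avail, cc$expr, cc$labels)
  expect_identical(nrow(ad$pairs), 7L)
  expect_true(all(ad$pairs$g_up %in% avail & ad$pairs$g_down %in% avail))
  votes <- count_votes(cc$expr, ad$pairs)
  x <- dplyr::inner_join(votes, cc$labels, by = "sample_id")
  ref <- oracle_best_k(x$votes, x$group, 7L)
  expect_identical(ad$k, as.integer(ref$k))
  expect_equal(ad$training$f_score, ref$f)

  expect_error(adapt_to_platform(sig, character(0), cc$expr, cc$labels),
               class = "reopairs_data_error")
})

test_that("signatures serialise to JSON and classify identically after reload", {
  cfg <- small_config(seed = 9L)
  coh <- generate_cohort(cfg)
  sig <- train_signature(coh$expr, coh$labels, log2 = FALSE, cohort = "demo")
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$k, sig$k)
  expect_equal(back$fd_cutoff, sig$fd_cutoff)
  expect_equal(back$pairs$fd, sig$pairs$fd)
  expect_equal(classify_samples(coh$expr, back), classify_samples(coh$expr, sig))

  expect_error(read_signature(withr::local_tempfile(fileext = ".json")),
               class = "reopairs_data_error")
})

test_that("tidy and glance summarise a signature", {
  pairs <- tibble::tibble(g_up = c("A", "C"), g_down = c("B", "D"),
                          fd = c(0.9, 0.8), p1 = c(0.95, 0.9), p2 = c(0.05, 0.1))
  sig <- reo_signature(pairs, k = 2, fd_cutoff = 0.8,
                       training = list(n_pos = 10L, n_neg = 20L, f_score = 0.9))
  expect_identical(tidy(sig), pairs)
  g <- glance(sig)
  expect_identical(g$n_pairs, 2L)
  expect_identical(g$k, 2L)
  expect_equal(g$training_f_score, 0.9)
  expect_error(reo_signature(pairs, k = 5), class = "reopairs_data_error")
  expect_error(reo_signature(dplyr::mutate(pairs, g_down = c("B", "A")), k = 1),
               class = "reopairs_data_error")
})
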