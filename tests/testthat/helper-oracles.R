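# Independent reference implementations used as oracles. Each is written from
# the definition (enumeration, brute force, explicit loops) and shares no code
# with the package internals it checks.

# Two-sided Fisher p by hypergeometric enumeration: sum the probabilities of
# every table with the observed margins whose probability does not exceed the
# observed one (with the conventional 1 + 1e-7 relative slack for
# floating-point ties between symmetric tables).
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  m1 <- a + c
  n <- r1 + r2
  support <- max(0L, m1 - r2):min(r1, m1)
  logp <- lchoose(r1, support) + lchoose(r2, m1 - support) - lchoose(n, m1)
  probs <- exp(logp)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up BH written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  raw <- m * p[o] / seq_len(m)          # m * p_(i) / i in rank order
  q_sorted <- pmin(1, rev(cummin(rev(raw)))) # min over j >= i
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# AUC as the mean over all positive/negative score comparisons, half credit
# for ties.
oracle_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  tot <- 0
  for (x in sp) {
    for (y in sn) {
      tot <- tot + (x > y) + 0.5 * (x == y)
    }
  }
  tot / (length(sp) * length(sn))
}

# Greedy redundancy removal re-implemented with character sets.
oracle_greedy_removal <- function(pairs) {
  ord <- order(-pairs$fd,
               if ("p_value" %in% names(pairs)) pairs$p_value else rep(0, nrow(pairs)),
               pairs$g_up, pairs$g_down)
  pairs <- pairs[ord, , drop = FALSE]
  seen <- character(0)
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    if (!(pairs$g_up[r] %in% seen) && !(pairs$g_down[r] %in% seen)) {
      keep[r] <- TRUE
      seen <- c(seen, pairs$g_up[r], pairs$g_down[r])
    }
  }
  pairs[keep, , drop = FALSE]
}

# Exhaustive vote-rule scan from the definition: for each k compute the
# confusion of "positive iff votes >= k" and its F-score; ties -> larger k.
oracle_best_k <- function(votes, group, m) {
  best <- NULL
  for (k in 1:m) {
    pred_pos <- votes >= k
    tp <- sum(pred_pos & group == 1L)
    fn <- sum(!pred_pos & group == 1L)
    fp <- sum(pred_pos & group == 2L)
    tn <- sum(!pred_pos & group == 2L)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    f <- if (sens + spec == 0) 0 else 2 * sens * spec / (sens + spec)
    if (is.null(best) || f >= best$f) {
      best <- list(k = k, f = f, sens = sens, spec = spec)
    }
  }
  best
}
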