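#' Remove gene-sharing redundancy from an oriented pair list
#'
#' Sweeps the pairs in order of frequency difference descending (ties broken
#' by p-value ascending, then lexicographic pair ids) and keeps a pair only
#' if neither of its genes occurs in an already-kept pair — so for every gene
#' only the pair with the largest FD survives. Output preserves sweep order;
#' the kept set depends only on the input set, not its row order.
#'
#' @param pairs A tibble with columns `g_up`, `g_down`, `fd` (and optionally
#'   `p_value`, used for tie-breaking), e.g. from [screen_pairs()].
#' @return The non-redundant subset, in sweep order.
#' @export
remove_redundant_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0L) {
    return(pairs)
  }
  if (!all(c("g_up", "g_down", "fd") %in% names(pairs))) {
    abort_data("Pairs need `g_up`, `g_down` and `fd` columns.")
  }
  if (!"p_value" %in% names(pairs)) {
    ord <- order(-pairs$fd, pairs$g_up, pairs$g_down)
  } else {
    ord <- order(-pairs$fd, pairs$p_value, pairs$g_up, pairs$g_down)
  }
  pairs <- pairs[ord, , drop = FALSE]
  genes <- unique(c(pairs$g_up, pairs$g_down))
  i1 <- match(pairs$g_up, genes)
  i2 <- match(pairs$g_down, genes)
  used <- logical(length(genes))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    a <- i1[r]
    b <- i2[r]
    if (!used[a] && !used[b]) {
      keep[r] <- TRUE
      used[a] <- TRUE
      used[b] <- TRUE
    }
  }
  pairs[keep, , drop = FALSE]
}

# logical pairs-by-samples matrix of E_up > E_down; hard error on missing genes
pair_vote_matrix <- function(m, pairs) {
  missing <- setdiff(unique(c(pairs$g_up, pairs$g_down)), rownames(m))
  if (length(missing)) {
    abort_data(sprintf(
      "Signature genes absent from the expression table: %s. Use adapt_to_platform() to restrict the signature first.",
      fmt_ids(missing)
    ))
  }
  m[pairs$g_up, , drop = FALSE] > m[pairs$g_down, , drop = FALSE]
}

#' Count signature votes per sample
#'
#' For each sample, the number of pairs whose positive-class pattern
#' `E_up > E_down` holds (ties cast no vote).
#'
#' @param expr Expression tibble (one or more samples).
#' @param pairs Oriented pair tibble (`g_up`, `g_down`) or a signature object.
#' @return A tibble `sample_id`, `votes`.
#' @export
count_votes <- function(expr, pairs) {
  if (inherits(pairs, "reo_signature")) pairs <- pairs$pairs
  m <- expr_matrix(expr)
  v <- pair_vote_matrix(m, pairs)
  tibble(sample_id = colnames(m), votes = as.integer(colSums(v)))
}

#' Harmonic mean of sensitivity and specificity
#'
#' `2 * sens * spec / (sens + spec)`; 0 when both are zero. (This F-score
#' balances the two error types of a two-group rule; it is not the
#' precision/recall F1.)
#'
#' @param sensitivity,specificity Numeric vectors in `[0, 1]`.
#' @return The harmonic means.
#' @examples
#' f_score(1, 0.62) # ~0.765
#' @export
f_score <- function(sensitivity, specificity) {
  if (anyNA(sensitivity) || anyNA(specificity) ||
      any(sensitivity < 0 | sensitivity > 1) || any(specificity < 0 | specificity > 1)) {
    abort_data("sensitivity and specificity must lie in [0, 1].")
  }
  s <- sensitivity + specificity
  out <- ifelse(s == 0, 0, 2 * sensitivity * specificity / s)
  as.numeric(out)
}

# core vote-threshold scan on integer vote vectors
optimize_k <- function(votes_pos, votes_neg, m) {
  if (length(votes_pos) == 0L || length(votes_neg) == 0L) {
    abort_data("Both groups must be non-empty to optimise the vote rule.")
  }
  if (any(c(votes_pos, votes_neg) < 0) || any(c(votes_pos, votes_neg) > m)) {
    abort_data("Votes must lie in [0, panel size].")
  }
  cnt_pos <- tabulate(votes_pos + 1L, nbins = m + 1L)
  cnt_neg <- tabulate(votes_neg + 1L, nbins = m + 1L)
  ge_pos <- rev(cumsum(rev(cnt_pos))) # ge_pos[v + 1] = #positives with votes >= v
  ge_neg <- rev(cumsum(rev(cnt_neg)))
  k <- seq_len(m)
  tp <- ge_pos[k + 1L]
  fp <- ge_neg[k + 1L]
  sens <- tp / length(votes_pos)
  spec <- 1 - fp / length(votes_neg)
  f <- f_score(sens, spec)
  best <- max(which(f == max(f))) # ties -> larger k (stricter rule)
  list(k = best, f_score = f[best], sensitivity = sens[best],
       specificity = spec[best], f_by_k = f)
}

#' Optimise the majority-vote threshold on training data
#'
#' Evaluates the rule "predict positive iff votes >= k" for every
#' `k in 1..m` against the training labels and returns the k with the largest
#' F-score (harmonic mean of sensitivity and specificity); ties are broken
#' toward larger k, the stricter rule.
#'
#' @param votes A tibble `sample_id`, `votes` (from [count_votes()]).
#' @param labels Phenotype labels covering the same samples.
#' @param m Panel size (the maximum possible vote count).
#' @return A one-row tibble `k`, `f_score`, `sensitivity`, `specificity`.
#' @export
optimize_vote_rule <- function(votes, labels, m) {
  if (!is.data.frame(votes) || !all(c("sample_id", "votes") %in% names(votes))) {
    abort_data("`votes` must be a tibble with sample_id and votes columns.")
  }
  labels <- as_phenotype_labels(labels)
  x <- dplyr::inner_join(votes, labels, by = "sample_id")
  if (nrow(x) < nrow(labels)) {
    abort_data("Every labeled sample needs a vote count.")
  }
  opt <- optimize_k(x$votes[x$group == 1L], x$votes[x$group == 2L], m)
  tibble(k = opt$k, f_score = opt$f_score,
         sensitivity = opt$sensitivity, specificity = opt$specificity)
}

#' Construct a gene-pair vote signature
#'
#' Assembles a signature from an oriented pair table and a vote threshold,
#' e.g. to encode a published panel for use with [classify_samples()] and
#' [adapt_to_platform()]. Invariants enforced: `1 <= k <=` panel size and no
#' gene appearing in more than one pair.
#'
#' @param pairs Tibble with columns `g_up`, `g_down` (and usually `fd`, `p1`,
#'   `p2`).
#' @param k Vote threshold: a sample is called positive when at least `k`
#'   pairs show `E_up > E_down`.
#' @param fd_cutoff Frequency-difference cutoff that defined the panel
#'   (metadata).
#' @param training Optional list of training provenance (`cohort`, `n_pos`,
#'   `n_neg`, `f_score`, ...).
#' @return An object of class `reo_signature`.
#' @export
reo_signature <- function(pairs, k, fd_cutoff = NA_real_, training = list()) {
  pairs <- as_tibble(pairs)
  if (!all(c("g_up", "g_down") %in% names(pairs)) || nrow(pairs) == 0L) {
    abort_data("`pairs` needs non-empty g_up/g_down columns.")
  }
  if (!is_count(k) || k < 1 || k > nrow(pairs)) {
    abort_data("`k` must be an integer in 1..number of pairs.")
  }
  genes <- c(pairs$g_up, pairs$g_down)
  if (anyDuplicated(genes)) {
    abort_data(sprintf("A gene may appear in only one pair; repeated: %s",
                       fmt_ids(unique(genes[duplicated(genes)]))))
  }
  new_signature(pairs, as.integer(k), fd_cutoff, training)
}

new_signature <- function(pairs, k, fd_cutoff, training, scan = NULL) {
  pairs <- as_tibble(pairs)
  genes <- c(pairs$g_up, pairs$g_down)
  if (anyDuplicated(genes)) {
    abort_internal("A signature must not reuse a gene across pairs.")
  }
  if (k < 1L || k > nrow(pairs)) {
    abort_internal("Vote threshold k must lie in 1..panel size.")
  }
  structure(
    list(version = "1.0", pairs = pairs, k = as.integer(k),
         fd_cutoff = fd_cutoff, training = training, scan = scan),
    class = "reo_signature"
  )
}

#' Scan frequency-difference cutoffs and pick the best vote classifier
#'
#' Builds one candidate panel per FD cutoff on a grid of multiples of
#' `spacing` spanning the candidates' FD range (anchoring at grid multiples
#' keeps cutoffs platform-independent). For each cutoff the pairs with
#' `fd >= cutoff` are pruned by [remove_redundant_pairs()] and the vote
#' threshold k is optimised on the training cohort; the panel reaching the
#' largest training F-score becomes the signature. Ties prefer the larger
#' cutoff (smaller, higher-FD panel), then the larger k.
#'
#' @param candidates Oriented pair tibble from [screen_pairs()]; non-empty.
#' @param expr Training expression tibble.
#' @param labels Training phenotype labels.
#' @param spacing Cutoff grid spacing (default 0.01).
#' @param removal_stage `"per_panel"` (default: redundancy removal inside each
#'   cutoff panel) or `"global"` (once, before the scan).
#' @param cohort Optional cohort name recorded in the signature.
#' @return A list with `signature` (an `reo_signature`) and `scan`, a tibble
#'   with one row per cutoff: `fd_cutoff`, `panel_size`, `best_k`,
#'   `best_f_score`, `sensitivity`, `specificity`.
#' @export
fd_cutoff_scan <- function(candidates, expr, labels, spacing = 0.01,
                           removal_stage = c("per_panel", "global"),
                           cohort = NULL) {
  removal_stage <- match.arg(removal_stage)
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0L) {
    abort_data("No candidate pairs to scan.")
  }
  if (!(is.numeric(spacing) && length(spacing) == 1L && spacing > 0)) {
    abort_config("`spacing` must be a positive number.")
  }
  m <- expr_matrix(expr)
  labels <- check_labels(m, labels)
  if (removal_stage == "global") {
    candidates <- remove_redundant_pairs(candidates)
  }
  # deterministic sweep order once; every cutoff panel is drawn from a prefix
  ord <- order(-candidates$fd, candidates$p_value, candidates$g_up, candidates$g_down)
  candidates <- candidates[ord, , drop = FALSE]

  votes_all <- pair_vote_matrix(m, candidates)
  pos <- match(labels$sample_id[labels$group == 1L], colnames(m))
  neg <- match(labels$sample_id[labels$group == 2L], colnames(m))

  genes_used <- unique(c(candidates$g_up, candidates$g_down))
  i1 <- match(candidates$g_up, genes_used)
  i2 <- match(candidates$g_down, genes_used)
  # greedy sweep over the first `limit` (fd-sorted) rows: keep a pair iff
  # neither gene was kept before
  greedy_rows <- function(limit) {
    used <- logical(length(genes_used))
    keep <- integer(0)
    for (r in seq_len(limit)) {
      a <- i1[r]
      b <- i2[r]
      if (!used[a] && !used[b]) {
        keep <- c(keep, r)
        used[a] <- TRUE
        used[b] <- TRUE
      }
    }
    keep
  }

  hi <- floor(max(candidates$fd) / spacing + 1e-9)
  lo <- ceiling(min(candidates$fd) / spacing - 1e-9)
  cutoffs <- if (hi < lo) min(candidates$fd) else seq(hi, lo) * spacing

  scan <- vector("list", length(cutoffs))
  best <- NULL
  for (s in seq_along(cutoffs)) {
    cut <- cutoffs[s]
    limit <- sum(candidates$fd >= cut - 1e-9)
    if (limit == 0L) next
    rows <- if (removal_stage == "per_panel") greedy_rows(limit) else seq_len(limit)
    votes <- if (length(rows) == 1L) {
      as.integer(votes_all[rows, ])
    } else {
      as.integer(colSums(votes_all[rows, , drop = FALSE]))
    }
    opt <- optimize_k(votes[pos], votes[neg], length(rows))
    scan[[s]] <- tibble(fd_cutoff = cut, panel_size = length(rows),
                        best_k = opt$k, best_f_score = opt$f_score,
                        sensitivity = opt$sensitivity, specificity = opt$specificity)
    # strictly-greater keeps the earlier (larger) cutoff on ties; k ties were
    # already broken toward larger k inside optimize_k
    if (is.null(best) || opt$f_score > best$f + 1e-12) {
      best <- list(panel = candidates[rows, , drop = FALSE], cut = cut, opt = opt,
                   f = opt$f_score)
    }
  }
  scan <- dplyr::bind_rows(scan)
  class(scan) <- c("reo_scan", class(scan))
  if (is.null(best)) {
    abort_internal("No cutoff produced a non-empty panel.")
  }
  training <- list(
    cohort = cohort %||% NA_character_,
    n_pos = length(pos), n_neg = length(neg),
    f_score = best$opt$f_score,
    sensitivity = best$opt$sensitivity,
    specificity = best$opt$specificity
  )
  sig <- new_signature(best$panel, best$opt$k, best$cut, training, scan = scan)
  list(signature = sig, scan = scan)
}

#' Train a gene-pair vote signature end to end
#'
#' Convenience wrapper chaining [de_screen()], [screen_pairs()] and
#' [fd_cutoff_scan()] on one training cohort.
#'
#' @param expr Training expression tibble.
#' @param labels Training phenotype labels.
#' @param de_fdr FDR threshold of the differential-expression gate.
#' @param pair_fdr FDR threshold of the pair screen.
#' @param spacing FD cutoff grid spacing.
#' @param de_method,log2,d0 Passed to [de_screen()].
#' @param pair_space Passed to [screen_pairs()].
#' @param removal_stage Passed to [fd_cutoff_scan()].
#' @param cohort Optional cohort name recorded in the signature.
#' @return An `reo_signature`; its `counts` attribute records the stage sizes
#'   (DE genes, candidate pairs, panels scanned).
#' @export
train_signature <- function(expr, labels, de_fdr = 0.01, pair_fdr = 0.01,
                            spacing = 0.01,
                            de_method = c("welch_t", "moderated_t"),
                            log2 = TRUE, d0 = 4,
                            pair_space = c("de_by_all", "de_by_de"),
                            removal_stage = c("per_panel", "global"),
                            cohort = NULL) {
  de <- de_screen(expr, labels, alpha = de_fdr, method = de_method,
                  log2 = log2, d0 = d0)
  if (nrow(de) == 0L) {
    abort_data("No differentially expressed genes at the requested FDR; loosen `de_fdr`.")
  }
  cand <- screen_pairs(expr, labels, de$gene_id, alpha = pair_fdr,
                       pair_space = pair_space)
  if (nrow(cand) == 0L) {
    abort_data("No gene pairs pass the pair FDR; loosen `pair_fdr`.")
  }
  fit <- fd_cutoff_scan(cand, expr, labels, spacing = spacing,
                        removal_stage = removal_stage, cohort = cohort)
  sig <- fit$signature
  attr(sig, "counts") <- list(
    n_de_genes = nrow(de),
    n_candidate_pairs = nrow(cand),
    n_panels_scanned = nrow(fit$scan)
  )
  sig
}

#' Classify samples with a gene-pair vote signature
#'
#' A sample is called positive when at least `k` of the signature's pairs show
#' their positive-class ordering. Because only within-sample orderings enter
#' the rule, the call is unchanged by any per-sample strictly increasing
#' transform of the expression values.
#'
#' @param expr Expression tibble containing all signature genes.
#' @param sig An `reo_signature`.
#' @return A tibble `sample_id`, `votes`, `predicted` (1 = positive,
#'   2 = negative).
#' @export
classify_samples <- function(expr, sig) {
  if (!inherits(sig, "reo_signature")) {
    abort_data("`sig` must be an reo_signature.")
  }
  v <- count_votes(expr, sig)
  v$predicted <- ifelse(v$votes >= sig$k, 1L, 2L)
  v
}

#' Restrict a signature to the genes measurable on a platform
#'
#' Drops every pair with a gene outside `available_genes` and re-optimises the
#' vote threshold of the reduced panel on the original training cohort; the
#' FD cutoff is inherited from the full signature.
#'
#' @param sig An `reo_signature`.
#' @param available_genes Character vector of measurable gene identifiers.
#' @param training_expr,training_labels The training cohort used to re-derive
#'   the vote threshold.
#' @return A new `reo_signature` with the surviving pairs and re-optimised k.
#' @export
adapt_to_platform <- function(sig, available_genes, training_expr, training_labels) {
  if (!inherits(sig, "reo_signature")) {
    abort_data("`sig` must be an reo_signature.")
  }
  keep <- sig$pairs$g_up %in% available_genes & sig$pairs$g_down %in% available_genes
  if (!any(keep)) {
    abort_data("No signature pair is fully measurable on this platform.")
  }
  if (all(keep)) {
    return(sig)
  }
  pairs <- sig$pairs[keep, , drop = FALSE]
  m <- expr_matrix(training_expr)
  labels <- check_labels(m, training_labels)
  votes <- count_votes(training_expr, pairs)
  x <- dplyr::inner_join(votes, labels, by = "sample_id")
  opt <- optimize_k(x$votes[x$group == 1L], x$votes[x$group == 2L], nrow(pairs))
  training <- sig$training
  training$f_score <- opt$f_score
  training$sensitivity <- opt$sensitivity
  training$specificity <- opt$specificity
  training$adapted_from <- nrow(sig$pairs)
  new_signature(pairs, opt$k, sig$fd_cutoff, training, scan = NULL)
}

#' Write a signature to versioned JSON
#'
#' The file records pair order and orientation, the vote threshold, the FD
#' cutoff and the training provenance; classification is reproducible from
#' the file alone.
#'
#' @param sig An `reo_signature`.
#' @param path Output path.
#' @return `sig`, invisibly.
#' @export
write_signature <- function(sig, path) {
  if (!inherits(sig, "reo_signature")) {
    abort_data("`sig` must be an reo_signature.")
  }
  payload <- list(
    version = sig$version,
    pairs = sig$pairs[, intersect(c("g_up", "g_down", "fd", "p1", "p2"), names(sig$pairs))],
    k = sig$k,
    fd_cutoff = sig$fd_cutoff,
    training = sig$training
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sig)
}

#' Read a signature written by [write_signature()]
#'
#' @param path JSON path.
#' @return An `reo_signature`.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: %s", path))
  }
  x <- jsonlite::fromJSON(path)
  if (is.null(x$pairs) || is.null(x$k)) {
    abort_data(sprintf("'%s' is not a signature file (missing pairs/k).", path))
  }
  new_signature(as_tibble(x$pairs), as.integer(x$k),
                x$fd_cutoff %||% NA_real_,
                as.list(x$training))
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf(
    "<reo_signature> %d gene pairs, vote threshold k = %d (positive iff votes >= k)\n",
    nrow(x$pairs), x$k
  ))
  cat(sprintf("  FD cutoff: %s | training F-score: %s (sens %s, spec %s)\n",
              format(x$fd_cutoff, digits = 3),
              format(x$training$f_score, digits = 3),
              format(x$training$sensitivity, digits = 3),
              format(x$training$specificity, digits = 3)))
  print(utils::head(x$pairs, 5))
  if (nrow(x$pairs) > 5) cat(sprintf("  ... and %d more pairs\n", nrow(x$pairs) - 5L))
  invisible(x)
}

#' @rdname reo_signature_methods
#' @export
tidy.reo_signature <- function(x, ...) {
  x$pairs
}

#' Broom-style accessors for gene-pair signatures
#'
#' `tidy()` returns the oriented pair table; `glance()` a one-row summary of
#' the fitted classifier.
#'
#' @param x An `reo_signature`.
#' @param ... Unused.
#' @return A tibble.
#' @name reo_signature_methods
#' @export
glance.reo_signature <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    k = x$k,
    fd_cutoff = x$fd_cutoff,
    training_f_score = x$training$f_score %||% NA_real_,
    training_sensitivity = x$training$sensitivity %||% NA_real_,
    training_specificity = x$training$specificity %||% NA_real_,
    n_pos = x$training$n_pos %||% NA_integer_,
    n_neg = x$training$n_neg %||% NA_integer_
  )
}
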