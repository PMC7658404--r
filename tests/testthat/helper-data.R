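# In-code fixtures shared across test files.

# gene-by-sample tibble from a matrix of values
tiny_expr <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  genes <- genes %||% rownames(values) %||% sprintf("g%02d", seq_len(nrow(values)))
  samples <- samples %||% colnames(values) %||% sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  tibble::tibble(gene_id = genes, tibble::as_tibble(values))
}

make_labels <- function(samples, groups) {
  tibble::tibble(sample_id = samples, group = as.integer(groups))
}

# a small but realistic cohort: quick enough for per-test use
small_config <- function(seed = 7L, ...) {
  synthetic_config(n_genes = 300L, n_pos = 20L, n_neg = 30L,
                   n_planted_pairs = 5L, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
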