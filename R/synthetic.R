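#' Configuration of a synthetic two-group cohort
#'
#' Describes a cohort with a log-scale Gaussian expression background and a
#' set of planted gene pairs whose ordering `E_up > E_down` holds with
#' probability `pi_pos` in positive samples and `pi_neg` in negative samples.
#' The planted-pair identities and the per-gene baselines are functions of
#' the config seed alone, so cohorts generated from the same config (e.g. a
#' training and a held-out split) share the same planted structure while
#' their samples are independent.
#'
#' Defaults emulate a log2-microarray study: baselines spread with sd 2
#' around 8, within-gene noise sd 0.4, and the reference design of 2000
#' genes, 30 disjoint planted pairs with ordering probabilities 0.95/0.05 and
#' a 60 + 120 positive/negative training split.
#'
#' @param n_genes Number of genes.
#' @param n_pos,n_neg Samples per group for a default split.
#' @param n_planted_pairs Number of planted pairs (gene-disjoint unless
#'   `overlap_pairs`).
#' @param pi_pos,pi_neg Probability that the planted ordering holds in a
#'   positive / negative sample (`0 <= pi_neg <= pi_pos <= 1`; equality gives
#'   a null cohort).
#' @param base_log_mean,base_log_mean_sd Mean and sd of the per-gene baseline
#'   (log2 scale).
#' @param noise_sd Within-gene, per-sample Gaussian noise sd.
#' @param seed Structure seed (planted pairs, baselines, methylation sites).
#' @param overlap_pairs Plant chained pairs sharing genes (to exercise
#'   redundancy removal) instead of gene-disjoint pairs.
#' @param dropout_genes Number of genes recorded as absent from a hypothetical
#'   validation platform (for [adapt_to_platform()] exercises).
#' @param n_meth_sites,n_dm_sites,beta_shift Methylation companion: total CpG
#'   sites, differentially methylated sites, and the beta increase planted in
#'   the positive group.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L, n_pos = 60L, n_neg = 120L,
                             n_planted_pairs = 30L, pi_pos = 0.95, pi_neg = 0.05,
                             base_log_mean = 8, base_log_mean_sd = 2,
                             noise_sd = 0.4, seed = 1L,
                             overlap_pairs = FALSE, dropout_genes = 0L,
                             n_meth_sites = 1000L, n_dm_sites = 100L,
                             beta_shift = 0.3) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
    n_neg = as.integer(n_neg), n_planted_pairs = as.integer(n_planted_pairs),
    pi_pos = pi_pos, pi_neg = pi_neg,
    base_log_mean = base_log_mean, base_log_mean_sd = base_log_mean_sd,
    noise_sd = noise_sd, seed = as.integer(seed),
    overlap_pairs = isTRUE(overlap_pairs), dropout_genes = as.integer(dropout_genes),
    n_meth_sites = as.integer(n_meth_sites), n_dm_sites = as.integer(n_dm_sites),
    beta_shift = beta_shift
  )
  if (!(pi_neg >= 0 && pi_neg <= pi_pos && pi_pos <= 1)) {
    abort_config("Need 0 <= pi_neg <= pi_pos <= 1.")
  }
  needed <- if (cfg$overlap_pairs) cfg$n_planted_pairs + 1L else 2L * cfg$n_planted_pairs
  if (needed > cfg$n_genes) {
    abort_config("Too many planted pairs for the number of genes.")
  }
  if (cfg$n_pos < 1L || cfg$n_neg < 1L || cfg$n_genes < 2L) {
    abort_config("Need at least one sample per group and two genes.")
  }
  if (cfg$noise_sd < 0 || cfg$base_log_mean_sd < 0) {
    abort_config("Standard deviations must be non-negative.")
  }
  if (!(cfg$beta_shift > 0 && cfg$beta_shift < 1)) {
    abort_config("beta_shift must lie in (0, 1).")
  }
  if (cfg$n_dm_sites > cfg$n_meth_sites) {
    abort_config("n_dm_sites cannot exceed n_meth_sites.")
  }
  structure(cfg, class = "synthetic_config")
}

# structure (baselines, planted pairing, dropout list) from the config seed
cohort_structure <- function(cfg) {
  with_rng(cfg$seed, {
    gene_id <- sprintf("g%05d", seq_len(cfg$n_genes))
    mu <- rnorm(cfg$n_genes, cfg$base_log_mean, cfg$base_log_mean_sd)
    if (cfg$overlap_pairs) {
      chain <- sample(cfg$n_genes, cfg$n_planted_pairs + 1L)
      up <- chain[-length(chain)]
      down <- chain[-1L]
    } else {
      picked <- sample(cfg$n_genes, 2L * cfg$n_planted_pairs)
      up <- picked[seq(1L, length(picked), by = 2L)]
      down <- picked[seq(2L, length(picked), by = 2L)]
    }
    mu[down] <- mu[up] # paired genes share a baseline so only ordering differs
    dropout <- if (cfg$dropout_genes > 0L) sample(gene_id, cfg$dropout_genes) else character(0)
    list(gene_id = gene_id, mu = mu, up = up, down = down, dropout = dropout)
  })
}

#' Generate a synthetic cohort with planted gene-pair orderings
#'
#' Baseline gene means are drawn on a log scale; unplanted genes receive
#' independent Gaussian noise per sample. For each planted pair a per-sample
#' Bernoulli draw (probability `pi_pos` or `pi_neg` by group) decides which
#' gene is shifted up by `delta = 2 * noise_sd` and which down before noise;
#' where residual noise still contradicts the draw, the pair's two values are
#' swapped within that sample (the genes share a baseline, so marginal
#' distributions are unaffected). The planted ordering therefore holds with
#' probability exactly `pi_pos` / `pi_neg`, and the ground truth is exact per
#' sample.
#'
#' @param cfg A [synthetic_config()].
#' @param n_pos,n_neg Group sizes (default from `cfg`); override to draw a
#'   held-out split.
#' @param seed Sample-level seed (default `cfg$seed`); the planted structure
#'   always comes from `cfg$seed`, so different sample seeds give independent
#'   cohorts with identical planted pairs.
#' @param sample_prefix Prefix of the generated sample identifiers.
#' @return A list: `expr` (expression tibble), `labels` (`sample_id`,
#'   `group`), and `truth` with `planted_pairs` (tibble `g_up`, `g_down`,
#'   `pi_pos`, `pi_neg`), `delta` and `dropout_genes`.
#' @export
generate_cohort <- function(cfg, n_pos = cfg$n_pos, n_neg = cfg$n_neg,
                            seed = cfg$seed, sample_prefix = "s") {
  if (!inherits(cfg, "synthetic_config")) {
    abort_config("`cfg` must come from synthetic_config().")
  }
  st <- cohort_structure(cfg)
  n <- n_pos + n_neg
  group <- rep(c(1L, 2L), c(n_pos, n_neg))
  sample_id <- sprintf("%s%04d", sample_prefix, seq_len(n))
  delta <- 2 * cfg$noise_sd
  m <- with_rng(seed, {
    m <- matrix(st$mu, nrow = cfg$n_genes, ncol = n)
    pi_s <- ifelse(group == 1L, cfg$pi_pos, cfg$pi_neg)
    on <- matrix(FALSE, nrow = length(st$up), ncol = n)
    for (p in seq_along(st$up)) {
      on[p, ] <- rbinom(n, 1L, pi_s) == 1L
      shift <- ifelse(on[p, ], delta, -delta)
      m[st$up[p], ] <- m[st$up[p], ] + shift
      m[st$down[p], ] <- m[st$down[p], ] - shift
    }
    m <- m + matrix(rnorm(cfg$n_genes * n, 0, cfg$noise_sd), nrow = cfg$n_genes)
    # enforce each Bernoulli draw exactly: where residual noise contradicts the
    # intended ordering, swap the pair's two values (the genes share a baseline,
    # so marginals are preserved and the planted frequency is exactly pi)
    for (p in seq_along(st$up)) {
      realized <- m[st$up[p], ] > m[st$down[p], ]
      bad <- realized != on[p, ]
      if (any(bad)) {
        tmp <- m[st$up[p], bad]
        m[st$up[p], bad] <- m[st$down[p], bad]
        m[st$down[p], bad] <- tmp
      }
    }
    m
  })
  dimnames(m) <- list(st$gene_id, sample_id)
  list(
    expr = matrix_expr(m),
    labels = tibble(sample_id = sample_id, group = group),
    truth = list(
      planted_pairs = tibble(
        g_up = st$gene_id[st$up], g_down = st$gene_id[st$down],
        pi_pos = cfg$pi_pos, pi_neg = cfg$pi_neg
      ),
      delta = delta,
      dropout_genes = st$dropout
    )
  )
}

#' Expand a gene-level matrix to probe level
#'
#' Each gene becomes `replicates` probes (`<gene>_p1`, ...) whose values are
#' the gene value plus an optional probe-specific offset plus per-cell noise.
#' Decoy probes that map to no gene, or to multiple genes, are appended with
#' background values; [collapse_probes()] must discard them.
#'
#' @param expr Gene-level expression tibble.
#' @param replicates Probes per gene (>= 1).
#' @param probe_noise_sd Per-cell Gaussian noise sd.
#' @param probe_offset_sd Probe-specific additive offset sd (default 0, so the
#'   probe mean is an unbiased estimate of the gene value).
#' @param n_unmapped,n_multimapped Decoy probe counts.
#' @param seed RNG seed.
#' @return A list: `probes` (probe-level expression tibble) and `map`
#'   (tibble `probe_id`, `gene_id`, `multimapped`).
#' @export
to_probe_level <- function(expr, replicates = 3L, probe_noise_sd = 0.1,
                           probe_offset_sd = 0, n_unmapped = 0L,
                           n_multimapped = 0L, seed = 1L) {
  if (!is_count(replicates) || replicates < 1L) {
    abort_config("`replicates` must be a positive integer.")
  }
  m <- expr_matrix(expr)
  with_rng(seed, {
    probe_id <- as.vector(t(outer(rownames(m), seq_len(replicates),
                                  function(g, r) sprintf("%s_p%d", g, r))))
    gene_id <- rep(rownames(m), each = replicates)
    vals <- m[gene_id, , drop = FALSE]
    # one offset per probe, recycled across sample columns
    vals <- vals + rnorm(length(gene_id), 0, probe_offset_sd)
    vals <- vals + matrix(rnorm(length(vals), 0, probe_noise_sd), nrow = nrow(vals))
    rownames(vals) <- probe_id
    map <- tibble(probe_id = probe_id, gene_id = gene_id, multimapped = FALSE)
    if (n_unmapped > 0L) {
      uid <- sprintf("decoy_u%03d", seq_len(n_unmapped))
      vals <- rbind(vals, matrix(rnorm(n_unmapped * ncol(m), mean(m), 1),
                                 nrow = n_unmapped, dimnames = list(uid, colnames(m))))
      map <- dplyr::bind_rows(map, tibble(probe_id = uid, gene_id = NA_character_,
                                          multimapped = FALSE))
    }
    if (n_multimapped > 0L) {
      mid <- sprintf("decoy_m%03d", seq_len(n_multimapped))
      vals <- rbind(vals, matrix(rnorm(n_multimapped * ncol(m), mean(m), 1),
                                 nrow = n_multimapped, dimnames = list(mid, colnames(m))))
      map <- dplyr::bind_rows(map, tibble(probe_id = mid, gene_id = NA_character_,
                                          multimapped = TRUE))
    }
    list(probes = matrix_expr(vals), map = map)
  })
}

#' Corrupt a cohort with per-sample monotone distortions
#'
#' Applies an independently drawn strictly increasing transform to every
#' sample column: a positive-slope affine map, an exponential warp, or
#' replacement by within-sample ranks. All within-sample orderings — and
#' therefore every REO statistic and classification — are unchanged.
#'
#' @param expr Expression tibble.
#' @param family `"affine_pos"`, `"exp"` or `"rank"`.
#' @param seed RNG seed (used by the affine family's random coefficients).
#' @return A distorted expression tibble with the same genes and samples.
#' @export
corrupt_monotone <- function(expr, family = c("affine_pos", "exp", "rank"), seed = 1L) {
  family <- match.arg(family)
  m <- expr_matrix(expr)
  m <- switch(family,
    affine_pos = with_rng(seed, {
      a <- runif(ncol(m), 0.5, 2)
      b <- runif(ncol(m), -3, 3)
      sweep(sweep(m, 2L, a, `*`), 2L, b, `+`)
    }),
    exp = exp(m / 4),
    rank = apply(m, 2L, rank, ties.method = "average")
  )
  matrix_expr(m)
}

#' Generate synthetic methylation intensities matched to a cohort
#'
#' Background beta values sit near a low (0.1) or high (0.9) methylation mode;
#' the planted differentially methylated sites start at the low mode and gain
#' `beta_shift` in group-1 samples. Methylated/unmethylated intensities are
#' back-solved from the target beta and a log-normal total intensity `T`:
#' `M = beta * (T + 100)`, `U = T - M`, so that `M / (U + M + 100)` equals the
#' target exactly.
#'
#' @param cfg A [synthetic_config()] (fields `n_meth_sites`, `n_dm_sites`,
#'   `beta_shift`, structure seed).
#' @param labels Phenotype labels of the target samples.
#' @param seed Sample-level seed (default derived from `cfg$seed`).
#' @return A list: `meth` (a [methylation_data()] with chromosome annotation)
#'   and `truth` (`dm_sites`, the planted hypermethylated site ids).
#' @export
generate_methylation <- function(cfg, labels, seed = cfg$seed + 5000L) {
  if (!inherits(cfg, "synthetic_config")) {
    abort_config("`cfg` must come from synthetic_config().")
  }
  labels <- as_phenotype_labels(labels)
  n <- nrow(labels)
  st <- with_rng(cfg$seed, {
    site_id <- sprintf("cg%06d", seq_len(cfg$n_meth_sites))
    chromosome <- sample(c(paste0("chr", 1:22), "chrX", "chrY"),
                         cfg$n_meth_sites, replace = TRUE,
                         prob = c(rep(1, 22), 0.5, 0.25))
    mode <- sample(c(0.1, 0.9), cfg$n_meth_sites, replace = TRUE)
    dm <- sample(cfg$n_meth_sites, cfg$n_dm_sites)
    mode[dm] <- 0.1 # planted sites start low so the shift stays inside (0, 1)
    list(site_id = site_id, chromosome = chromosome, mode = mode, dm = dm)
  })
  out <- with_rng(seed, {
    beta <- matrix(st$mode, nrow = cfg$n_meth_sites, ncol = n) +
      matrix(rnorm(cfg$n_meth_sites * n, 0, 0.03), nrow = cfg$n_meth_sites)
    beta[st$dm, labels$group == 1L] <- beta[st$dm, labels$group == 1L] + cfg$beta_shift
    beta <- pmin(pmax(beta, 0.01), 0.95)
    total <- matrix(rlnorm(cfg$n_meth_sites * n, log(2000), 0.3),
                    nrow = cfg$n_meth_sites)
    # guarantee U >= 0: T must exceed beta * 100 / (1 - beta)
    total <- pmax(total, beta * 100 / (1 - beta) + 50)
    M <- beta * (total + 100)
    U <- total - M
    list(M = M, U = U)
  })
  dimnames(out$M) <- dimnames(out$U) <- list(st$site_id, labels$sample_id)
  meth <- methylation_data(out$M, out$U,
                           annotation = tibble(site_id = st$site_id,
                                               chromosome = st$chromosome))
  list(meth = meth, truth = list(dm_sites = st$site_id[sort(st$dm)]))
}
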