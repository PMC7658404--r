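# Allowed configuration schema: section -> permitted keys. Unknown keys are a
# hard config error naming the offending path, so typos never silently change
# a threshold.
pipeline_schema <- list(
  "." = c("seed", "out_dir", "stages", "inputs", "simulate", "train",
          "classify", "evaluate"),
  inputs = c("expr", "labels", "positive_label"),
  simulate = c("n_genes", "n_pos", "n_neg", "n_planted_pairs", "pi_pos",
               "pi_neg", "base_log_mean", "base_log_mean_sd", "noise_sd",
               "overlap_pairs", "dropout_genes", "n_meth_sites", "n_dm_sites",
               "beta_shift"),
  train = c("de_fdr", "pair_fdr", "spacing", "de_method", "log2", "d0",
            "pair_space", "removal_stage", "cohort"),
  classify = c("signature", "expr"),
  evaluate = c("truth", "n_boot")
)

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) {
    abort_config("The pipeline config must be a YAML mapping / named list.")
  }
  check_keys <- function(x, section) {
    allowed <- pipeline_schema[[section]]
    extra <- setdiff(names(x), allowed)
    if (length(extra)) {
      path <- if (section == ".") extra[1L] else paste(section, extra[1L], sep = ".")
      abort_config(sprintf("Unknown config key: %s", path))
    }
  }
  check_keys(cfg, ".")
  for (section in intersect(names(cfg), names(pipeline_schema)[-1L])) {
    if (!is.null(cfg[[section]])) check_keys(cfg[[section]], section)
  }
  if (!is.null(cfg$stages)) {
    bad <- setdiff(cfg$stages, c("simulate", "train", "classify", "evaluate"))
    if (length(bad)) {
      abort_config(sprintf("Unknown stage: %s", bad[1L]))
    }
  }
  invisible(cfg)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[reopairs] ", fmt), ...))
}

#' Run the simulate/train/classify/evaluate pipeline from a config
#'
#' Executes the requested stages in order against a single YAML (or list)
#' configuration, writes every stage artifact under `out_dir` and emits a
#' reproducibility manifest (`manifest.json`) recording the config hash, the
#' seed, the package version, input file digests and the counts at every
#' stage. Re-running with identical inputs reproduces identical stage counts.
#'
#' Thresholds actually applied (DE FDR, pair FDR, spacing, chosen k) are
#' logged to the console and recorded in the manifest.
#'
#' @param config Path to a YAML file, or an equivalent named list. Sections:
#'   `simulate` (arguments of [synthetic_config()]), `train`
#'   ([train_signature()] thresholds), `classify`, `evaluate`, plus `seed`,
#'   `out_dir`, `stages` and optional `inputs` (`expr`, `labels` file paths
#'   used instead of simulation).
#' @param out_dir Output directory (overrides the config).
#' @param seed Seed (overrides the config).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  input_files <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_config(sprintf("Config file not found: %s", config))
    }
    input_files <- config
    config <- yaml::read_yaml(config)
  }
  validate_pipeline_config(config)
  seed <- seed %||% config$seed %||% 1L
  if (!is_count(seed)) {
    abort_config("`seed` must be a single non-negative integer.")
  }
  seed <- as.integer(seed)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) {
    abort_config("An output directory is required (config key `out_dir`).")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% c("simulate", "train", "classify", "evaluate")
  started <- Sys.time()
  counts <- list()
  artifacts <- character(0)
  pipeline_log("seed = %d, stages: %s", seed, paste(stages, collapse = ", "))

  expr <- NULL
  labels <- NULL
  positive <- config$inputs$positive_label %||% "CIMP+"
  if (!is.null(config$inputs$expr)) {
    input_files <- c(input_files, config$inputs$expr, config$inputs$labels)
    expr <- read_expression(config$inputs$expr)
    labels <- read_labels(config$inputs$labels, positive = positive)
  }

  if ("simulate" %in% stages) {
    sim_args <- config$simulate %||% list()
    cfg <- do.call(synthetic_config, c(sim_args, list(seed = seed)))
    cohort <- generate_cohort(cfg)
    expr <- cohort$expr
    labels <- cohort$labels
    write_expression(expr, file.path(out_dir, "expr.tsv"))
    write_labels(labels, file.path(out_dir, "labels.tsv"), positive = positive)
    jsonlite::write_json(
      list(planted_pairs = cohort$truth$planted_pairs,
           delta = cohort$truth$delta,
           dropout_genes = cohort$truth$dropout_genes),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
    artifacts <- c(artifacts, "expr.tsv", "labels.tsv", "truth.json")
    counts$n_genes <- nrow(expr)
    counts$n_samples <- nrow(labels)
    counts$n_planted_pairs <- nrow(cohort$truth$planted_pairs)
    pipeline_log("simulate: %d genes x %d samples, %d planted pairs",
                 counts$n_genes, counts$n_samples, counts$n_planted_pairs)
  }

  sig <- NULL
  if ("train" %in% stages) {
    if (is.null(expr)) {
      abort_config("Training needs simulated data or `inputs.expr`/`inputs.labels`.")
    }
    tr <- config$train %||% list()
    sig <- train_signature(
      expr, labels,
      de_fdr = tr$de_fdr %||% 0.01,
      pair_fdr = tr$pair_fdr %||% 0.01,
      spacing = tr$spacing %||% 0.01,
      de_method = tr$de_method %||% "welch_t",
      log2 = tr$log2 %||% !("simulate" %in% stages),
      d0 = tr$d0 %||% 4,
      pair_space = tr$pair_space %||% "de_by_all",
      removal_stage = tr$removal_stage %||% "per_panel",
      cohort = tr$cohort %||% "training"
    )
    write_signature(sig, file.path(out_dir, "signature.json"))
    artifacts <- c(artifacts, "signature.json")
    tc <- attr(sig, "counts")
    counts$n_de_genes <- tc$n_de_genes
    counts$n_candidate_pairs <- tc$n_candidate_pairs
    counts$n_panels_scanned <- tc$n_panels_scanned
    counts$fd_cutoff <- sig$fd_cutoff
    counts$panel_size <- nrow(sig$pairs)
    counts$k <- sig$k
    pipeline_log(
      "train: de_fdr=%s pair_fdr=%s spacing=%s -> %d DE genes, %d candidate pairs, %d panels; signature %d pairs, fd >= %s, k = %d (F = %.3f)",
      tr$de_fdr %||% 0.01, tr$pair_fdr %||% 0.01, tr$spacing %||% 0.01,
      counts$n_de_genes, counts$n_candidate_pairs, counts$n_panels_scanned,
      counts$panel_size, format(counts$fd_cutoff, digits = 3), counts$k,
      sig$training$f_score
    )
  }

  calls <- NULL
  if ("classify" %in% stages) {
    cl <- config$classify %||% list()
    if (!is.null(cl$signature)) {
      input_files <- c(input_files, cl$signature)
      sig <- read_signature(cl$signature)
    }
    if (is.null(sig)) {
      abort_config("Classification needs a trained or supplied signature.")
    }
    cexpr <- expr
    if (!is.null(cl$expr)) {
      input_files <- c(input_files, cl$expr)
      cexpr <- read_expression(cl$expr)
    }
    if (is.null(cexpr)) {
      abort_config("Classification needs expression data.")
    }
    calls <- classify_samples(cexpr, sig)
    readr::write_tsv(calls, file.path(out_dir, "calls.tsv"))
    artifacts <- c(artifacts, "calls.tsv")
    counts$n_classified <- nrow(calls)
    counts$n_predicted_positive <- sum(calls$predicted == 1L)
    pipeline_log("classify: %d samples, %d called positive (votes >= %d of %d)",
                 counts$n_classified, counts$n_predicted_positive, sig$k,
                 nrow(sig$pairs))
  }

  if ("evaluate" %in% stages) {
    ev <- config$evaluate %||% list()
    truth <- labels
    if (!is.null(ev$truth)) {
      input_files <- c(input_files, ev$truth)
      truth <- read_labels(ev$truth, positive = positive)
    }
    if (is.null(calls) || is.null(truth)) {
      abort_config("Evaluation needs classifications and reference labels.")
    }
    cc <- confusion_counts(calls, truth)
    met <- metrics_from_confusion(cc)
    auc <- roc_auc(calls, truth, n_boot = ev$n_boot %||% 2000L, seed = seed)
    metrics <- list(
      confusion = as.list(cc),
      sensitivity = met$sensitivity, specificity = met$specificity, f = met$f,
      auc = auc$auc, ci = c(auc$ci_lower, auc$ci_upper)
    )
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "metrics.json")
    counts$sensitivity <- met$sensitivity
    counts$specificity <- met$specificity
    counts$f_score <- met$f
    counts$auc <- auc$auc
    pipeline_log("evaluate: sens %.3f, spec %.3f, F %.3f, AUC %.3f",
                 met$sensitivity, met$specificity, met$f, auc$auc)
  }

  input_files <- unique(input_files[!is.na(input_files) & file.exists(input_files)])
  manifest <- list(
    command = "run_pipeline",
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("reopairs")),
    input_digests = as.list(tools::md5sum(input_files)),
    stages = stages,
    counts = counts,
    artifacts = artifacts,
    timestamps = list(started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
                      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
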