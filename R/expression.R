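#' Validate a genes-by-samples expression table
#'
#' An expression table holds one row per gene and one numeric column per
#' sample; the first column carries the gene identifiers. `as_expression()`
#' checks the container invariants — unique gene and sample identifiers,
#' numeric and finite values — and returns the table as a tibble whose first
#' column is named `gene_id`.
#'
#' Values are used as given: no log transform or normalisation is applied,
#' because every downstream ordering statistic is invariant to per-sample
#' monotone transforms. Only the differential-expression stand-in test
#' ([de_screen()]) cares about the scale, via its explicit `log2` flag.
#'
#' @param x A data frame: first column gene identifiers, remaining columns
#'   numeric expression values, column names = sample identifiers.
#' @return A tibble with first column `gene_id` and one numeric column per
#'   sample.
#' @examples
#' as_expression(data.frame(gene = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4)))
#' @export
as_expression <- function(x) {
  if (!is.data.frame(x)) {
    abort_data("An expression table must be a data frame (genes in rows, samples in columns).")
  }
  if (ncol(x) < 2L) {
    abort_data("An expression table needs a gene-identifier column plus at least one sample column.")
  }
  gene_id <- as.character(x[[1L]])
  if (anyNA(gene_id) || any(gene_id == "")) {
    abort_data("Gene identifiers must be non-missing, non-empty strings.")
  }
  if (anyDuplicated(gene_id)) {
    dup <- unique(gene_id[duplicated(gene_id)])
    abort_data(sprintf("Duplicated gene identifiers: %s", fmt_ids(dup)))
  }
  sample_id <- colnames(x)[-1L]
  if (anyDuplicated(sample_id)) {
    dup <- unique(sample_id[duplicated(sample_id)])
    abort_data(sprintf("Duplicated sample identifiers: %s", fmt_ids(dup)))
  }
  vals <- x[-1L]
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(bad_col)) {
    abort_data(sprintf("Non-numeric sample columns: %s", fmt_ids(bad_col)))
  }
  for (s in names(vals)) {
    bad <- which(!is.finite(vals[[s]]))
    if (length(bad)) {
      abort_data(sprintf(
        "Non-finite expression values, e.g. gene '%s', sample '%s'. Impute or drop before use (see `read_expression(impute=)`).",
        gene_id[bad[1L]], s
      ))
    }
  }
  out <- as_tibble(x)
  names(out)[1L] <- "gene_id"
  out$gene_id <- gene_id
  out
}

#' Read an expression matrix from a delimited file
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; every other cell must be numeric. gzip-compressed files are
#' read transparently. Missing cells are rejected by default — silent
#' imputation can flip orderings — with per-row median imputation as the only
#' offered fallback.
#'
#' @param path File path (`.gz` allowed).
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param impute `"none"` (reject missing cells, default) or `"row_median"`.
#' @return A validated expression tibble (see [as_expression()]); row and
#'   column order are preserved from the file.
#' @export
read_expression <- function(path, dialect = c("tsv", "csv"), impute = c("none", "row_median")) {
  dialect <- match.arg(dialect)
  impute <- match.arg(impute)
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: %s", path))
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  raw <- reader(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  if (ncol(raw) < 2L) {
    abort_data(sprintf("'%s' has no sample columns.", path))
  }
  gene_id <- raw[[1L]]
  missing_tokens <- c("", "NA", "na", "N/A")
  out <- vector("list", ncol(raw) - 1L)
  names(out) <- colnames(raw)[-1L]
  for (j in seq_along(out)) {
    s <- colnames(raw)[j + 1L]
    cell <- raw[[j + 1L]]
    is_missing <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is_missing & is.na(num))
    if (length(bad)) {
      abort_data(sprintf(
        "Non-numeric cell at row %d (gene '%s'), column '%s': '%s'",
        bad[1L], gene_id[bad[1L]], s, cell[bad[1L]]
      ))
    }
    out[[j]] <- num
  }
  m <- do.call(cbind, out)
  if (anyNA(m)) {
    if (impute == "none") {
      bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
      abort_data(sprintf(
        "Missing value at gene '%s', sample '%s'. Re-run with impute = \"row_median\" to impute, or fix the file.",
        gene_id[bad[1L]], colnames(m)[bad[2L]]
      ))
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      row <- m[i, ]
      if (all(is.na(row))) {
        abort_data(sprintf("Gene '%s' has no observed values; cannot impute.", gene_id[i]))
      }
      row[is.na(row)] <- stats::median(row, na.rm = TRUE)
      m[i, ] <- row
    }
  }
  as_expression(tibble(gene_id = gene_id, as_tibble(m)))
}

#' Write an expression matrix to a delimited file
#'
#' Values are written with full (shortest round-trippable) precision, so a
#' write/read cycle reproduces the matrix exactly.
#'
#' @param expr Expression tibble (see [as_expression()]).
#' @param path Output path; a `.gz` suffix writes gzip.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  expr <- as_expression(expr)
  if (dialect == "tsv") readr::write_tsv(expr, path) else readr::write_csv(expr, path)
  invisible(expr)
}

# expression tibble -> double matrix with gene rownames
expr_matrix <- function(expr) {
  expr <- as_expression(expr)
  m <- as.matrix(expr[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

matrix_expr <- function(m) {
  tibble(gene_id = rownames(m), as_tibble(m))
}

#' Validate phenotype labels
#'
#' Labels assign each sample to group 1 (the positive class, e.g. CIMP+) or
#' group 2 (the negative class). Accepts either a `group` column already coded
#' 1/2 or a character `label` column together with the `positive` string.
#'
#' @param x Data frame with a `sample_id` column and either an integer `group`
#'   column (values 1 and 2) or a character `label` column.
#' @param positive The label string denoting the positive class when `x`
#'   carries a `label` column (default `"CIMP+"`).
#' @return A tibble with columns `sample_id` (character) and `group`
#'   (integer, 1 = positive, 2 = negative).
#' @export
as_phenotype_labels <- function(x, positive = "CIMP+") {
  if (!is.data.frame(x) || !"sample_id" %in% names(x)) {
    abort_data("Labels must be a data frame with a `sample_id` column.")
  }
  sample_id <- as.character(x$sample_id)
  if (anyDuplicated(sample_id)) {
    abort_data(sprintf(
      "Duplicated sample identifiers in labels: %s",
      fmt_ids(unique(sample_id[duplicated(sample_id)]))
    ))
  }
  if ("group" %in% names(x)) {
    group <- as.integer(x$group)
    if (anyNA(group) || !all(group %in% c(1L, 2L))) {
      abort_data("`group` must contain only 1 (positive class) and 2 (negative class).")
    }
  } else if ("label" %in% names(x)) {
    group <- ifelse(as.character(x$label) == positive, 1L, 2L)
  } else {
    abort_data("Labels need a `group` (1/2) or `label` (character) column.")
  }
  tibble(sample_id = sample_id, group = group)
}

#' Read phenotype labels from a two-column TSV
#'
#' @param path Two-column TSV `sample_id`, `label`.
#' @param positive Label string of the positive class (default `"CIMP+"`).
#' @return A labels tibble (`sample_id`, `group`), see [as_phenotype_labels()].
#' @export
read_labels <- function(path, positive = "CIMP+") {
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: %s", path))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (ncol(x) < 2L) {
    abort_data(sprintf("'%s' must have two columns: sample_id, label.", path))
  }
  names(x)[1:2] <- c("sample_id", "label")
  as_phenotype_labels(x[1:2], positive = positive)
}

#' Write phenotype labels to a two-column TSV
#'
#' @param labels Labels tibble (`sample_id`, `group`).
#' @param path Output path.
#' @param positive,negative Label strings written for groups 1 and 2.
#' @return `labels`, invisibly.
#' @export
write_labels <- function(labels, path, positive = "CIMP+", negative = "CIMP-") {
  labels <- as_phenotype_labels(labels)
  readr::write_tsv(
    tibble(sample_id = labels$sample_id,
           label = ifelse(labels$group == 1L, positive, negative)),
    path
  )
  invisible(labels)
}

# Check that labels refer to samples present in `m` (a matrix or expression
# tibble) and that both groups are non-empty. Returns the validated labels.
check_labels <- function(expr, labels, min_per_group = 1L) {
  labels <- as_phenotype_labels(labels)
  samples <- if (is.matrix(expr)) colnames(expr) else colnames(expr)[-1L]
  missing <- setdiff(labels$sample_id, samples)
  if (length(missing)) {
    abort_data(sprintf("Labeled samples absent from the expression table: %s", fmt_ids(missing)))
  }
  n1 <- sum(labels$group == 1L)
  n2 <- sum(labels$group == 2L)
  if (n1 < min_per_group || n2 < min_per_group) {
    abort_data(sprintf(
      "Both groups need at least %d sample(s); got %d positive and %d negative.",
      min_per_group, n1, n2
    ))
  }
  labels
}
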