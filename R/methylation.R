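#' Methylation beta values from signal intensities
#'
#' The methylation level of a CpG site is estimated from the methylated (M)
#' and unmethylated (U) probe intensities as `M / (U + M + 100)`; the +100
#' regularises low-intensity sites. For finite non-negative intensities the
#' result lies in `[0, 1)` and is strictly increasing in M for fixed U.
#'
#' @param M,U Numeric matrices (or data frames) of identical shape with
#'   non-negative entries.
#' @return A numeric matrix of beta values, same shape and dimnames as `M`.
#' @examples
#' compute_beta(matrix(100), matrix(0)) # 0.5
#' @export
compute_beta <- function(M, U) {
  M <- as.matrix(M)
  U <- as.matrix(U)
  storage.mode(M) <- "double"
  storage.mode(U) <- "double"
  if (!identical(dim(M), dim(U))) {
    abort_data("M and U must have identical dimensions.")
  }
  if (anyNA(M) || anyNA(U) || any(!is.finite(M)) || any(!is.finite(U))) {
    abort_data("M and U must be finite.")
  }
  if (any(M < 0) || any(U < 0)) {
    abort_data("Signal intensities must be non-negative.")
  }
  M / (U + M + 100)
}

#' Bundle methylation intensities with site annotation
#'
#' @param M,U Site-by-sample intensity matrices with site identifiers as
#'   rownames (or expression-style tibbles whose first column is the site id).
#' @param annotation Optional data frame `site_id`, `chromosome`; required by
#'   [filter_sites()].
#' @return An object of class `methylation_data`: a list with `sites`
#'   (tibble `site_id`, `chromosome`), `M`, `U` and derived `beta` matrices.
#' @export
methylation_data <- function(M, U, annotation = NULL) {
  to_mat <- function(x) {
    if (is.data.frame(x)) expr_matrix(x) else {
      x <- as.matrix(x)
      storage.mode(x) <- "double"
      x
    }
  }
  M <- to_mat(M)
  U <- to_mat(U)
  if (is.null(rownames(M)) || is.null(colnames(M))) {
    abort_data("Intensity matrices need site rownames and sample colnames.")
  }
  if (!identical(dimnames(M), dimnames(U))) {
    abort_data("M and U must share identical site and sample identifiers.")
  }
  sites <- tibble(site_id = rownames(M), chromosome = NA_character_)
  if (!is.null(annotation)) {
    if (!all(c("site_id", "chromosome") %in% names(annotation))) {
      abort_data("Site annotation needs `site_id` and `chromosome` columns.")
    }
    annotation <- as_tibble(annotation)
    missing <- setdiff(rownames(M), annotation$site_id)
    if (length(missing)) {
      abort_data(sprintf("Sites missing from the annotation: %s", fmt_ids(missing)))
    }
    idx <- match(rownames(M), annotation$site_id)
    sites$chromosome <- as.character(annotation$chromosome[idx])
  }
  structure(
    list(sites = sites, M = M, U = U, beta = compute_beta(M, U)),
    class = "methylation_data"
  )
}

#' @export
print.methylation_data <- function(x, ...) {
  cat(sprintf(
    "<methylation_data> %d sites x %d samples (beta in [%.3f, %.3f])\n",
    nrow(x$M), ncol(x$M), min(x$beta), max(x$beta)
  ))
  invisible(x)
}

#' Read methylation intensities from paired TSV matrices
#'
#' @param m_path,u_path TSV matrices of methylated / unmethylated intensities
#'   with identical site rows and sample columns.
#' @param annotation_path Optional TSV with columns `site_id`, `chromosome`.
#' @param dialect `"tsv"` or `"csv"`.
#' @return A [methylation_data()] object.
#' @export
read_methylation <- function(m_path, u_path, annotation_path = NULL,
                             dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  M <- read_expression(m_path, dialect = dialect)
  U <- read_expression(u_path, dialect = dialect)
  anno <- NULL
  if (!is.null(annotation_path)) {
    anno <- readr::read_tsv(annotation_path,
                            col_types = readr::cols(.default = readr::col_character()),
                            progress = FALSE)
    names(anno)[1:2] <- c("site_id", "chromosome")
  }
  methylation_data(M, U, annotation = anno)
}

#' Restrict methylation data to shared sites off excluded chromosomes
#'
#' Keeps exactly the sites that belong to `shared_sites` (e.g. the
#' intersection of two array manifests) and whose chromosome is not excluded
#' (sex chromosomes by default); site order is preserved. An empty result is
#' a warning, not an error.
#'
#' @param data A [methylation_data()] object with chromosome annotation.
#' @param shared_sites Character vector of site identifiers to keep.
#' @param excluded_chroms Chromosomes to drop (default `c("chrX", "chrY")`).
#' @return A filtered `methylation_data` object.
#' @export
filter_sites <- function(data, shared_sites, excluded_chroms = c("chrX", "chrY")) {
  if (!inherits(data, "methylation_data")) {
    abort_data("`data` must be a methylation_data object.")
  }
  if (anyNA(data$sites$chromosome)) {
    abort_data("Chromosome annotation is required to filter sites.")
  }
  keep <- data$sites$site_id %in% shared_sites &
    !(data$sites$chromosome %in% excluded_chroms)
  if (!any(keep)) {
    rlang::warn("No sites survive the filter; returning an empty methylation_data.")
  }
  structure(
    list(
      sites = data$sites[keep, , drop = FALSE],
      M = data$M[keep, , drop = FALSE],
      U = data$U[keep, , drop = FALSE],
      beta = data$beta[keep, , drop = FALSE]
    ),
    class = "methylation_data"
  )
}
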