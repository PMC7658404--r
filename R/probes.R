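#' Read a probe-to-gene map
#'
#' The file has two columns, `probe_id` and `gene_id`. An empty `gene_id`
#' marks an unmapped probe; the same `probe_id` repeated with different gene
#' identifiers marks a multimapped probe. Both are discarded by
#' [collapse_probes()].
#'
#' @param path Two-column TSV.
#' @return A tibble with one row per probe: `probe_id`, `gene_id` (`NA` when
#'   unmapped or multimapped) and `multimapped` (logical).
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: %s", path))
  }
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       na = character(), progress = FALSE)
  if (ncol(x) < 2L) {
    abort_data(sprintf("'%s' must have two columns: probe_id, gene_id.", path))
  }
  names(x)[1:2] <- c("probe_id", "gene_id")
  x$gene_id[x$gene_id == ""] <- NA_character_
  x[1:2] |>
    dplyr::distinct() |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(
      multimapped = dplyr::n_distinct(.data$gene_id[!is.na(.data$gene_id)]) > 1L,
      gene_id = if (multimapped[1L]) NA_character_ else .data$gene_id[1L],
      .groups = "drop"
    ) |>
    dplyr::select("probe_id", "gene_id", "multimapped")
}

as_probe_map <- function(map) {
  if (!is.data.frame(map) || !all(c("probe_id", "gene_id") %in% names(map))) {
    abort_data("A probe map needs `probe_id` and `gene_id` columns.")
  }
  map <- as_tibble(map)
  map$probe_id <- as.character(map$probe_id)
  map$gene_id <- as.character(map$gene_id)
  map$gene_id[!is.na(map$gene_id) & map$gene_id == ""] <- NA_character_
  if (!"multimapped" %in% names(map)) map$multimapped <- FALSE
  if (anyDuplicated(map$probe_id)) {
    abort_data(sprintf(
      "Probe map must have one row per probe; duplicated: %s",
      fmt_ids(unique(map$probe_id[duplicated(map$probe_id)]))
    ))
  }
  map$gene_id[map$multimapped] <- NA_character_
  map
}

#' Collapse probe-level measurements to gene level
#'
#' Probes mapping to the same gene are averaged (arithmetic mean on the loaded
#' scale) to obtain a single measurement per gene and sample. Probes that map
#' to no gene, or to multiple genes, are discarded. Output genes are sorted
#' lexicographically, so the result does not depend on probe row order.
#'
#' @param probe_expr Probe-level expression tibble (first column probe ids).
#' @param map Probe map (see [read_probe_map()]); every probe in `probe_expr`
#'   must appear in it.
#' @return A gene-level expression tibble.
#' @examples
#' pe <- tibble::tibble(probe_id = c("p1", "p2"), s1 = c(2, 4))
#' pm <- tibble::tibble(probe_id = c("p1", "p2"), gene_id = "gA")
#' collapse_probes(pe, pm) # gA = 3
#' @export
collapse_probes <- function(probe_expr, map) {
  probe_expr <- as_expression(probe_expr)
  map <- as_probe_map(map)
  absent <- setdiff(probe_expr$gene_id, map$probe_id)
  if (length(absent)) {
    abort_data(sprintf("Probes absent from the probe map: %s", fmt_ids(absent)))
  }
  gene_of <- setNames(map$gene_id, map$probe_id)[probe_expr$gene_id]
  keep <- !is.na(gene_of)
  if (!any(keep)) {
    abort_data("No probe maps to a gene; nothing to collapse.")
  }
  m <- as.matrix(probe_expr[keep, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  g <- gene_of[keep]
  sums <- rowsum(m, group = g, reorder = TRUE)
  counts <- as.vector(rowsum(rep(1, length(g)), group = g, reorder = TRUE))
  out <- sums / counts
  as_expression(tibble(gene_id = rownames(out), as_tibble(out)))
}
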