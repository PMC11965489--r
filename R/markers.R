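#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the smaller group has at most 8 values and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param group_a,group_b Numeric vectors; missing values dropped.
#'
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b)) {
    abort("Both groups must contain non-missing values.")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (min(length(a), length(b)) <= 8 && !ties) {
    wilcox.test(a, b, exact = TRUE)$p.value
  } else {
    suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
  }
}

#' Rank CpGs as markers of one cell type
#'
#' For each CpG, the mean-beta difference between the target cell type and
#' all other samples and a two-sided Wilcoxon rank-sum p-value are
#' computed. CpGs are ranked by descending `|delta|` and by ascending `p`
#' (average ranks for ties), the two rankings are combined by their
#' geometric mean, and the CpGs with the lowest combined rank are selected.
#' Selection ties are broken by larger `|delta|`, then CpG id.
#'
#' @param beta CpG x sample matrix of reference betas.
#' @param labels Cell-type label per sample (aligned with columns).
#' @param target The cell type to find markers for.
#' @param n_top Number of marker CpGs to select.
#'
#' @return A list with `ranking` (tibble: `cpg_id`, `delta`, `p`,
#'   `rank_delta`, `rank_p`, `combined_rank`) and `selected` (character
#'   vector of `n_top` CpG ids in selection order).
#' @export
rank_markers <- function(beta, labels, target, n_top = 100) {
  check_beta_matrix(beta)
  labels <- as.character(labels)
  if (length(labels) != ncol(beta)) {
    abort("`labels` must align with the columns of `beta`.")
  }
  in_target <- labels == target
  if (sum(in_target) < 2 || sum(!in_target) < 2) {
    abort("At least 2 samples are required inside and outside the target type.")
  }
  if (n_top > nrow(beta)) abort("`n_top` exceeds the number of CpGs.")
  tgt <- beta[, in_target, drop = FALSE]
  rest <- beta[, !in_target, drop = FALSE]
  delta <- rowMeans(tgt, na.rm = TRUE) - rowMeans(rest, na.rm = TRUE)
  p <- vapply(seq_len(nrow(beta)), function(i) {
    wilcoxon_rank_sum(tgt[i, ], rest[i, ])
  }, numeric(1))
  rank_delta <- rank(-abs(delta), ties.method = "average")
  rank_p <- rank(p, ties.method = "average")
  ranking <- tibble::tibble(
    cpg_id = rownames(beta),
    delta = unname(delta),
    p = p,
    rank_delta = unname(rank_delta),
    rank_p = unname(rank_p),
    combined_rank = sqrt(unname(rank_delta) * unname(rank_p))
  )
  ord <- order(ranking$combined_rank, -abs(ranking$delta), ranking$cpg_id)
  list(ranking = ranking, selected = ranking$cpg_id[ord][seq_len(n_top)])
}

#' Build a cell-type reference panel
#'
#' Runs [rank_markers()] for every listed cell type, takes the union of
#' the per-type marker selections (duplicates collapsed), and fills the
#' panel with the mean beta of each marker CpG within each cell type
#' (complete-case per CpG).
#'
#' @param beta CpG x sample matrix of reference betas.
#' @param labels Cell-type label per sample.
#' @param types Cell types to include as panel columns (default: all
#'   observed labels).
#' @param n_top_per_type Markers selected per type before the union.
#' @param level Panel level tag (`"primary"`, `"immune-subtype"`,
#'   `"epithelial-subtype"`, or free text).
#'
#' @return A `reference_panel`: marker-CpG x cell-type matrix of mean betas
#'   with attributes `level`, `n_top_per_type`, and `markers` (the per-type
#'   selections).
#' @export
build_panel <- function(beta, labels, types = unique(labels),
                        n_top_per_type = 100, level = "primary") {
  labels <- as.character(labels)
  for (ty in types) {
    if (!any(labels == ty)) abort(sprintf("Cell type '%s' has no samples.", ty))
  }
  selections <- lapply(types, function(ty) {
    rank_markers(beta, labels, ty, n_top = n_top_per_type)$selected
  })
  names(selections) <- types
  marker_cpgs <- sort(unique(unlist(selections)))
  panel <- vapply(types, function(ty) {
    rowMeans(beta[marker_cpgs, labels == ty, drop = FALSE], na.rm = TRUE)
  }, numeric(length(marker_cpgs)))
  panel <- matrix(panel, nrow = length(marker_cpgs),
                  dimnames = list(marker_cpgs, types))
  structure(panel, class = c("reference_panel", class(panel)),
            level = level, n_top_per_type = n_top_per_type,
            markers = selections)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel: %d CpGs x %d cell types, level '%s'>\n",
              nrow(x), ncol(x), attr(x, "level")))
  print(utils::head(unclass(x)))
  invisible(x)
}

#' Write / read a reference panel
#'
#' The panel matrix is written as TSV (CpG id first column, one column per
#' cell type) with a JSON sidecar (`<path>.json`) recording the panel
#' level, per-type marker count, and the per-type marker selections.
#'
#' @param panel A [build_panel()] result.
#' @param path TSV file path.
#'
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   the `reference_panel`.
#' @export
write_panel <- function(panel, path) {
  df <- dplyr::bind_cols(tibble::tibble(cpg_id = rownames(panel)),
                         tibble::as_tibble(unclass(panel)))
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(level = attr(panel, "level"),
         n_top_per_type = attr(panel, "n_top_per_type"),
         markers = attr(panel, "markers")),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df$cpg_id
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(m, class = c("reference_panel", class(m)),
            level = meta$level, n_top_per_type = meta$n_top_per_type,
            markers = as.list(meta$markers))
}
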