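#' Estimate cell-type fractions by constrained projection
#'
#' Each bulk sample's beta values at the panel CpGs are regressed onto the
#' panel columns by non-negative least squares; the fitted coefficients
#' are renormalized to sum to 1. Missing CpGs are dropped per sample;
#' samples covering less than `min_overlap` of the panel CpGs raise an
#' error. Fractions below `1e-6` after renormalization are snapped to 0
#' and the vector renormalized once more, stabilising downstream ratios.
#'
#' @param bulk CpG x sample matrix of bulk betas (any superset of the
#'   panel CpGs; restricted internally).
#' @param panel A [build_panel()] result or plain CpG x cell-type matrix.
#' @param min_overlap Minimum fraction of panel CpGs a sample must cover.
#'
#' @return A tibble of class `fraction_estimate`: `sample_id`, one column
#'   per cell type (fractions in `[0, 1]` summing to 1), and `residual`
#'   (root-mean-square residual of the constrained fit). The panel level
#'   is stored in the `"panel_level"` attribute.
#' @export
deconvolve <- function(bulk, panel, min_overlap = 0.8) {
  check_beta_matrix(bulk)
  types <- colnames(panel)
  common <- intersect(rownames(panel), rownames(bulk))
  if (length(common) < min_overlap * nrow(panel)) {
    abort(sprintf(
      "Only %d of %d panel CpGs present in the bulk matrix (floor %.0f%%).",
      length(common), nrow(panel), 100 * min_overlap
    ))
  }
  P <- unclass(panel)[common, , drop = FALSE]
  if (qr(P)$rank < ncol(P)) {
    abort("Reference panel is rank-deficient (collinear cell-type columns).")
  }
  B <- bulk[common, , drop = FALSE]
  fits <- purrr::map(seq_len(ncol(B)), function(j) {
    y <- B[, j]
    ok <- !is.na(y)
    if (sum(ok) < min_overlap * nrow(panel)) {
      abort(sprintf(
        "Sample '%s' covers only %d of %d panel CpGs (floor %.0f%%).",
        colnames(B)[j], sum(ok), nrow(panel), 100 * min_overlap
      ))
    }
    fit <- pracma::lsqnonneg(P[ok, , drop = FALSE], y[ok])
    w <- fit$x
    if (sum(w) <= 0) {
      w <- rep(1 / length(w), length(w))
    } else {
      w <- w / sum(w)
    }
    w[w < 1e-6] <- 0
    w <- w / sum(w)
    resid <- y[ok] - P[ok, , drop = FALSE] %*% fit$x
    tibble::tibble(sample_id = colnames(B)[j],
                   !!!setNames(as.list(w), types),
                   residual = sqrt(mean(resid^2)))
  })
  out <- dplyr::bind_rows(fits)
  attr(out, "panel_level") <- attr(panel, "level") %||% "unknown"
  class(out) <- c("fraction_estimate", class(out))
  out
}

#' Hierarchical deconvolution of a parent cell type into subtypes
#'
#' Runs a flat deconvolution against the primary panel, a second
#' deconvolution against a subtype panel whose types partition one parent
#' type, and rescales the subtype fractions so they sum to the parent
#' fraction; all non-parent fractions pass through unchanged. The expanded
#' vector sums to 1 whenever the flat one did.
#'
#' @param bulk CpG x sample matrix of bulk betas.
#' @param primary_panel Panel containing `parent_type` as a column.
#' @param subtype_panel Panel whose cell types partition `parent_type`.
#' @param parent_type Name of the column of `primary_panel` being split.
#' @param min_overlap Coverage floor passed to both fits.
#'
#' @return A `fraction_estimate` tibble over the expanded type set
#'   (non-parent primary types plus subtype columns).
#' @export
hierarchical_deconvolve <- function(bulk, primary_panel, subtype_panel,
                                    parent_type, min_overlap = 0.8) {
  if (!parent_type %in% colnames(primary_panel)) {
    abort(sprintf("'%s' is not a column of the primary panel.", parent_type))
  }
  primary <- deconvolve(bulk, primary_panel, min_overlap = min_overlap)
  sub <- tryCatch(
    deconvolve(bulk, subtype_panel, min_overlap = min_overlap),
    error = function(e) {
      abort(paste0("Subtype fit failed: ", conditionMessage(e)))
    }
  )
  sub_types <- colnames(subtype_panel)
  parent_frac <- primary[[parent_type]]
  sub_scaled <- as.matrix(sub[sub_types]) * parent_frac
  out <- primary |>
    dplyr::select(-dplyr::all_of(parent_type), -"residual") |>
    dplyr::bind_cols(tibble::as_tibble(sub_scaled)) |>
    dplyr::mutate(residual = primary$residual)
  attr(out, "panel_level") <- paste0(
    attr(primary_panel, "level") %||% "primary", "+",
    attr(subtype_panel, "level") %||% "subtype"
  )
  class(out) <- c("fraction_estimate", class(out))
  out
}

#' Granulocyte / lymphocyte ratio from immune-subtype fractions
#'
#' @param fractions A `fraction_estimate` over immune subtypes.
#' @param granulocytes Cell types counted as granulocytes (those present
#'   in `fractions` are used).
#' @param lymphocytes Cell types counted as lymphocytes.
#'
#' @return A tibble with `sample_id` and `glr`; samples with zero
#'   lymphocyte fraction get `Inf` with a warning.
#' @export
granulocyte_lymphocyte_ratio <- function(fractions,
                                         granulocytes = c("neutrophil", "MDSC"),
                                         lymphocytes = c("B", "NK",
                                                         "CD4T", "CD8T")) {
  gran <- intersect(granulocytes, names(fractions))
  lym <- intersect(lymphocytes, names(fractions))
  if (!length(gran) || !length(lym)) {
    abort("`fractions` must include at least one granulocyte and one lymphocyte type.")
  }
  g <- rowSums(as.matrix(fractions[gran]))
  l <- rowSums(as.matrix(fractions[lym]))
  if (any(l == 0)) {
    warn("Zero lymphocyte fraction in some samples; ratio reported as Inf.")
  }
  tibble::tibble(sample_id = fractions$sample_id, glr = g / l)
}

#' Tidy a fraction estimate into long format
#'
#' @param x A `fraction_estimate`.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `cell_type`, `fraction`.
#' @export
tidy.fraction_estimate <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = -c("sample_id", "residual"),
                        names_to = "cell_type", values_to = "fraction") |>
    dplyr::select("sample_id", "cell_type", "fraction")
}

#' Stacked-bar plot of estimated cell-type fractions
#'
#' @param object A `fraction_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fraction_estimate <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                 fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated fraction", fill = "cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
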