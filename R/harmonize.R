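#' Locate the two modes of a bimodal beta-value distribution
#'
#' Beta values from methylation assays concentrate near the unmethylated
#' and methylated extremes. This finds the two modes by kernel density
#' estimation: local maxima of the density are located and the highest
#' maximum on each side of 0.5 is returned.
#'
#' @param values Numeric vector of beta values in `[0, 1]`; at least 100
#'   values spanning both tails are expected for a stable estimate.
#' @param bw Density bandwidth passed to [stats::density()].
#'
#' @return Numeric vector `c(lower, upper)` with the lower mode in
#'   `[0, 0.5)` and the upper mode in `[0.5, 1]`. Errors if either side
#'   holds no local maximum (unimodal input).
#' @export
estimate_beta_modes <- function(values, bw = "nrd0") {
  values <- values[!is.na(values)]
  if (length(values) < 100) {
    abort("At least 100 non-missing values are required to locate modes.")
  }
  d <- density(values, bw = bw, from = -0.05, to = 1.05, n = 2048)
  y <- d$y
  peak <- which(y > dplyr::lag(y, default = -Inf) &
                  y >= dplyr::lead(y, default = -Inf))
  modes <- d$x[peak]
  lower <- modes[modes < 0.5]
  upper <- modes[modes >= 0.5]
  if (!length(lower) || !length(upper)) {
    abort("Distribution is not bimodal: no density maximum on one side of 0.5.")
  }
  lo <- lower[which.max(y[peak][modes < 0.5])]
  hi <- upper[which.max(y[peak][modes >= 0.5])]
  c(lower = clamp01(lo), upper = clamp01(hi))
}

#' Linear transform matching sequencing modes onto array modes
#'
#' Sequencing beta values (read proportions) have distribution modes at
#' exactly 0 and 1, while array betas mode at interior values because of
#' background intensity. The unique line mapping the source mode pair onto
#' the target mode pair aligns the two distributions:
#' `slope = (t_hi - t_lo) / (s_hi - s_lo)`,
#' `intercept = t_lo - slope * s_lo`. With sequencing modes `(0, 1)` and
#' array modes `(0.017, 0.955)` this gives
#' `beta_adjusted = 0.938 * beta + 0.017`.
#'
#' @param source_modes Mode pair of the distribution to be rescaled
#'   (lower, upper); must be distinct.
#' @param target_modes Mode pair to map onto; distinct and ordered.
#'
#' @return A list of class `linear_transform` with `slope` and `intercept`.
#' @export
derive_mode_matching_transform <- function(source_modes, target_modes) {
  s <- as.numeric(source_modes)
  t <- as.numeric(target_modes)
  if (length(s) != 2 || length(t) != 2) abort("Mode pairs must have length 2.")
  if (abs(s[2] - s[1]) < .Machine$double.eps) {
    abort("Source modes coincide; the transform is undefined.")
  }
  if (t[1] >= t[2]) abort("Target modes must be strictly ordered.")
  slope <- (t[2] - t[1]) / (s[2] - s[1])
  intercept <- t[1] - slope * s[1]
  if (slope <= 0) abort("Transform slope must be positive.")
  structure(list(slope = slope, intercept = intercept),
            class = "linear_transform")
}

#' @export
print.linear_transform <- function(x, ...) {
  cat(sprintf("beta_adjusted = %.4g * beta + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

#' Rescale sequencing beta values onto the array scale
#'
#' Applies `slope * beta + intercept` elementwise, clamped to `[0, 1]`
#' (a no-op for mode-matching transforms between distributions inside the
#' unit interval, but a guard for user-supplied lines). Missing entries
#' stay missing; ordering of beta values is preserved since the slope is
#' positive.
#'
#' @param beta CpG x sample matrix of sequencing betas in `[0, 1]`.
#' @param transform A [derive_mode_matching_transform()] result.
#'
#' @return The rescaled matrix.
#' @export
harmonize_sequencing_betas <- function(beta, transform) {
  check_beta_matrix(beta)
  if (!inherits(transform, "linear_transform")) {
    abort("`transform` must be a linear_transform.")
  }
  out <- transform$slope * beta + transform$intercept
  out[!is.na(out)] <- clamp01(out[!is.na(out)])
  out
}

#' Select CpGs usable across array and sequencing datasets
#'
#' The array defines the CpG universe. A CpG is retained when it is
#' present on the array, covered (not entirely missing) in every RRBS
#' dataset, and missing in at most `max_missing_fraction` of all samples
#' pooled across datasets (strict `>` excludes).
#'
#' @param datasets Named list of CpG x sample beta matrices.
#' @param platforms Named character vector (`"array"`, `"WGBS"`, `"RRBS"`)
#'   aligned with `datasets`; at least one array dataset is required.
#' @param max_missing_fraction Maximum tolerated overall missingness.
#'
#' @return Character vector of retained CpG ids.
#' @export
filter_cross_platform_cpgs <- function(datasets, platforms,
                                       max_missing_fraction = 0.10) {
  if (is.null(names(datasets)) || !setequal(names(datasets), names(platforms))) {
    abort("`datasets` and `platforms` must share the same names.")
  }
  platforms <- platforms[names(datasets)]
  array_sets <- names(datasets)[platforms == "array"]
  if (!length(array_sets)) {
    abort("At least one array dataset is required to define the CpG universe.")
  }
  universe <- Reduce(union, lapply(datasets[array_sets], rownames))
  keep <- universe
  for (nm in names(datasets)[platforms == "RRBS"]) {
    m <- datasets[[nm]]
    covered <- rownames(m)[rowSums(!is.na(m)) > 0]
    keep <- intersect(keep, covered)
  }
  if (!length(keep)) abort("No CpGs survive the cross-platform intersection.")
  missing_counts <- rep(0, length(keep))
  names(missing_counts) <- keep
  n_samples <- 0
  for (m in datasets) {
    n_samples <- n_samples + ncol(m)
    idx <- match(keep, rownames(m))
    miss <- matrix(TRUE, length(keep), ncol(m))
    found <- !is.na(idx)
    miss[found, ] <- is.na(m[idx[found], , drop = FALSE])
    missing_counts <- missing_counts + rowSums(miss)
  }
  retained <- keep[missing_counts / n_samples <= max_missing_fraction]
  if (!length(retained)) abort("No CpGs survive the missingness filter.")
  sort(retained)
}
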