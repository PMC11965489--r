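#' Quality-control thresholds
#'
#' Container for the sample/probe QC cascade parameters. Defaults are the
#' customary mouse-array cutoffs: samples with median methylated or
#' unmethylated log2 intensity below 9.5 are removed; probes with detection
#' p-value above 0.01 are failed; samples and then probes with more than
#' 10% failures are removed; the covariate check uses the 1000 most
#' variable probes and the top 10 principal components.
#'
#' @param min_median_log_intensity Minimum per-sample median log2 intensity
#'   (applies to both the methylated and unmethylated channel).
#' @param detection_p_max Detection p-value above which a measurement is
#'   regarded as failed.
#' @param max_sample_failed_fraction Samples failing more than this
#'   fraction of probes are removed (strict `>`).
#' @param max_probe_failed_fraction Probes failing in more than this
#'   fraction of retained samples are removed (strict `>`).
#' @param n_variable_probes Probes entering the PCA, ranked by standard
#'   deviation.
#' @param n_pcs Principal components tested against covariates.
#'
#' @return A validated `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_median_log_intensity = 9.5,
                          detection_p_max = 0.01,
                          max_sample_failed_fraction = 0.10,
                          max_probe_failed_fraction = 0.10,
                          n_variable_probes = 1000,
                          n_pcs = 10) {
  structure(
    list(
      min_median_log_intensity = as.numeric(min_median_log_intensity),
      detection_p_max = check_fraction(detection_p_max, "detection_p_max"),
      max_sample_failed_fraction =
        check_fraction(max_sample_failed_fraction, "max_sample_failed_fraction"),
      max_probe_failed_fraction =
        check_fraction(max_probe_failed_fraction, "max_probe_failed_fraction"),
      n_variable_probes = check_count(n_variable_probes, "n_variable_probes"),
      n_pcs = check_count(n_pcs, "n_pcs")
    ),
    class = "qc_thresholds"
  )
}

#' Remove samples with low median array intensities
#'
#' A sample is removed when its median methylated *or* median unmethylated
#' log2 intensity falls strictly below the threshold; samples at exactly
#' the threshold are retained.
#'
#' @param intensities Data frame with columns `sample_id`, `median_meth`,
#'   `median_unmeth` (log2 intensity units).
#' @param thresholds A [qc_thresholds()].
#'
#' @return A tibble with one row per sample: `sample_id`, the two medians,
#'   `removed` (logical), and `reason` (`NA` for retained samples).
#' @export
filter_low_intensity_samples <- function(intensities,
                                         thresholds = qc_thresholds()) {
  required <- c("sample_id", "median_meth", "median_unmeth")
  missing_cols <- setdiff(required, names(intensities))
  if (length(missing_cols)) {
    abort(paste0("`intensities` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(intensities$median_meth) || anyNA(intensities$median_unmeth)) {
    abort("Both intensity medians must be present for every sample.")
  }
  cut <- thresholds$min_median_log_intensity
  tibble::as_tibble(intensities[required]) |>
    dplyr::mutate(
      removed = .data$median_meth < cut | .data$median_unmeth < cut,
      reason = dplyr::if_else(
        .data$removed,
        sprintf("median intensity below %g", cut),
        NA_character_
      )
    )
}

#' Apply the detection-failure QC cascade
#'
#' Measurements with detection p-value above `detection_p_max` are marked
#' failed and their beta values set missing. Then, in this order: samples
#' whose failed fraction exceeds `max_sample_failed_fraction` are removed,
#' and probes whose failed fraction — recomputed over the retained samples —
#' exceeds `max_probe_failed_fraction` are removed. Both comparisons are
#' strict. Re-running the cascade on its own output removes nothing.
#'
#' @param beta CpG x sample matrix of beta values.
#' @param detection_p CpG x sample matrix of detection p-values, same
#'   dimensions and dimnames as `beta`.
#' @param thresholds A [qc_thresholds()].
#'
#' @return A list of class `qc_report` with `beta` (filtered matrix, failed
#'   cells set `NA`), `removed_samples` (tibble of `sample_id`, `reason`,
#'   `failed_fraction`), `removed_probes` (tibble of `cpg_id`,
#'   `failed_fraction`), and `failure_mask` (logical matrix on the input
#'   dimensions).
#' @export
apply_failure_cascade <- function(beta, detection_p,
                                  thresholds = qc_thresholds()) {
  check_beta_matrix(beta)
  if (!identical(dim(beta), dim(detection_p))) {
    abort("`detection_p` dimensions must match `beta`.")
  }
  failed <- detection_p > thresholds$detection_p_max
  failed[is.na(failed)] <- TRUE
  beta[failed] <- NA_real_

  sample_frac <- colMeans(failed)
  drop_samples <- sample_frac > thresholds$max_sample_failed_fraction
  kept <- beta[, !drop_samples, drop = FALSE]
  kept_failed <- failed[, !drop_samples, drop = FALSE]

  probe_frac <- rowMeans(kept_failed)
  drop_probes <- probe_frac > thresholds$max_probe_failed_fraction
  kept <- kept[!drop_probes, , drop = FALSE]

  structure(
    list(
      beta = kept,
      removed_samples = tibble::tibble(
        sample_id = colnames(beta)[drop_samples],
        reason = sprintf("failed fraction %.3f > %g",
                         sample_frac[drop_samples],
                         thresholds$max_sample_failed_fraction),
        failed_fraction = unname(sample_frac[drop_samples])
      ),
      removed_probes = tibble::tibble(
        cpg_id = rownames(beta)[drop_probes],
        failed_fraction = unname(probe_frac[drop_probes])
      ),
      failure_mask = failed
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC failure cascade:",
      nrow(x$removed_samples), "sample(s) and",
      nrow(x$removed_probes), "probe(s) removed;",
      ncol(x$beta), "samples x", nrow(x$beta), "probes retained.\n")
  invisible(x)
}

#' Test principal components for covariate associations
#'
#' Selects the most variable probes (sample standard deviation, `n - 1`
#' denominator, ties broken by CpG id), computes principal components over
#' samples, and tests each covariate against each component: numeric
#' covariates by the two-sided test of zero Pearson correlation,
#' categorical covariates by Kruskal-Wallis. P-values are reported raw for
#' inspection; no multiplicity correction is applied.
#'
#' @param beta CpG x sample matrix; probes with missing values are dropped
#'   before ranking.
#' @param covariates Data frame with `sample_id` plus one column per
#'   covariate to test. Constant covariates are skipped with a warning.
#' @param thresholds A [qc_thresholds()] supplying `n_variable_probes` and
#'   `n_pcs`.
#'
#' @return A tibble with `covariate`, `pc`, `test`, `statistic`, `p_value`.
#' @export
pc_covariate_check <- function(beta, covariates,
                               thresholds = qc_thresholds()) {
  check_beta_matrix(beta)
  if (ncol(beta) < 2) abort("At least 2 samples are required.")
  if (!"sample_id" %in% names(covariates)) {
    abort("`covariates` must have a `sample_id` column.")
  }
  covariates <- covariates[match(colnames(beta), covariates$sample_id), ,
                           drop = FALSE]
  if (anyNA(covariates$sample_id)) {
    abort("`covariates` must cover every sample in `beta`.")
  }
  complete <- beta[stats::complete.cases(beta), , drop = FALSE]
  n_take <- thresholds$n_variable_probes
  if (nrow(complete) < n_take) {
    warn(sprintf("Only %d complete probes available; using all of them.",
                 nrow(complete)))
    n_take <- nrow(complete)
  }
  sds <- apply(complete, 1, sd)
  ord <- order(-sds, rownames(complete))
  top <- complete[ord[seq_len(n_take)], , drop = FALSE]
  n_pcs <- min(thresholds$n_pcs, ncol(top) - 1, nrow(top))
  pcs <- prcomp(t(top), center = TRUE, scale. = FALSE)$x[, seq_len(n_pcs),
                                                         drop = FALSE]
  cov_names <- setdiff(names(covariates), "sample_id")
  rows <- purrr::map(cov_names, function(nm) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warn(sprintf("Covariate '%s' is constant; skipped.", nm))
      return(NULL)
    }
    purrr::map(seq_len(n_pcs), function(j) {
      if (is.numeric(v)) {
        ct <- cor.test(v, pcs[, j])
        tibble::tibble(covariate = nm, pc = j, test = "pearson",
                       statistic = unname(ct$statistic),
                       p_value = ct$p.value)
      } else {
        kw <- kruskal.test(pcs[, j], factor(v))
        tibble::tibble(covariate = nm, pc = j, test = "kruskal-wallis",
                       statistic = unname(kw$statistic),
                       p_value = kw$p.value)
      }
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
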