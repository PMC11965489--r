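#' Run the discovery stage: QC, ranking, signature definition
#'
#' End-to-end discovery analysis: the detection-failure QC cascade (when
#' detection p-values are supplied), automatic exclusion of tumor-labelled
#' samples, per-tissue exposure rankings, geometric-mean combination, and
#' carcinogen-signature definition with scaling anchored in healthy
#' samples of `scale_tissue`. Stage counts are logged as messages.
#'
#' @param beta CpG x sample matrix of the discovery cohort.
#' @param samples Sample sheet with `sample_id`, `tissue`, `exposure`.
#' @param detection_p Optional CpG x sample detection p-value matrix.
#' @param intensities Optional per-sample intensity medians for
#'   [filter_low_intensity_samples()].
#' @param thresholds A [qc_thresholds()].
#' @param k Signature size per direction.
#' @param scale_tissue Tissue anchoring the score scaling.
#' @param tumor_tissues Tissue labels excluded from signature development.
#' @param output_dir Optional directory: the signature JSON and QC tables
#'   are written there.
#'
#' @return A list with `signature` (a `carcinogen_signature`), `qc`
#'   (a `qc_report` or `NULL`), `removed_low_intensity` (tibble or `NULL`),
#'   and `n_samples_used` / `n_cpgs_used`.
#' @export
run_discovery <- function(beta, samples, detection_p = NULL,
                          intensities = NULL,
                          thresholds = qc_thresholds(), k = 1000,
                          scale_tissue = "mammary_gland",
                          tumor_tissues = c("mammary_tumor", "tumor"),
                          output_dir = NULL) {
  check_beta_matrix(beta)
  for (nm in c("sample_id", "tissue", "exposure")) {
    if (!nm %in% names(samples)) {
      abort(sprintf(
        "Discovery sample sheet lacks required column '%s'.", nm
      ))
    }
  }

  low_int <- NULL
  if (!is.null(intensities)) {
    low_int <- filter_low_intensity_samples(intensities, thresholds)
    keep <- low_int$sample_id[!low_int$removed]
    beta <- beta[, colnames(beta) %in% keep, drop = FALSE]
    if (!is.null(detection_p)) {
      detection_p <- detection_p[, colnames(beta), drop = FALSE]
    }
    log_stage("qc/intensity", sum(low_int$removed), " sample(s) removed, ",
              ncol(beta), " retained")
  }

  qc <- NULL
  if (!is.null(detection_p)) {
    qc <- apply_failure_cascade(beta, detection_p, thresholds)
    beta <- qc$beta
    log_stage("qc/cascade", nrow(qc$removed_samples), " sample(s), ",
              nrow(qc$removed_probes), " probe(s) removed; ",
              nrow(beta), " CpGs x ", ncol(beta), " samples retained")
  }

  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  normal <- !(samples$tissue %in% tumor_tissues)
  if (any(!normal)) {
    log_stage("signature", sum(!normal),
              " tumor sample(s) excluded from signature development")
  }
  beta <- beta[, normal, drop = FALSE]
  samples <- samples[normal, , drop = FALSE]

  signature <- define_carcinogen_signature(beta, samples, k = k,
                                           scale_tissue = scale_tissue)
  log_stage("signature", "defined ", length(signature$hyper_cpgs),
            " hyper + ", length(signature$hypo_cpgs), " hypo CpGs; scale (",
            signif(signature$scale_location, 4), ", ",
            signif(signature$scale_spread, 4), ")")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_signature(signature, file.path(output_dir, "carcinogen_signature.json"))
    if (!is.null(qc)) {
      readr::write_csv(qc$removed_samples,
                       file.path(output_dir, "qc_removed_samples.csv"))
      readr::write_csv(qc$removed_probes,
                       file.path(output_dir, "qc_removed_probes.csv"))
    }
  }
  list(signature = signature, qc = qc, removed_low_intensity = low_int,
       n_samples_used = ncol(beta), n_cpgs_used = nrow(beta))
}

tissue_composition <- function(beta, tissue, primary_panel, immune_panel,
                               epithelial_panel) {
  if (is.null(primary_panel)) return(NULL)
  if (tissue %in% c("mammary_gland", "breast") && !is.null(epithelial_panel)) {
    fr <- hierarchical_deconvolve(beta, primary_panel, epithelial_panel,
                                  parent_type = "epithelial")
    lp <- intersect(c("luminal_progenitor", "luminal progenitor"), names(fr))
    if (length(lp)) {
      return(tibble::tibble(sample_id = fr$sample_id,
                            composition = fr[[lp[1]]],
                            composition_metric = "luminal_progenitor_fraction"))
    }
  }
  if (tissue == "blood" && !is.null(immune_panel)) {
    fr <- hierarchical_deconvolve(beta, primary_panel, immune_panel,
                                  parent_type = "immune")
    glr <- granulocyte_lymphocyte_ratio(fr)
    return(tibble::tibble(sample_id = glr$sample_id,
                          composition = glr$glr,
                          composition_metric = "granulocyte_lymphocyte_ratio"))
  }
  fr <- deconvolve(beta, primary_panel)
  if (!"epithelial" %in% names(fr)) return(NULL)
  tibble::tibble(sample_id = fr$sample_id, composition = fr$epithelial,
                 composition_metric = "epithelial_fraction")
}

#' Run the intervention stage: scoring, composition, survival grid
#'
#' Scores every sample of an intervention cohort with the four epigenetic
#' biomarkers — scaled carcinogen signature, a tissue-appropriate
#' cell-composition summary (luminal-progenitor fraction in mammary gland
#' via hierarchical deconvolution, granulocyte/lymphocyte ratio in blood,
#' epithelial fraction elsewhere), mitotic clock, and PRBS mean — and, per
#' tissue, performs the median-split tumor-free survival analysis for each
#' biomarker: Kaplan-Meier curves for the high/low strata, a
#' single-covariate Cox model comparing high versus low, and the log-rank
#' test.
#'
#' @param beta CpG x sample matrix of the intervention cohort.
#' @param samples Sample sheet with `sample_id`, `mouse_id`, `tissue`.
#' @param records Per-mouse survival records (`subject_id`, `time`,
#'   `event`).
#' @param signature A serialized-and-reloaded or freshly defined
#'   `carcinogen_signature` (discovery scaling is reused, not re-fitted).
#' @param clock_def,prbs_def [cpg_set_definition()]s for the mitotic clock
#'   and PRBS score.
#' @param primary_panel,immune_panel,epithelial_panel Optional reference
#'   panels for composition summaries; composition is skipped when
#'   `primary_panel` is `NULL`.
#' @param min_subjects Tissues with fewer subjects are skipped with a
#'   warning.
#' @param output_dir Optional directory for the results CSVs.
#'
#' @return A list with `sample_table` (one row per sample: biomarker
#'   values) and `survival_grid` (one row per tissue x biomarker:
#'   `hr`, `ci_lower`, `ci_upper`, `p_value`, `logrank_p`, `n`,
#'   `n_events`, and a `km` list-column of stratified [km_estimate()]s).
#' @export
run_intervention <- function(beta, samples, records, signature,
                             clock_def, prbs_def,
                             primary_panel = NULL, immune_panel = NULL,
                             epithelial_panel = NULL,
                             min_subjects = 4, output_dir = NULL) {
  check_beta_matrix(beta)
  for (nm in c("sample_id", "mouse_id", "tissue")) {
    if (!nm %in% names(samples)) {
      abort(sprintf("Intervention sample sheet lacks column '%s'.", nm))
    }
  }
  check_records(records)
  if (!"subject_id" %in% names(records)) {
    abort("`records` must have a `subject_id` column.")
  }
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]

  per_tissue <- lapply(unique(samples$tissue), function(tis) {
    idx <- samples$tissue == tis
    b <- beta[, idx, drop = FALSE]
    tab <- tibble::tibble(
      sample_id = colnames(b),
      mouse_id = samples$mouse_id[idx],
      tissue = tis,
      carcinogen = score_carcinogen(b, signature, scaled = TRUE)$score,
      mitotic_clock = score_cpg_set(b, clock_def)$score,
      prbs = score_cpg_set(b, prbs_def)$score
    )
    comp <- tissue_composition(b, tis, primary_panel, immune_panel,
                               epithelial_panel)
    if (!is.null(comp)) tab <- dplyr::left_join(tab, comp, by = "sample_id")
    tab
  })
  sample_table <- dplyr::bind_rows(per_tissue)
  log_stage("intervention", nrow(sample_table), " samples scored across ",
            length(per_tissue), " tissue(s)")

  biomarkers <- intersect(c("carcinogen", "composition", "mitotic_clock",
                            "prbs"), names(sample_table))
  grid <- purrr::map(unique(sample_table$tissue), function(tis) {
    tab <- sample_table[sample_table$tissue == tis, , drop = FALSE]
    rec <- records[match(tab$mouse_id, records$subject_id), , drop = FALSE]
    ok <- !is.na(rec$subject_id)
    tab <- tab[ok, , drop = FALSE]
    rec <- rec[ok, , drop = FALSE]
    if (nrow(tab) < min_subjects) {
      warn(sprintf("Tissue '%s' has %d subject(s) (< %d); skipped.",
                   tis, nrow(tab), min_subjects))
      return(NULL)
    }
    purrr::map(biomarkers, function(bm) {
      v <- tab[[bm]]
      if (is.null(v) || anyNA(v)) return(NULL)
      strata <- median_split(v)
      cox <- cox_single(rec, strata)
      lr <- logrank_test(rec, strata)
      tibble::tibble(
        tissue = tis, biomarker = bm,
        hr = cox$hr, ci_lower = cox$ci_lower, ci_upper = cox$ci_upper,
        p_value = cox$p, logrank_p = lr$p_value,
        n = cox$n, n_events = cox$n_events, separation = cox$separation,
        km = list(km_estimate(rec, strata))
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(sample_table,
                     file.path(output_dir, "intervention_sample_table.csv"))
    readr::write_csv(dplyr::select(grid, -"km"),
                     file.path(output_dir, "intervention_survival_grid.csv"))
  }
  list(sample_table = sample_table, survival_grid = grid)
}
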