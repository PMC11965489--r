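#' Rank CpGs by exposure-associated methylation change within one tissue
#'
#' For a single tissue, CpGs are ranked by the signed difference in mean
#' beta between exposed and unexposed samples: the hyper ranking orders
#' differences descending (rank 1 = largest gain of methylation under
#' exposure), the hypo ranking ascending. Ties receive average ranks.
#' Tumor samples must not be passed: signatures are derived from normal
#' tissue only, by caller contract.
#'
#' @param beta CpG x sample matrix for one tissue.
#' @param exposure Per-sample exposure labels (exactly two levels, e.g.
#'   `"P/D+"` / `"P/D-"`).
#' @param exposed_level The label of the exposed group (default `"P/D+"`).
#'
#' @return A tibble with `cpg_id`, `delta` (exposed minus unexposed mean
#'   beta), `rank_hyper`, `rank_hypo`.
#' @export
rank_tissue_cpgs <- function(beta, exposure, exposed_level = "P/D+") {
  check_beta_matrix(beta)
  exposure <- as.character(exposure)
  if (length(exposure) != ncol(beta)) {
    abort("`exposure` must align with the columns of `beta`.")
  }
  exposed <- exposure == exposed_level
  if (sum(exposed) < 2 || sum(!exposed) < 2) {
    abort("At least 2 samples per exposure group are required.")
  }
  delta <- rowMeans(beta[, exposed, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, !exposed, drop = FALSE], na.rm = TRUE)
  tibble::tibble(
    cpg_id = rownames(beta),
    delta = unname(delta),
    rank_hyper = rank(-delta, ties.method = "average"),
    rank_hypo = rank(delta, ties.method = "average")
  )
}

#' Combine per-tissue CpG rankings by geometric mean
#'
#' Aggregates one rank vector per tissue into a single pan-tissue ranking:
#' per CpG the geometric mean of its tissue ranks is taken and the result
#' re-ranked ascending, so combined rank 1 marks the CpG most consistently
#' extreme across tissues.
#'
#' @param rankings A list of named numeric rank vectors (names = CpG ids),
#'   one per tissue, all over the same CpG universe.
#'
#' @return A tibble with `cpg_id`, `geo_mean_rank`, `combined_rank`.
#' @export
combine_rankings_geometric <- function(rankings) {
  if (!length(rankings)) abort("`rankings` must be non-empty.")
  universe <- names(rankings[[1]])
  if (is.null(universe)) abort("Rank vectors must be named by CpG id.")
  mat <- vapply(rankings, function(r) {
    if (!setequal(names(r), universe)) {
      abort("All rank vectors must cover the same CpG universe.")
    }
    r[universe]
  }, numeric(length(universe)))
  mat <- matrix(mat, nrow = length(universe))
  geo <- exp(rowMeans(log(mat)))
  tibble::tibble(
    cpg_id = universe,
    geo_mean_rank = geo,
    combined_rank = rank(geo, ties.method = "average")
  )
}

#' Define the pan-tissue carcinogen signature
#'
#' For each tissue of a discovery cohort, CpGs are ranked by the signed
#' exposed-minus-unexposed mean-beta difference ([rank_tissue_cpgs()]);
#' hyper and hypo rankings are separately combined across tissues by
#' geometric mean, and the top `k` CpGs of each combined ranking form the
#' signature. Should the two sets intersect (possible after geometric-mean
#' combination), overlapping CpGs are removed from both and each set is
#' refilled from the next ranks. The raw score — mean beta over the hyper
#' set minus mean beta over the hypo set — is then scaled to zero mean and
#' unit sample standard deviation in the healthy (unexposed) samples of
#' `scale_tissue` from the same cohort.
#'
#' @param beta CpG x sample matrix of the discovery cohort (normal tissue
#'   only; exclude tumor samples before calling).
#' @param samples Sample sheet with `sample_id`, `tissue`, `exposure`
#'   matching the columns of `beta`.
#' @param k Number of CpGs in each of the hyper and hypo sets.
#' @param scale_tissue Tissue whose unexposed samples anchor the scaling.
#' @param exposed_level Label of the exposed group.
#'
#' @return A list of class `carcinogen_signature`: `hyper_cpgs`,
#'   `hypo_cpgs` (ordered, disjoint, length `k` each), `scale_location`,
#'   `scale_spread`, `k`.
#' @export
define_carcinogen_signature <- function(beta, samples, k = 1000,
                                        scale_tissue = "mammary_gland",
                                        exposed_level = "P/D+") {
  check_beta_matrix(beta)
  if (!all(c("sample_id", "tissue", "exposure") %in% names(samples))) {
    abort("`samples` needs `sample_id`, `tissue`, `exposure` columns.")
  }
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) {
    abort("`samples` must cover every column of `beta`.")
  }
  if (2 * k > nrow(beta)) {
    abort("Fewer than 2k CpGs available for signature construction.")
  }
  tissues <- unique(samples$tissue)
  per_tissue <- lapply(sort(tissues), function(tis) {
    idx <- samples$tissue == tis
    rank_tissue_cpgs(beta[, idx, drop = FALSE], samples$exposure[idx],
                     exposed_level = exposed_level)
  })
  hyper_comb <- combine_rankings_geometric(
    lapply(per_tissue, function(r) setNames(r$rank_hyper, r$cpg_id))
  )
  hypo_comb <- combine_rankings_geometric(
    lapply(per_tissue, function(r) setNames(r$rank_hypo, r$cpg_id))
  )
  hyper_order <- hyper_comb$cpg_id[order(hyper_comb$geo_mean_rank,
                                         hyper_comb$cpg_id)]
  hypo_order <- hypo_comb$cpg_id[order(hypo_comb$geo_mean_rank,
                                       hypo_comb$cpg_id)]
  hyper <- hyper_order[seq_len(k)]
  hypo <- hypo_order[seq_len(k)]
  overlap <- intersect(hyper, hypo)
  # fixed resolution for set overlap (possible after geometric-mean
  # combination): drop shared CpGs from both pools and refill from the next
  # ranks until the two k-sets are disjoint
  hyper_pool <- hyper_order
  hypo_pool <- hypo_order
  while (length(overlap)) {
    hyper_pool <- setdiff(hyper_pool, overlap)
    hypo_pool <- setdiff(hypo_pool, overlap)
    if (length(hyper_pool) < k || length(hypo_pool) < k) {
      abort("Too few CpGs to refill disjoint hyper/hypo sets.")
    }
    hyper <- head(hyper_pool, k)
    hypo <- head(hypo_pool, k)
    overlap <- intersect(hyper, hypo)
  }
  sig <- structure(
    list(hyper_cpgs = hyper, hypo_cpgs = hypo,
         scale_location = 0, scale_spread = 1, k = as.integer(k)),
    class = "carcinogen_signature"
  )
  healthy <- samples$tissue == scale_tissue & samples$exposure != exposed_level
  if (!any(healthy)) {
    abort(sprintf("No healthy '%s' samples available for scaling.",
                  scale_tissue))
  }
  raw <- score_carcinogen(beta[, healthy, drop = FALSE], sig,
                          scaled = FALSE)$score
  if (length(raw) < 2 || sd(raw) == 0) {
    abort("Cannot scale: healthy scaling group has no score variance.")
  }
  sig$scale_location <- mean(raw)
  sig$scale_spread <- sd(raw)
  sig
}

#' @export
print.carcinogen_signature <- function(x, ...) {
  cat(sprintf(
    "<carcinogen_signature: %d hyper + %d hypo CpGs; scale (%.4g, %.4g)>\n",
    length(x$hyper_cpgs), length(x$hypo_cpgs),
    x$scale_location, x$scale_spread
  ))
  invisible(x)
}

#' Score samples with a carcinogen signature
#'
#' The raw score is the mean beta over the hyper CpG set minus the mean
#' beta over the hypo set; the scaled score subtracts the stored location
#' and divides by the stored spread (standardised units anchored in the
#' healthy scaling group of the discovery cohort — scoring a new cohort
#' reuses those parameters, no re-fitting).
#'
#' @param beta CpG x sample matrix.
#' @param signature A [define_carcinogen_signature()] result.
#' @param scaled Return standardized scores (default) or raw beta-unit
#'   scores.
#' @param min_coverage Minimum fraction of signature CpGs that must be
#'   present (non-missing) in a sample.
#'
#' @return A tibble with `sample_id`, `score`, `n_missing`.
#' @export
score_carcinogen <- function(beta, signature, scaled = TRUE,
                             min_coverage = 0.8) {
  check_beta_matrix(beta)
  if (!inherits(signature, "carcinogen_signature")) {
    abort("`signature` must be a carcinogen_signature.")
  }
  all_cpgs <- c(signature$hyper_cpgs, signature$hypo_cpgs)
  hyper_idx <- match(signature$hyper_cpgs, rownames(beta))
  hypo_idx <- match(signature$hypo_cpgs, rownames(beta))
  scores <- vapply(seq_len(ncol(beta)), function(j) {
    hv <- beta[hyper_idx[!is.na(hyper_idx)], j]
    lv <- beta[hypo_idx[!is.na(hypo_idx)], j]
    present <- sum(!is.na(hv)) + sum(!is.na(lv))
    if (present < min_coverage * length(all_cpgs)) {
      abort(sprintf(
        "Sample '%s' covers %d of %d signature CpGs (floor %.0f%%).",
        colnames(beta)[j], present, length(all_cpgs), 100 * min_coverage
      ))
    }
    c(mean(hv, na.rm = TRUE) - mean(lv, na.rm = TRUE),
      length(all_cpgs) - present)
  }, numeric(2))
  raw <- scores[1, ]
  out <- tibble::tibble(
    sample_id = colnames(beta),
    score = if (scaled) {
      (raw - signature$scale_location) / signature$scale_spread
    } else raw,
    n_missing = as.integer(scores[2, ])
  )
  out
}

#' Write / read a carcinogen signature as JSON
#'
#' Serializes the ordered CpG sets and scaling parameters so one discovery
#' scaling can be reused across cohorts.
#'
#' @param signature A `carcinogen_signature`.
#' @param path JSON file path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   the `carcinogen_signature`.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(unclass(signature), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(hyper_cpgs = as.character(x$hyper_cpgs),
         hypo_cpgs = as.character(x$hypo_cpgs),
         scale_location = as.numeric(x$scale_location),
         scale_spread = as.numeric(x$scale_spread),
         k = as.integer(x$k)),
    class = "carcinogen_signature"
  )
}
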