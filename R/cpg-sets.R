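#' Define a flat CpG-set score
#'
#' A flat CpG set scored by its mean beta value — the representation used
#' for the mitotic clock (polycomb-target promoter CpGs) and the PRBS
#' methylation score (CpGs under progesterone-receptor binding peaks).
#'
#' @param cpg_ids Character vector of unique CpG ids (non-empty).
#' @param label Score label, e.g. `"mitotic_clock"` or `"prbs"`.
#' @param provenance Named list recording the selection parameters.
#'
#' @return A `cpg_set_definition` list.
#' @export
cpg_set_definition <- function(cpg_ids, label, provenance = list()) {
  cpg_ids <- as.character(cpg_ids)
  if (!length(cpg_ids) || anyDuplicated(cpg_ids) || anyNA(cpg_ids)) {
    abort("`cpg_ids` must be non-empty and unique.")
  }
  structure(list(cpg_ids = cpg_ids, label = as.character(label),
                 provenance = provenance),
            class = "cpg_set_definition")
}

#' @export
print.cpg_set_definition <- function(x, ...) {
  cat(sprintf("<cpg_set_definition '%s': %d CpGs>\n",
              x$label, length(x$cpg_ids)))
  invisible(x)
}

#' Write / read a CpG-set definition as JSON
#'
#' @param definition A [cpg_set_definition()].
#' @param path JSON file path.
#' @return `write_cpg_set()` returns `path` invisibly; `read_cpg_set()`
#'   the definition.
#' @export
write_cpg_set <- function(definition, path) {
  jsonlite::write_json(unclass(definition), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cpg_set
#' @export
read_cpg_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cpg_set_definition(x$cpg_ids, x$label, as.list(x$provenance))
}

#' Read a BED3+ peak file
#'
#' Parses the first three columns (chrom, start, end) of a BED file.
#' Coordinates are kept 0-based half-open as in the format. Malformed
#' lines (fewer than three fields, non-numeric or inverted coordinates)
#' are reported with their line numbers.
#'
#' @param path BED file path.
#'
#' @return A tibble with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t| +")
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad)) {
    abort(sprintf("Malformed BED line(s) (fewer than 3 fields): %s",
                  paste(line_no[bad], collapse = ", ")))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad)) {
    abort(sprintf("Malformed BED coordinates at line(s): %s",
                  paste(line_no[bad], collapse = ", ")))
  }
  tibble::tibble(chrom = chrom, start = start, end = end)
}

#' Select CpGs overlapping binding-site peaks
#'
#' Identifies array CpGs whose position falls inside any peak interval.
#' BED intervals are 0-based half-open; CpG annotation positions are
#' 1-based, so a 1-based position `p` overlaps `[start, end)` exactly when
#' `start < p <= end`.
#'
#' @param peaks Tibble from [read_bed()] (or with `chrom`, `start`, `end`).
#' @param cpg_annotation Tibble with `cpg_id`, `chrom`, `pos` (1-based).
#' @param label Label for the resulting definition.
#'
#' @return A [cpg_set_definition()] of the overlapping CpGs.
#' @export
select_prbs_cpgs <- function(peaks, cpg_annotation, label = "prbs") {
  for (nm in c("chrom", "start", "end")) {
    if (!nm %in% names(peaks)) abort(sprintf("`peaks` lacks column '%s'.", nm))
  }
  for (nm in c("cpg_id", "chrom", "pos")) {
    if (!nm %in% names(cpg_annotation)) {
      abort(sprintf("`cpg_annotation` lacks column '%s'.", nm))
    }
  }
  hit <- logical(nrow(cpg_annotation))
  for (chr in unique(cpg_annotation$chrom)) {
    ci <- which(cpg_annotation$chrom == chr)
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (!nrow(pk)) next
    # convert to closed 1-based intervals: [start+1, end]
    q <- IRanges::IRanges(start = cpg_annotation$pos[ci],
                          width = 1)
    s <- IRanges::IRanges(start = pk$start + 1, end = pk$end)
    hit[ci] <- IRanges::overlapsAny(q, s)
  }
  sel <- cpg_annotation$cpg_id[hit]
  if (!length(sel)) abort("No CpGs overlap the supplied peaks.")
  cpg_set_definition(sel, label,
                     provenance = list(n_peaks = nrow(peaks),
                                       n_cpgs_tested = nrow(cpg_annotation)))
}

#' Select mitotic-clock CpGs at polycomb-target promoters
#'
#' Maps a human polycomb-group-target (PCGT) gene list to mouse homologs,
#' collects CpGs within `window` bp of any mapped gene's transcription
#' start site (inclusive on both ends), and keeps those with mean beta
#' below `max_fetal_mean` in every listed fetal tissue — CpGs unmethylated
#' in fetal tissue whose methylation accrues with cell division.
#'
#' @param pcgt_genes Character vector of human PCGT gene symbols.
#' @param homolog_map Tibble with `human_symbol`, `mouse_symbol`.
#' @param tss_annotation Tibble with `gene` (mouse symbol), `chrom`, `tss`
#'   (1-based position).
#' @param cpg_annotation Tibble with `cpg_id`, `chrom`, `pos` (1-based).
#' @param fetal_beta CpG x sample matrix of fetal-tissue betas.
#' @param fetal_samples Tibble with `sample_id`, `tissue` for `fetal_beta`.
#' @param window Maximum distance to a TSS in bp (`|pos - tss| <= window`).
#' @param max_fetal_mean Fetal mean-methylation ceiling (strict `<` in
#'   every tissue).
#'
#' @return A [cpg_set_definition()] labelled `"mitotic_clock"`.
#' @export
select_mitotic_clock_cpgs <- function(pcgt_genes, homolog_map,
                                      tss_annotation, cpg_annotation,
                                      fetal_beta, fetal_samples,
                                      window = 200, max_fetal_mean = 0.10) {
  mapped <- homolog_map$mouse_symbol[homolog_map$human_symbol %in% pcgt_genes]
  mapped <- unique(mapped[!is.na(mapped)])
  if (!length(mapped)) abort("The homolog map covers none of the PCGT genes.")
  tss <- tss_annotation[tss_annotation$gene %in% mapped, , drop = FALSE]
  if (!nrow(tss)) abort("No TSS annotation for the mapped genes.")

  near <- logical(nrow(cpg_annotation))
  for (chr in unique(tss$chrom)) {
    ci <- which(cpg_annotation$chrom == chr)
    ti <- tss$tss[tss$chrom == chr]
    if (!length(ci) || !length(ti)) next
    q <- IRanges::IRanges(start = cpg_annotation$pos[ci], width = 1)
    s <- IRanges::IRanges(start = ti - window, end = ti + window)
    near[ci] <- IRanges::overlapsAny(q, s)
  }
  candidates <- cpg_annotation$cpg_id[near]
  candidates <- candidates[candidates %in% rownames(fetal_beta)]
  if (!length(candidates)) abort("No candidate CpGs near mapped TSSs.")

  fetal_samples <- fetal_samples[match(colnames(fetal_beta),
                                       fetal_samples$sample_id), ]
  tissues <- unique(fetal_samples$tissue)
  fetal_means <- vapply(tissues, function(tis) {
    rowMeans(fetal_beta[candidates,
                        fetal_samples$tissue == tis, drop = FALSE],
             na.rm = TRUE)
  }, numeric(length(candidates)))
  fetal_means <- matrix(fetal_means, nrow = length(candidates))
  keep <- rowSums(fetal_means < max_fetal_mean) == length(tissues)
  sel <- candidates[keep]
  if (!length(sel)) abort("No CpGs pass the fetal-methylation filter.")
  cpg_set_definition(
    sel, "mitotic_clock",
    provenance = list(n_pcgt_genes = length(pcgt_genes),
                      n_mapped_genes = length(mapped),
                      n_tss_candidates = length(candidates),
                      window = window, max_fetal_mean = max_fetal_mean,
                      fetal_tissues = tissues)
  )
}

#' Score samples by mean beta over a CpG set
#'
#' Arithmetic mean of the beta values at the definition's CpGs, computed
#' over the CpGs present in each sample; the count of missing CpGs is
#' reported. Samples covering less than `min_coverage` of the set error.
#'
#' @param beta CpG x sample matrix.
#' @param definition A [cpg_set_definition()].
#' @param min_coverage Minimum fraction of the set that must be present.
#'
#' @return A tibble with `sample_id`, `score` (in `[0, 1]`), `n_missing`.
#' @export
score_cpg_set <- function(beta, definition, min_coverage = 0.8) {
  check_beta_matrix(beta)
  if (!inherits(definition, "cpg_set_definition")) {
    abort("`definition` must be a cpg_set_definition.")
  }
  idx <- match(definition$cpg_ids, rownames(beta))
  n_set <- length(definition$cpg_ids)
  res <- vapply(seq_len(ncol(beta)), function(j) {
    v <- beta[idx[!is.na(idx)], j]
    present <- sum(!is.na(v))
    if (present < min_coverage * n_set) {
      abort(sprintf(
        "Sample '%s' covers %d of %d CpGs in set '%s' (floor %.0f%%).",
        colnames(beta)[j], present, n_set, definition$label,
        100 * min_coverage
      ))
    }
    c(mean(v, na.rm = TRUE), n_set - present)
  }, numeric(2))
  tibble::tibble(sample_id = colnames(beta),
                 score = res[1, ],
                 n_missing = as.integer(res[2, ]))
}
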