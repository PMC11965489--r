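#' Read and write beta matrices
#'
#' Beta matrices are stored as TSV (optionally gzip-compressed by file
#' extension): CpG ids in the first column, one column per sample, empty
#' cells for missing values. On read, values are validated to `[0, 1]`
#' (the offending CpG and sample are named otherwise) and duplicate CpG
#' ids are rejected.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#'
#' @return `read_beta_matrix()` returns a CpG x sample numeric matrix;
#'   `write_beta_matrix()` returns `path` invisibly.
#' @export
read_beta_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double(),
                                                cpg_id = readr::col_character()))
  if (names(df)[1] != "cpg_id") names(df)[1] <- "cpg_id"
  if (anyDuplicated(df$cpg_id)) {
    abort(sprintf("Duplicate CpG id(s): %s",
                  paste(unique(df$cpg_id[duplicated(df$cpg_id)]),
                        collapse = ", ")))
  }
  m <- as.matrix(df[-1])
  rownames(m) <- df$cpg_id
  check_beta_matrix(m)
  m
}

#' @param beta CpG x sample matrix.
#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(beta, path) {
  check_beta_matrix(beta)
  df <- dplyr::bind_cols(tibble::tibble(cpg_id = rownames(beta)),
                         tibble::as_tibble(beta))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and write sample sheets
#'
#' Sample sheets are CSV files with one row per sample; `sample_id` is
#' required, the remaining columns (tissue, exposure, intervention,
#' platform, cell type, survival time/event) depend on the stage.
#'
#' @param path CSV file path.
#' @return `read_sample_sheet()` returns a tibble;
#'   `write_sample_sheet()` returns `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"sample_id" %in% names(df)) {
    abort("Sample sheet must have a `sample_id` column.")
  }
  df
}

#' @param samples Sample-sheet data frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A run configuration names the input files (beta matrix, sample sheet,
#' optional detection p-values, annotations, peaks), the stage parameters
#' (defaulting to the package defaults when absent), the output directory,
#' and the seed. Referenced input paths are checked for existence.
#'
#' @param path YAML file path.
#'
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in intersect(names(cfg),
                       c("beta", "samples", "detection_p", "records",
                         "signature", "primary_panel", "immune_panel",
                         "epithelial_panel", "clock_def", "prbs_def",
                         "peaks", "cpg_annotation"))) {
    if (!file.exists(cfg[[nm]])) {
      abort(sprintf("Configured path `%s` does not exist: %s", nm, cfg[[nm]]))
    }
  }
  structure(cfg, class = "run_config")
}

log_stage <- function(stage, ..., log_file = NULL) {
  msg <- sprintf("[%s] %s", stage, paste0(...))
  message(msg)
  if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  invisible(msg)
}
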