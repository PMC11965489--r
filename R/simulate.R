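#' Scenario configuration for the synthetic methylation study
#'
#' Bundles every parameter of the simulated two-arm mouse study: cohort
#' layout (tissues, group sizes), planted exposure effects on CpG subsets,
#' measurement noise, and the tumor-latency model used for survival
#' simulation. Defaults mirror the discovery design the package targets:
#' nine normal tissues, nine mice per exposure group, administrative
#' censoring at 23 weeks (161 days).
#'
#' @param n_cpgs Number of CpGs on the simulated array.
#' @param tissues Character vector of tissue names sampled from every mouse.
#' @param n_per_group Mice per (exposure, intervention) cell; each mouse
#'   contributes one sample per tissue.
#' @param effect_size_hyper,effect_size_hypo Beta-scale shift planted at the
#'   affected CpGs in exposed mice (added at hyper CpGs, subtracted at hypo
#'   CpGs).
#' @param n_affected_hyper,n_affected_hypo Number of planted hyper- and
#'   hypo-methylated CpGs.
#' @param noise_sd Standard deviation of truncated Gaussian measurement
#'   noise on the beta scale.
#' @param seed Integer seed; mandatory. A single scenario seed fans out to
#'   per-stage child seeds by fixed offsets.
#' @param followup_days Administrative censoring horizon in days from
#'   pellet implantation.
#' @param baseline_hazard Baseline tumor hazard (events/day) at signature
#'   score 0.
#' @param log_hr_per_unit_signature Log hazard ratio per unit of signature
#'   score in the latency model.
#' @param interventions Intervention arms to simulate (`"M-"` alone for a
#'   discovery-style cohort; `c("M-", "M+")` for an intervention cohort).
#' @param intervention_attenuation Fraction of the planted exposure effect
#'   removed in `"M+"` mice (0 = no effect of the intervention, 1 = full
#'   reversal).
#' @param background_modes Pair of beta values at which unmethylated /
#'   methylated background CpGs concentrate on the array scale.
#'
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_cpgs = 10000,
                            tissues = c("mammary_gland", "cervix", "oviduct",
                                        "blood", "adipose", "kidney",
                                        "liver", "lung", "spleen"),
                            n_per_group = 9,
                            effect_size_hyper = 0.2,
                            effect_size_hypo = 0.2,
                            n_affected_hyper = 1500,
                            n_affected_hypo = 1500,
                            noise_sd = 0.01,
                            seed,
                            followup_days = 161,
                            baseline_hazard = 0.02,
                            log_hr_per_unit_signature = 1.1,
                            interventions = "M-",
                            intervention_attenuation = 0.5,
                            background_modes = c(0.017, 0.955)) {
  if (missing(seed)) abort("`seed` is mandatory in `scenario_config()`.")
  cfg <- list(
    n_cpgs = check_count(n_cpgs, "n_cpgs"),
    tissues = as.character(tissues),
    n_per_group = check_count(n_per_group, "n_per_group"),
    effect_size_hyper = check_fraction(effect_size_hyper, "effect_size_hyper"),
    effect_size_hypo = check_fraction(effect_size_hypo, "effect_size_hypo"),
    n_affected_hyper = check_count(n_affected_hyper, "n_affected_hyper", min = 0),
    n_affected_hypo = check_count(n_affected_hypo, "n_affected_hypo", min = 0),
    noise_sd = check_fraction(noise_sd, "noise_sd"),
    seed = check_count(seed, "seed", min = 0),
    followup_days = check_fraction(followup_days, "followup_days", hi = Inf),
    baseline_hazard = check_fraction(baseline_hazard, "baseline_hazard", hi = Inf),
    log_hr_per_unit_signature = as.numeric(log_hr_per_unit_signature),
    interventions = match.arg(interventions, c("M-", "M+"), several.ok = TRUE),
    intervention_attenuation =
      check_fraction(intervention_attenuation, "intervention_attenuation"),
    background_modes = sort(as.numeric(background_modes))
  )
  if (length(cfg$tissues) < 1) abort("At least one tissue is required.")
  if (cfg$n_affected_hyper + cfg$n_affected_hypo > cfg$n_cpgs) {
    abort("Planted CpG counts exceed `n_cpgs`.")
  }
  if (any(cfg$background_modes <= 0) || any(cfg$background_modes >= 1) ||
      cfg$background_modes[1] >= cfg$background_modes[2]) {
    abort("`background_modes` must be strictly ordered within (0, 1).")
  }
  structure(cfg, class = "scenario_config")
}

#' Cell-type model for reference-methylome simulation
#'
#' Describes a set of cell types distinguished by disjoint marker-CpG sets:
#' at a type's markers its methylome differs from every other type by
#' `marker_delta` (in expectation); everywhere else all types share a
#' bimodal background.
#'
#' @param cell_types Character vector of cell-type names.
#' @param markers_per_type Number of marker CpGs planted per type
#'   (disjoint across types).
#' @param marker_delta Beta-scale separation between the target type and
#'   all others at the target's markers.
#' @param background_modes Pair of beta values for the unmethylated /
#'   methylated background, strictly ordered in (0, 1).
#'
#' @return A validated `cell_type_model` list.
#' @export
cell_type_model <- function(cell_types,
                            markers_per_type = 100,
                            marker_delta = 0.8,
                            background_modes = c(0.017, 0.955)) {
  cell_types <- as.character(cell_types)
  if (length(cell_types) < 2 || anyDuplicated(cell_types)) {
    abort("`cell_types` must be >= 2 distinct names.")
  }
  bg <- as.numeric(background_modes)
  if (length(bg) != 2 || any(bg <= 0) || any(bg >= 1) || bg[1] >= bg[2]) {
    abort("`background_modes` must be strictly ordered within (0, 1).")
  }
  structure(
    list(
      cell_types = cell_types,
      markers_per_type = check_count(markers_per_type, "markers_per_type"),
      marker_delta = check_fraction(marker_delta, "marker_delta"),
      background_modes = bg
    ),
    class = "cell_type_model"
  )
}

# Latent methylomes live on the sequencing scale (modes exactly 0 and 1);
# the array observation compresses them onto background_modes, mirroring how
# array background intensity shifts the observed modes inward.
latent_methylomes <- function(model, n_cpgs, seed) {
  set.seed(seed)
  types <- model$cell_types
  n_types <- length(types)
  n_markers <- model$markers_per_type * n_types
  if (n_markers > n_cpgs) abort("Marker sets exceed `n_cpgs`.")
  cpg_ids <- sprintf("cpg_%05d", seq_len(n_cpgs))
  base_state <- rbinom(n_cpgs, 1, 0.5)
  meth <- matrix(rep(as.numeric(base_state), n_types),
                 nrow = n_cpgs, dimnames = list(cpg_ids, types))
  marker_idx <- matrix(seq_len(n_markers), ncol = n_types)
  markers <- list()
  for (j in seq_len(n_types)) {
    idx <- marker_idx[, j]
    meth[idx, ] <- 0
    meth[idx, j] <- model$marker_delta
    markers[[types[j]]] <- cpg_ids[idx]
  }
  list(methylomes = meth, markers = markers)
}

observe_platform <- function(latent, platform, background_modes,
                             noise_sd, read_depth, rrbs_coverage) {
  n <- length(latent)
  if (platform == "array") {
    lo <- background_modes[1]
    hi <- background_modes[2]
    obs <- lo + (hi - lo) * latent
    if (noise_sd > 0) obs <- obs + rnorm(n, 0, noise_sd)
    return(clamp01(obs))
  }
  obs <- rbinom(n, read_depth, clamp01(latent)) / read_depth
  if (platform == "RRBS") {
    covered <- runif(n) < rrbs_coverage
    obs[!covered] <- NA_real_
  }
  obs
}

#' Simulate reference methylomes for panel construction
#'
#' Draws per-sample methylomes from a [cell_type_model()] and observes them
#' through a platform model: `"array"` adds truncated Gaussian noise and
#' compresses betas onto the background modes; `"WGBS"` and `"RRBS"` sample
#' binomial read counts (modes at exactly 0 and 1), with `"RRBS"` covering
#' only a fraction of CpGs (the rest missing).
#'
#' @param model A [cell_type_model()].
#' @param n_cpgs Number of CpGs simulated.
#' @param n_samples_per_type Samples drawn per cell type.
#' @param platform One of `"array"`, `"WGBS"`, `"RRBS"`.
#' @param seed Integer seed.
#' @param noise_sd Beta-scale biological variability added to latent
#'   methylomes before observation.
#' @param read_depth Binomial read depth for sequencing platforms.
#' @param rrbs_coverage Fraction of CpGs covered by RRBS.
#'
#' @return A list with `beta` (CpG x sample matrix), `samples` (tibble with
#'   `sample_id`, `cell_type`, `platform`), and `truth` (latent per-type
#'   methylomes and planted marker sets).
#' @export
simulate_reference_methylomes <- function(model, n_cpgs = 2000,
                                          n_samples_per_type = 5,
                                          platform = c("array", "WGBS", "RRBS"),
                                          seed,
                                          noise_sd = 0.01,
                                          read_depth = 30,
                                          rrbs_coverage = 0.08) {
  if (!inherits(model, "cell_type_model")) abort("`model` must be a cell_type_model.")
  platform <- match.arg(platform)
  check_count(n_samples_per_type, "n_samples_per_type")
  if (missing(seed)) abort("`seed` is mandatory.")
  truth <- latent_methylomes(model, n_cpgs, child_seed(seed, 1))
  set.seed(child_seed(seed, 2))
  types <- model$cell_types
  samples <- tidyr::expand_grid(cell_type = types,
                                rep = seq_len(n_samples_per_type)) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%02d", .data$cell_type, .data$rep),
      platform = platform
    ) |>
    dplyr::select("sample_id", "cell_type", "platform")
  beta <- matrix(NA_real_, n_cpgs, nrow(samples),
                 dimnames = list(rownames(truth$methylomes), samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    latent <- clamp01(truth$methylomes[, samples$cell_type[i]] +
                        rnorm(n_cpgs, 0, noise_sd))
    beta[, i] <- observe_platform(latent, platform, model$background_modes,
                                  noise_sd, read_depth, rrbs_coverage)
  }
  list(beta = beta, samples = samples, truth = truth)
}

#' Draw cell-type fraction vectors from a Dirichlet distribution
#'
#' @param n Number of samples.
#' @param types Cell-type names (columns of the result).
#' @param alpha Dirichlet concentration, recycled over types.
#' @param seed Integer seed.
#'
#' @return A tibble with `sample_id` and one fraction column per type; rows
#'   sum to 1.
#' @export
simulate_dirichlet_fractions <- function(n, types, alpha = 1, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  k <- length(types)
  alpha <- rep_len(alpha, k)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  frac <- g / rowSums(g)
  colnames(frac) <- types
  dplyr::bind_cols(tibble::tibble(sample_id = sprintf("bulk_%03d", seq_len(n))),
                   tibble::as_tibble(frac))
}

#' Simulate bulk methylomes as cell-type mixtures
#'
#' Bulk beta values are the fraction-weighted average of cell-type
#' methylomes plus truncated Gaussian noise, clamped to `[0, 1]`. True
#' fractions are returned alongside the data for recovery tests.
#'
#' @param methylomes CpG x cell-type matrix of methylomes (e.g. the `truth`
#'   component of [simulate_reference_methylomes()], or a reference panel).
#' @param fractions Tibble as returned by [simulate_dirichlet_fractions()],
#'   or a matrix with one row per sample and one column per cell type; each
#'   row must lie on the unit simplex.
#' @param noise_sd Beta-scale measurement noise.
#' @param seed Integer seed.
#'
#' @return A list with `beta` (CpG x sample matrix) and `fractions` (tibble
#'   of true mixing fractions).
#' @export
simulate_bulk_mixtures <- function(methylomes, fractions, noise_sd = 0, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  if (is.data.frame(fractions)) {
    ids <- fractions$sample_id %||% sprintf("bulk_%03d", seq_len(nrow(fractions)))
    frac <- as.matrix(fractions[setdiff(names(fractions), "sample_id")])
    rownames(frac) <- ids
  } else {
    frac <- as.matrix(fractions)
    if (is.null(rownames(frac))) {
      rownames(frac) <- sprintf("bulk_%03d", seq_len(nrow(frac)))
    }
  }
  if (is.null(colnames(frac))) colnames(frac) <- colnames(methylomes)
  if (!setequal(colnames(frac), colnames(methylomes))) {
    abort("Fraction columns must match the methylome cell types.")
  }
  frac <- frac[, colnames(methylomes), drop = FALSE]
  if (any(frac < -1e-12) || any(abs(rowSums(frac) - 1) > 1e-8)) {
    abort("Each fraction vector must be non-negative and sum to 1.")
  }
  set.seed(seed)
  bulk <- methylomes %*% t(frac)
  if (noise_sd > 0) bulk <- bulk + rnorm(length(bulk), 0, noise_sd)
  bulk <- clamp01(bulk)
  list(
    beta = bulk,
    fractions = dplyr::bind_cols(tibble::tibble(sample_id = rownames(frac)),
                                 tibble::as_tibble(frac))
  )
}

#' Simulate a multi-tissue exposure cohort
#'
#' Generates one array sample per (mouse, tissue) with a bimodal CpG
#' background shared across tissues. Exposed mice (`"P/D+"`) are shifted
#' upward by `effect_size_hyper` at the planted hyper CpGs and downward by
#' `effect_size_hypo` at the planted hypo CpGs, consistently across all
#' tissues; intervention mice (`"M+"`) have the planted effect attenuated
#' by `intervention_attenuation`. Planted CpG ids are recorded as ground
#' truth.
#'
#' @param config A [scenario_config()].
#'
#' @return A list with `beta` (CpG x sample matrix), `samples` (tibble with
#'   `sample_id`, `mouse_id`, `tissue`, `exposure`, `intervention`,
#'   `platform`), and `truth` (`hyper_cpgs`, `hypo_cpgs`).
#' @export
simulate_discovery_cohort <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config.")
  }
  if (length(config$tissues) < 2) abort("At least 2 tissues are required.")
  if (config$n_per_group < 2) {
    abort("Group sizes < 2 leave rank statistics undefined.")
  }
  set.seed(child_seed(config$seed, 11))
  n_cpgs <- config$n_cpgs
  cpg_ids <- sprintf("cpg_%05d", seq_len(n_cpgs))
  lo <- config$background_modes[1]
  hi <- config$background_modes[2]
  base_state <- rbinom(n_cpgs, 1, 0.5)
  base <- ifelse(base_state == 1, hi, lo)

  # plant hyper effects at unmethylated CpGs and hypo effects at methylated
  # ones so the shifts are not clipped by the [0,1] bounds
  unmeth <- which(base_state == 0)
  meth <- which(base_state == 1)
  if (length(unmeth) < config$n_affected_hyper ||
      length(meth) < config$n_affected_hypo) {
    abort("Not enough background CpGs to plant the requested effects.")
  }
  hyper_idx <- sort(sample(unmeth, config$n_affected_hyper))
  hypo_idx <- sort(sample(meth, config$n_affected_hypo))

  groups <- tidyr::expand_grid(exposure = c("P/D-", "P/D+"),
                               intervention = config$interventions)
  mice <- groups |>
    dplyr::mutate(mice = purrr::map(dplyr::row_number(), ~ seq_len(config$n_per_group))) |>
    tidyr::unnest("mice") |>
    dplyr::mutate(mouse_id = sprintf("mouse_%03d", dplyr::row_number())) |>
    dplyr::select("mouse_id", "exposure", "intervention")
  samples <- tidyr::expand_grid(mouse_id = mice$mouse_id,
                                tissue = config$tissues) |>
    dplyr::left_join(mice, by = "mouse_id") |>
    dplyr::mutate(
      sample_id = paste(.data$mouse_id, .data$tissue, sep = "."),
      platform = "array"
    ) |>
    dplyr::select("sample_id", "mouse_id", "tissue", "exposure",
                  "intervention", "platform")

  beta <- matrix(NA_real_, n_cpgs, nrow(samples),
                 dimnames = list(cpg_ids, samples$sample_id))
  # small per-(tissue, CpG) offsets give tissues distinct methylomes without
  # disturbing the planted pan-tissue exposure effect
  tissue_offset <- matrix(rnorm(n_cpgs * length(config$tissues), 0, 0.01),
                          n_cpgs, length(config$tissues),
                          dimnames = list(NULL, config$tissues))
  for (i in seq_len(nrow(samples))) {
    mu <- base + tissue_offset[, samples$tissue[i]]
    if (samples$exposure[i] == "P/D+") {
      atten <- if (samples$intervention[i] == "M+") {
        1 - config$intervention_attenuation
      } else 1
      mu[hyper_idx] <- mu[hyper_idx] + atten * config$effect_size_hyper
      mu[hypo_idx] <- mu[hypo_idx] - atten * config$effect_size_hypo
    }
    if (config$noise_sd > 0) mu <- mu + rnorm(n_cpgs, 0, config$noise_sd)
    beta[, i] <- clamp01(mu)
  }
  list(
    beta = beta, samples = samples,
    truth = list(hyper_cpgs = cpg_ids[hyper_idx], hypo_cpgs = cpg_ids[hypo_idx])
  )
}

#' Simulate censored tumor-latency outcomes
#'
#' Tumor latency is exponential with per-subject hazard
#' `baseline_hazard * exp(log_hr_per_unit_signature * score)`; observation
#' is administratively censored at `followup_days`. The event flag is 1
#' exactly when the latency falls before the censoring horizon.
#'
#' @param scores Named numeric vector of per-subject signature scores, or a
#'   data frame with `subject_id` and `score` columns.
#' @param config A [scenario_config()] providing `baseline_hazard`,
#'   `log_hr_per_unit_signature`, `followup_days`, and the seed.
#'
#' @return A tibble with `subject_id`, `time` (days), `event` (0/1).
#' @export
simulate_survival <- function(scores, config) {
  if (!inherits(config, "scenario_config")) {
    abort("`config` must be a scenario_config.")
  }
  if (is.data.frame(scores)) {
    ids <- scores$subject_id
    scores <- setNames(scores$score, ids)
  }
  if (is.null(names(scores))) {
    names(scores) <- sprintf("subject_%03d", seq_along(scores))
  }
  if (any(!is.finite(scores))) abort("`scores` must all be finite.")
  if (config$baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  set.seed(child_seed(config$seed, 21))
  hazard <- config$baseline_hazard *
    exp(config$log_hr_per_unit_signature * scores)
  latency <- rexp(length(scores), rate = hazard)
  event <- as.integer(latency < config$followup_days)
  tibble::tibble(
    subject_id = names(scores),
    time = pmin(latency, config$followup_days),
    event = event
  )
}
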