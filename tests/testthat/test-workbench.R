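test_that("beta matrices round-trip through (gzipped) TSV with validation", {
  dir <- withr::local_tempdir()
  set.seed(241)
  beta <- toy_beta(runif(60), 20, 3)
  beta[2, 1] <- NA
  path <- file.path(dir, "beta.tsv.gz")
  write_beta_matrix(beta, path)
  back <- read_beta_matrix(path)
  expect_equal(back, beta)

  bad <- beta; bad[3, 2] <- 1.2
  df <- dplyr::bind_cols(tibble::tibble(cpg_id = rownames(bad)),
                         tibble::as_tibble(bad))
  bad_path <- file.path(dir, "bad.tsv")
  readr::write_tsv(df, bad_path)
  expect_error(read_beta_matrix(bad_path), "cpg_03.*s02")

  dup <- df; dup$cpg_id[2] <- dup$cpg_id[1]
  dup_path <- file.path(dir, "dup.tsv")
  readr::write_tsv(dup, dup_path)
  expect_error(read_beta_matrix(dup_path), "Duplicate")
})

test_that("sample sheets and run configs are read with path validation", {
  dir <- withr::local_tempdir()
  sheet <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "blood",
                          exposure = c("P/D+", "P/D-"))
  p <- file.path(dir, "samples.csv")
  write_sample_sheet(sheet, p)
  expect_equal(read_sample_sheet(p), sheet)

  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(samples = p, k = 100, seed = 1), cfg_path)
  cfg <- read_run_config(cfg_path)
  expect_equal(cfg$k, 100)
  yaml::write_yaml(list(beta = file.path(dir, "missing.tsv")), cfg_path)
  expect_error(read_run_config(cfg_path), "does not exist")
})

test_that("discovery run performs QC, excludes tumors, and is deterministic", {
  cfg <- scenario_config(n_cpgs = 1500,
                         tissues = c("mammary_gland", "cervix", "blood"),
                         n_per_group = 6, n_affected_hyper = 200,
                         n_affected_hypo = 200, seed = 251)
  d <- simulate_discovery_cohort(cfg)
  # mark some samples as tumor tissue: they must not shape the signature
  tumor_sheet <- d$samples
  tumor_sheet$tissue[1:3] <- "mammary_tumor"
  set.seed(252)
  detp <- toy_beta(sample(c(0, 1), length(d$beta), TRUE, prob = c(0.97, 0.03)),
                   nrow(d$beta), ncol(d$beta),
                   cpg_ids = rownames(d$beta), sample_ids = colnames(d$beta))
  intens <- tibble::tibble(sample_id = colnames(d$beta),
                           median_meth = 10.5, median_unmeth = 10.5)
  intens$median_meth[intens$sample_id == colnames(d$beta)[5]] <- 9.0

  res <- suppressMessages(
    run_discovery(d$beta, tumor_sheet, detection_p = detp,
                  intensities = intens, k = 150)
  )
  expect_s3_class(res$signature, "carcinogen_signature")
  expect_equal(res$removed_low_intensity$sample_id[
    res$removed_low_intensity$removed], colnames(d$beta)[5])
  expect_length(res$signature$hyper_cpgs, 150)

  res2 <- suppressMessages(
    run_discovery(d$beta, tumor_sheet, detection_p = detp,
                  intensities = intens, k = 150)
  )
  expect_identical(res2$signature, res$signature)

  no_exposure <- dplyr::select(d$samples, -"exposure")
  expect_error(run_discovery(d$beta, no_exposure), "exposure")
})

test_that("planted exposure effects separate scaled discovery scores", {
  cfg <- scenario_config(n_cpgs = 1500,
                         tissues = c("mammary_gland", "cervix"),
                         n_per_group = 9, n_affected_hyper = 200,
                         n_affected_hypo = 200, seed = 261)
  d <- simulate_discovery_cohort(cfg)
  res <- suppressMessages(run_discovery(d$beta, d$samples, k = 150))
  sc <- score_carcinogen(d$beta, res$signature)
  exposed <- d$samples$exposure == "P/D+"
  expect_lt(wilcox.test(sc$score[exposed], sc$score[!exposed])$p.value, 0.01)
})

test_that("intervention run produces the tissue-by-biomarker survival grid", {
  cfg <- scenario_config(n_cpgs = 2000,
                         tissues = c("mammary_gland", "cervix", "oviduct",
                                     "blood"),
                         n_per_group = 50, n_affected_hyper = 300,
                         n_affected_hypo = 300, seed = 271,
                         interventions = c("M-", "M+"))
  d <- simulate_discovery_cohort(cfg)
  sig <- suppressMessages(
    run_discovery(d$beta, d$samples, k = 300)
  )$signature
  clock <- cpg_set_definition(d$truth$hyper_cpgs[1:150], "mitotic_clock")
  prbs <- cpg_set_definition(rownames(d$beta)[1601:1900], "prbs")

  # tumor latency driven by the mammary mitotic clock (standardised)
  mam <- d$samples$tissue == "mammary_gland"
  clock_scores <- score_cpg_set(d$beta[, mam], clock)$score
  z <- (clock_scores - mean(clock_scores)) / sd(clock_scores)
  records <- simulate_survival(
    setNames(z, d$samples$mouse_id[mam]),
    scenario_config(seed = 272, baseline_hazard = 0.01,
                    log_hr_per_unit_signature = 1.1)
  )

  res <- suppressMessages(suppressWarnings(
    run_intervention(d$beta, d$samples, records, sig,
                     clock_def = clock, prbs_def = prbs)
  ))
  expect_setequal(unique(res$survival_grid$tissue), cfg$tissues)
  expect_setequal(unique(res$survival_grid$biomarker),
                  c("carcinogen", "mitotic_clock", "prbs"))
  expect_equal(nrow(res$sample_table), ncol(d$beta))
  expect_true(all(c("carcinogen", "mitotic_clock", "prbs") %in%
                    names(res$sample_table)))

  mam_clock <- res$survival_grid[
    res$survival_grid$tissue == "mammary_gland" &
      res$survival_grid$biomarker == "mitotic_clock", ]
  expect_gt(mam_clock$hr, 1)
  expect_lt(mam_clock$p_value, 0.05)
})

test_that("grid p-values are uniform when outcomes are permuted", {
  cfg <- scenario_config(n_cpgs = 600, tissues = c("mammary_gland", "blood"),
                         n_per_group = 10, n_affected_hyper = 100,
                         n_affected_hypo = 100, seed = 281)
  d <- simulate_discovery_cohort(cfg)
  sig <- suppressMessages(run_discovery(d$beta, d$samples, k = 100))$signature
  clock <- cpg_set_definition(rownames(d$beta)[401:500], "mitotic_clock")
  prbs <- cpg_set_definition(rownames(d$beta)[501:600], "prbs")
  mice <- unique(d$samples$mouse_id)
  base_records <- simulate_survival(
    setNames(rnorm(length(mice)), mice),
    scenario_config(seed = 282, log_hr_per_unit_signature = 0)
  )
  set.seed(283)
  pvals <- unlist(lapply(1:50, function(i) {
    rec <- base_records
    rec$subject_id <- sample(rec$subject_id)
    res <- suppressMessages(suppressWarnings(
      run_intervention(d$beta, d$samples, rec, sig,
                       clock_def = clock, prbs_def = prbs)
    ))
    res$survival_grid$p_value[res$survival_grid$biomarker == "carcinogen"]
  }))
  rej <- sum(pvals < 0.05)
  bounds <- stats::qbinom(c(0.005, 0.995), length(pvals), 0.05)
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})
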