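test_that("reference methylomes separate cell types by marker_delta", {
  model <- cell_type_model(c("epithelial", "immune"), markers_per_type = 20,
                           marker_delta = 0.8)
  ref <- simulate_reference_methylomes(model, n_cpgs = 500,
                                       n_samples_per_type = 4,
                                       platform = "array", seed = 11,
                                       noise_sd = 0)
  truth <- ref$truth
  for (ty in model$cell_types) {
    other <- setdiff(model$cell_types, ty)
    diffs <- truth$methylomes[truth$markers[[ty]], ty] -
      truth$methylomes[truth$markers[[ty]], other]
    expect_true(all(abs(diffs - 0.8) < 0.01))
  }
  expect_true(all(ref$beta >= 0 & ref$beta <= 1))
})

test_that("sequencing platforms mode at exactly 0 and 1, arrays at background modes", {
  model <- cell_type_model(c("a", "b"), markers_per_type = 10)
  wgbs <- simulate_reference_methylomes(model, n_cpgs = 2000,
                                        n_samples_per_type = 3,
                                        platform = "WGBS", seed = 5,
                                        read_depth = 500)
  modes <- estimate_beta_modes(as.vector(wgbs$beta))
  expect_lt(abs(modes["lower"] - 0), 0.02)
  expect_lt(abs(modes["upper"] - 1), 0.02)
  # exact atoms at the extremes, the hallmark of read-proportion betas
  expect_gt(mean(wgbs$beta == 0), 0.2)
  expect_gt(mean(wgbs$beta == 1), 0.2)

  arr <- simulate_reference_methylomes(model, n_cpgs = 2000,
                                       n_samples_per_type = 3,
                                       platform = "array", seed = 5)
  amodes <- estimate_beta_modes(as.vector(arr$beta))
  expect_lt(abs(amodes["lower"] - 0.017), 0.02)
  expect_lt(abs(amodes["upper"] - 0.955), 0.02)
})

test_that("RRBS covers only a fraction of CpGs and platforms are validated", {
  model <- cell_type_model(c("a", "b"), markers_per_type = 5)
  rrbs <- simulate_reference_methylomes(model, n_cpgs = 2000,
                                        n_samples_per_type = 2,
                                        platform = "RRBS", seed = 3,
                                        rrbs_coverage = 0.08)
  cover <- mean(!is.na(rrbs$beta))
  expect_lt(abs(cover - 0.08), 0.02)
  expect_error(
    simulate_reference_methylomes(model, platform = "EPIC", seed = 1),
    "should be one of"
  )
  expect_error(
    simulate_reference_methylomes(model, n_cpgs = 5, seed = 1),
    "exceed"
  )
})

test_that("identical seeds reproduce byte-identical simulations", {
  model <- cell_type_model(c("a", "b", "c"), markers_per_type = 10)
  r1 <- simulate_reference_methylomes(model, n_cpgs = 300,
                                      n_samples_per_type = 3,
                                      platform = "array", seed = 99)
  r2 <- simulate_reference_methylomes(model, n_cpgs = 300,
                                      n_samples_per_type = 3,
                                      platform = "array", seed = 99)
  expect_identical(r1$beta, r2$beta)
  r3 <- simulate_reference_methylomes(model, n_cpgs = 300,
                                      n_samples_per_type = 3,
                                      platform = "array", seed = 100)
  expect_false(identical(r1$beta, r3$beta))
})

test_that("bulk mixtures are fraction-weighted averages on the simplex", {
  meth <- toy_beta(c(0.2, 0.9, 0.1, 0.8, 0.5, 0.3), 3, 2,
                   sample_ids = c("t1", "t2"))
  pure <- simulate_bulk_mixtures(meth, matrix(c(1, 0), 1, 2), seed = 1)
  expect_equal(unname(pure$beta[, 1]), unname(meth[, "t1"]))
  half <- simulate_bulk_mixtures(meth, matrix(c(0.5, 0.5), 1, 2), seed = 1)
  expect_equal(unname(half$beta[, 1]), unname(rowMeans(meth)))
  expect_error(
    simulate_bulk_mixtures(meth, matrix(c(0.5, 0.6), 1, 2), seed = 1),
    "sum to 1"
  )

  fr <- simulate_dirichlet_fractions(20, c("t1", "t2"), seed = 8)
  expect_equal(rowSums(as.matrix(fr[c("t1", "t2")])), rep(1, 20))
  fr2 <- simulate_dirichlet_fractions(20, c("t1", "t2"), seed = 8)
  expect_identical(fr, fr2)
})

test_that("discovery cohort plants pan-tissue exposure effects", {
  cfg <- scenario_config(n_cpgs = 800, tissues = c("mammary_gland", "liver"),
                         n_per_group = 9, n_affected_hyper = 100,
                         n_affected_hypo = 100, effect_size_hyper = 0.2,
                         effect_size_hypo = 0.2, noise_sd = 0.01, seed = 21)
  d <- simulate_discovery_cohort(cfg)
  expect_identical(dim(d$beta), c(800L, 36L))
  exp_idx <- d$samples$exposure == "P/D+"
  delta <- rowMeans(d$beta[, exp_idx]) - rowMeans(d$beta[, !exp_idx])
  top100 <- rownames(d$beta)[order(-delta)][1:100]
  expect_true(all(top100 %in% d$truth$hyper_cpgs))
  bottom100 <- rownames(d$beta)[order(delta)][1:100]
  expect_true(all(bottom100 %in% d$truth$hypo_cpgs))

  d2 <- simulate_discovery_cohort(cfg)
  expect_identical(d$truth, d2$truth)
  expect_identical(d$beta, d2$beta)
})

test_that("null discovery cohorts carry no exposure effect", {
  cfg <- scenario_config(n_cpgs = 500, tissues = c("a", "b"),
                         n_per_group = 9, effect_size_hyper = 0,
                         effect_size_hypo = 0, n_affected_hyper = 50,
                         n_affected_hypo = 50, noise_sd = 0.02, seed = 4)
  d <- simulate_discovery_cohort(cfg)
  exp_idx <- d$samples$exposure == "P/D+"
  delta <- rowMeans(d$beta[, exp_idx]) - rowMeans(d$beta[, !exp_idx])
  # planted CpGs indistinguishable from background under the null
  planted <- rownames(d$beta) %in% c(d$truth$hyper_cpgs, d$truth$hypo_cpgs)
  expect_gt(t.test(delta[planted], delta[!planted])$p.value, 0.01)
})

test_that("survival simulation respects the hazard model and censoring", {
  cfg <- scenario_config(seed = 31, followup_days = 0)
  s0 <- simulate_survival(setNames(rnorm(20), letters[1:20]), cfg)
  expect_true(all(s0$event == 0))
  expect_true(all(s0$time == 0))

  cfg_null <- scenario_config(seed = 32, log_hr_per_unit_signature = 0,
                              followup_days = 1e6)
  scores <- rnorm(400)
  sn <- simulate_survival(scores, cfg_null)
  tau <- cor.test(scores, sn$time, method = "kendall")
  expect_gt(tau$p.value, 0.01)

  expect_error(simulate_survival(c(1, Inf), cfg), "finite")
})
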