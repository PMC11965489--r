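make_panel <- function(mat, level = "primary") {
  structure(mat, class = c("reference_panel", class(mat)), level = level,
            n_top_per_type = nrow(mat), markers = list())
}

test_that("pure and noiseless two-component mixtures are recovered", {
  set.seed(101)
  P <- toy_beta(runif(40), 20, 2, sample_ids = c("ty1", "ty2"))
  panel <- make_panel(P)
  bulk <- P[, "ty1", drop = FALSE]
  colnames(bulk) <- "b1"
  est <- deconvolve(bulk, panel)
  expect_equal(est$ty1, 1, tolerance = 1e-9)
  expect_equal(est$ty2, 0, tolerance = 1e-9)

  mix <- 0.3 * P[, "ty1"] + 0.7 * P[, "ty2"]
  bulk2 <- matrix(mix, ncol = 1, dimnames = list(rownames(P), "b2"))
  est2 <- deconvolve(bulk2, panel)
  expect_equal(est2$ty1, 0.3, tolerance = 1e-6)
  expect_equal(est2$ty2, 0.7, tolerance = 1e-6)
})

test_that("fractions are a simplex and rank-deficient panels are rejected", {
  set.seed(102)
  P <- toy_beta(runif(60), 20, 3, sample_ids = c("a", "b", "c"))
  panel <- make_panel(P)
  bulk <- toy_beta(runif(60), 20, 3)
  est <- deconvolve(bulk, panel)
  expect_true(all(as.matrix(est[c("a", "b", "c")]) >= 0))
  expect_equal(rowSums(as.matrix(est[c("a", "b", "c")])), rep(1, 3),
               tolerance = 1e-9)

  Pbad <- P
  Pbad[, "b"] <- Pbad[, "a"]
  expect_error(deconvolve(bulk, make_panel(Pbad)), "rank-deficient")

  small <- bulk[1:10, , drop = FALSE]
  expect_error(deconvolve(small, panel), "floor")
})

test_that("adding CpGs constant across types leaves fractions unchanged", {
  set.seed(103)
  P <- toy_beta(runif(40), 20, 2, sample_ids = c("a", "b"))
  panel <- make_panel(P)
  bulk <- matrix(0.4 * P[, "a"] + 0.6 * P[, "b"], ncol = 1,
                 dimnames = list(rownames(P), "s"))
  base <- deconvolve(bulk, panel)
  extra <- matrix(0.5, 5, 2,
                  dimnames = list(paste0("flat_", 1:5), c("a", "b")))
  panel2 <- make_panel(rbind(P, extra))
  bulk2 <- rbind(bulk, matrix(0.5, 5, 1,
                              dimnames = list(paste0("flat_", 1:5), "s")))
  aug <- deconvolve(bulk2, panel2)
  expect_equal(aug$a, base$a, tolerance = 1e-8)
})

test_that("simulator mixtures are recovered within RMSE 0.05 and improve as noise shrinks", {
  model <- cell_type_model(c("epithelial", "fibroblast", "fat", "immune"),
                           markers_per_type = 50, marker_delta = 0.6)
  ref <- simulate_reference_methylomes(model, n_cpgs = 1000,
                                       n_samples_per_type = 5,
                                       platform = "array", seed = 111)
  panel <- build_panel(ref$beta, ref$samples$cell_type, n_top_per_type = 50)
  lo <- model$background_modes[1]
  hi <- model$background_modes[2]
  meth_arr <- lo + (hi - lo) * ref$truth$methylomes
  fr <- simulate_dirichlet_fractions(50, model$cell_types, seed = 112)
  rmse_at <- function(noise) {
    mix <- simulate_bulk_mixtures(meth_arr, fr, noise_sd = noise, seed = 113)
    est <- deconvolve(mix$beta, panel)
    sqrt(colMeans((as.matrix(est[model$cell_types]) -
                     as.matrix(fr[model$cell_types]))^2))
  }
  rmse <- rmse_at(0.02)
  expect_true(all(rmse <= 0.05))
  grid <- vapply(c(0.08, 0.04, 0.02, 0.005), function(ns) mean(rmse_at(ns)),
                 numeric(1))
  expect_true(all(diff(grid) <= 1e-6))
})

test_that("hierarchical deconvolution rescales subtypes to the parent fraction", {
  set.seed(121)
  sub_types <- c("luminal_progenitor", "mature_luminal")
  S <- toy_beta(runif(60), 30, 2, sample_ids = sub_types)
  parent <- (S[, 1] + S[, 2]) / 2
  other <- runif(30)
  P <- cbind(epithelial = parent, stroma = other)
  rownames(P) <- rownames(S)
  bulk <- matrix(0.4 * (0.5 * S[, 1] + 0.5 * S[, 2]) + 0.6 * other,
                 ncol = 1, dimnames = list(rownames(S), "s1"))
  est <- hierarchical_deconvolve(bulk, make_panel(P), make_panel(S, "epi-sub"),
                                 parent_type = "epithelial")
  expect_equal(est$luminal_progenitor + est$mature_luminal, 0.4,
               tolerance = 0.02)
  total <- est$stroma + est$luminal_progenitor + est$mature_luminal
  expect_equal(total, 1, tolerance = 1e-9)

  # parent fraction 0: subtypes forced to 0 regardless of the subtype fit
  bulk0 <- matrix(other, ncol = 1, dimnames = list(rownames(S), "s0"))
  est0 <- hierarchical_deconvolve(bulk0, make_panel(P),
                                  make_panel(S, "epi-sub"),
                                  parent_type = "epithelial")
  if (est0$stroma == 1) {
    expect_equal(est0$luminal_progenitor, 0)
    expect_equal(est0$mature_luminal, 0)
  }
  expect_error(
    hierarchical_deconvolve(bulk, make_panel(P), make_panel(S), "nope"),
    "not a column"
  )
})

test_that("hierarchical recovery of immune subtypes stays within RMSE 0.07", {
  model <- cell_type_model(c("B", "NK", "CD4T", "CD8T", "neutrophil"),
                           markers_per_type = 40, marker_delta = 0.7)
  ref <- simulate_reference_methylomes(model, n_cpgs = 1000,
                                       n_samples_per_type = 5,
                                       platform = "array", seed = 131)
  sub_panel <- build_panel(ref$beta, ref$samples$cell_type,
                           n_top_per_type = 40, level = "immune-subtype")
  lo <- model$background_modes[1]
  hi <- model$background_modes[2]
  meth_arr <- lo + (hi - lo) * ref$truth$methylomes
  fr <- simulate_dirichlet_fractions(30, model$cell_types, seed = 132)
  mix <- simulate_bulk_mixtures(meth_arr, fr, noise_sd = 0.02, seed = 133)
  est <- deconvolve(mix$beta, sub_panel)
  rmse <- sqrt(colMeans((as.matrix(est[model$cell_types]) -
                           as.matrix(fr[model$cell_types]))^2))
  expect_true(all(rmse <= 0.07))
})

test_that("granulocyte/lymphocyte ratio matches hand arithmetic", {
  fr <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    neutrophil = c(0.6, 0, 0.25),
    MDSC = c(0, 0, 0.05),
    B = c(0.1, 0.5, 0.3),
    NK = c(0.1, 0.2, 0.1),
    CD4T = c(0.05, 0.2, 0.2),
    CD8T = c(0.05, 0.1, 0.1),
    residual = 0
  )
  class(fr) <- c("fraction_estimate", class(fr))
  glr <- granulocyte_lymphocyte_ratio(fr)
  expect_equal(glr$glr, c(0.6 / 0.3, 0, 0.3 / 0.7))

  fr0 <- fr
  fr0$B <- fr0$NK <- fr0$CD4T <- fr0$CD8T <- 0
  expect_warning(glr0 <- granulocyte_lymphocyte_ratio(fr0), "Inf")
  expect_true(all(is.infinite(glr0$glr[c(1, 3)])))
})

test_that("fraction estimates tidy into long format and plot", {
  set.seed(141)
  P <- toy_beta(runif(40), 20, 2, sample_ids = c("a", "b"))
  bulk <- toy_beta(runif(40), 20, 2)
  est <- deconvolve(bulk, make_panel(P))
  long <- tidy(est)
  expect_identical(names(long), c("sample_id", "cell_type", "fraction"))
  expect_equal(nrow(long), 4)
  expect_s3_class(autoplot(est), "ggplot")
})
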