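# Small programmatic fixtures and independent oracles shared across tests.

toy_beta <- function(values, n_cpgs, n_samples,
                     cpg_ids = sprintf("cpg_%02d", seq_len(n_cpgs)),
                     sample_ids = sprintf("s%02d", seq_len(n_samples))) {
  matrix(values, n_cpgs, n_samples, dimnames = list(cpg_ids, sample_ids))
}

# Independent two-sided permutation p-value for the rank-sum statistic.
permutation_wilcoxon_p <- function(a, b, n_perm = 20000, seed = 1) {
  set.seed(seed)
  pooled <- c(a, b)
  n_a <- length(a)
  obs <- sum(rank(pooled)[seq_len(n_a)])
  mu <- n_a * (length(pooled) + 1) / 2
  perm <- replicate(n_perm, {
    idx <- sample(length(pooled), n_a)
    sum(rank(pooled)[idx])
  })
  mean(abs(perm - mu) >= abs(obs - mu))
}

# Cox partial likelihood for one continuous covariate, no ties assumed;
# used as a brute-force maximization oracle.
cox_partial_loglik <- function(beta_coef, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta_coef * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force marker ranking oracle mirroring the documented contract.
oracle_rank_markers <- function(beta, labels, target, n_top) {
  in_t <- labels == target
  delta <- rowMeans(beta[, in_t, drop = FALSE]) -
    rowMeans(beta[, !in_t, drop = FALSE])
  p <- apply(beta, 1, function(v) {
    fieldmark::wilcoxon_rank_sum(v[in_t], v[!in_t])
  })
  rd <- rank(-abs(delta), ties.method = "average")
  rp <- rank(p, ties.method = "average")
  comb <- sqrt(rd * rp)
  ord <- order(comb, -abs(delta), rownames(beta))
  rownames(beta)[ord][seq_len(n_top)]
}
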