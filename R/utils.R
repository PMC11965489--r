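# Shared validation helpers for beta matrices and sample sheets.

check_beta_matrix <- function(beta, allow_na = TRUE, arg = "beta") {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    abort(sprintf("`%s` must be a numeric matrix (CpG x sample).", arg))
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    abort(sprintf("`%s` must have CpG rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(beta))) {
    abort(sprintf("`%s` has duplicated CpG ids.", arg))
  }
  vals <- beta[!is.na(beta)]
  if (!allow_na && anyNA(beta)) {
    abort(sprintf("`%s` must not contain missing values.", arg))
  }
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`%s` has values outside [0,1], e.g. CpG '%s', sample '%s'.",
      arg, rownames(beta)[bad[1]], colnames(beta)[bad[2]]
    ))
  }
  invisible(beta)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g].", name, lo, hi))
  }
  as.numeric(x)
}

clamp01 <- function(x) {
  # which() keeps NAs untouched and the dim/dimnames of matrices intact
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

# Deterministic child seeds: a single scenario seed fans out by fixed offsets so
# each simulation stage is independently reproducible. Kept below 2^31.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647)
}

geometric_mean <- function(x) exp(mean(log(x)))
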