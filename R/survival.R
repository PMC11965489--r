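check_records <- function(records) {
  for (nm in c("time", "event")) {
    if (!nm %in% names(records)) {
      abort(sprintf("`records` lacks column '%s'.", nm))
    }
  }
  if (!nrow(records)) abort("`records` must contain at least one record.")
  if (any(records$time < 0)) abort("Survival times must be non-negative.")
  if (!all(records$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  records
}

#' Kaplan-Meier estimate of tumor-free survival
#'
#' Product-limit estimator of the survival function; censored times reduce
#' the risk set without producing a step. Optionally stratified by group.
#'
#' @param records Data frame with `time` (days from pellet implantation)
#'   and `event` (1 = tumor first measured, 0 = censored), optionally
#'   `subject_id`.
#' @param groups Optional per-record stratum labels.
#'
#' @return A tibble of class `km_fit` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, and `group` when stratified.
#' @export
km_estimate <- function(records, groups = NULL) {
  check_records(records)
  if (is.null(groups)) {
    fit <- survival::survfit(
      survival::Surv(records$time, records$event) ~ 1
    )
    out <- tibble::tibble(
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, surv = fit$surv
    )
  } else {
    groups <- as.character(groups)
    if (length(groups) != nrow(records)) {
      abort("`groups` must align with `records`.")
    }
    fit <- survival::survfit(
      survival::Surv(records$time, records$event) ~ groups
    )
    out <- tibble::tibble(
      group = rep(sub("^groups=", "", names(fit$strata)), fit$strata),
      time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
      n_censor = fit$n.censor, surv = fit$surv
    )
  }
  class(out) <- c("km_fit", class(out))
  out
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"group" %in% names(df)) df$group <- "all"
  start <- df |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, surv = 1)
  dplyr::bind_rows(start, df) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time, y = .data$surv,
                                 colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days from implantation",
                  y = "tumor-free survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Split subjects at the median signature value
#'
#' Scores strictly above the median are labelled `"high"`; scores at or
#' below the median — including ties at the median — are `"low"`, a
#' deterministic and conservative convention.
#'
#' @param scores Numeric vector of per-subject signature values.
#'
#' @return Character vector of `"high"` / `"low"` labels.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) abort("At least 2 subjects are required.")
  if (anyNA(scores)) abort("`scores` must not contain missing values.")
  if (length(unique(scores)) == 1) {
    abort("All scores identical: no median split possible.")
  }
  m <- median(scores)
  ifelse(scores > m, "high", "low")
}

#' Single-covariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with the Efron approximation for tied
#' event times (the common situation in small rodent cohorts with weekly
#' follow-up). The Wald 95% confidence interval is
#' `exp(coef +/- 1.96 * SE)`. Monotone partial likelihood (complete
#' separation of the groups) is flagged: the coefficient is reported at
#' the iteration cap with `separation = TRUE`.
#'
#' @param records Data frame with `time` and `event`.
#' @param covariate Numeric or two-level covariate aligned with `records`
#'   (e.g. the [median_split()] labels).
#'
#' @return A list of class `cox_fit`: `coef`, `hr`, `ci_lower`, `ci_upper`,
#'   `se`, `p`, `n`, `n_events`, `separation`, and for factor covariates
#'   the `comparison` string.
#' @export
cox_single <- function(records, covariate) {
  check_records(records)
  if (length(covariate) != nrow(records)) {
    abort("`covariate` must align with `records`.")
  }
  if (sum(records$event) < 1) abort("At least one event is required.")
  comparison <- NA_character_
  if (!is.numeric(covariate)) {
    lev <- sort(unique(as.character(covariate)))
    if (length(lev) != 2) {
      abort("Non-numeric covariates must have exactly two levels.")
    }
    # reference = first level alphabetically, except the conventional
    # high-vs-low contrast which is reported as high over low
    if (setequal(lev, c("high", "low"))) lev <- c("low", "high")
    comparison <- paste(lev[2], "vs", lev[1])
    covariate <- as.numeric(factor(covariate, levels = lev)) - 1
  }
  if (length(unique(covariate)) < 2) abort("`covariate` is constant.")
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(records$time, records$event) ~ covariate,
      ties = "efron"
    ),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    warn("Monotone partial likelihood: coefficient reported at the iteration cap.")
  }
  coef <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  z <- coef / se
  structure(
    list(
      coef = coef, hr = exp(coef),
      ci_lower = exp(coef - 1.96 * se), ci_upper = exp(coef + 1.96 * se),
      se = se, p = 2 * stats::pnorm(-abs(z)),
      n = nrow(records), n_events = sum(records$event),
      separation = separation, comparison = comparison
    ),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: HR %.3f (95%% CI %.3f-%.3f), p = %.3g, %d events/%d subjects\n",
              x$hr, x$ci_lower, x$ci_upper, x$p, x$n_events, x$n))
  if (x$separation) cat("  [flagged: monotone likelihood]\n")
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A [cox_single()] result.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate` (log hazard), `hr`,
#'   `std.error`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(
    term = if (is.na(x$comparison)) "covariate" else x$comparison,
    estimate = x$coef, hr = x$hr, std.error = x$se, p.value = x$p,
    conf.low = x$ci_lower, conf.high = x$ci_upper
  )
}

#' Glance at a Cox fit
#'
#' @param x A [cox_single()] result.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_events`, `separation`.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, separation = x$separation)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' one degree of freedom. With no events the statistic is 0 and p = 1.
#'
#' @param records Data frame with `time` and `event`.
#' @param groups Two-level group labels aligned with `records`.
#'
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records, groups) {
  check_records(records)
  groups <- as.character(groups)
  if (length(groups) != nrow(records)) {
    abort("`groups` must align with `records`.")
  }
  if (length(unique(groups)) != 2) abort("Exactly 2 groups are required.")
  if (sum(records$event) == 0) {
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1))
  }
  sd <- survival::survdiff(
    survival::Surv(records$time, records$event) ~ groups
  )
  tibble::tibble(statistic = unname(sd$chisq), df = 1L,
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
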