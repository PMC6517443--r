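# Stage 7: Kaplan-Meier estimation and log-rank comparison between
# expression-stratified patient groups.

#' Stratify patients at an expression quantile
#'
#' Patients strictly above the type-7 (linear interpolation) `q`-quantile of
#' expression form the `high` group; ties at the threshold go `low`. The
#' default 0.75 splits the upper quartile from the lower three quartiles.
#'
#' @param expr Named numeric vector of per-patient expression (>= 4 values).
#' @param q Quantile in \[0, 1).
#' @return Named character vector of `"high"`/`"low"` labels.
#' @export
stratify_by_quantile <- function(expr, q = 0.75) {
  if (length(expr) < 4L) stop("need at least 4 patients")
  thr <- stats::quantile(expr, q, type = 7, names = FALSE)
  stats::setNames(ifelse(expr > thr, "high", "low"), names(expr))
}

#' Kaplan-Meier product-limit estimate
#'
#' Censored records decrement the risk set without dropping the survival
#' estimate. With no censoring the estimate equals empirical survival.
#'
#' @param records data.frame with `time` (> 0), `event` (1 = death,
#'   0 = censored) and optionally `group`.
#' @return data.frame `time`, `n_risk`, `n_event`, `survival` (and `group`
#'   when grouped), one row per distinct event/censor time.
#' @export
kaplan_meier <- function(records) {
  if (!all(c("time", "event") %in% names(records)))
    stop("records need `time` and `event` columns")
  if (any(records$time <= 0)) stop("times must be > 0")
  grouped <- "group" %in% names(records) && length(unique(records$group)) > 1L
  fit <- if (grouped)
    survival::survfit(survival::Surv(time, event) ~ group, data = records)
  else survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv, stringsAsFactors = FALSE
  )
  if (grouped)
    out$group <- sub("^group=", "", rep(names(fit$strata), fit$strata))
  out
}

#' Log-rank test between two survival groups
#'
#' Standard log-rank chi-square with 1 degree of freedom.
#'
#' @param records data.frame with `time`, `event` and a two-level `group`.
#' @return A `stat_test` with the chi-square statistic and p-value.
#' @export
logrank_test <- function(records) {
  if (!all(c("time", "event", "group") %in% names(records)))
    stop("records need `time`, `event` and `group` columns")
  if (length(unique(records$group)) != 2L) stop("need exactly two groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = records)
  new_stat_test(sd$chisq, stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                "log-rank")
}
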