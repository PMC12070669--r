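# Rule-stratified prognosis: Kaplan-Meier curves, log-rank comparison and a
# univariate Cox model for the hazard ratio between panel-rule strata. All
# heavy lifting is delegated to the survival package; these wrappers fix the
# conventions (Breslow ties, Wald CI) and the degenerate-input behavior.

as_surv_inputs <- function(time, event) {
  if (length(time) != length(event)) abort("time/event length mismatch")
  if (anyNA(time) || anyNA(event)) abort("missing follow-up values")
  if (any(time <= 0)) abort("follow-up times must be > 0")
  if (!all(event %in% c(0, 1, TRUE, FALSE))) abort("event flags must be 0/1")
  list(time = as.numeric(time), event = as.integer(event))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times in years (> 0).
#' @param event event flags (1 = event, 0 = censored).
#' @return data frame of class `cd_km` with `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (the step function; survival starts at 1 and is
#'   non-increasing).
#' @export
km_estimate <- function(time, event) {
  s <- as_surv_inputs(time, event)
  fit <- survival::survfit(survival::Surv(s$time, s$event) ~ 1)
  structure(data.frame(time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv),
            class = c("cd_km", "data.frame"))
}

#' Log-rank test between two strata
#'
#' Standard observed-minus-expected chi-square statistic with 1 degree of
#' freedom. With no events at all the comparison is vacuous: the statistic is
#' 0 and p = 1, with a warning.
#'
#' @inheritParams km_estimate
#' @param group two-level factor/character/logical stratum labels.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  s <- as_surv_inputs(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) abort("exactly two non-empty strata required")
  if (sum(s$event) == 0) {
    warning("no events in either stratum: log-rank test is vacuous, p = 1")
    return(list(chisq = 0, df = 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(s$time, s$event) ~ group)
  list(chisq = sd$chisq, df = 1L, p = pchisq(sd$chisq, 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards estimate between two strata
#'
#' Fits a Cox model with the single binary covariate `group` (Breslow tie
#' handling by default) and returns the hazard ratio of `level` relative to
#' the other stratum with its Wald CI on the log scale. A stratum with no
#' events makes the partial likelihood monotone; the estimate is flagged and
#' the CI unbounded.
#'
#' @inheritParams logrank_test
#' @param level the stratum whose hazard goes in the numerator; default is
#'   the second factor level.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level confidence level.
#' @return list of class `cd_hazard`: `hr`, `ci_low`, `ci_high`, `p`,
#'   `monotone` (TRUE when a stratum had no events).
#' @export
cox_univariate <- function(time, event, group, level = NULL,
                           ties = c("breslow", "efron"), conf_level = 0.95) {
  ties <- match.arg(ties)
  s <- as_surv_inputs(time, event)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) abort("exactly two non-empty strata required")
  if (!is.null(level)) group <- stats::relevel(group, ref = setdiff(levels(group), level))
  ev_by <- tapply(s$event, group, sum)
  monotone <- any(ev_by == 0)
  if (monotone)
    warning("no events in stratum '", names(ev_by)[ev_by == 0][1],
            "': monotone partial likelihood, CI unbounded")
  fit_call <- quote(survival::coxph(survival::Surv(s$time, s$event) ~ group,
                                    ties = ties))
  # non-convergence of a monotone likelihood is already flagged above
  fit <- if (monotone) suppressWarnings(eval(fit_call)) else eval(fit_call)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(hr = exp(beta),
                 ci_low = exp(beta - z * se),
                 ci_high = exp(beta + z * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 monotone = monotone,
                 level = levels(group)[2]),
            class = "cd_hazard")
}

#' @export
print.cd_hazard <- function(x, ...) {
  cat(sprintf("HR[%s] = %.2f (95%% CI %.2f-%.2f), p = %.2g%s\n",
              x$level, x$hr, x$ci_low, x$ci_high, x$p,
              if (x$monotone) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Rule-stratified prognosis for one endpoint
#'
#' Convenience wrapper: stratifies a cohort by a panel rule, then computes the
#' per-stratum Kaplan-Meier curves, the log-rank test and the Cox hazard
#' ratio of the rule-negative (remission-call) stratum.
#'
#' @param x a [cohort()] with follow-up columns (see [generate_survival()]).
#' @param endpoint `"relapse"`, `"hosp"` or `"surg"`.
#' @param rule,cuts passed to [apply_rule()].
#' @return list with `endpoint`, `km` (per-stratum [km_estimate()]s),
#'   `logrank`, `cox` (HR of the remission call vs active call).
#' @export
prognosis_by_rule <- function(x, endpoint = c("relapse", "hosp", "surg"),
                              rule = "two_of_three", cuts = cutoff_set()) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0("fu_", endpoint, "_t"); ecol <- paste0("fu_", endpoint, "_e")
  if (!all(c(tcol, ecol) %in% names(x))) abort("cohort has no follow-up for '%s'", endpoint)
  stratum <- factor(as.character(apply_rule(x, rule, cuts)),
                    levels = c("active", "remission"))
  list(endpoint = endpoint,
       n = table(stratum),
       km = lapply(split(seq_len(nrow(x)), stratum), function(i)
         km_estimate(x[[tcol]][i], x[[ecol]][i])),
       logrank = logrank_test(x[[tcol]], x[[ecol]], stratum),
       cox = cox_univariate(x[[tcol]], x[[ecol]], stratum, level = "remission"))
}
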