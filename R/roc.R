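# Empirical ROC machinery. The positive class is endoscopic remission and low
# marker values point toward remission, so a remission call at threshold t is
# "value <= t"; informative markers then have AUC > 0.5 without any manual
# sign flipping by the caller.

check_two_classes <- function(rem, what = "truth") {
  if (anyNA(rem)) abort("missing values in %s", what)
  if (!any(rem)) abort("no remission cases in %s", what)
  if (all(rem)) abort("no active cases in %s", what)
  invisible(rem)
}

#' Empirical ROC curve of a continuous marker for remission
#'
#' One operating point per observed unique marker value (remission call:
#' `value <= threshold`) plus the two degenerate corners. Sensitivity is the
#' fraction of remission patients called remission; specificity the fraction
#' of active patients called active.
#'
#' @param values numeric marker values.
#' @param truth remission labels: logical (`TRUE` = remission) or
#'   `"remission"`/`"active"`.
#' @return object of class `cd_roc`: a data frame `threshold`, `sens`, `spec`
#'   ordered by threshold, with attributes `n_pos` (remission), `n_neg`
#'   (active) and the orientation tag.
#' @export
empirical_roc <- function(values, truth) {
  rem <- check_two_classes(as_remission(truth))
  if (length(values) != length(rem)) abort("values/truth length mismatch")
  if (anyNA(values)) abort("missing marker values")
  thr <- c(-Inf, sort(unique(values)))
  sens <- vapply(thr, function(t) mean(values[rem] <= t), 0)
  spec <- vapply(thr, function(t) mean(values[!rem] > t), 0)
  if (spec[length(spec)] > 0) { # global max not in the active group
    thr <- c(thr, Inf); sens <- c(sens, 1); spec <- c(spec, 0)
  }
  structure(
    data.frame(threshold = thr, sens = sens, spec = spec),
    class = c("cd_roc", "data.frame"),
    n_pos = sum(rem), n_neg = sum(!rem),
    orientation = "low marker value indicates remission"
  )
}

#' Mann-Whitney AUC for remission, with a DeLong confidence interval
#'
#' The probability that a randomly chosen remission patient has a lower marker
#' value than a randomly chosen active patient, ties counted half. This equals
#' the trapezoidal area under [empirical_roc()]. The 95% CI uses the DeLong
#' structural-component variance on the logit-free scale, truncated to
#' `[0, 1]`.
#'
#' @inheritParams empirical_roc
#' @param conf_level confidence level.
#' @return object of class `cd_auc`: list with `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(values, truth, conf_level = 0.95) {
  rem <- check_two_classes(as_remission(truth))
  if (length(values) != length(rem)) abort("values/truth length mismatch")
  if (anyNA(values)) abort("missing marker values")
  v <- delong_components(-values, rem)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(v$var, 0))
  structure(list(auc = v$auc,
                 ci_low = max(0, v$auc - z * se),
                 ci_high = min(1, v$auc + z * se),
                 n_pos = sum(rem), n_neg = sum(!rem)),
            class = "cd_auc")
}

#' @export
print.cd_auc <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), n_remission=%d n_active=%d\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

# placement values for scores oriented so HIGH score = positive class
delong_components <- function(score, positive) {
  xs <- score[positive]; ys <- score[!positive]
  m <- length(xs); n <- length(ys)
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)   # per-positive placements
  v01 <- colMeans(psi)   # per-negative placements
  auc <- mean(psi)
  var <- if (m > 1 && n > 1) stats::var(v10) / m + stats::var(v01) / n else NA_real_
  list(auc = auc, v10 = v10, v01 = v01, var = var)
}

#' Youden-index cutoff from an empirical ROC curve
#'
#' Maximizes J = sensitivity + specificity - 1 over the observed (finite)
#' thresholds; ties are broken toward the smallest cutoff. A marker value
#' exactly equal to the returned cutoff is classified as remission
#' (the "negative marker" side), matching [dichotomize()].
#'
#' @param roc a [empirical_roc()] result, or a marker vector (then `truth`
#'   must be given).
#' @param truth remission labels when `roc` is a marker vector.
#' @return object of class `cd_cutoff`: list with `cutoff`, `youden_j`,
#'   `sens`, `spec`.
#' @export
youden_cutoff <- function(roc, truth = NULL) {
  if (!inherits(roc, "cd_roc")) roc <- empirical_roc(roc, truth)
  fin <- is.finite(roc$threshold)
  j <- roc$sens[fin] + roc$spec[fin] - 1
  thr <- roc$threshold[fin]
  best <- which(j == max(j))[1L]  # thresholds ascend, so first max = smallest
  structure(list(cutoff = thr[best], youden_j = j[best],
                 sens = roc$sens[fin][best], spec = roc$spec[fin][best]),
            class = "cd_cutoff")
}

#' @export
print.cd_cutoff <- function(x, ...) {
  cat(sprintf("Youden cutoff %g (J = %.3f; sens %.3f, spec %.3f)\n",
              x$cutoff, x$youden_j, x$sens, x$spec))
  invisible(x)
}
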