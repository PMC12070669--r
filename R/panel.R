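# Combination rules over the dichotomized marker triple. A marker is
# "negative" (pointing toward remission) when its value is at or below the
# cutoff; fecal calprotectin may be unavailable. The positive class of every
# rule is endoscopic remission.

.status_levels <- c("negative", "positive", "unavailable")
.decision_levels <- c("remission", "active", "indeterminate")

#' Marker cutoffs
#'
#' The dichotomization thresholds for the three markers. Defaults are the
#' Youden-index cutoffs fitted in the source study: LRG 13.2 µg/mL, CRP 0.15
#' mg/dL, Fcal 180 µg/g.
#'
#' @param lrg,crp,fcal positive cutoffs in marker units.
#' @return list of class `cd_cutoffs`.
#' @export
cutoff_set <- function(lrg = 13.2, crp = 0.15, fcal = 180) {
  if (any(c(lrg, crp, fcal) <= 0) || anyNA(c(lrg, crp, fcal)))
    abort("all cutoffs must be positive")
  structure(list(lrg = lrg, crp = crp, fcal = fcal), class = "cd_cutoffs")
}

#' Dichotomize the marker triple at a cutoff set
#'
#' A marker is `negative` iff its value is less than or equal to its cutoff
#' (a value exactly at the cutoff counts as remission-side), `positive`
#' otherwise. Missing fecal calprotectin gives `unavailable`; missing serum
#' markers are an error, since blood is always drawn.
#'
#' @param x a [cohort()], or a list/data frame with elements `lrg`, `crp`,
#'   `fcal` (vectors allowed).
#' @param cuts a [cutoff_set()].
#' @return data frame of factors `lrg`, `crp`, `fcal` with levels
#'   `negative`, `positive`, `unavailable`.
#' @export
dichotomize <- function(x, cuts = cutoff_set()) {
  stopifnot(inherits(cuts, "cd_cutoffs"))
  lrg <- x$lrg; crp <- x$crp; fcal <- x$fcal
  if (anyNA(lrg) || anyNA(crp)) abort("serum markers (lrg, crp) may not be missing")
  st <- function(v, cut) {
    out <- ifelse(is.na(v), "unavailable", ifelse(v <= cut, "negative", "positive"))
    factor(out, levels = .status_levels)
  }
  data.frame(lrg = st(lrg, cuts$lrg), crp = st(crp, cuts$crp),
             fcal = st(fcal, cuts$fcal))
}

status_counts <- function(status) {
  s <- cbind(as.character(status$lrg), as.character(status$crp),
             as.character(status$fcal))
  rowSums(s == "negative")
}

#' k-of-n majority rule
#'
#' Calls remission when at least `k` of the three marker statuses are
#' negative. With `k = 2` this is the two-of-three majority rule (remission
#' iff 2+ markers negative, active iff 2+ positive); with `k = 3` the
#' all-negative rule. All three statuses must be available.
#'
#' @param status data frame from [dichotomize()] (columns `lrg`, `crp`,
#'   `fcal`).
#' @param k minimum number of negative markers for a remission call.
#' @return factor of `remission`/`active` calls.
#' @export
classify_k_of_n <- function(status, k = 2) {
  if (any(status$fcal == "unavailable"))
    abort("fcal unavailable for %d record(s): the %d-of-3 rule needs all three markers",
          sum(status$fcal == "unavailable"), k)
  if (any(status$lrg == "unavailable") || any(status$crp == "unavailable"))
    abort("serum marker status unavailable")
  neg <- status_counts(status)
  factor(ifelse(neg >= k, "remission", "active"), levels = .decision_levels[1:2])
}

#' Sequential two-step triage rule
#'
#' Step one reads the two serum markers. Concordant patients are classified
#' immediately: double-negative is remission, double-positive is active, and
#' fecal calprotectin is never consulted. Only for discordant serum statuses
#' is Fcal obtained as the second step, and its status decides (negative =
#' remission). A discordant patient whose Fcal cannot be resolved is
#' `indeterminate`, never silently classified.
#'
#' `fcal_source` is a provider contract: a function taking the integer indices
#' of the discordant patients and returning their Fcal statuses. This keeps
#' the measurement lazy, so the fraction of Fcal tests actually spared is
#' observable (see [fcal_sparing_rate()]). A plain vector of statuses (or of
#' Fcal values, dichotomized at `cuts`) is also accepted.
#'
#' @param crp_status,lrg_status factors/characters in
#'   `negative`/`positive`.
#' @param fcal_source function(indices) -> statuses, or a vector of statuses
#'   (`unavailable`/`NA` allowed) or of numeric Fcal values.
#' @param cuts a [cutoff_set()], used only to dichotomize numeric
#'   `fcal_source` values.
#' @return list with `decision` (factor `remission`/`active`/`indeterminate`)
#'   and `fcal_used` (logical; `TRUE` only for serum-discordant patients).
#' @export
classify_two_step <- function(crp_status, lrg_status, fcal_source = NULL,
                              cuts = cutoff_set()) {
  crp_status <- as.character(crp_status); lrg_status <- as.character(lrg_status)
  n <- length(crp_status)
  if (length(lrg_status) != n) abort("serum status length mismatch")
  if (!all(crp_status %in% c("negative", "positive")) ||
      !all(lrg_status %in% c("negative", "positive")))
    abort("serum statuses must be 'negative' or 'positive'")
  decision <- rep(NA_character_, n)
  decision[crp_status == "negative" & lrg_status == "negative"] <- "remission"
  decision[crp_status == "positive" & lrg_status == "positive"] <- "active"
  discordant <- is.na(decision)
  fcal_used <- discordant
  if (any(discordant)) {
    idx <- which(discordant)
    fs <- if (is.function(fcal_source)) fcal_source(idx)
          else if (is.null(fcal_source)) rep(NA_character_, length(idx))
          else fcal_source[idx]
    if (is.numeric(fs))
      fs <- ifelse(is.na(fs), "unavailable",
                   ifelse(fs <= cuts$fcal, "negative", "positive"))
    fs <- as.character(fs)
    fs[is.na(fs)] <- "unavailable"
    decision[idx] <- c(negative = "remission", positive = "active",
                       unavailable = "indeterminate")[fs]
  }
  list(decision = factor(decision, levels = .decision_levels),
       fcal_used = fcal_used)
}

#' Apply a named panel rule to a cohort
#'
#' Convenience dispatcher over the rule zoo: `"two_of_three"` and
#' `"all_three"` ([classify_k_of_n()] with k = 2 and 3), the pairwise
#' both-negative rules `"crp_lrg"`, `"crp_fcal"`, `"fcal_lrg"` (remission iff
#' both named markers are negative), and `"two_step"`
#' ([classify_two_step()]).
#'
#' @param x a [cohort()].
#' @param rule rule name.
#' @param cuts a [cutoff_set()].
#' @return factor of decisions; for `"two_step"` the logical attribute
#'   `fcal_used` records which patients needed the second step.
#' @export
apply_rule <- function(x, rule = c("two_of_three", "all_three", "crp_lrg",
                                   "crp_fcal", "fcal_lrg", "two_step"),
                       cuts = cutoff_set()) {
  rule <- match.arg(rule)
  status <- dichotomize(x, cuts)
  both_negative <- function(a, b)
    factor(ifelse(a == "unavailable" | b == "unavailable", NA,
                  ifelse(a == "negative" & b == "negative", "remission", "active")),
           levels = .decision_levels[1:2])
  switch(rule,
    two_of_three = classify_k_of_n(status, 2),
    all_three    = classify_k_of_n(status, 3),
    crp_lrg      = both_negative(status$crp, status$lrg),
    crp_fcal     = both_negative(status$crp, status$fcal),
    fcal_lrg     = both_negative(status$fcal, status$lrg),
    two_step     = {
      ts <- classify_two_step(status$crp, status$lrg, status$fcal)
      structure(ts$decision, fcal_used = ts$fcal_used)
    })
}

#' Fraction of patients classified without measuring fecal calprotectin
#'
#' Under the two-step rule, patients with concordant serum statuses never need
#' the stool test. This is the economic argument for the rule.
#'
#' @param x a [cohort()].
#' @param cuts a [cutoff_set()].
#' @return fraction in `[0, 1]`.
#' @export
fcal_sparing_rate <- function(x, cuts = cutoff_set()) {
  if (anyNA(x$lrg) || anyNA(x$crp)) abort("serum markers may not be missing")
  crp_neg <- x$crp <= cuts$crp
  lrg_neg <- x$lrg <= cuts$lrg
  mean(crp_neg == lrg_neg)
}

#' Confusion matrix with remission as the positive class
#'
#' @param decisions factor/character of `remission`/`active` calls
#'   (`indeterminate` is an error: resolve or drop those first).
#' @param truth remission labels (see [empirical_roc()]).
#' @return object of class `cd_confusion`: list with `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(decisions, truth) {
  truth <- as_remission(truth)
  decisions <- as.character(decisions)
  if (length(decisions) != length(truth)) abort("decisions/truth length mismatch")
  if (anyNA(decisions) || any(decisions == "indeterminate"))
    abort("decisions contain indeterminate or missing calls")
  pred <- decisions == "remission"
  new_confusion(tp = sum(pred & truth), fn = sum(!pred & truth),
                fp = sum(pred & !truth), tn = sum(!pred & !truth))
}

#' @param tp,fn,fp,tn non-negative integer cell counts.
#' @rdname confusion_matrix
#' @export
new_confusion <- function(tp, fn, fp, tn) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    abort("confusion cells must be non-negative integers")
  structure(as.list(cells), class = "cd_confusion")
}

#' @export
print.cd_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(call = c("remission", "active"),
                              truth = c("remission", "active")))
  print(m)
  invisible(x)
}

#' Diagnostic summary of a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, PPV `tp/(tp+fp)`, NPV
#' `tn/(tn+fn)`, accuracy, and the AUC of the binary rule, which is exactly
#' the balanced accuracy `(sens + spec)/2`. Each proportion carries a 95%
#' binomial CI by the requested method; the AUC CI is a Wald interval on the
#' balanced-accuracy scale and is flagged approximate. A metric with a zero
#' denominator is reported as undefined (`NA`), never coerced to 0 or 1.
#'
#' @param cm a [confusion_matrix()].
#' @param ci_method `"clopper_pearson"` (default) or `"wald"`.
#' @param conf_level confidence level.
#' @return object of class `cd_diag_summary`: data frame with one row per
#'   metric (`sens`, `spec`, `ppv`, `npv`, `accuracy`, `auc`) and columns
#'   `estimate`, `lower`, `upper`, `k`, `n`, `ci_method`.
#' @export
summarize_confusion <- function(cm, ci_method = c("clopper_pearson", "wald"),
                                conf_level = 0.95) {
  stopifnot(inherits(cm, "cd_confusion"))
  ci_method <- match.arg(ci_method)
  defs <- list(sens = c(cm$tp, cm$tp + cm$fn),
               spec = c(cm$tn, cm$fp + cm$tn),
               ppv = c(cm$tp, cm$tp + cm$fp),
               npv = c(cm$tn, cm$tn + cm$fn),
               accuracy = c(cm$tp + cm$tn, cm$tp + cm$fn + cm$fp + cm$tn))
  rows <- lapply(names(defs), function(met) {
    kn <- defs[[met]]
    if (kn[2] == 0)
      return(data.frame(metric = met, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, k = kn[1], n = kn[2],
                        ci_method = "undefined"))
    ci <- binomial_ci(kn[1], kn[2], ci_method, conf_level)
    data.frame(metric = met, estimate = ci$estimate, lower = ci$lower,
               upper = ci$upper, k = kn[1], n = kn[2], ci_method = ci_method)
  })
  out <- do.call(rbind, rows)
  # AUC of a binary rule = balanced accuracy; Wald CI (approximate)
  sens <- out$estimate[out$metric == "sens"]; n_pos <- cm$tp + cm$fn
  spec <- out$estimate[out$metric == "spec"]; n_neg <- cm$fp + cm$tn
  if (!is.na(sens) && !is.na(spec)) {
    auc <- (sens + spec) / 2
    z <- qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(sens * (1 - sens) / n_pos + spec * (1 - spec) / n_neg) / 2
    out <- rbind(out, data.frame(metric = "auc", estimate = auc,
                                 lower = max(0, auc - z * se),
                                 upper = min(1, auc + z * se),
                                 k = NA, n = n_pos + n_neg,
                                 ci_method = "wald_balanced_accuracy"))
  } else {
    out <- rbind(out, data.frame(metric = "auc", estimate = NA_real_,
                                 lower = NA_real_, upper = NA_real_,
                                 k = NA, n = NA, ci_method = "undefined"))
  }
  rownames(out) <- out$metric
  class(out) <- c("cd_diag_summary", "data.frame")
  out
}

#' @export
print.cd_diag_summary <- function(x, ...) {
  y <- as.data.frame(x)
  pct <- y$metric != "auc"
  fmt <- ifelse(pct,
                sprintf("%.1f%% (%.1f-%.1f)", 100 * y$estimate, 100 * y$lower, 100 * y$upper),
                sprintf("%.3f (%.3f-%.3f)", y$estimate, y$lower, y$upper))
  fmt[is.na(y$estimate)] <- "undefined"
  print(data.frame(metric = y$metric, value = fmt, ci_method = y$ci_method),
        row.names = FALSE)
  invisible(x)
}
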