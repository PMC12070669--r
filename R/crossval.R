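# Stratified k-fold cross-validation of the threshold panel rules. Cutoffs
# are refit on the training folds (Youden index per marker) and the held-out
# decisions of all folds are pooled into a single confusion matrix, so the
# pooled summary covers every patient exactly once.

#' Stratified fold assignment
#'
#' Random fold labels in `1..k`, stratified by the truth label so that fold
#' sizes within each stratum differ by at most one. Reproducible given `seed`.
#'
#' @param n number of records.
#' @param k number of folds, `2 <= k <= n`.
#' @param truth remission labels of length `n` (see [empirical_roc()]).
#' @param seed integer.
#' @return integer vector of fold labels.
#' @export
kfold_indices <- function(n, k, truth, seed) {
  if (k < 2 || k > n) abort("k must be in [2, n]")
  truth <- as_remission(truth)
  if (length(truth) != n) abort("truth length mismatch")
  folds <- integer(n)
  with_seed(seed, {
    # rotate the label sequence across strata so the remainder folds differ,
    # keeping total fold sizes balanced as well as per-stratum sizes
    offset <- 0L
    for (s in unique(truth)) {
      idx <- which(truth == s)
      folds[idx[sample.int(length(idx))]] <- (seq_along(idx) - 1L + offset) %% k + 1L
      offset <- (offset + length(idx)) %% k
    }
    folds
  })
}

fit_cutoffs <- function(x, truth) {
  cutoff_set(
    lrg = youden_cutoff(x$lrg, truth)$cutoff,
    crp = youden_cutoff(x$crp, truth)$cutoff,
    fcal = youden_cutoff(x$fcal, truth)$cutoff
  )
}

#' Cross-validated evaluation of a panel rule
#'
#' For each of `k` stratified folds, the per-marker Youden cutoffs are fitted
#' on the training folds only (unless `refit = FALSE`, in which case `cuts`
#' is used throughout -- then the pooled result equals the apparent one), the
#' rule is applied to the held-out fold, and all held-out decisions are pooled
#' into one confusion matrix.
#'
#' @param x a [cohort()] with complete markers (run [apply_exclusions()]
#'   first).
#' @param rule rule name, see [apply_rule()].
#' @param k number of folds.
#' @param seed integer driving the fold assignment.
#' @param refit refit cutoffs per training fold (default) or keep `cuts`.
#' @param cuts a [cutoff_set()]; starting cutoffs when `refit = FALSE`.
#' @param ci_method CI method for the pooled summary.
#' @return object of class `cd_cv`: list with `rule`, `k`, `folds`,
#'   `fold_cutoffs`, pooled `decisions` (cohort order), `confusion`,
#'   `summary`, and pooled `auc` (balanced accuracy of the pooled matrix).
#' @export
cv_evaluate <- function(x, rule = "two_of_three", k = 10, seed = 20140901L,
                        refit = TRUE, cuts = cutoff_set(),
                        ci_method = "clopper_pearson") {
  stopifnot(inherits(x, "cd_cohort"))
  if (anyNA(x$fcal))
    abort("fcal missing for %d record(s): run apply_exclusions() first", sum(is.na(x$fcal)))
  truth <- is_endoscopic_remission(x$msescd)
  check_two_classes(truth)
  folds <- kfold_indices(nrow(x), k, truth, seed)
  decisions <- rep(NA_character_, nrow(x))
  fold_cutoffs <- vector("list", k)
  for (f in seq_len(k)) {
    train <- folds != f
    if (length(unique(truth[train])) < 2)
      abort("training folds for fold %d contain a single class; lower k", f)
    fc <- if (refit) fit_cutoffs(as.data.frame(x)[train, ], truth[train]) else cuts
    fold_cutoffs[[f]] <- fc
    held <- which(!train)
    decisions[held] <- as.character(
      apply_rule(as.data.frame(x)[held, , drop = FALSE], rule, fc))
  }
  cm <- confusion_matrix(decisions, truth)
  sm <- summarize_confusion(cm, ci_method)
  structure(list(rule = rule, k = k, seed = seed, refit = refit,
                 folds = folds, fold_cutoffs = fold_cutoffs,
                 decisions = factor(decisions, levels = c("remission", "active")),
                 confusion = cm, summary = sm,
                 auc = sm["auc", "estimate"]),
            class = "cd_cv")
}

#' @export
print.cd_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV of rule '%s' (pooled over %d patients)\n",
              x$k, x$rule, length(x$folds)))
  print(x$summary)
  invisible(x)
}

#' Select the number of folds with the highest pooled diagnostic ability
#'
#' Evaluates `k` over `ks` (default 2 to 10) and returns the `k` maximizing
#' the pooled AUC (or accuracy), ties broken toward the smallest `k`. Note
#' that choosing k to maximize performance is optimistically biased; the
#' returned table keeps all candidates visible.
#'
#' @inheritParams cv_evaluate
#' @param ks candidate fold counts.
#' @param metric selection metric: `"auc"` (balanced accuracy of the pooled
#'   matrix, default) or `"accuracy"`.
#' @return list with `k`, `result` (the winning [cv_evaluate()] object) and
#'   `by_k` (data frame `k`, `auc`, `accuracy`).
#' @export
select_k <- function(x, rule = "two_of_three", seed = 20140901L, ks = 2:10,
                     metric = c("auc", "accuracy"), refit = TRUE,
                     cuts = cutoff_set()) {
  metric <- match.arg(metric)
  res <- lapply(ks, function(k) cv_evaluate(x, rule, k, seed, refit, cuts))
  by_k <- data.frame(
    k = ks,
    auc = vapply(res, function(r) r$auc, 0),
    accuracy = vapply(res, function(r) r$summary["accuracy", "estimate"], 0)
  )
  best <- which(by_k[[metric]] == max(by_k[[metric]]))[1L]  # smallest k wins ties
  list(k = ks[best], result = res[[best]], by_k = by_k)
}

#' Compare cross-validated rules against a reference rule
#'
#' Each rule is cross-validated (with `k` chosen by [select_k()] when `k` is
#' `NULL`), and its pooled held-out decisions are compared with the reference
#' rule's by the DeLong test on the binary prediction scores. This mirrors
#' comparing the cross-validated AUCs of competing marker combinations.
#'
#' @inheritParams cv_evaluate
#' @param rules character vector of rule names (see [apply_rule()]).
#' @param reference the reference rule (must be in `rules` or is added).
#' @param k fold count for all rules, or `NULL` to select per rule.
#' @return data frame with one row per non-reference rule: `rule`, `k`,
#'   `auc`, `auc_reference`, `z`, `p`.
#' @export
compare_rules <- function(x, rules = c("two_of_three", "all_three", "crp_fcal",
                                       "fcal_lrg", "crp_lrg"),
                          reference = "two_of_three", k = NULL,
                          seed = 20140901L) {
  rules <- union(reference, rules)
  run <- function(rule) {
    if (is.null(k)) select_k(x, rule, seed)$result
    else cv_evaluate(x, rule, k, seed)
  }
  fits <- setNames(lapply(rules, run), rules)
  truth <- is_endoscopic_remission(x$msescd)
  score <- function(fit) ifelse(fit$decisions == "remission", 0, 1) # low = remission
  ref <- fits[[reference]]
  out <- lapply(setdiff(rules, reference), function(rule) {
    dl <- delong_test(score(fits[[rule]]), score(ref), truth)
    data.frame(rule = rule, k = fits[[rule]]$k, auc = fits[[rule]]$auc,
               auc_reference = ref$auc, z = dl$z, p = dl$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  attr(out, "reference_fit") <- ref
  out
}
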