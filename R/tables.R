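# Reconstruction and audit of published accuracy tables. Published combination
# tables print five proportions (sens, spec, PPV, NPV, accuracy) to one
# decimal over known class sizes (116 remission / 114 active), so the integer
# confusion matrix behind each row is recoverable and every cell can be
# cross-checked -- including rows that turn out to be internally inconsistent.

#' Published summary tables bundled with the package
#'
#' The accuracy tables, cutoffs, class sizes, marker marginals and hazard
#' ratios that the audit and the synthetic generator are calibrated against,
#' as a list parsed from the package's JSON fixture. Rows known to be
#' internally inconsistent carry an `annotation`.
#'
#' @return named list.
#' @export
printed_tables <- function() {
  path <- system.file("extdata", "printed_tables.json", package = "cdtriad",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Reconstruct a confusion matrix from printed sensitivity and specificity
#'
#' With the class sizes known, `tp` is the nearest integer to
#' `sens * n_pos` and `tn` the nearest integer to `spec * n_neg`; the
#' remaining cells follow by complement.
#'
#' @param sens,spec proportions in `[0, 1]` (not percentages).
#' @param n_pos,n_neg class sizes (remission, active).
#' @return a [new_confusion()] object.
#' @export
#' @examples
#' reconstruct_confusion(0.897, 0.807, 116, 114)  # tp 104, fn 12, fp 22, tn 92
reconstruct_confusion <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, n_pos >= 1, n_neg >= 1)
  tp <- round(sens * n_pos)
  tn <- round(spec * n_neg)
  new_confusion(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

# the five printed proportions of a (tp, tn) pair, as percentages (vectorized)
metrics_pct <- function(tp, tn, n_pos, n_neg) {
  fn <- n_pos - tp; fp <- n_neg - tn
  list(sens = 100 * tp / n_pos,
       spec = 100 * tn / n_neg,
       ppv = ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_),
       npv = ifelse(tn + fn > 0, 100 * tn / (tn + fn), NA_real_),
       accuracy = 100 * (tp + tn) / (n_pos + n_neg))
}

#' Audit a printed table row against its reconstructed confusion matrix
#'
#' Computes the five proportions from `cm`, rounds them half away from zero to
#' `decimals` decimal places (the display convention of the printed tables),
#' and reports the match with the printed percentages; the rule AUC, when
#' printed, is checked as `(sens + spec)/2` from the exact counts rounded to
#' three decimals. Independently, an exhaustive search over all integer
#' `(tp, tn)` pairs finds the matrix minimizing the number of mismatched
#' printed cells, so a row that no matrix can explain is detected rather than
#' silently "corrected".
#'
#' @param cm a [confusion_matrix()] (usually from [reconstruct_confusion()]).
#' @param printed named numeric vector/list with `sens`, `spec`, `ppv`, `npv`,
#'   `accuracy` as printed percentages, optionally `auc` on the 0-1 scale.
#' @param decimals printed decimal places of the percentages.
#' @return list of class `cd_audit`: `metrics` (data frame `metric`,
#'   `computed`, `printed`, `match`), `n_mismatch`, and `best_fit` (`tp`,
#'   `tn`, `n_mismatch` of the best exhaustive fit over the five
#'   percentages).
#' @export
consistency_audit <- function(cm, printed, decimals = 1) {
  stopifnot(inherits(cm, "cd_confusion"))
  printed <- unlist(printed)
  need <- c("sens", "spec", "ppv", "npv", "accuracy")
  if (!all(need %in% names(printed)))
    abort("'printed' must contain %s", paste(need, collapse = ", "))
  n_pos <- cm$tp + cm$fn; n_neg <- cm$fp + cm$tn
  comp <- metrics_pct(cm$tp, cm$tn, n_pos, n_neg)
  rows <- data.frame(
    metric = need,
    computed = round_half_away(unlist(comp[need]), decimals),
    printed = as.numeric(printed[need])
  )
  if ("auc" %in% names(printed)) {
    auc <- round_half_away((cm$tp / n_pos + cm$tn / n_neg) / 2, 3)
    rows <- rbind(rows, data.frame(metric = "auc", computed = auc,
                                   printed = as.numeric(printed["auc"])))
  }
  rows$match <- !is.na(rows$computed) & rows$computed == rows$printed
  # exhaustive search: which integer matrix explains most printed percentages?
  grid <- expand.grid(tp = 0:n_pos, tn = 0:n_neg)
  g <- metrics_pct(grid$tp, grid$tn, n_pos, n_neg)
  mm <- 0L
  for (met in need) {
    gv <- round_half_away(g[[met]], decimals)
    mm <- mm + (is.na(gv) | gv != as.numeric(printed[met]))
  }
  best <- which.min(mm)
  structure(list(
    metrics = rows,
    n_mismatch = sum(!rows$match),
    best_fit = list(tp = grid$tp[best], tn = grid$tn[best],
                    n_mismatch = as.integer(min(mm)))
  ), class = "cd_audit")
}

#' @export
print.cd_audit <- function(x, ...) {
  print(x$metrics, row.names = FALSE)
  cat(sprintf("mismatches: %d | best integer fit tp=%d tn=%d (%d cell(s) unexplainable)\n",
              x$n_mismatch, x$best_fit$tp, x$best_fit$tn, x$best_fit$n_mismatch))
  invisible(x)
}

#' Audit every bundled printed table row
#'
#' Runs [reconstruct_confusion()] + [consistency_audit()] over all rows of the
#' bundled 2-marker/3-marker accuracy tables.
#'
#' @return data frame with one row per printed table row: `table`, `rule`,
#'   `n_mismatch` (reconstruction audit, five percentages + AUC when
#'   printed), `best_fit_mismatch` (cells no integer matrix can explain),
#'   `consistent` (`best_fit_mismatch == 0`), `annotation`.
#' @export
audit_printed_tables <- function() {
  pt <- printed_tables()
  n_pos <- pt$study$n_remission; n_neg <- pt$study$n_active
  one <- function(row, table) {
    printed <- c(sens = row$sens, spec = row$spec, ppv = row$ppv,
                 npv = row$npv, accuracy = row$accuracy, auc = row$auc)
    cm <- reconstruct_confusion(row$sens / 100, row$spec / 100, n_pos, n_neg)
    a <- consistency_audit(cm, printed)
    data.frame(table = table, rule = row$rule,
               n_mismatch = a$n_mismatch,
               best_fit_mismatch = a$best_fit$n_mismatch,
               consistent = a$best_fit$n_mismatch == 0L,
               annotation = if (is.null(row$annotation)) "" else row$annotation,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(pt$table2, one, table = "table2")),
    do.call(rbind, lapply(pt$table3, one, table = "table3"))
  )
  rownames(out) <- NULL
  out
}
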