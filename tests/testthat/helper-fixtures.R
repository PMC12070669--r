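# Small fixtures built in code.

# hand-written cohort of n patients; markers default to benign values,
# msescd alternates remission/active
toy_cohort <- function(n = 6, fcal = rep(100, n), msescd = rep(c(0, 5), length.out = n),
                       lrg = rep(10, n), crp = rep(0.05, n)) {
  cohort(data.frame(
    id = sprintf("T%02d", seq_len(n)),
    age_dx = 30, sex = "M", location = "L1", behavior = "B1", cdai = 100,
    lrg = lrg, crp = crp, fcal = fcal, msescd = msescd,
    stringsAsFactors = FALSE
  ))
}

# noiseless, perfectly separable cohort: constant marker values per class, so
# any training fold yields a cutoff that also separates the held-out fold
separable_cohort <- function(n = 40) {
  rem <- rep(c(TRUE, FALSE), length.out = n)
  toy_cohort(n,
             msescd = ifelse(rem, 0, 6),
             lrg = ifelse(rem, 8, 20),
             crp = ifelse(rem, 0.03, 0.5),
             fcal = ifelse(rem, 50, 400))
}

# all 8 serum/fcal status combinations
all_status_combos <- function() {
  expand.grid(lrg = c("negative", "positive"),
              crp = c("negative", "positive"),
              fcal = c("negative", "positive"),
              stringsAsFactors = FALSE)
}

# brute-force Youden scan used as an oracle against youden_cutoff()
youden_oracle <- function(values, rem) {
  thr <- sort(unique(values))
  j <- vapply(thr, function(t) mean(values[rem] <= t) + mean(values[!rem] > t) - 1, 0)
  list(cutoff = thr[which(j == max(j))[1]], youden_j = max(j))
}

# Youden cutoffs for all three markers at once
fit_cutoffs_for_test <- function(x, truth) {
  cutoff_set(lrg = youden_cutoff(x$lrg, truth)$cutoff,
             crp = youden_cutoff(x$crp, truth)$cutoff,
             fcal = youden_cutoff(x$fcal, truth)$cutoff)
}

# trapezoidal area under a cd_roc curve in (FPR, sens) space
trapezoid_auc <- function(roc) {
  fpr <- 1 - roc$spec
  ord <- order(fpr, roc$sens)
  x <- fpr[ord]; y <- roc$sens[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
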