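test_that("dichotomization is <= cutoff negative, with unavailable fcal", {
  cuts <- cutoff_set()  # 13.2 / 0.15 / 180
  st <- dichotomize(list(lrg = 8.5, crp = 0.04, fcal = 61), cuts)
  expect_true(all(unlist(st) == "negative"))
  st <- dichotomize(list(lrg = 16.7, crp = 0.22, fcal = 687), cuts)
  expect_true(all(unlist(st) == "positive"))
  # boundary: a value exactly at the cutoff is remission-side
  st <- dichotomize(list(lrg = 13.2, crp = 0.15, fcal = 180), cuts)
  expect_true(all(unlist(st) == "negative"))
  st <- dichotomize(list(lrg = 10, crp = 0.5, fcal = NA), cuts)
  expect_equal(as.character(st$fcal), "unavailable")
  expect_error(dichotomize(list(lrg = NA, crp = 0.1, fcal = 50), cuts), "serum")
  expect_error(cutoff_set(lrg = -1), "positive")
})

test_that("k-of-n majority rule counts negative markers", {
  st <- function(...) {
    v <- c(...)
    data.frame(lrg = v[1], crp = v[2], fcal = v[3])
  }
  expect_equal(as.character(classify_k_of_n(st("negative", "negative", "positive"), 2)),
               "remission")
  expect_equal(as.character(classify_k_of_n(st("negative", "positive", "positive"), 2)),
               "active")
  expect_equal(as.character(classify_k_of_n(st("negative", "negative", "negative"), 3)),
               "remission")
  expect_equal(as.character(classify_k_of_n(st("negative", "negative", "positive"), 3)),
               "active")
  expect_error(classify_k_of_n(st("negative", "negative", "unavailable"), 2),
               "all three")
})

test_that("the two-step rule triages on serum concordance and defers to Fcal", {
  ts <- classify_two_step("negative", "negative")
  expect_equal(as.character(ts$decision), "remission")
  expect_false(ts$fcal_used)
  ts <- classify_two_step("positive", "positive")
  expect_equal(as.character(ts$decision), "active")
  expect_false(ts$fcal_used)
  ts <- classify_two_step("negative", "positive", "negative")
  expect_equal(as.character(ts$decision), "remission")
  expect_true(ts$fcal_used)
  ts <- classify_two_step("positive", "negative", "positive")
  expect_equal(as.character(ts$decision), "active")
  # unresolvable fcal in the discordant arm is explicit, never guessed
  ts <- classify_two_step("negative", "positive")
  expect_equal(as.character(ts$decision), "indeterminate")
})

test_that("the lazy fcal provider is consulted only for discordant serum", {
  crp <- c("negative", "positive", "negative", "positive")
  lrg <- c("negative", "positive", "positive", "negative")
  asked <- NULL
  provider <- function(idx) {
    asked <<- idx
    rep("negative", length(idx))
  }
  ts <- classify_two_step(crp, lrg, provider)
  expect_equal(asked, c(3, 4))  # concordant rows 1-2 never trigger measurement
  expect_equal(ts$fcal_used, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(as.character(ts$decision),
               c("remission", "active", "remission", "remission"))
  # numeric fcal values are dichotomized at the cutoff set
  ts2 <- classify_two_step(crp, lrg, c(999, 999, 100, 300))
  expect_equal(as.character(ts2$decision),
               c("remission", "active", "remission", "active"))
})

test_that("two-step rule is equivalent to the 2-of-3 majority rule", {
  combos <- all_status_combos()
  ts <- classify_two_step(combos$crp, combos$lrg, combos$fcal)
  kn <- classify_k_of_n(combos, k = 2)
  expect_equal(as.character(ts$decision), as.character(kn))
  # and fcal is needed exactly when the serum markers disagree
  expect_equal(ts$fcal_used, combos$crp != combos$lrg)
})

test_that("confusion matrix counts with remission as the positive class", {
  pred <- c("remission", "remission", "active", "active")
  truth <- c(TRUE, FALSE, TRUE, FALSE)
  cm <- confusion_matrix(pred, truth)
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  all_right <- confusion_matrix(ifelse(truth, "remission", "active"), truth)
  expect_equal(all_right$fn + all_right$fp, 0)
  inverted <- confusion_matrix(ifelse(truth, "active", "remission"), truth)
  expect_equal(inverted$tp + inverted$tn, 0)
  expect_error(confusion_matrix(pred[1:3], truth), "length")
  expect_error(confusion_matrix(c("remission", "indeterminate"), c(TRUE, FALSE)),
               "indeterminate")
})

test_that("diagnostic summary reproduces reconstructed published rows", {
  # perfect rule
  s <- summarize_confusion(new_confusion(116, 0, 0, 114))
  expect_true(all(s$estimate == 1))
  # 3-marker cross-validated row: counts 104/12/22/92
  s <- summarize_confusion(new_confusion(104, 12, 22, 92))
  est <- setNames(s$estimate, s$metric)
  expect_equal(round_half_away(100 * est[c("sens", "spec", "ppv", "npv", "accuracy")], 1),
               c(sens = 89.7, spec = 80.7, ppv = 82.5, npv = 88.5, accuracy = 85.2))
  expect_equal(round_half_away(est[["auc"]], 3), 0.852)
  # all-negative row: counts 66/50/0/114
  s <- summarize_confusion(new_confusion(66, 50, 0, 114))
  est <- setNames(s$estimate, s$metric)
  expect_equal(est[["spec"]], 1)
  expect_equal(est[["ppv"]], 1)
  expect_equal(round_half_away(100 * est[c("npv", "accuracy")], 1),
               c(npv = 69.5, accuracy = 78.3))
  # its all-success CIs use the exact lower bounds
  expect_equal(round_half_away(100 * s["spec", "lower"], 1), 96.8)  # n = 114
  expect_equal(round_half_away(100 * s["ppv", "lower"], 1), 94.6)  # n = 66
})

test_that("zero-denominator metrics are undefined, not coerced", {
  s <- summarize_confusion(new_confusion(0, 0, 3, 7))  # no remission cases
  expect_true(is.na(s["sens", "estimate"]))
  expect_equal(s["sens", "ci_method"], "undefined")
  expect_true(is.na(s["auc", "estimate"]))
  s2 <- summarize_confusion(new_confusion(0, 5, 0, 7))  # no remission calls
  expect_true(is.na(s2["ppv", "estimate"]))
  expect_equal(s2["spec", "estimate"], 1)
})

test_that("summary of counted decisions is invariant to record order", {
  set.seed(111)
  truth <- runif(60) < 0.5
  pred <- ifelse(runif(60) < 0.8, ifelse(truth, "remission", "active"),
                 ifelse(truth, "active", "remission"))
  s1 <- summarize_confusion(confusion_matrix(pred, truth))
  o <- sample(60)
  s2 <- summarize_confusion(confusion_matrix(pred[o], truth[o]))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("fcal sparing rate is the concordant-serum fraction", {
  cuts <- cutoff_set()
  dneg <- toy_cohort(4, lrg = rep(8, 4), crp = rep(0.05, 4))
  expect_equal(fcal_sparing_rate(dneg, cuts), 1)
  disc <- toy_cohort(4, lrg = rep(8, 4), crp = rep(0.5, 4))
  expect_equal(fcal_sparing_rate(disc, cuts), 0)
  x <- apply_exclusions(generate_cohort(cohort_config(n = 230, seed = 12)))
  rate <- fcal_sparing_rate(x, cuts)
  ts <- apply_rule(x, "two_step", cuts)
  expect_equal(rate, 1 - mean(attr(ts, "fcal_used")))
  expect_true(rate > 0 && rate < 1)
})
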