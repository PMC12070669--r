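test_that("default config encodes the published study conditions", {
  cfg <- cohort_config()
  expect_equal(sum(cfg$msescd_category_probs), 1, tolerance = 1e-14)
  expect_equal(cfg$msescd_category_probs, c(97, 19, 54, 57, 3) / 230)
  expect_equal(cfg$missing_fcal_rate, 38 / 268)
  expect_error(cohort_config(copula_correlation = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("the mixture solver hits the printed quartiles and AUC", {
  prm <- solve_marker_mixture(202, 61, 687, auc = 0.876, p_rem = 116 / 230)
  p <- 116 / 230
  mix_cdf <- function(x) p * plnorm(x, prm$meanlog0, prm$sdlog0) +
    (1 - p) * plnorm(x, prm$meanlog1, prm$sdlog1)
  expect_equal(mix_cdf(202), 0.5, tolerance = 1e-9)
  expect_equal(mix_cdf(61), 0.25, tolerance = 1e-9)
  expect_equal(mix_cdf(687), 0.75, tolerance = 1e-9)
  # stratum separation: P(X0 < X1) for independent lognormals
  auc <- pnorm((prm$meanlog1 - prm$meanlog0) / sqrt(prm$sdlog0^2 + prm$sdlog1^2))
  expect_equal(auc, 0.876, tolerance = 1e-9)
})

test_that("generation is deterministic in (config, seed) and leaves the RNG alone", {
  cfg <- cohort_config(n = 120, seed = 7)
  set.seed(99); before <- rnorm(1)
  set.seed(99)
  a <- generate_cohort(cfg)
  expect_identical(rnorm(1), before)  # global stream untouched
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$lrg, c2$lrg))
})

test_that("edge cases: empty cohort and degenerate zero-scale markers", {
  expect_equal(nrow(generate_cohort(cohort_config(n = 0))), 0)
  cfg <- cohort_config(n = 50, seed = 3, missing_fcal_rate = 0)
  for (m in c("lrg", "crp", "fcal")) {
    cfg$markers[[m]]$sdlog0 <- 0
    cfg$markers[[m]]$sdlog1 <- 0
  }
  x <- generate_cohort(cfg)
  rem <- is_endoscopic_remission(x$msescd)
  for (m in c("lrg", "crp", "fcal")) {
    expect_equal(unique(x[[m]][rem]), exp(cfg$markers[[m]]$meanlog0))
    expect_equal(unique(x[[m]][!rem]), exp(cfg$markers[[m]]$meanlog1))
  }
})

test_that("marginals, category histogram and missingness recover at large n", {
  cfg <- cohort_config(n = 100000, seed = 20260920)
  x <- generate_cohort(cfg)
  targets <- list(lrg = c(13.1, 8.5, 16.7), crp = c(0.10, 0.04, 0.22),
                  fcal = c(202, 61, 687))
  for (m in names(targets)) {
    q <- quantile(x[[m]], c(.5, .25, .75), na.rm = TRUE, names = FALSE)
    expect_equal(q, targets[[m]], tolerance = 0.10)
  }
  expect_equal(mean(is.na(x$fcal)), 38 / 268, tolerance = 0.1)
  cat_counts <- table(cut(x$msescd, c(-1, 0, 2, 4, 10, 15)))
  expect_equal(as.numeric(cat_counts) / nrow(x), c(97, 19, 54, 57, 3) / 230,
               tolerance = 0.05)
  expect_true(all(x$msescd >= 0 & x$msescd <= 15))
})

test_that("markers correlate with endoscopic severity at study size", {
  for (seed in c(1, 2, 3)) {
    x <- generate_cohort(cohort_config(n = 230, seed = seed))
    x <- apply_exclusions(x)
    for (m in c("lrg", "crp", "fcal"))
      expect_gt(spearman_cor(x[[m]], x$msescd), 0.3)
  }
})

test_that("survival generation recovers the configured hazard ratio", {
  cfg <- cohort_config(n = 5000, seed = 42)
  x <- apply_exclusions(generate_cohort(cfg))
  x <- generate_survival(x, cfg)
  stratum <- classify_k_of_n(dichotomize(x), k = 2)
  est <- cox_univariate(x$fu_relapse_t, x$fu_relapse_e, stratum, level = "remission")
  expect_gt(est$hr, 0.15)
  expect_lt(est$hr, 0.27)
  expect_true(est$ci_low < 0.20 && 0.20 < est$ci_high)
})

test_that("degenerate survival configs behave as declared", {
  cfg <- cohort_config(n = 80, seed = 5)
  x <- apply_exclusions(generate_cohort(cfg))
  # immediate censoring window: nobody can have an event
  cfg2 <- cfg; cfg2$survival$censor <- c(1e-9, 2e-9)
  y <- generate_survival(x, cfg2)
  expect_equal(sum(y$fu_relapse_e), 0)
  expect_true(all(y$fu_relapse_t > 0))
  # nonpositive rates are rejected
  cfg3 <- cfg; cfg3$survival$relapse$rate <- 0
  expect_error(generate_survival(x, cfg3), "positive")
  # missing fcal blocks the default rule stratum
  expect_error(generate_survival(generate_cohort(cohort_config(n = 100, seed = 6)),
                                 cfg),
               "fcal is missing")
})

test_that("a null hazard ratio produces null log-rank behavior", {
  cfg <- cohort_config(n = 150, seed = 10)
  for (ep in c("relapse", "hosp", "surg")) cfg$survival[[ep]]$hr <- 1
  p <- vapply(1:40, function(i) {
    x <- apply_exclusions(generate_cohort(cohort_config(n = 150, seed = i)))
    y <- generate_survival(x, cfg, seed = 1000 + i)
    stratum <- classify_k_of_n(dichotomize(y), k = 2)
    logrank_test(y$fu_relapse_t, y$fu_relapse_e, stratum)$p
  }, 0)
  # under the null, small p-values appear at their nominal rate
  expect_lt(mean(p < 0.05), 0.2)
  expect_gt(mean(p < 0.5), 0.2)
})
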