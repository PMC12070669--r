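test_that("mSES-CD total sums 18 item scores and validates the 0-3 scale", {
  expect_identical(msescd_total(matrix(0, 6, 3)), 0L)
  expect_identical(msescd_total(matrix(3, 6, 3)), 54L)
  one_seg <- matrix(0, 6, 3); one_seg[2, ] <- c(1, 1, 1)
  expect_identical(msescd_total(one_seg), 3L)
  expect_error(msescd_total(matrix(4, 6, 3)), "0, 1, 2, 3")
  expect_error(msescd_total(matrix(0, 5, 3)), "6 segments")
})

test_that("mSES-CD total is monotone in every item score", {
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(sample(0:2, 18, TRUE), 6, 3)
    i <- sample(6, 1); j <- sample(3, 1)
    m2 <- m; m2[i, j] <- m[i, j] + 1
    expect_gt(msescd_total(m2), msescd_total(m))
  }
})

test_that("remission definitions use the published thresholds", {
  expect_true(is_endoscopic_remission(0))
  expect_true(is_endoscopic_remission(2))
  expect_false(is_endoscopic_remission(3))
  expect_error(is_endoscopic_remission(-1), "non-negative")
  expect_true(is_clinical_remission(0))
  expect_true(is_clinical_remission(149))
  expect_false(is_clinical_remission(150))
  expect_error(is_clinical_remission(-5), "non-negative")
})

test_that("cohort validation catches structural problems", {
  x <- toy_cohort(4)
  expect_s3_class(x, "cd_cohort")
  df <- as.data.frame(x)
  df2 <- df; df2$id[2] <- df2$id[1]
  expect_error(cohort(df2), "duplicate")
  df3 <- df; df3$lrg[1] <- NA
  expect_error(cohort(df3), "serum")
  df4 <- df; df4$crp[3] <- -1
  expect_error(cohort(df4), "negative")
  df5 <- df; df5$msescd[1] <- 2.5
  expect_error(cohort(df5), "msescd")
  df6 <- df; df6$extra_col <- 1
  expect_error(cohort(df6), "unknown")
})

test_that("quantitation flags mark out-of-range assays without altering values", {
  x <- toy_cohort(4, lrg = c(4.9, 5.0, 100, 101), fcal = c(0.5, 0.65, 84000, NA))
  fl <- quantitation_flags(x)
  expect_identical(fl$lrg_oor, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(fl$fcal_oor, c(TRUE, FALSE, FALSE, NA))
  expect_identical(x$lrg, c(4.9, 5.0, 100, 101))  # never clamped
})

test_that("exclusion removes exactly the missing-Fcal records with a complete log", {
  x <- toy_cohort(10, fcal = c(100, NA, 200, NA, 50, 60, NA, 80, 90, 10))
  kept <- apply_exclusions(x)
  expect_equal(nrow(kept), 7)
  log <- exclusion_log(kept)
  expect_equal(nrow(log), 3)
  expect_setequal(log$id, c("T02", "T04", "T07"))
  expect_equal(nrow(kept) + nrow(log), nrow(x))
  # idempotent
  again <- apply_exclusions(kept)
  expect_equal(as.data.frame(again), as.data.frame(kept))
  expect_equal(nrow(exclusion_log(again)), 3)
  # identity when nothing is missing
  clean <- toy_cohort(5)
  expect_equal(as.data.frame(apply_exclusions(clean)), as.data.frame(clean))
})

test_that("cohort CSV round-trip is the identity, including missing fcal", {
  x <- generate_cohort(cohort_config(n = 230, seed = 404))
  x <- generate_survival(x, cohort_config(n = 230, seed = 404),
                         stratum = ifelse(is_endoscopic_remission(x$msescd),
                                          "remission", "active"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(x, path)
  y <- read_cohort(path)
  expect_identical(names(x), names(y))
  for (nm in names(x)) expect_identical(x[[nm]], y[[nm]])
  expect_true(anyNA(y$fcal))
})

test_that("cohort CSV reader names the offending row and column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age_dx,sex,location,behavior,cdai,lrg,crp,fcal,msescd",
               "a,30,M,L1,B1,100,10,0.05,100,0",
               "b,30,M,L1,B1,100,oops,0.05,100,0"), path)
  expect_error(read_cohort(path), "'lrg', row 2")

  writeLines(c("id,age_dx,sex,location,behavior,cdai,lrg,crp,fcal,msescd,mystery",
               "a,30,M,L1,B1,100,10,0.05,100,0,1"), path)
  expect_error(read_cohort(path), "mystery")

  writeLines(c("id,age_dx,sex,location,behavior,cdai,lrg,crp,fcal,msescd",
               "a,30,M,L1,B1,100,10,0.05,100,0",
               "a,30,F,L2,B2,120,11,0.06,,1"), path)
  expect_error(read_cohort(path), "duplicate")

  # empty fcal cell reads as missing; minimal single-row file works
  writeLines(c("id,age_dx,sex,location,behavior,cdai,lrg,crp,fcal,msescd",
               "a,30,M,L1,B1,100,10,0.05,,0"), path)
  y <- read_cohort(path)
  expect_equal(nrow(y), 1)
  expect_true(is.na(y$fcal))
})

test_that("per-segment columns fill in an empty msescd total", {
  path <- withr::local_tempfile(fileext = ".csv")
  segs <- paste0("seg", rep(1:6, times = 3), "_",
                 rep(c("ulcer_size", "ulcer_area", "lesion_area"), each = 6))
  header <- paste(c("id,age_dx,sex,location,behavior,cdai,lrg,crp,fcal,msescd",
                    paste(segs, collapse = ",")), collapse = ",")
  vals <- rep(0, 18); vals[1] <- 2; vals[7] <- 1  # seg1 ulcer_size 2, ulcer_area 1
  writeLines(c(header,
               paste(c("a,30,M,L1,B1,100,10,0.05,100,",
                       paste(vals, collapse = ",")), collapse = ",")), path)
  expect_equal(read_cohort(path)$msescd, 3)
})
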