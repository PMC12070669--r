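# Cohort data model: one row per patient, markers in their clinical units,
# mSES-CD endoscopic score, CDAI, optional per-endpoint follow-up.

.cohort_cols <- c("id", "age_dx", "sex", "location", "behavior", "cdai",
                  "lrg", "crp", "fcal", "msescd")
.fu_cols <- c("fu_relapse_t", "fu_relapse_e", "fu_hosp_t", "fu_hosp_e",
              "fu_surg_t", "fu_surg_e")
.seg_cols <- as.vector(outer(paste0("seg", 1:6), c("ulcer_size", "ulcer_area",
              "lesion_area"), function(a, b) paste(a, b, sep = "_")))

# quantitation ranges of the assays; values outside are flagged, never clamped
.lrg_range  <- c(5.0, 100)
.fcal_range <- c(0.65, 84000)

#' Construct and validate a patient cohort
#'
#' A cohort is a `data.frame` (class `cd_cohort`) with one row per patient and
#' the columns `id`, `age_dx`, `sex` (`"M"`/`"F"`), `location`
#' (`"L1"`/`"L2"`/`"L3"`), `behavior` (`"B1"`/`"B2"`/`"B3"`), `cdai`, the
#' marker triple `lrg` (µg/mL), `crp` (mg/dL), `fcal` (µg/g), `msescd`, and
#' optional follow-up columns `fu_{relapse,hosp,surg}_{t,e}` (time in years,
#' event flag 0/1). `fcal` may be `NA` (stool specimen not obtained); missing
#' fecal calprotectin is a first-class state distinct from 0, so the exclusion
#' flow of a real study can be reproduced. Serum markers must be observed.
#'
#' @param df data frame with the columns above (follow-up columns optional).
#' @param provenance free-form list recording where the rows came from
#'   (source file, or generator config and seed).
#' @param exclusion_log data frame with columns `id`, `reason` for patients
#'   already removed upstream (usually empty).
#' @return a `cd_cohort` data frame.
#' @seealso [read_cohort()], [generate_cohort()], [apply_exclusions()]
#' @export
cohort <- function(df, provenance = list(), exclusion_log = empty_exclusion_log()) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.cohort_cols, names(df))
  if (length(missing_cols))
    abort("cohort is missing column(s): %s", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), c(.cohort_cols, .fu_cols, .seg_cols))
  if (length(extra))
    abort("unknown cohort column(s): %s", paste(extra, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    abort("duplicate patient id(s): %s",
          paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  for (m in intersect(c("lrg", "crp", "fcal", "cdai", "msescd", "age_dx", .fu_cols),
                      names(df))) {
    if (!is.numeric(df[[m]]) && !all(is.na(df[[m]])))
      abort("column '%s' must be numeric", m)
    df[[m]] <- as.numeric(df[[m]])  # one storage type, so round-trips compare
  }
  if (anyNA(df$lrg) || anyNA(df$crp))
    abort("serum markers (lrg, crp) may not be missing")
  for (m in c("lrg", "crp")) if (any(df[[m]] < 0))
    abort("negative values in '%s'", m)
  if (any(df$fcal < 0, na.rm = TRUE)) abort("negative values in 'fcal'")
  if (anyNA(df$msescd) || any(df$msescd < 0 | df$msescd != floor(df$msescd)))
    abort("'msescd' must be a non-negative integer")
  if (any(df$msescd > 54)) abort("'msescd' exceeds the maximum total of 54")
  if (anyNA(df$cdai) || any(df$cdai < 0)) abort("'cdai' must be non-negative")
  for (tcol in intersect(.fu_cols[c(1, 3, 5)], names(df))) {
    if (any(df[[tcol]] <= 0, na.rm = TRUE)) abort("'%s' must be > 0", tcol)
  }
  for (ecol in intersect(.fu_cols[c(2, 4, 6)], names(df))) {
    if (!all(df[[ecol]] %in% c(0, 1, NA))) abort("'%s' must be 0/1", ecol)
  }
  structure(df, class = c("cd_cohort", "data.frame"),
            provenance = provenance, exclusion_log = exclusion_log)
}

empty_exclusion_log <- function() {
  data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
}

#' @export
print.cd_cohort <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<cd_cohort> %d patients", n))
  if (n) {
    cat(sprintf(" | endoscopic remission %d (%.0f%%) | missing Fcal %d",
                sum(x$msescd <= 2), 100 * mean(x$msescd <= 2),
                sum(is.na(x$fcal))))
  }
  cat("\n")
  nexcl <- nrow(attr(x, "exclusion_log"))
  if (nexcl) cat(sprintf("  exclusion log: %d patient(s)\n", nexcl))
  invisible(x)
}

#' Total mSES-CD score from per-segment item scores
#'
#' The modified Simple Endoscopic Score for Crohn's Disease rates three items
#' (ulcer size, ulcer area, lesion area) in six bowel segments (proximal
#' ileum, distal ileum, right colon, transverse colon, left colon, rectum),
#' each item on a 0-3 scale. The total is the sum of the 18 item scores,
#' ranging 0-54.
#'
#' @param scores 6 x 3 numeric matrix or data frame (segments x items), every
#'   entry in `{0, 1, 2, 3}`.
#' @return integer total in `[0, 54]`.
#' @export
#' @examples
#' msescd_total(matrix(0, 6, 3))               # 0
#' msescd_total(matrix(3, 6, 3))               # 54
msescd_total <- function(scores) {
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(6, 3)))
    abort("expected 6 segments x 3 items, got %d x %d", nrow(scores), ncol(scores))
  if (anyNA(scores) || !all(scores %in% 0:3))
    abort("every item score must be an integer in {0, 1, 2, 3}")
  as.integer(sum(scores))
}

#' Endoscopic remission from the mSES-CD total
#'
#' Endoscopic remission is an mSES-CD total of 0 to 2.
#'
#' @param msescd non-negative integer total (vectorized).
#' @return logical, `TRUE` for remission.
#' @export
is_endoscopic_remission <- function(msescd) {
  if (anyNA(msescd) || any(msescd < 0)) abort("'msescd' must be non-negative")
  msescd <= 2
}

#' Clinical remission from the CDAI
#'
#' Clinical remission is a Crohn's Disease Activity Index strictly below 150.
#'
#' @param cdai non-negative score (vectorized).
#' @return logical, `TRUE` for clinical remission.
#' @export
is_clinical_remission <- function(cdai) {
  if (anyNA(cdai) || any(cdai < 0)) abort("'cdai' must be non-negative")
  cdai < 150
}

#' Flag marker values outside the assay quantitation range
#'
#' LRG is quantitative over 5.0-100 µg/mL and fecal calprotectin over
#' 0.65-84000 µg/g. Values outside these ranges are flagged but never
#' altered; the flags let downstream users decide how to treat extrapolated
#' readings.
#'
#' @param x a [cohort()].
#' @return data frame with `id`, `lrg_oor`, `fcal_oor` (logical; `NA` when the
#'   marker is missing).
#' @export
quantitation_flags <- function(x) {
  stopifnot(inherits(x, "cd_cohort"))
  data.frame(
    id = x$id,
    lrg_oor = x$lrg < .lrg_range[1] | x$lrg > .lrg_range[2],
    fcal_oor = x$fcal < .fcal_range[1] | x$fcal > .fcal_range[2],
    stringsAsFactors = FALSE
  )
}

#' Exclude patients whose fecal calprotectin could not be measured
#'
#' Removes records with missing `fcal` (insufficient stool specimen) and logs
#' each excluded id with its reason. The operation is idempotent and
#' bookkeeping-complete: retained + logged = input.
#'
#' @param x a [cohort()].
#' @return the filtered `cd_cohort`; the cumulative exclusion log is available
#'   via `attr(, "exclusion_log")` and [exclusion_log()].
#' @export
apply_exclusions <- function(x) {
  stopifnot(inherits(x, "cd_cohort"))
  drop <- is.na(x$fcal)
  log_new <- data.frame(id = x$id[drop],
                        reason = rep("fcal not measurable", sum(drop)),
                        stringsAsFactors = FALSE)
  kept <- as.data.frame(x)[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  cohort(kept, provenance = attr(x, "provenance"),
         exclusion_log = rbind(attr(x, "exclusion_log"), log_new))
}

#' @rdname apply_exclusions
#' @export
exclusion_log <- function(x) attr(x, "exclusion_log")

#' Read / write a cohort CSV
#'
#' The interchange format is a plain CSV with header `id, age_dx, sex,
#' location, behavior, cdai, lrg, crp, fcal, msescd` plus optional follow-up
#' columns `fu_relapse_t, fu_relapse_e, fu_hosp_t, fu_hosp_e, fu_surg_t,
#' fu_surg_e` and optional per-segment item columns
#' `seg{1..6}_{ulcer_size,ulcer_area,lesion_area}`. An empty cell is a missing
#' value. When segment columns are present and `msescd` is empty, the total is
#' computed with [msescd_total()]. Writing uses 17 significant digits so that
#' `read_cohort(write_cohort(x))` is the identity.
#'
#' @param path file path.
#' @return `read_cohort()`: a [cohort()]. `write_cohort()`: `path`, invisibly.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(id = "character"))
  extra <- setdiff(names(df), c(.cohort_cols, .fu_cols, .seg_cols))
  if (length(extra))
    abort("unknown column(s) in %s: %s", path, paste(extra, collapse = ", "))
  for (m in intersect(c("age_dx", "cdai", "lrg", "crp", "fcal", "msescd",
                        .fu_cols, .seg_cols), names(df))) {
    if (is.character(df[[m]])) {
      df[[m]][!nzchar(trimws(df[[m]]))] <- NA
      bad <- which(!is.na(df[[m]]) & is.na(suppressWarnings(as.numeric(df[[m]]))))
      if (length(bad))
        abort("non-numeric value in column '%s', row %d ('%s')", m, bad[1], df[[m]][bad[1]])
    }
    df[[m]] <- as.numeric(df[[m]])  # read.csv may infer integer/logical
  }
  segs <- intersect(.seg_cols, names(df))
  if (length(segs) == 18 && ("msescd" %in% names(df)) && anyNA(df$msescd)) {
    need <- which(is.na(df$msescd))
    for (i in need)
      df$msescd[i] <- msescd_total(matrix(as.numeric(df[i, .seg_cols]), 6, 3))
  }
  cohort(df, provenance = list(source = path))
}

#' @param x a [cohort()].
#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cd_cohort"))
  out <- as.data.frame(x)
  for (j in names(out)) {
    if (is.numeric(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- ""
      out[[j]] <- s
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
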