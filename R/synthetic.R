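# Synthetic cohort generator. Markers are log-normal conditional on
# endoscopic status (remission vs active), with a distinct location and
# log-scale per stratum, coupled across markers by a Gaussian copula that
# leaves the marginals untouched. mSES-CD is sampled by category (only the
# category histogram of the study population is published) and uniformly
# within category.

.msescd_cat_lo <- c(0, 1, 3, 5, 11)
.msescd_cat_hi <- c(0, 2, 4, 10, 15)

#' Default generator configuration
#'
#' Builds a [generate_cohort()] configuration whose mixture marginals
#' reproduce published cohort characteristics of a Crohn's disease
#' surveillance population:
#' mSES-CD category counts 97 / 19 / 54 / 57 / 3 over the categories
#' 0, 1-2, 3-4, 5-10, 11-15 (hence 116/230 in endoscopic remission),
#' marker medians (IQR) of LRG 13.1 (8.5-16.7) µg/mL, CRP 0.10 (0.04-0.22)
#' mg/dL, Fcal 202 (61-687) µg/g, single-marker AUCs for remission of
#' 0.886 / 0.816 / 0.876, and a 38/268 rate of unmeasurable fecal
#' calprotectin. Per-stratum log-normal location/scale parameters are solved
#' numerically so that the remission/active mixture hits all three printed
#' quartiles exactly while the stratum separation matches the target AUC
#' (see [solve_marker_mixture()]).
#'
#' @param n number of patients to enrol (before the missing-Fcal exclusion).
#' @param seed integer seed stored in the config; all generation is a pure
#'   function of (config, seed).
#' @param copula_correlation 3x3 positive-definite cross-marker correlation of
#'   the Gaussian copula (residual dependence within stratum). The default,
#'   0.3 off-diagonal, is a free parameter of the generator: conditional
#'   inter-marker correlations are not published.
#' @param missing_fcal_rate probability that the stool specimen is
#'   insufficient (missing completely at random).
#' @param survival per-endpoint exponential event rates (events per
#'   person-year in the rule-positive, i.e. unfavorable, stratum), hazard
#'   ratios of the rule-negative stratum, and the uniform censoring window in
#'   years.
#' @return a list of class `cd_cohort_config`.
#' @export
cohort_config <- function(n = 268L,
                          seed = 20140901L,
                          copula_correlation = matrix(c(1, .3, .3, .3, 1, .3, .3, .3, 1), 3),
                          missing_fcal_rate = 38 / 268,
                          survival = list(
                            relapse = list(rate = 0.080, hr = 0.20),
                            hosp    = list(rate = 0.030, hr = 0.21),
                            surg    = list(rate = 0.028, hr = 0.24),
                            censor  = c(0.5, 7.0)
                          )) {
  probs <- c(97, 19, 54, 57, 3) / 230
  p_rem <- sum(probs[1:2])
  markers <- list(
    lrg  = solve_marker_mixture(13.1, 8.5, 16.7, auc = 0.886, p_rem = p_rem),
    crp  = solve_marker_mixture(0.10, 0.04, 0.22, auc = 0.816, p_rem = p_rem),
    fcal = solve_marker_mixture(202, 61, 687, auc = 0.876, p_rem = p_rem)
  )
  cfg <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    msescd_category_probs = probs,
    markers = markers,
    copula_correlation = copula_correlation,
    missing_fcal_rate = missing_fcal_rate,
    # demographics, matched on marginals only
    sex_p_male = 149 / 230,
    location_probs = c(L1 = 50, L2 = 47, L3 = 133) / 230,
    behavior_probs = c(B1 = 75, B2 = 94, B3 = 61) / 230,
    age_dx = list(meanlog = log(24), sdlog = log(34 / 19) / (2 * qnorm(0.75))),
    cdai = list(meanlog = log(135), sdlog = log(179 / 58) / (2 * qnorm(0.75)),
                severity_link = 0.3),
    survival = survival
  )
  class(cfg) <- "cd_cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (abs(sum(cfg$msescd_category_probs) - 1) > 1e-12)
    abort("mSES-CD category probabilities must sum to 1")
  R <- cfg$copula_correlation
  if (!isTRUE(all.equal(R, t(R))) || inherits(try(chol(R), silent = TRUE), "try-error"))
    abort("copula correlation matrix must be symmetric positive-definite")
  if (cfg$missing_fcal_rate < 0 || cfg$missing_fcal_rate > 1)
    abort("missing_fcal_rate must be in [0, 1]")
  for (ep in c("relapse", "hosp", "surg")) {
    s <- cfg$survival[[ep]]
    if (is.null(s) || s$rate <= 0 || s$hr <= 0)
      abort("survival rate and hazard ratio for '%s' must be positive", ep)
  }
  invisible(cfg)
}

#' Solve a two-stratum log-normal mixture from printed quartiles and AUC
#'
#' Finds per-stratum log-normal parameters (`meanlog0`, `sdlog0` for the
#' remission stratum; `meanlog1`, `sdlog1` for the active stratum) such that
#' the mixture with remission weight `p_rem` has exactly the target median and
#' quartiles, and the two strata are separated so that
#' `P(X_remission < X_active) = auc` (the Mann-Whitney AUC of the marker for
#' remission). Three free parameters (common location, mean log-scale,
#' log-scale asymmetry) are matched to the three log-quantile equations by a
#' damped Newton iteration; the AUC constraint fixes the location offset.
#'
#' @param med,q1,q3 target mixture median and quartiles (marker units).
#' @param auc target Mann-Whitney AUC of the marker for remission.
#' @param p_rem mixture weight of the remission stratum.
#' @return list with `meanlog0`, `sdlog0`, `meanlog1`, `sdlog1` and the
#'   `targets` used.
#' @export
solve_marker_mixture <- function(med, q1, q3, auc, p_rem) {
  stopifnot(q1 < med, med < q3, auc > 0.5, auc < 1, p_rem > 0, p_rem < 1)
  z <- qnorm(auc)
  mix_q <- function(q, mu0, mu1, s0, s1) {
    f <- function(x) p_rem * stats::plnorm(x, mu0, s0) +
      (1 - p_rem) * stats::plnorm(x, mu1, s1) - q
    uniroot(f, c(med * 1e-9, med * 1e9), tol = med * 1e-12)$root
  }
  obj <- function(par) { # par = (mid-location, log mean-scale, scale asymmetry)
    s0 <- exp(par[2] - par[3]); s1 <- exp(par[2] + par[3])
    d <- z * sqrt(s0^2 + s1^2) / 2
    mu0 <- par[1] - d; mu1 <- par[1] + d
    c(log(mix_q(0.50, mu0, mu1, s0, s1) / med),
      log(mix_q(0.25, mu0, mu1, s0, s1) / q1),
      log(mix_q(0.75, mu0, mu1, s0, s1) / q3))
  }
  par <- c(log(med), log(log(q3 / q1) / 1.349), 0)
  for (it in 1:200) {
    f0 <- obj(par)
    if (max(abs(f0)) < 1e-11) break
    J <- matrix(0, 3, 3)
    for (j in 1:3) { e <- par; e[j] <- e[j] + 1e-7; J[, j] <- (obj(e) - f0) / 1e-7 }
    par <- par - pmin(pmax(solve(J, f0), -0.5), 0.5)
  }
  s0 <- exp(par[2] - par[3]); s1 <- exp(par[2] + par[3])
  d <- z * sqrt(s0^2 + s1^2) / 2
  list(meanlog0 = par[1] - d, sdlog0 = s0,
       meanlog1 = par[1] + d, sdlog1 = s1,
       targets = list(med = med, q1 = q1, q3 = q3, auc = auc, p_rem = p_rem))
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` patients: an mSES-CD category from the configured
#' histogram with a uniform integer total within the category; the marker
#' triple from the stratum-conditional log-normals of the config, coupled by
#' its Gaussian copula; fecal calprotectin set missing (insufficient stool)
#' completely at random at the configured rate; and demographics matched on
#' marginals. Identical `(config, seed)` gives an identical cohort; the global
#' RNG state is left untouched.
#'
#' @param config a [cohort_config()].
#' @param seed integer; defaults to `config$seed`.
#' @return a [cohort()] without follow-up columns (see [generate_survival()]).
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_config(config)
  n <- config$n
  with_seed(seed, {
    if (n == 0L) {
      df <- data.frame(id = character(), age_dx = numeric(), sex = character(),
                       location = character(), behavior = character(),
                       cdai = numeric(), lrg = numeric(), crp = numeric(),
                       fcal = numeric(), msescd = integer(),
                       stringsAsFactors = FALSE)
      return(cohort(df, provenance = list(generator = "cohort_config", seed = seed)))
    }
    ci <- sample.int(5L, n, replace = TRUE, prob = config$msescd_category_probs)
    width <- .msescd_cat_hi[ci] - .msescd_cat_lo[ci] + 1L
    ms <- .msescd_cat_lo[ci] + floor(runif(n) * width)
    rem <- ms <= 2
    # Gaussian copula: correlated uniforms, then per-stratum lognormal quantiles
    Z <- matrix(rnorm(n * 3), n, 3) %*% chol(config$copula_correlation)
    U <- pnorm(Z)
    mk <- function(u, prm) {
      stats::qlnorm(u, ifelse(rem, prm$meanlog0, prm$meanlog1),
                    ifelse(rem, prm$sdlog0, prm$sdlog1))
    }
    lrg <- mk(U[, 1], config$markers$lrg)
    crp <- mk(U[, 2], config$markers$crp)
    fcal <- mk(U[, 3], config$markers$fcal)
    fcal[runif(n) < config$missing_fcal_rate] <- NA
    # CDAI: lognormal marginal with a weak latent link to endoscopic severity
    sev_z <- qnorm((rank(ms, ties.method = "random") - 0.5) / n)
    a <- config$cdai$severity_link
    cdai_z <- a * sev_z + sqrt(1 - a^2) * rnorm(n)
    cdai <- round(exp(config$cdai$meanlog + config$cdai$sdlog * cdai_z))
    df <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      age_dx = round(stats::rlnorm(n, config$age_dx$meanlog, config$age_dx$sdlog)),
      sex = ifelse(runif(n) < config$sex_p_male, "M", "F"),
      location = sample(names(config$location_probs), n, TRUE, config$location_probs),
      behavior = sample(names(config$behavior_probs), n, TRUE, config$behavior_probs),
      cdai = cdai,
      lrg = lrg, crp = crp, fcal = fcal,
      msescd = as.integer(ms),
      stringsAsFactors = FALSE
    )
    cohort(df, provenance = list(generator = "cohort_config", seed = seed))
  })
}

#' Attach synthetic follow-up to a cohort
#'
#' Event times are exponential within stratum: the rule-positive (unfavorable)
#' stratum gets the configured baseline rate, the rule-negative stratum that
#' rate times the configured hazard ratio. Censoring is independent uniform
#' over the configured window (emulating staggered enrolment with a fixed
#' analysis date). The default stratum is the two-of-three majority rule at
#' the cutoffs in `cuts`, so records must have complete markers (run
#' [apply_exclusions()] first) unless `stratum` is supplied.
#'
#' @param x a [cohort()].
#' @param config a [cohort_config()] (its `survival` entry is used).
#' @param stratum optional factor/character of `"remission"`/`"active"` rule
#'   calls; defaults to [classify_k_of_n()] with `k = 2` at `cuts`.
#' @param cuts a [cutoff_set()] used when `stratum` is derived.
#' @param seed integer; defaults to `config$seed + 1` so that marker and
#'   follow-up streams differ.
#' @return the cohort with the six follow-up columns filled in.
#' @export
generate_survival <- function(x, config = cohort_config(), stratum = NULL,
                              cuts = cutoff_set(), seed = config$seed + 1L) {
  stopifnot(inherits(x, "cd_cohort"))
  validate_config(config)
  if (is.null(stratum)) {
    if (anyNA(x$fcal))
      abort("fcal is missing for %d record(s); exclude them or supply 'stratum'",
            sum(is.na(x$fcal)))
    stratum <- classify_k_of_n(dichotomize(x, cuts), k = 2)
  }
  favorable <- as.character(stratum) == "remission"
  if (length(favorable) != nrow(x)) abort("'stratum' length mismatch")
  cw <- config$survival$censor
  df <- as.data.frame(x)
  df <- with_seed(seed, {
    for (ep in c("relapse", "hosp", "surg")) {
      s <- config$survival[[ep]]
      h <- ifelse(favorable, s$rate * s$hr, s$rate)
      tt <- rexp(nrow(df), rate = pmax(h, 1e-300))
      cc <- runif(nrow(df), cw[1], cw[2])
      df[[paste0("fu_", ep, "_t")]] <- pmin(tt, cc)
      df[[paste0("fu_", ep, "_e")]] <- as.integer(tt <= cc)
    }
    df
  })
  cohort(df, provenance = c(attr(x, "provenance"), list(survival_seed = seed)),
         exclusion_log = attr(x, "exclusion_log"))
}
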