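# Supporting statistics: DeLong comparison of correlated AUCs, Spearman rank
# correlation, Mann-Whitney rank-sum test, and binomial confidence intervals.

#' DeLong test for two correlated AUCs
#'
#' Compares the remission AUCs of two markers measured on the same patients,
#' using the DeLong placement-value variance of the paired AUC difference.
#' Markers follow the package orientation (low value = remission).
#'
#' @param marker_a,marker_b numeric marker values on the same subjects.
#' @param truth remission labels (see [empirical_roc()]).
#' @return list with `auc_a`, `auc_b`, `z`, `p` (two-sided), `var_diff`.
#' @export
delong_test <- function(marker_a, marker_b, truth) {
  rem <- check_two_classes(as_remission(truth))
  if (length(marker_a) != length(rem) || length(marker_b) != length(rem))
    abort("marker/truth length mismatch")
  a <- delong_components(-marker_a, rem)
  b <- delong_components(-marker_b, rem)
  m <- sum(rem); n <- sum(!rem)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (vd <= .Machine$double.eps) {
    warning("degenerate DeLong variance (identical placement values); p = 1")
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = p, var_diff = vd)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), e.g. between a
#' marker and the mSES-CD endoscopic score.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation; `NA` with a warning when either vector is
#'   constant (the coefficient is undefined).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x/y length mismatch")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort("missing values")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(rank(x), rank(y))
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two groups. With both group sizes at most 8 and no
#' ties across the pooled sample, the exact null distribution of U is used;
#' otherwise the normal approximation with tie-corrected variance.
#'
#' @param a,b numeric vectors (e.g. marker values in the remission and active
#'   groups).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact distribution;
#'   default decides as above.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation.
#' @return list with `U` (statistic of group `a`), `p`, `variance` (of U under
#'   the null, tie-corrected; `NA` in exact mode), `method`.
#' @export
ranksum_test <- function(a, b, exact = NULL, continuity = FALSE) {
  if (!length(a) || !length(b)) abort("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) abort("missing values")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  ties <- table(r)
  has_ties <- any(ties > 1)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- n1 <= 8 && n2 <= 8 && !has_ties
  if (exact && has_ties) {
    warning("ties present: falling back to the tie-corrected normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)))
    return(list(U = U, p = p, variance = NA_real_, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    warning("all observations tied: p = 1")
    return(list(U = U, p = 1, variance = v, method = "normal"))
  }
  z <- (U - mu)
  if (continuity) z <- z - sign(z) * 0.5
  p <- 2 * pnorm(-abs(z / sqrt(v)))
  list(U = U, p = min(1, p), variance = v, method = "normal")
}

#' Binomial proportion confidence interval
#'
#' Either the Wald interval `p +/- z * sqrt(p(1-p)/n)` truncated to `[0, 1]`,
#' or the exact Clopper-Pearson interval from beta quantiles. For `k = n` the
#' Clopper-Pearson lower bound is `(alpha/2)^(1/n)`; e.g. 114/114 gives 0.968
#' and 66/66 gives 0.946 at 95% confidence.
#'
#' @param k number of successes.
#' @param n number of trials (>= 1).
#' @param method `"clopper_pearson"` (default) or `"wald"`.
#' @param conf_level confidence level.
#' @return list with `estimate`, `lower`, `upper`, `method`.
#' @export
binomial_ci <- function(k, n, method = c("clopper_pearson", "wald"),
                        conf_level = 0.95) {
  method <- match.arg(method)
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) || n < 1 ||
      k < 0 || k > n || k != floor(k) || n != floor(n))
    abort("need integers 0 <= k <= n with n >= 1")
  alpha <- 1 - conf_level
  p <- k / n
  if (method == "wald") {
    z <- qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half); hi <- min(1, p + half)
  } else {
    lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  }
  list(estimate = p, lower = lo, upper = hi, method = method)
}
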