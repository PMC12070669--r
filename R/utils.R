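#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the display convention of
#' most clinical tables, unlike [round()] which rounds half to even). Used by
#' the printed-table consistency audit so that, e.g., 85.25 renders as 85.3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_away(0.5, 0)   # 1
#' round(0.5)                # 0 (half to even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with call.=FALSE and sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# run expr with a private RNG stream seeded at `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# coerce remission labels: logical, or factor/character with a level that
# matches "remission" (the positive class)
as_remission <- function(truth) {
  if (is.logical(truth)) return(truth)
  if (is.factor(truth)) truth <- as.character(truth)
  if (is.character(truth)) {
    ok <- truth %in% c("remission", "active")
    if (!all(ok)) abort("truth labels must be 'remission'/'active' or logical")
    return(truth == "remission")
  }
  if (is.numeric(truth) && all(truth %in% c(0, 1))) return(truth == 1)
  abort("cannot interpret truth labels of class %s", class(truth)[1])
}
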