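#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), as used for the reported
#' percentages and ratios. Base `round()` rounds half to even, which would
#' turn e.g. 22.85 into 22.8 rather than 22.9.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @keywords internal
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fraction of a gene set annotated to a term, as a percent
#'
#' Computes `100 * observed / set_size` rounded half-up to one decimal, the
#' "Fraction \[%\]" column of the per-area summary tables.
#'
#' @param observed number of query-set genes annotated to the term.
#' @param set_size size of the (annotated) query set; must be positive.
#' @return percent on \[0, 100\] with one decimal.
#' @examples
#' fraction_percent(243, 2954)  # 8.2
#' fraction_percent(554, 2954)  # 18.8
#' @export
fraction_percent <- function(observed, set_size) {
  stopifnot(length(observed) == length(set_size) || length(set_size) == 1L)
  if (any(set_size <= 0)) stop("set_size must be positive")
  if (any(observed > set_size)) stop("observed exceeds set_size")
  if (any(observed < 0)) stop("observed must be non-negative")
  round_half_up(100 * observed / set_size, 1L)
}

#' Ratio of two term-membership counts, one decimal
#'
#' @param a,b positive counts; reports `a / b` rounded half-up to one decimal.
#' @return numeric scalar.
#' @examples
#' count_ratio(688, 274)  # 2.5
#' @export
count_ratio <- function(a, b) {
  if (b <= 0) stop("denominator count must be positive")
  round_half_up(a / b, 1L)
}

# derive a 32-bit sub-seed for a named pipeline stage from the run seed
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

trimws_vec <- function(x) trimws(as.character(x), which = "both")

`%||%` <- function(a, b) if (is.null(a)) b else a
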