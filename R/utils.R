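# Shared numeric helpers.

#' Round half away from zero
#'
#' Rounds to a fixed number of decimal digits with ties going up
#' (`0.5 -> 1`), the convention used in printed summary tables, rather than
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits to keep (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.4))
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

#' Integer percentage of a count
#'
#' `100 * count / total`, rounded half-up to a whole percent — the form used
#' when reporting top-k hit rates and overlap partitions.
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @return Integer-valued numeric vector of percentages.
#' @examples
#' pct_round(129, 377)
#' @export
pct_round <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total)
}

# Single-linkage grouping of sorted 1-d values: values whose consecutive gaps
# are <= tol fall in one group. Returns integer group ids aligned with the
# *input* order.
single_linkage_groups <- function(x, tol) {
  if (length(x) == 0L) return(integer(0))
  ord <- order(x)
  xs <- x[ord]
  new_group <- c(TRUE, diff(xs) > tol)
  gid_sorted <- cumsum(new_group)
  gid <- integer(length(x))
  gid[ord] <- gid_sorted
  gid
}

# ppm mass error of candidate masses relative to a reference mass.
ppm_error <- function(mass, reference) {
  (mass - reference) / reference * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a
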