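# Internal numeric helpers shared across modules.

# Round half away from zero. Staffing numbers in this package are always
# rounded commercially (-1.6 -> -2, 4.5 -> 5), never banker's-rounded.
rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)

# Ceiling with a guard against floating-point dust (12.000000000000002 -> 12).
ceil_tol <- function(x) ceiling(round(x, 9))

#' Largest-remainder apportionment
#'
#' Distribute an integer number of `seats` over categories in proportion to
#' `quotas` (any non-negative weights). Each category first receives the
#' floor of its exact share; remaining seats go to the largest fractional
#' remainders, ties broken by position.
#'
#' @param quotas Non-negative numeric weights (need not sum to `seats`).
#' @param seats Integer total to distribute.
#' @return Integer vector summing exactly to `seats`, same names as `quotas`.
#' @export
largest_remainder <- function(quotas, seats) {
  stopifnot(all(quotas >= 0), seats >= 0, seats == as.integer(seats))
  if (seats == 0 || sum(quotas) == 0) {
    return(stats::setNames(integer(length(quotas)), names(quotas)))
  }
  exact <- quotas / sum(quotas) * seats
  base <- floor(exact)
  left <- seats - sum(base)
  if (left > 0) {
    rem <- exact - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(quotas))
}

# Stop unless x is a single finite number.
assert_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}

# Shift-type cycle used everywhere: a day is day -> evening -> night.
SHIFT_TYPES <- c("day", "evening", "night")

# Map shift index 1..H onto its shift type, starting at a day shift.
shift_type_of <- function(t) SHIFT_TYPES[((t - 1L) %% 3L) + 1L]
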