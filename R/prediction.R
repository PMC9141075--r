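#' One-shift-ahead expected census
#'
#' Step 1 of the reallocation process. The planner propagates the current
#' census of every unit through the per-shift transition matrices (so the
#' prediction for one unit draws on all units it is coupled to) and adds
#' the expected admissions. The result is real-valued; converting to whole
#' nurses happens in [required_nurses()].
#'
#' @param matrices a `transition_set` (rows must sum to 1).
#' @param census named current census over the units of both groups.
#' @param admissions expected admissions per unit over the horizon (a named
#'   vector, or a single 0); the planner uses the scenario's mean rates,
#'   not a sampled value.
#' @param steps prediction horizon in shifts (default 1, the 8 h horizon;
#'   larger values apply the matrix power, with mean admissions added each
#'   step).
#' @return Named expected census per unit.
#' @export
predict_census <- function(matrices, census, admissions = 0, steps = 1L) {
  stopifnot(steps >= 1L)
  out <- census * 0
  for (group in c("newborn", "adult")) {
    ids <- group_units(matrices, group)
    if (!all(ids %in% names(census))) {
      stop("census does not cover the transition-matrix units")
    }
    P <- matrices[[group]]
    rs <- rowSums(P)
    if (any(abs(rs - 1) > 1e-6)) stop("transition rows must sum to 1")
    Q <- P[, ids, drop = FALSE]
    adm <- if (length(admissions) == 1L) {
      stats::setNames(rep(as.numeric(admissions), length(ids)), ids)
    } else {
      admissions[ids]
    }
    if (any(adm < 0)) stop("admissions must be non-negative")
    x <- as.numeric(census[ids])
    for (s in seq_len(steps)) x <- as.numeric(x %*% Q) + adm
    out[ids] <- x
  }
  out
}

#' Required nurses from a census
#'
#' Converts (expected or realized) censuses to whole nurses with the
#' nurse-to-patient ratio of the unit and shift type, rounding up:
#' fractional nurses cannot be scheduled, and a unit with any patients
#' needs at least one nurse.
#'
#' @param census named census per unit (real-valued allowed).
#' @param ntp patients-per-nurse matrix (shift types x units).
#' @param shift_type `"day"`, `"evening"` or `"night"`.
#' @return Named integer vector of required nurses.
#' @export
required_nurses <- function(census, ntp, shift_type) {
  shift_type <- match.arg(shift_type, SHIFT_TYPES)
  ids <- colnames(ntp)
  stopifnot(all(ids %in% names(census)))
  d <- ceil_tol(as.numeric(census[ids]) / ntp[shift_type, ])
  stats::setNames(as.integer(pmax(d, 0L)), ids)
}

#' Staffing state of a shift
#'
#' Joins scheduled availability and required nurses into the per-unit
#' excess `e = a - d`: negative means the unit is short, zero means it has
#' exactly enough, positive means more than enough.
#'
#' @param a named available (scheduled) nurses per unit.
#' @param d named required nurses per unit.
#' @param shift_type optional label carried along.
#' @return A `staffing_state` list with `a`, `d`, `e`.
#' @export
staffing_gap <- function(a, d, shift_type = NULL) {
  stopifnot(identical(names(a), names(d)), all(a >= 0), all(d >= 0))
  structure(list(a = a, d = d, e = a - d, shift_type = shift_type),
            class = "staffing_state")
}

#' @export
print.staffing_state <- function(x, ...) {
  cat("<staffing_state>",
      if (!is.null(x$shift_type)) sprintf("[%s]", x$shift_type), "\n")
  print(rbind(available = x$a, required = x$d, excess = x$e))
  invisible(x)
}
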