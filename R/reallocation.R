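#' Skill-based pairwise reallocation (greedy, centralized)
#'
#' Step 2 of the reallocation process. Nurses move from units with surplus
#' (`e > 0`) to units with shortage (`e < 0`) wherever the skill matrix
#' permits, all units decided simultaneously by a central planner. The
#' pairwise rule `N[j -> i] = min(-e_i, e_j) * Z[j, i]` can over-commit a
#' donor with several partners, so it is realized sequentially: receivers
#' are processed in decreasing shortage (ties by unit order), and each
#' receiver draws from the donor with the currently largest surplus (ties
#' by unit order), residuals updated after every move. Donor and receiver
#' feasibility therefore hold by construction.
#'
#' @param state a `staffing_state` (or a named excess vector `e`).
#' @param Z skill matrix; moves `j -> i` require `Z[j, i] = 1`.
#' @return A `realloc_plan`: list with `moves` (units x units counts), `M`
#'   (total nurses moved), `float_deployed` (zeros here) and `residual_e`.
#' @export
pairwise_reallocate <- function(state, Z) {
  e <- if (inherits(state, "staffing_state")) state$e else state
  ids <- names(e)
  stopifnot(!is.null(ids), all(ids %in% colnames(Z)))
  moves <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  res <- e
  receivers <- ids[order(res, seq_along(ids))]      # most negative first
  receivers <- receivers[res[receivers] < 0]
  for (i in receivers) {
    while (res[i] < 0) {
      donors <- ids[res[ids] > 0 & Z[ids, i] == 1 & ids != i]
      if (length(donors) == 0L) break
      j <- donors[order(-res[donors], match(donors, ids))][1L]
      k <- min(-res[i], res[j])
      moves[j, i] <- moves[j, i] + as.integer(k)
      res[i] <- res[i] + k
      res[j] <- res[j] - k
    }
  }
  new_plan(moves, stats::setNames(integer(length(ids)), ids), res)
}

new_plan <- function(moves, float_deployed, residual_e) {
  structure(list(moves = moves, M = sum(moves),
                 float_deployed = float_deployed, residual_e = residual_e),
            class = "realloc_plan")
}

#' @export
print.realloc_plan <- function(x, ...) {
  cat(sprintf("<realloc_plan> %d nurse(s) moved, %d from the float pool\n",
              x$M, sum(x$float_deployed)))
  idx <- which(x$moves > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    for (r in seq_len(nrow(idx))) {
      cat(sprintf("  %s -> %s: %d\n", rownames(x$moves)[idx[r, 1]],
                  colnames(x$moves)[idx[r, 2]], x$moves[idx[r, 1], idx[r, 2]]))
    }
  }
  invisible(x)
}

#' Flex rate: share of scheduled nurses reallocated
#'
#' `r = 100 * sum(M_n) / sum(a_n)` over a set of shifts, where `M_n` counts
#' nurses moved (including float deployments) and `a_n` the scheduled
#' nurses. Reported to the nearest whole percent; the raw fraction is kept
#' as an attribute.
#'
#' @param moved total nurses reallocated: a number, a vector over shifts,
#'   or a list of `realloc_plan`s.
#' @param scheduled total scheduled nurses: a number or a vector over shifts.
#' @return Whole-percent rate with attribute `"fraction"`.
#' @export
flex_rate <- function(moved, scheduled) {
  if (is.list(moved)) {
    moved <- vapply(moved, function(p) p$M + sum(p$float_deployed), numeric(1))
  }
  M <- sum(moved); A <- sum(scheduled)
  if (A <= 0) stop("total scheduled nurses must be positive")
  frac <- M / A
  structure(as.numeric(rhalf(100 * frac)), fraction = frac)
}

#' Build a centralized float pool from a roster
#'
#' Per shift type, `f = round(sum(a_i) * r)` nurses are pulled out of the
#' unit rosters into an all-qualified pool; each unit loses about
#' `a_i * r`, with a largest-remainder correction so the pulled headcounts
#' sum exactly to `f`.
#'
#' @param roster shift-type x unit matrix of scheduled nurses.
#' @param r pool fraction in `[0, 1)`.
#' @return A `float_pool`: list with `pool` (nurses per shift type),
#'   `roster` (reduced availability) and `rate`.
#' @export
build_float_pool <- function(roster, r) {
  assert_scalar(r, "r")
  if (r < 0 || r >= 1) stop("pool rate must be in [0, 1)")
  reduced <- roster
  pool <- stats::setNames(integer(nrow(roster)), rownames(roster))
  for (st in rownames(roster)) {
    a <- roster[st, ]
    f <- as.integer(rhalf(sum(a) * r))
    pull <- largest_remainder(a * r, f)
    # largest_remainder apportions proportionally, which equals a_i * r
    # floored plus remainder repair; never exceeds a_i for r < 1
    if (any(a - pull < 0)) stop("pool rate drives a unit roster negative")
    reduced[st, ] <- a - pull
    pool[st] <- f
  }
  structure(list(pool = pool, roster = reduced, rate = r),
            class = "float_pool")
}

# Deploy up to f pool nurses, one at a time, to the currently largest
# shortage (ties by unit order).
deploy_float <- function(e, f) {
  dep <- stats::setNames(integer(length(e)), names(e))
  res <- e
  while (f > 0 && any(res < 0)) {
    i <- which.min(res)          # most negative; which.min breaks ties by order
    dep[i] <- dep[i] + 1L
    res[i] <- res[i] + 1
    f <- f - 1L
  }
  list(deployed = dep, residual = res)
}

#' Run one flexibility strategy on a staffing state
#'
#' * Model 0: no intervention; the plan is empty.
#' * Model 1: skill-based pairwise reallocation with the configuration's
#'   skill matrix.
#' * Model 2: float nurses only, deployed one at a time to the largest
#'   remaining shortage; no unit-to-unit moves.
#' * Model 3: float deployment first, then pairwise reallocation on the
#'   residual gaps.
#'
#' For models 2 and 3 the state must already be built on the reduced
#' (post-pooling) roster, and `float` gives the pool size for this shift.
#'
#' @param model_id 0, 1, 2 or 3.
#' @param state a `staffing_state`.
#' @param config a `care_system` (its skill matrix is used for models 1/3).
#' @param float pool nurses available this shift (models 2/3).
#' @return A `realloc_plan`.
#' @export
run_model <- function(model_id, state, config, float = 0L) {
  e <- state$e
  ids <- names(e)
  empty <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  zero <- stats::setNames(integer(length(ids)), ids)
  if (!model_id %in% 0:3) stop("unknown model id: ", model_id)
  if (model_id %in% c(2L, 3L) && is.null(float)) {
    stop("models 2 and 3 require a float pool")
  }
  switch(as.character(model_id),
    "0" = new_plan(empty, zero, e),
    "1" = pairwise_reallocate(state, config$skill),
    "2" = {
      d <- deploy_float(e, float)
      new_plan(empty, d$deployed, d$residual)
    },
    "3" = {
      d <- deploy_float(e, float)
      p <- pairwise_reallocate(d$residual, config$skill)
      new_plan(p$moves, d$deployed, p$residual_e)
    }
  )
}
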