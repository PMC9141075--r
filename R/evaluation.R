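#' Round staffing averages for decision making
#'
#' Rounds half away from zero: -0.3 -> 0, -1.6 -> -2, 4.5 -> 5. An average
#' shortage of less than half a shift (4 care hours) can be absorbed
#' informally, while anything larger needs at least one formal extra shift,
#' so raw averages are rounded to whole nurses before strategies are
#' compared.
#'
#' @param x numeric.
#' @return Rounded numeric of the same shape.
#' @export
round_staffing <- function(x) rhalf(x)

#' Best strategy by under- and overstaffing
#'
#' The best strategy by understaffing maximizes `U` (understaffing is
#' non-positive, so "max" means closest to zero); by overstaffing it
#' minimizes `O`. Ties return sets.
#'
#' @param results data.frame with columns `response`, `U`, `O` (raw or
#'   rounded), or a list of `scenario_result`s.
#' @param rounded compare on [round_staffing()]ed values (default TRUE, as
#'   in the decision tables).
#' @return List with `B_u`, `B_o` (character vectors of response ids) and
#'   the comparison table.
#' @export
select_best_strategy <- function(results, rounded = TRUE) {
  tab <- as_results_table(results)
  if (nrow(tab) < 1) stop("need at least one response")
  u <- if (rounded) round_staffing(tab$U) else tab$U
  o <- if (rounded) round_staffing(tab$O) else tab$O
  list(B_u = tab$response[u == max(u)],
       B_o = tab$response[o == min(o)],
       table = transform(tab, U_cmp = u, O_cmp = o))
}

as_results_table <- function(results) {
  if (is.data.frame(results)) return(results)
  data.frame(
    response = vapply(results, `[[`, character(1), "response_id"),
    U = vapply(results, `[[`, numeric(1), "U"),
    O = vapply(results, `[[`, numeric(1), "O"),
    stringsAsFactors = FALSE)
}

#' Decision regret of a chosen strategy across demand conditions
#'
#' For each demand condition, regret is the gap between the best achievable
#' understaffing and the chosen strategy's understaffing,
#' `U_best - U_chosen` (both non-positive; 0 means the choice stays best
#' under that condition).
#'
#' @param results_by_condition named list of results tables (or lists of
#'   `scenario_result`s), one per demand condition.
#' @param chosen response id evaluated under every condition.
#' @param rounded compare rounded values.
#' @return Named numeric vector of regret per condition (>= 0).
#' @export
decision_regret <- function(results_by_condition, chosen, rounded = TRUE) {
  vapply(results_by_condition, function(res) {
    tab <- as_results_table(res)
    if (!chosen %in% tab$response) {
      stop(sprintf("'%s' was not evaluated under every condition", chosen))
    }
    u <- if (rounded) round_staffing(tab$U) else tab$U
    max(u) - u[tab$response == chosen]
  }, numeric(1))
}

#' Training cost of cross-training nurses
#'
#' @param nurse_count nurses to train.
#' @param unit_cost cost per nurse (default EUR 20,000).
#' @return Cost in EUR.
#' @export
training_cost <- function(nurse_count, unit_cost = 20000) {
  stopifnot(all(nurse_count >= 0))
  nurse_count * unit_cost
}

#' The packaged case-study flexibility-rate distribution
#'
#' Empirical per-shift flexibility rates observed when simulating the
#' skill-based strategy on the case-study year (365 observations): rate in
#' whole percents and frequency.
#'
#' @return data.frame with `rate_percent`, `frequency`, `cumulative_pct`.
#' @export
case_study_flex_distribution <- function() {
  df <- utils::read.csv(system.file(
    "extdata", "case_study_flex_rate_distribution.csv", package = "nurseflex"))
  df$cumulative_pct <- 100 * cumsum(df$frequency) / sum(df$frequency)
  df
}

#' Smallest flex rate covering a share of observed shifts
#'
#' Given an empirical flexibility-rate distribution, returns the smallest
#' tabulated rate whose cumulative share reaches `coverage`: the minimum
#' structural flexibility that would have sufficed in that share of cases.
#'
#' @param distribution a `flex_rate_series`, or a data.frame with columns
#'   `rate`/`rate_percent` and `frequency`.
#' @param coverage required cumulative share (default 0.95).
#' @return Rate in whole percent.
#' @export
minimum_sufficient_flex_rate <- function(distribution, coverage = 0.95) {
  stopifnot(coverage > 0, coverage <= 1)
  df <- if (inherits(distribution, "flex_rate_series")) {
    distribution$per_shift
  } else {
    distribution
  }
  rate_col <- if ("rate" %in% names(df)) "rate" else "rate_percent"
  cum <- cumsum(df$frequency) / sum(df$frequency)
  df[[rate_col]][which(cum >= coverage - 1e-12)[1]]
}

#' Flexible nurses needed per shift type
#'
#' `round(rate * scheduled)` nurses per shift type: at a 13% flexibility
#' rate the case-study system needs 4 (day), 3 (evening) and 2 (night)
#' flexible nurses.
#'
#' @param roster shift-type x unit roster matrix, or a named vector of
#'   per-shift-type totals.
#' @param rate flexibility rate as a fraction (0.13) or whole percent (13).
#' @return Named integer vector per shift type.
#' @export
size_flexible_nurses <- function(roster, rate) {
  if (rate > 1) rate <- rate / 100
  totals <- if (is.matrix(roster)) rowSums(roster) else roster
  stats::setNames(as.integer(rhalf(totals * rate)), names(totals))
}

#' Flexible beds implied by the flexible nurses
#'
#' Each shift type's flexible nurses are apportioned over the printed units
#' (the O1 newborn and adult beds count as one O1 ward here) by
#' largest-remainder on bed share - wards holding more of the system's beds
#' contribute more flexible capacity - and each unit's flexible nurses are
#' converted to beds through that shift type's nurse-to-patient ratio.
#'
#' With the default rule the night shift allocates its two flexible nurses
#' to O1 and N1 (18 beds); the case study instead reports the night pair on
#' O1 and N3 (22 beds) without stating its rule. Pass
#' `override = list(night = c(O1 = 1, N3 = 1))` to reproduce that variant.
#'
#' @param config a `care_system`.
#' @param flexible_nurses named vector per shift type, e.g. from
#'   [size_flexible_nurses()].
#' @param override optional named list of explicit per-unit nurse
#'   allocations replacing the apportionment for given shift types.
#' @return List per shift type with `nurses` (per unit), `beds` (per unit)
#'   and `total_beds`.
#' @export
size_flexible_beds <- function(config, flexible_nurses, override = NULL) {
  ids <- unit_ids(config)
  # collapse the O1 sub-units back onto the printed ward
  ward_of <- stats::setNames(sub("^O1[na]$", "O1", ids), ids)
  wards <- unique(ward_of)
  beds <- vapply(wards, function(w) sum(config$units$beds[ward_of == w]),
                 numeric(1))
  out <- list()
  for (st in names(flexible_nurses)) {
    n <- flexible_nurses[[st]]
    alloc <- if (!is.null(override[[st]])) {
      a <- stats::setNames(integer(length(wards)), wards)
      a[names(override[[st]])] <- override[[st]]
      a
    } else {
      largest_remainder(beds, as.integer(n))
    }
    ratio <- vapply(wards, function(w) {
      config$ntp[st, which(ward_of == w)[1]]
    }, numeric(1))
    bed_alloc <- alloc * ratio
    out[[st]] <- list(nurses = alloc, beds = bed_alloc,
                      total_beds = sum(bed_alloc))
  }
  out
}

#' Full decision summary over simulated responses
#'
#' Combines rounded under-/overstaffing, training costs, best-strategy
#' sets, regret of the chosen set across demand conditions, and the optimal
#' responses: within the best-performing set (by rounded understaffing,
#' then overstaffing), the cheapest responses.
#'
#' @param results_by_condition named list (one entry per demand condition)
#'   of results tables with columns `response`, `U`, `O`, `cost`.
#' @param reference_condition condition used for selection (default the
#'   first, the actual-demand condition).
#' @return A `decision_summary` list.
#' @export
decision_summary <- function(results_by_condition,
                             reference_condition = names(results_by_condition)[1]) {
  ref <- as_results_table(results_by_condition[[reference_condition]])
  if (is.null(ref$cost)) stop("results need a 'cost' column")
  best <- select_best_strategy(ref)
  # lexicographic: understaffing, then overstaffing, then cost
  cand <- ref[ref$response %in% best$B_u, , drop = FALSE]
  o <- round_staffing(cand$O)
  cand <- cand[o == min(o), , drop = FALSE]
  optimal <- cand$response[cand$cost == min(cand$cost)]
  regret <- sapply(optimal, function(ch)
    decision_regret(results_by_condition, ch), simplify = FALSE)
  structure(list(B_u = best$B_u, B_o = best$B_o, optimal = optimal,
                 regret = regret, table = ref,
                 reference_condition = reference_condition),
            class = "decision_summary")
}

#' @export
print.decision_summary <- function(x, ...) {
  cat("<decision_summary>\n")
  cat("  best by understaffing:", paste(x$B_u, collapse = ", "), "\n")
  cat("  best by overstaffing: ", paste(x$B_o, collapse = ", "), "\n")
  cat("  optimal (performance then cost):",
      paste(x$optimal, collapse = ", "), "\n")
  invisible(x)
}
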