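#' The study's response grid
#'
#' The eleven what-if responses: the current six-unit layout without
#' intervention (R0), with skill-based reallocation (R1), with a float pool
#' at the rate derived from R1 (R2) or at 20%/40% (R2_20, R2_40), with the
#' combined strategy (R3); the two-department layout with each strategy
#' (R4-R7); and the one-department layout (R8). A float rate of `NA` means
#' "derive it from a model-1 pass on the same trace", which is how the pool
#' of R2/R3 (and R6/R7) is sized at the strategic level.
#'
#' @return data.frame with columns `response`, `layout`, `model`,
#'   `float_rate`.
#' @export
response_grid <- function() {
  data.frame(
    response = c("R0", "R1", "R2", "R2_20", "R2_40", "R3",
                 "R4", "R5", "R6", "R7", "R8"),
    layout = c(rep("current", 6), rep("config1_two_departments", 4),
               "config2_one_department"),
    model = c(0L, 1L, 2L, 2L, 2L, 3L, 0L, 1L, 2L, 3L, 0L),
    float_rate = c(NA, NA, NA, 0.20, 0.40, NA, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Specify one simulation scenario
#'
#' @param response_id a response label, usually from [response_grid()].
#' @param layout care-system layout.
#' @param model_id flexibility strategy 0-3.
#' @param demand_scenario a [demand_scenario()].
#' @param float_rate pool fraction; `NA` derives it from a model-1 pass on
#'   the same trace (only relevant for models 2/3).
#' @param replications independent demand replications to average over.
#' @param seed base seed; replication k runs the demand scenario with seed
#'   `seed + k - 1`.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(response_id, layout, model_id, demand_scenario,
                          float_rate = NA, replications = 1L,
                          seed = demand_scenario$seed) {
  layout <- match.arg(layout, LAYOUTS)
  stopifnot(model_id %in% 0:3, replications >= 1)
  if (demand_scenario$horizon_shifts < 3L) stop("horizon must be >= 3 shifts")
  structure(list(response_id = response_id, layout = layout,
                 model_id = as.integer(model_id),
                 demand_scenario = demand_scenario,
                 float_rate = float_rate,
                 replications = as.integer(replications),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

# One planning-and-execution pass over a realized trace.
#
# For every shift t: the planner, working during shift t-1, predicts the
# census of shift t from the census observed at the start of shift t-1
# (expected transitions + mean admissions), converts it to required nurses,
# and commits the strategy's reallocation against the scheduled roster.
# The realized census of shift t then fixes actual demand; pooled layouts
# may still rebalance within their structural matrix (nurses of a pooled
# department are one workforce), and the leftover gaps are scored.
run_trace <- function(config, trace, model_id, float_pool = NULL,
                      structural = NULL) {
  ids <- unit_ids(config)
  H <- nrow(trace$census) - 1L
  lam <- trace$scenario$arrival_rates[ids]
  matrices <- attr(trace, "matrices")
  if (is.null(matrices)) matrices <- default_transition_matrices()
  if (is.null(structural)) structural <- structural_matrix(config$layout, config$units)
  roster <- if (!is.null(float_pool)) float_pool$roster else config$roster
  pool <- if (!is.null(float_pool)) float_pool$pool else
    stats::setNames(integer(3), SHIFT_TYPES)

  U <- O <- M <- A <- numeric(H)
  residual <- matrix(0, H, length(ids), dimnames = list(NULL, ids))
  for (t in seq_len(H)) {
    st <- trace$shift_type[t]
    base <- if (t == 1L) trace$census[1L, ] else trace$census[t - 1L, ]
    pred <- predict_census(matrices, base, lam)
    d_pred <- required_nurses(pred, config$ntp, st)
    a <- roster[st, ]
    plan <- run_model(model_id, staffing_gap(a, d_pred, st), config, pool[st])
    a_post <- a - rowSums(plan$moves) + colSums(plan$moves) + plan$float_deployed

    d_real <- required_nurses(trace$census[t, ], config$ntp, st)
    rebal <- pairwise_reallocate(a_post - d_real, structural)
    e <- rebal$residual_e
    # float nurses not committed at planning time stay centrally available:
    # they absorb realized shortages, and whoever is still unused is surplus
    leftover <- pool[st] - sum(plan$float_deployed)
    late <- deploy_float(e, leftover)
    e <- late$residual
    U[t] <- sum(pmin(e, 0))
    O[t] <- sum(pmax(e, 0)) + (leftover - sum(late$deployed))
    M[t] <- plan$M + sum(plan$float_deployed) + sum(late$deployed)
    A[t] <- sum(config$roster[st, ])   # scheduled, pre-pooling
    residual[t, ] <- e
  }
  list(U = U, O = O, M = M, A = A, residual = residual,
       shift_type = trace$shift_type)
}

# Flex fraction a model-1 pass produces on a trace (used to size the float
# pool of models 2/3 when the rate is not given).
derive_flex_fraction <- function(config, trace) {
  skill_cfg <- config
  if (config$layout != "current") {
    skill_cfg$skill <- derive_skill_matrix(config$layout, config$units)
  }
  run <- run_trace(skill_cfg, trace, model_id = 1L)
  attr(flex_rate(run$M, run$A), "fraction")
}

#' Run one what-if scenario
#'
#' Simulates `replications` independent demand traces, runs the planning
#' loop of the requested strategy on each, and aggregates per-shift
#' under-/overstaffing. Understaffing is the per-shift sum of negative
#' residual gaps (reported negative, as in the study's tables);
#' overstaffing the sum of positive gaps.
#'
#' @param spec a [scenario_spec()].
#' @param config_library named list of `care_system`s per layout; defaults
#'   to the packaged fixture in all three layouts.
#' @param matrices a `transition_set`.
#' @param trace optionally, a pre-simulated `demand_trace` shared across
#'   responses (forces `replications = 1`).
#' @return A `scenario_result` with fields `U`, `O` (means), `sd_U`, `sd_O`
#'   (per-shift SDs), `flex_percent`, per-shift series (`U_t`, `O_t`,
#'   `M_t`, `A_t`), per-unit `residual`, and the pool rate actually used.
#' @export
run_scenario <- function(spec, config_library = NULL,
                         matrices = default_transition_matrices(),
                         trace = NULL) {
  config <- if (is.null(config_library)) {
    perinatology_care_system(spec$layout)
  } else {
    config_library[[spec$layout]]
  }
  structural <- structural_matrix(config$layout, config$units)

  traces <- if (!is.null(trace)) {
    list(trace)
  } else {
    lapply(seq_len(spec$replications), function(k) {
      sc <- spec$demand_scenario
      sc$seed <- spec$seed + k - 1L
      tr <- simulate_trace(config, sc, matrices)
      attr(tr, "matrices") <- matrices
      tr
    })
  }
  for (k in seq_along(traces)) attr(traces[[k]], "matrices") <- matrices

  rate_used <- NA_real_
  runs <- lapply(traces, function(tr) {
    float_pool <- NULL
    if (spec$model_id %in% c(2L, 3L)) {
      r <- spec$float_rate
      if (is.na(r)) r <- derive_flex_fraction(config, tr)
      rate_used <<- r
      float_pool <- build_float_pool(config$roster, r)
    }
    run_trace(config, tr, spec$model_id, float_pool, structural)
  })

  U_t <- unlist(lapply(runs, `[[`, "U"))
  O_t <- unlist(lapply(runs, `[[`, "O"))
  M_t <- unlist(lapply(runs, `[[`, "M"))
  A_t <- unlist(lapply(runs, `[[`, "A"))
  residual <- do.call(rbind, lapply(runs, `[[`, "residual"))

  structure(list(
    response_id = spec$response_id, layout = spec$layout,
    model_id = spec$model_id, float_rate = rate_used,
    U = mean(U_t), O = mean(O_t),
    sd_U = stats::sd(U_t), sd_O = stats::sd(O_t),
    rep_U = vapply(runs, function(r) mean(r$U), numeric(1)),
    flex_percent = as.numeric(flex_rate(M_t, A_t)),
    U_t = U_t, O_t = O_t, M_t = M_t, A_t = A_t,
    residual = residual,
    shift_type = rep(traces[[1]]$shift_type, length(runs))),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (layout %s, model %d)\n",
              x$response_id, x$layout, x$model_id))
  cat(sprintf("  understaffed %.2f (sd %.2f), overstaffed %.2f (sd %.2f) per shift\n",
              x$U, x$sd_U, x$O, x$sd_O))
  if (!is.na(x$float_rate)) {
    cat(sprintf("  float-pool rate %.1f%%\n", 100 * x$float_rate))
  }
  invisible(x)
}

#' Empirical distribution of per-shift flexibility rates
#'
#' For a skill-based (model 1) run: the per-shift rate is 100 x nurses
#' reallocated that shift / nurses scheduled that shift. Rates are rounded
#' to whole percents and tabulated with cumulative shares; a per-day
#' aggregation (nurses moved per day / scheduled per day) is included,
#' since one year gives 365 day-level observations.
#'
#' @param result a `scenario_result` from a model-1 scenario.
#' @return A `flex_rate_series`: list with `per_shift` and `per_day`
#'   frequency tables (`rate`, `frequency`, `cumulative_pct`) and the raw
#'   rate vectors.
#' @export
flexibility_rate_series <- function(result) {
  if (!is.null(result$model_id) && result$model_id != 1L) {
    stop("flexibility-rate series is defined for model-1 results")
  }
  rates_shift <- 100 * result$M_t / result$A_t
  days <- (seq_along(result$M_t) - 1L) %/% 3L
  rates_day <- 100 * tapply(result$M_t, days, sum) / tapply(result$A_t, days, sum)
  tab <- function(r) {
    f <- table(factor(rhalf(r), levels = sort(unique(rhalf(r)))))
    data.frame(rate = as.numeric(names(f)), frequency = as.integer(f),
               cumulative_pct = 100 * cumsum(as.integer(f)) / sum(f))
  }
  structure(list(per_shift = tab(rates_shift), per_day = tab(rates_day),
                 rates_shift = as.numeric(rates_shift),
                 rates_day = as.numeric(rates_day)),
            class = "flex_rate_series")
}
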