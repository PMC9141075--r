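#' Define a full experiment manifest
#'
#' One manifest determines an entire study run: which responses, which
#' demand conditions (target CVs), horizon, replications and global seed.
#' Rerunning the same manifest reproduces byte-identical outputs.
#'
#' @param responses response table, defaults to [response_grid()].
#' @param demand_conditions named target CVs, default
#'   `c(actual = 0.31, variable = 0.49)`.
#' @param horizon shifts per run (default a year of 8 h shifts, 1095).
#' @param replications demand replications per scenario.
#' @param seed global seed.
#' @param dispersions optional named pre-calibrated dispersions per
#'   condition; when `NULL`, [calibrate_dispersion()] runs once per
#'   condition.
#' @param calibration_horizon shifts used per calibration evaluation.
#' @return An `experiment_manifest`.
#' @export
experiment_manifest <- function(responses = response_grid(),
                                demand_conditions = c(actual = 0.31,
                                                      variable = 0.49),
                                horizon = 1095L, replications = 1L,
                                seed = 1L, dispersions = NULL,
                                calibration_horizon = 900L) {
  if (nrow(responses) > 0 && anyDuplicated(responses$response)) {
    stop("response ids must be unique")
  }
  structure(list(responses = responses,
                 demand_conditions = demand_conditions,
                 horizon = as.integer(horizon),
                 replications = as.integer(replications),
                 seed = as.integer(seed), dispersions = dispersions,
                 calibration_horizon = as.integer(calibration_horizon)),
            class = "experiment_manifest")
}

#' Execute an experiment manifest
#'
#' Calibrates the generator per demand condition, simulates every response,
#' and writes the study tables: the raw summary (response, condition, mean
#' and SD of under-/overstaffing), the rounded decision table with training
#' costs, the flexibility-rate distribution of the skill-based strategy,
#' a JSON decision report, and a machine-readable run log. Both raw and
#' rounded summaries sit side by side in the result object.
#'
#' @param manifest an [experiment_manifest()].
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param config_library optional named list of `care_system`s per layout.
#' @param matrices a `transition_set`.
#' @return Invisibly, a list with `results` (per condition, per response),
#'   `summary` (data.frame), `decision`, `flex_series`, `dispersions`.
#' @export
run_manifest <- function(manifest, out_dir = NULL, config_library = NULL,
                         matrices = default_transition_matrices()) {
  if (is.null(config_library)) {
    config_library <- stats::setNames(lapply(LAYOUTS, perinatology_care_system),
                                      LAYOUTS)
  }
  base_cfg <- config_library[["current"]]
  responses <- manifest$responses
  if (nrow(responses) == 0L) {
    return(invisible(list(results = list(),
                          summary = data.frame(), decision = NULL,
                          flex_series = NULL, dispersions = NULL)))
  }

  dispersions <- manifest$dispersions
  results <- list()
  summary_rows <- list()
  flex_series <- NULL
  for (cond in names(manifest$demand_conditions)) {
    cv <- manifest$demand_conditions[[cond]]
    sc <- demand_scenario(horizon_shifts = manifest$horizon, target_cv = cv,
                          seed = manifest$seed)
    if (is.null(dispersions[[cond]])) {
      dispersions[[cond]] <- calibrate_dispersion(
        base_cfg, sc, matrices, horizon = manifest$calibration_horizon)
    }
    sc$dispersion <- dispersions[[cond]]

    cond_res <- list()
    for (r in seq_len(nrow(responses))) {
      row <- responses[r, ]
      spec <- scenario_spec(row$response, row$layout, row$model, sc,
                            float_rate = row$float_rate,
                            replications = manifest$replications,
                            seed = manifest$seed)
      res <- tryCatch(
        run_scenario(spec, config_library, matrices),
        error = function(e) stop(sprintf("scenario '%s' (%s) failed: %s",
                                         row$response, cond,
                                         conditionMessage(e)), call. = FALSE))
      cond_res[[row$response]] <- res
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        condition = cond, response = row$response, layout = row$layout,
        model = row$model,
        float_rate = if (is.na(res$float_rate)) NA_real_ else res$float_rate,
        U = res$U, sd_U = res$sd_U, O = res$O, sd_O = res$sd_O,
        U_rounded = round_staffing(res$U), O_rounded = round_staffing(res$O),
        cost = response_training_cost(row, res, base_cfg),
        stringsAsFactors = FALSE)
      if (row$response == "R1" && is.null(flex_series)) {
        flex_series <- flexibility_rate_series(res)
      }
    }
    results[[cond]] <- cond_res
  }
  summary <- do.call(rbind, summary_rows)

  by_cond <- lapply(results, function(cr) {
    tab <- as_results_table(cr)
    tab$cost <- summary$cost[match(tab$response, summary$response)]
    tab
  })
  decision <- decision_summary(by_cond)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary[, c("condition", "response", "layout", "model",
                                 "float_rate", "U", "sd_U", "O", "sd_O")],
                     file.path(out_dir, "staffing_raw.csv"), row.names = FALSE)
    utils::write.csv(summary[, c("condition", "response", "U_rounded",
                                 "O_rounded", "cost")],
                     file.path(out_dir, "staffing_rounded.csv"),
                     row.names = FALSE)
    if (!is.null(flex_series)) {
      utils::write.csv(flex_series$per_shift,
                       file.path(out_dir, "flex_rate_per_shift.csv"),
                       row.names = FALSE)
      utils::write.csv(flex_series$per_day,
                       file.path(out_dir, "flex_rate_per_day.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(B_u = decision$B_u, B_o = decision$B_o,
           optimal = decision$optimal, regret = decision$regret),
      file.path(out_dir, "decision.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("nurseflex")),
           seed = manifest$seed, horizon = manifest$horizon,
           replications = manifest$replications,
           demand_conditions = as.list(manifest$demand_conditions),
           dispersions = dispersions),
      file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(list(results = results, summary = summary, decision = decision,
                 flex_series = flex_series, dispersions = dispersions))
}

# Training cost of a response: pooled layouts price the retraining of the
# whole layout; a float pool prices round(rate * registry) nurses; the
# skill-based strategy on the current layout is free.
response_training_cost <- function(row, res, base_cfg) {
  if (row$layout == "config1_two_departments") {
    return(training_cost(nurses_to_train("config1_two_departments", base_cfg)))
  }
  if (row$layout == "config2_one_department") {
    return(training_cost(nurses_to_train("config2_one_department", base_cfg)))
  }
  if (row$model %in% c(2L, 3L)) {
    return(training_cost(nurses_to_train("model2", base_cfg,
                                         flex_rate = res$float_rate)))
  }
  0
}
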