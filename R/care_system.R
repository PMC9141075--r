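LAYOUTS <- c("current", "config1_two_departments", "config2_one_department")

#' Construct a care-system configuration
#'
#' Bundles the structural description of a care system and validates its
#' invariants. Most users will start from [perinatology_care_system()], the
#' packaged case-study fixture, and edit from there.
#'
#' @param units data.frame with columns `id`, `department`, `beds`,
#'   `patient_group` (`"newborn"`/`"adult"`) and `specialization_rank`
#'   (1 = most specialized within its department).
#' @param roster integer matrix, rows `day`/`evening`/`night`, one column per
#'   unit: scheduled nurses per shift type (repeats daily).
#' @param ntp numeric matrix, same shape as `roster`: patients one nurse
#'   covers in that unit and shift type.
#' @param skill binary skill matrix `Z` with `Z[j, i] = 1` iff nurses
#'   registered in location `j` may work in unit `i`; unit diagonal must be 1.
#' @param registry data.frame with columns `group`, `units` (list column of
#'   unit ids the group is qualified for) and `nurses`.
#' @param layout one of `"current"`, `"config1_two_departments"`,
#'   `"config2_one_department"`.
#' @param name free-text label.
#' @return An object of class `care_system`.
#' @export
care_system <- function(units, roster, ntp, skill, registry,
                        layout = "current", name = "care system") {
  layout <- match.arg(layout, LAYOUTS)
  stopifnot(is.data.frame(units),
            all(c("id", "department", "beds", "patient_group",
                  "specialization_rank") %in% names(units)))
  ids <- as.character(units$id)
  if (anyDuplicated(ids)) stop("duplicate unit ids")
  if (any(units$beds <= 0)) stop("all units must have beds > 0")
  if (!all(units$patient_group %in% c("newborn", "adult"))) {
    stop("patient_group must be 'newborn' or 'adult'")
  }
  for (dep in unique(units$department)) {
    rk <- units$specialization_rank[units$department == dep]
    if (anyDuplicated(rk)) {
      stop("specialization_rank must be a strict order within each department")
    }
  }
  roster <- as_shift_matrix(roster, ids, "roster")
  if (any(roster < 0) || any(roster != round(roster))) {
    stop("roster entries must be non-negative integers")
  }
  ntp <- as_shift_matrix(ntp, ids, "ntp")
  if (any(ntp <= 0)) stop("nurse-to-patient ratios must be positive")
  skill <- validate_skill_matrix(skill, ids)
  stopifnot(is.data.frame(registry),
            all(c("group", "units", "nurses") %in% names(registry)))

  structure(list(name = name, layout = layout, units = units,
                 roster = roster, ntp = ntp, skill = skill,
                 registry = registry),
            class = "care_system")
}

as_shift_matrix <- function(m, ids, what) {
  m <- as.matrix(m)
  if (!identical(rownames(m), SHIFT_TYPES)) {
    stop(sprintf("%s rows must be day, evening, night", what))
  }
  if (!identical(colnames(m), ids)) {
    stop(sprintf("%s columns must match unit ids in order", what))
  }
  m
}

validate_skill_matrix <- function(Z, ids) {
  Z <- as.matrix(Z)
  if (!all(Z %in% c(0, 1))) stop("skill matrix must be binary")
  if (!identical(colnames(Z), ids)) stop("skill matrix columns must be units")
  n_units <- length(ids)
  if (!identical(rownames(Z)[seq_len(n_units)], ids)) {
    stop("skill matrix rows must start with the units in order")
  }
  if (any(diag(Z[seq_len(n_units), , drop = FALSE]) != 1)) {
    stop("every unit must be qualified for itself (diagonal 1)")
  }
  if (nrow(Z) > n_units) {
    extra <- rownames(Z)[-seq_len(n_units)]
    if (!identical(extra, "pool")) stop("only a trailing 'pool' row is allowed")
    if (any(Z["pool", ] != 1)) stop("float-pool row must be all ones")
  }
  storage.mode(Z) <- "integer"
  class(Z) <- c("skill_matrix", class(Z))
  Z
}

#' @export
print.care_system <- function(x, ...) {
  cat(sprintf("<care_system> %s [layout: %s]\n", x$name, x$layout))
  cat(sprintf("  units: %s (total %d beds)\n",
              paste(x$units$id, collapse = ", "), sum(x$units$beds)))
  cat(sprintf("  scheduled nurses/day: %s (total %d)\n",
              paste(sprintf("%s %d", rownames(x$roster), rowSums(x$roster)),
                    collapse = ", "), sum(x$roster)))
  cat(sprintf("  registry: %d nurses in %d qualification groups\n",
              sum(x$registry$nurses), nrow(x$registry)))
  invisible(x)
}

unit_ids <- function(config) as.character(config$units$id)

#' The packaged perinatology case-study system
#'
#' Loads the seven-unit perinatology fixture shipped with the package
#' (70 beds; 28/21/17 nurses scheduled for day/evening/night; 176 employed
#' nurses) and attaches the skill matrix of the requested layout. The
#' printed roster has a single O1 column; it is split over the O1n (7-bed)
#' and O1a (25-bed) locations in proportion to beds using largest-remainder
#' rounding, unless an explicit split is given.
#'
#' @param layout care-system layout: the current six-unit system, two pooled
#'   departments (`config1_two_departments`), or one pooled department
#'   (`config2_one_department`).
#' @param o1_split optional named list with integer vectors `day`,
#'   `evening`, `night`, each `c(O1n =, O1a =)`, overriding the bed-share
#'   split of the O1 roster column.
#' @return A [care_system()] object.
#' @export
perinatology_care_system <- function(layout = "current", o1_split = NULL) {
  layout <- match.arg(layout, LAYOUTS)
  path <- system.file("extdata", "perinatology_care_system.json",
                      package = "nurseflex")
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  units <- cfg$units
  ids <- as.character(units$id)

  roster <- split_o1(cfg$roster, units, o1_split)
  ntp <- expand_o1(cfg$ntp_ratio, ids)
  skill <- derive_skill_matrix(layout, units)

  registry <- data.frame(group = cfg$registry$group,
                         nurses = as.integer(cfg$registry$nurses))
  registry$units <- cfg$registry$units

  care_system(units, roster, ntp, skill, registry, layout = layout,
              name = "Perinatology care system (case-study fixture)")
}

# Expand the six printed roster/ratio columns onto the seven model units,
# splitting the O1 roster by bed share (design choice: the source tables
# never print a per-sub-unit roster).
split_o1 <- function(block, units, o1_split = NULL) {
  ids <- as.character(units$id)
  beds_o1 <- stats::setNames(units$beds[match(c("O1n", "O1a"), ids)],
                             c("O1n", "O1a"))
  out <- matrix(0L, 3, length(ids), dimnames = list(SHIFT_TYPES, ids))
  for (st in SHIFT_TYPES) {
    row <- block[[st]]
    for (u in setdiff(names(row), c("comment", "O1"))) out[st, u] <- row[[u]]
    split <- if (!is.null(o1_split)) {
      o1_split[[st]]
    } else {
      largest_remainder(beds_o1, as.integer(row[["O1"]]))
    }
    stopifnot(sum(split) == row[["O1"]])
    out[st, "O1n"] <- split[["O1n"]]
    out[st, "O1a"] <- split[["O1a"]]
  }
  out
}

expand_o1 <- function(block, ids) {
  out <- matrix(0, 3, length(ids), dimnames = list(SHIFT_TYPES, ids))
  for (st in SHIFT_TYPES) {
    row <- block[[st]]
    for (u in setdiff(names(row), "comment")) {
      if (u == "O1") {
        out[st, "O1n"] <- row[[u]]
        out[st, "O1a"] <- row[[u]]
      } else {
        out[st, u] <- row[[u]]
      }
    }
  }
  out
}

#' Skill matrix for a care-system layout
#'
#' The current layout reads the packaged qualification matrix (specialized
#' nurses may step down to less specialized units within their department;
#' N3 and the O1 newborn beds are cross-linked). Configuration 1 pools each
#' department: within-department all-ones blocks plus the N3/O1n cross link.
#' Configuration 2 is one department: all ones.
#'
#' @param layout one of the three layouts.
#' @param units unit table (defaults to the packaged fixture's units).
#' @return A binary `skill_matrix` with units as rows and columns.
#' @export
derive_skill_matrix <- function(layout, units = NULL) {
  layout <- match.arg(layout, LAYOUTS)
  if (is.null(units)) {
    path <- system.file("extdata", "perinatology_care_system.json",
                        package = "nurseflex")
    units <- jsonlite::fromJSON(path)$units
  }
  ids <- as.character(units$id)
  n <- length(ids)
  if (layout == "current") {
    path <- system.file("extdata", "skill_matrix_current.csv",
                        package = "nurseflex")
    return(read_skill_matrix(path, ids))
  }
  Z <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (layout == "config2_one_department") {
    Z[] <- 1L
  } else {
    for (dep in unique(units$department)) {
      in_dep <- units$department == dep
      Z[in_dep, in_dep] <- 1L
    }
    # newborn cross link between the neonatology HC/MC unit and the
    # obstetric newborn beds survives the pooling
    if (all(c("N3", "O1n") %in% ids)) {
      Z["N3", "O1n"] <- 1L
      Z["O1n", "N3"] <- 1L
    }
  }
  validate_skill_matrix(Z, ids)
}

#' Structural (pooling) matrix of a layout
#'
#' Which locations share nurses *by construction* of the layout, independent
#' of any flexibility strategy: in the current layout every unit is on its
#' own (identity); in the pooled layouts nurses move freely inside a pooled
#' department (plus the N3/O1n cross link) or across the whole system.
#' The simulator uses this matrix to rebalance pooled departments against
#' realized demand within the working shift.
#'
#' @inheritParams derive_skill_matrix
#' @return A binary `skill_matrix`.
#' @export
structural_matrix <- function(layout, units = NULL) {
  layout <- match.arg(layout, LAYOUTS)
  if (layout != "current") return(derive_skill_matrix(layout, units))
  if (is.null(units)) {
    path <- system.file("extdata", "perinatology_care_system.json",
                        package = "nurseflex")
    units <- jsonlite::fromJSON(path)$units
  }
  ids <- as.character(units$id)
  Z <- diag(length(ids))
  dimnames(Z) <- list(ids, ids)
  validate_skill_matrix(Z, ids)
}

#' Add the float-pool row to a skill matrix
#'
#' Float nurses are qualified for every unit; there is no pool column
#' because nurses cannot be reallocated into the pool mid-shift.
#'
#' @param Z a `skill_matrix` without a pool row.
#' @return The matrix with a trailing all-ones `pool` row.
#' @export
add_float_row <- function(Z) {
  ids <- colnames(Z)
  if ("pool" %in% rownames(Z)) return(Z)
  Z2 <- rbind(unclass(Z), pool = rep(1L, length(ids)))
  validate_skill_matrix(Z2, ids)
}

#' Nurses that must be cross-trained for a strategy or layout
#'
#' Training headcounts for the decision layer: the skill-based strategy on
#' the current layout needs no training (specialized nurses already hold the
#' required skills); a float pool of rate `flex_rate` needs
#' `round(flex_rate * total)` nurses trained for all units; pooling the two
#' departments needs every N2 and N3 nurse plus (in the case-study system)
#' 10 obstetric nurses; one pooled department needs everyone.
#'
#' @param strategy `"model1_current"`, `"model2"`,
#'   `"config1_two_departments"` or `"config2_one_department"`.
#' @param registry a `care_system` or a registry data.frame; used for group
#'   headcounts and the system total.
#' @param flex_rate pool fraction in `[0, 1]` (model 2 only).
#' @param obstetrics_to_train obstetric nurses still needing training under
#'   configuration 1 (case-study value 10; most obstetric nurses are already
#'   qualified department-wide).
#' @return Integer headcount.
#' @export
nurses_to_train <- function(strategy, registry = perinatology_care_system(),
                            flex_rate = NULL, obstetrics_to_train = 10L) {
  strategy <- match.arg(strategy, c("model1_current", "model2",
                                    "config1_two_departments",
                                    "config2_one_department"))
  reg <- if (inherits(registry, "care_system")) registry$registry else registry
  total <- sum(reg$nurses)
  switch(strategy,
    model1_current = 0L,
    model2 = {
      if (is.null(flex_rate)) stop("model 2 needs a flex_rate")
      assert_scalar(flex_rate, "flex_rate")
      if (flex_rate < 0) stop("flex_rate must be non-negative")
      if (flex_rate > 1) stop("flex_rate must be at most 1")
      as.integer(rhalf(flex_rate * total))
    },
    config1_two_departments = {
      n2 <- reg$nurses[reg$group == "N2"]
      n3 <- reg$nurses[reg$group == "N3"]
      as.integer(n2 + n3 + obstetrics_to_train)
    },
    config2_one_department = as.integer(total)
  )
}

#' Read a skill matrix from labeled CSV
#'
#' @param path CSV with a `from` label column and one column per unit.
#' @param ids expected unit ids (defaults to the columns found).
#' @return A `skill_matrix`.
#' @export
read_skill_matrix <- function(path, ids = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- rn
  if (is.null(ids)) ids <- colnames(m)
  validate_skill_matrix(m[, ids, drop = FALSE], ids)
}

#' @rdname read_skill_matrix
#' @param Z matrix to write.
#' @export
write_skill_matrix <- function(Z, path) {
  df <- data.frame(from = rownames(Z), unclass(Z), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / load a care system as JSON
#'
#' Round-trips every block of the configuration (units, roster, ratios,
#' skill matrix, registry) so user-edited systems can be stored next to the
#' packaged fixture.
#'
#' @param config a `care_system`.
#' @param path file path.
#' @return `read_care_system` returns a `care_system`.
#' @export
write_care_system <- function(config, path) {
  obj <- list(
    name = config$name,
    layout = config$layout,
    units = config$units,
    roster = apply(config$roster, 1, as.list, simplify = FALSE),
    ntp_ratio = apply(config$ntp, 1, as.list, simplify = FALSE),
    skill_matrix = list(locations = rownames(config$skill),
                        units = colnames(config$skill),
                        Z = unname(unclass(config$skill))),
    registry = config$registry
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_care_system
#' @export
read_care_system <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  units <- obj$units
  ids <- as.character(units$id)
  mat_from <- function(block) {
    m <- do.call(rbind, lapply(SHIFT_TYPES, function(st) unlist(block[[st]])))
    dimnames(m) <- list(SHIFT_TYPES, names(block[[1]]))
    m[, ids, drop = FALSE]
  }
  Z <- obj$skill_matrix$Z
  dimnames(Z) <- list(obj$skill_matrix$locations, obj$skill_matrix$units)
  registry <- data.frame(group = obj$registry$group,
                         nurses = as.integer(obj$registry$nurses))
  registry$units <- obj$registry$units
  care_system(units, mat_from(obj$roster), mat_from(obj$ntp_ratio),
              validate_skill_matrix(Z, ids), registry,
              layout = obj$layout, name = obj$name)
}
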