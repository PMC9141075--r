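#' Per-shift patient transition matrices
#'
#' One matrix per patient group. Rows are the group's units, columns are
#' the same units plus an absorbing `exit` state; `P[i, j]` is the
#' probability that a patient in unit `i` at the start of an 8 h shift is in
#' state `j` at the start of the next shift. Newborns and adults never mix:
#' each group's matrix only reaches that group's units.
#'
#' @param newborn,adult row-stochastic matrices (rows renormalized to sum 1
#'   when `renormalize = TRUE`, because printed rows may carry rounding: the
#'   case-study O1n row 0.04/0.04/0.16/0.77 sums to 1.01).
#' @param renormalize divide each row by its sum.
#' @return A `transition_set`: list with elements `newborn` and `adult`.
#' @export
transition_matrices <- function(newborn, adult, renormalize = TRUE) {
  fix <- function(P, group) {
    P <- as.matrix(P)
    if (is.null(rownames(P)) || is.null(colnames(P))) {
      stop("transition matrices need unit row/column names")
    }
    if (utils::tail(colnames(P), 1) != "exit") {
      stop("last column must be the absorbing 'exit' state")
    }
    if (!identical(rownames(P), utils::head(colnames(P), -1))) {
      stop("rows must match the non-exit columns")
    }
    if (any(P < 0)) stop("negative transition probability")
    rs <- rowSums(P)
    if (renormalize) {
      P <- P / rs
    } else if (any(abs(rs - 1) > 1e-8)) {
      stop(sprintf("%s rows must sum to 1 (got %s)", group,
                   paste(signif(rs, 4), collapse = ", ")))
    }
    P
  }
  structure(list(newborn = fix(newborn, "newborn"), adult = fix(adult, "adult")),
            class = "transition_set")
}

#' Packaged default transition matrices
#'
#' Loads the per-shift transition matrices shipped with the package. Only
#' the O1n newborn row comes from the case study (4% to N1, 4% to N3, 16%
#' exit, 77% stay, renormalized); every other entry is a synthetic default
#' chosen so that stay probabilities imply lengths of stay of the right
#' order (NICU about two weeks, ward beds two to three days, delivery rooms
#' under a day) and so that about a third of O1n departures are transfers
#' into Neonatology, matching the reported 35% transfer share.
#'
#' @param renormalize passed to [transition_matrices()].
#' @return A `transition_set`.
#' @export
default_transition_matrices <- function(renormalize = TRUE) {
  nb <- read_transition_matrix(system.file(
    "extdata", "transitions_newborn_synthetic.csv", package = "nurseflex"))
  ad <- read_transition_matrix(system.file(
    "extdata", "transitions_adult_synthetic.csv", package = "nurseflex"))
  transition_matrices(nb, ad, renormalize = renormalize)
}

#' Read / write one transition matrix as CSV
#'
#' CSV layout: a `from` label column, one column per destination unit, and
#' a final `exit` column.
#'
#' @param path file path.
#' @return `read_transition_matrix` returns an unnormalized matrix.
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_transition_matrix
#' @param P matrix to write.
#' @export
write_transition_matrix <- function(P, path) {
  df <- data.frame(from = rownames(P), unclass(P), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Units covered by each patient group, in canonical order.
group_units <- function(matrices, group) rownames(matrices[[group]])
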