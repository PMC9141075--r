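# Shared fixtures and independent oracles, built in code.

# The packaged case-study system, loaded once per test run.
pcs <- perinatology_care_system()
pcs_matrices <- default_transition_matrices()

# A minimal two-unit care system: one newborn unit A, one adult unit B.
toy_system <- function(beds_a = 50L, beds_b = 50L,
                       roster_a = c(5L, 5L, 5L), roster_b = c(5L, 5L, 5L),
                       ratio = 2) {
  units <- data.frame(
    id = c("A", "B"), department = c("Neo", "Obs"),
    beds = c(beds_a, beds_b), patient_group = c("newborn", "adult"),
    specialization_rank = c(1L, 1L))
  roster <- rbind(day = c(roster_a[1], roster_b[1]),
                  evening = c(roster_a[2], roster_b[2]),
                  night = c(roster_a[3], roster_b[3]))
  colnames(roster) <- c("A", "B")
  ntp <- matrix(ratio, 3, 2, dimnames = list(SHIFT_TYPES_TEST, c("A", "B")))
  Z <- diag(2); dimnames(Z) <- list(c("A", "B"), c("A", "B"))
  registry <- data.frame(group = c("A", "B"), nurses = c(10L, 10L))
  registry$units <- list("A", "B")
  care_system(units, roster, ntp, Z, registry, name = "toy")
}

SHIFT_TYPES_TEST <- c("day", "evening", "night")

# Toy transition set: newborn unit A with stay probability p_a, adult unit
# B with stay probability p_b (remainder exits).
toy_matrices <- function(p_a = 1, p_b = 1) {
  nb <- matrix(c(p_a, 1 - p_a), 1, 2, dimnames = list("A", c("A", "exit")))
  ad <- matrix(c(p_b, 1 - p_b), 1, 2, dimnames = list("B", c("B", "exit")))
  transition_matrices(nb, ad, renormalize = FALSE)
}

# Independent brute-force oracle: the maximum total shortage coverable by
# any feasible integer move set under skill matrix Z (enumeration over all
# per-edge move counts; no reuse of the greedy code path).
oracle_cover <- function(e, Z) {
  ids <- names(e)
  donors <- ids[e > 0]; recvs <- ids[e < 0]
  eg <- expand.grid(j = donors, i = recvs, stringsAsFactors = FALSE)
  if (nrow(eg)) {
    keep <- mapply(function(j, i) Z[j, i] == 1 && j != i, eg$j, eg$i)
    eg <- eg[as.logical(keep), , drop = FALSE]
  }
  if (nrow(eg) == 0) return(0L)
  ej <- eg$j; ei <- eg$i
  best <- 0L
  rec <- function(k, sur, sho, covered) {
    if (k > length(ej)) { best <<- max(best, covered); return(invisible()) }
    j <- ej[k]; i <- ei[k]
    for (x in 0:min(sur[j], sho[i])) {
      s2 <- sur; s2[j] <- s2[j] - x
      h2 <- sho; h2[i] <- h2[i] - x
      rec(k + 1L, s2, h2, covered + x)
    }
  }
  rec(1L, e[donors], -e[recvs], 0L)
  best
}

# Shortage covered by the package's greedy rule, for comparison with the
# oracle.
greedy_cover <- function(e, Z) {
  p <- pairwise_reallocate(e, Z)
  sum(-pmin(e, 0)) - sum(-pmin(p$residual_e, 0))
}

# Downward-closed skill lattices on n units: every department assignment
# over at most two departments combined with a rank order; nurses may step
# down (equal or lower specialization) within their department.
rank_lattices <- function(n) {
  ids <- paste0("U", seq_len(n))
  out <- list()
  depts <- expand.grid(rep(list(1:2), n))
  ranks <- list(seq_len(n), rev(seq_len(n)),
                c(seq(2, n), 1L), c(n, seq_len(n - 1L)))
  for (d in seq_len(nrow(depts))) {
    for (rk in ranks) {
      Z <- diag(n); dimnames(Z) <- list(ids, ids)
      for (j in seq_len(n)) for (i in seq_len(n)) {
        if (depts[d, j] == depts[d, i] && rk[j] <= rk[i]) Z[j, i] <- 1
      }
      out[[length(out) + 1L]] <- Z
    }
  }
  unique(out)
}
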