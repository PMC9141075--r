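test_that("default transition matrices reproduce the quoted row and are stochastic", {
  m <- pcs_matrices
  # O1n newborn row prints 4%/4%/16%/77% (sum 1.01); rows are renormalized
  raw <- read_transition_matrix(system.file(
    "extdata", "transitions_newborn_synthetic.csv", package = "nurseflex"))
  expect_equal(unname(raw["O1n", c("N1", "N3", "exit", "O1n")]),
               c(0.04, 0.04, 0.16, 0.77))
  expect_equal(unname(m$newborn["O1n", c("N1", "N3", "exit", "O1n")]),
               c(0.04, 0.04, 0.16, 0.77) / 1.01)
  expect_equal(unname(rowSums(m$newborn)), rep(1, 4))
  expect_equal(unname(rowSums(m$adult)), rep(1, 3))
  # group separation: newborn rows cannot reach adult units
  expect_false("O2" %in% colnames(m$newborn))
  expect_false(any(c("N1", "O1n") %in% colnames(m$adult)))
})

test_that("transition constructor validates shape and normalization", {
  nb <- matrix(c(0.9, 0.2), 1, 2, dimnames = list("A", c("A", "exit")))
  ad <- matrix(c(1, 0), 1, 2, dimnames = list("B", c("B", "exit")))
  expect_error(transition_matrices(nb, ad, renormalize = FALSE), "sum to 1")
  m <- transition_matrices(nb, ad, renormalize = TRUE)
  expect_equal(unname(m$newborn["A", ]), c(0.9, 0.2) / 1.1)
  bad <- matrix(1, 1, 2, dimnames = list("A", c("exit", "A")))
  expect_error(transition_matrices(bad, ad), "last column")
})

test_that("identity transitions with no arrivals keep the census constant", {
  sys <- toy_system()
  sc <- demand_scenario(horizon_shifts = 30, arrival_rates = c(A = 0, B = 0),
                        dispersion = 0, seed = 5)
  tr <- simulate_trace(sys, sc, toy_matrices(1, 1),
                       init_census = c(A = 7L, B = 3L))
  expect_true(all(tr$census[, "A"] == 7L))
  expect_true(all(tr$census[, "B"] == 3L))
  expect_true(all(tr$exits == 0L))
})

test_that("census bookkeeping conserves patients at every shift", {
  sc <- demand_scenario(horizon_shifts = 120, dispersion = 1, seed = 7)
  tr <- simulate_trace(pcs, sc, pcs_matrices)
  H <- sc$horizon_shifts
  for (t in seq_len(H)) {
    inflow <- colSums(tr$transfers[t, , ]) + tr$admissions[t, ]
    outflow <- rowSums(tr$transfers[t, , ]) + tr$exits[t, ]
    expect_equal(tr$census[t + 1, ],
                 tr$census[t, ] - outflow + inflow - tr$refusals[t, ])
  }
  expect_true(all(t(tr$census) <= pcs$units$beds))
})

test_that("single-unit census decays geometrically at the stay probability", {
  p <- 0.8; n0 <- 400L
  sys <- toy_system(beds_a = 500L)
  sc <- demand_scenario(horizon_shifts = 6, arrival_rates = c(A = 0, B = 0),
                        dispersion = 0, seed = 11)
  tr <- simulate_trace(sys, sc, toy_matrices(p, 1),
                       init_census = c(A = n0, B = 0L))
  for (t in 1:6) {
    expected <- n0 * p^t
    se <- sqrt(n0 * p^t * (1 - p^t))
    expect_lt(abs(tr$census[t + 1, "A"] - expected), 3 * se + 1e-9)
  }
})

test_that("long-run occupancy matches the analytic immigration chain", {
  # A: stay 0.5, arrivals 2/shift -> stationary census 2 / (1 - 0.5) = 4
  sys <- toy_system(beds_a = 100L)
  m <- toy_matrices(0.5, 1)
  expect_equal(unname(stationary_census(m, c(A = 2, B = 0))), c(4, 0))
  sc <- demand_scenario(horizon_shifts = 3000, arrival_rates = c(A = 2, B = 0),
                        dispersion = 0, seed = 13)
  tr <- simulate_trace(sys, sc, m)
  # mean of an autocorrelated series: allow a generous effective-n cut
  se <- stats::sd(tr$census[, "A"]) / sqrt(3000 / 10)
  expect_lt(abs(mean(tr$census[-1, "A"]) - 4), 3 * se)
})

test_that("traces are bitwise reproducible from the seed", {
  sc <- demand_scenario(horizon_shifts = 60, dispersion = 2, seed = 99)
  t1 <- simulate_trace(pcs, sc, pcs_matrices)
  t2 <- simulate_trace(pcs, sc, pcs_matrices)
  expect_identical(t1$census, t2$census)
  expect_identical(t1$transfers, t2$transfers)
  sc2 <- sc; sc2$seed <- 100L
  t3 <- simulate_trace(pcs, sc2, pcs_matrices)
  expect_false(identical(t1$census, t3$census))
})

test_that("realized CV is monotone non-decreasing in dispersion", {
  sc <- demand_scenario(horizon_shifts = 900, seed = 3)
  cvs <- vapply(c(0, 4, 32), function(th) {
    sc$dispersion <- th
    realized_cv(simulate_trace(pcs, sc, pcs_matrices), pcs)
  }, numeric(1))
  expect_true(all(diff(cvs) >= 0))
})

test_that("dispersion calibration hits the target and flags the floor", {
  sc <- demand_scenario(horizon_shifts = 450, target_cv = 0.31, seed = 2)
  th <- calibrate_dispersion(pcs, sc, pcs_matrices)
  sc$dispersion <- th
  expect_lt(abs(realized_cv(simulate_trace(pcs, sc, pcs_matrices), pcs) - 0.31),
            0.02 + 1e-9)
  expect_error(
    calibrate_dispersion(pcs, sc, pcs_matrices, target_cv = 0.05),
    "feasible floor")
})
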