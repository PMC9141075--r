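test_that("pairwise reallocation honors shortages, surpluses and skills", {
  Z <- matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("B", "A"), c("B", "A")))[c("A", "B"), c("A", "B")]
  # Z[B, A] = 1: B's surplus may cover A
  p <- pairwise_reallocate(c(A = -2, B = 3), Z)
  expect_equal(p$moves["B", "A"], 2L)
  expect_equal(p$M, 2L)
  expect_equal(p$residual_e, c(A = 0, B = 1))
  # no shortage, no plan
  p0 <- pairwise_reallocate(c(A = 1, B = 2), Z)
  expect_equal(p0$M, 0L)
  # skill matrix forbids the move
  Zid <- diag(2); dimnames(Zid) <- list(c("A", "B"), c("A", "B"))
  p2 <- pairwise_reallocate(c(A = -2, B = 3), Zid)
  expect_equal(p2$M, 0L)
  expect_equal(p2$residual_e, c(A = -2, B = 3))
})

test_that("plans are always feasible and conserve nurses", {
  set.seed(7)
  ids <- colnames(pcs$skill)
  for (rep in 1:50) {
    e <- stats::setNames(sample(-4:4, 7, replace = TRUE), ids)
    p <- pairwise_reallocate(e, pcs$skill)
    expect_true(all(p$moves >= 0))
    expect_true(all(p$moves[pcs$skill == 0] == 0))
    expect_true(all(rowSums(p$moves) <= pmax(e, 0)))           # donor cap
    expect_true(all(colSums(p$moves) <= pmax(-e, 0)))          # receiver cap
    expect_equal(sum(p$residual_e), sum(e))                    # conservation
    expect_equal(p$residual_e, e - rowSums(p$moves) + colSums(p$moves))
  }
})

test_that("greedy matches the exhaustive oracle on all three-unit systems", {
  ids <- c("A", "B", "C")
  vals <- -3:3
  mismatches <- 0L
  beats_oracle <- 0L
  checked <- 0L
  for (zbits in 0:63) {
    Z <- diag(3); off <- which(row(Z) != col(Z))
    Z[off] <- as.integer(intToBits(zbits))[1:6]
    dimnames(Z) <- list(ids, ids)
    for (a in vals) for (b in vals) for (cc in vals) {
      e <- c(A = a, B = b, C = cc)
      if (sum(pmax(e, 0)) > 6) next
      g <- greedy_cover(e, Z)
      o <- oracle_cover(e, Z)
      checked <- checked + 1L
      if (g > o) beats_oracle <- beats_oracle + 1L
      if (g != o) mismatches <- mismatches + 1L
    }
  }
  expect_gt(checked, 20000L)
  expect_equal(beats_oracle, 0L)   # greedy can never exceed the optimum
  expect_equal(mismatches, 0L)
})

test_that("flex rate reproduces the worked example and rounds to percent", {
  r <- flex_rate(4, 38)
  expect_equal(as.numeric(r), 11)
  expect_equal(attr(r, "fraction"), 4 / 38)
  expect_equal(as.numeric(flex_rate(0, 38)), 0)
  expect_equal(as.numeric(flex_rate(7, 66)), 11)   # 10.61 -> 11
  expect_error(flex_rate(1, 0), "positive")
})

test_that("float pools are sized and drawn conservatively", {
  fp <- build_float_pool(pcs$roster, 0.07)
  expect_equal(unname(fp$pool["day"]), 2L)          # round(28 * 0.07)
  expect_equal(unname(rowSums(pcs$roster - fp$roster)), unname(fp$pool))
  expect_true(all(fp$roster >= 0))
  fp0 <- build_float_pool(pcs$roster, 0)
  expect_equal(fp0$pool, stats::setNames(rep(0L, 3), rownames(pcs$roster)))
  expect_equal(fp0$roster, pcs$roster)
  expect_error(build_float_pool(pcs$roster, 1.2), "rate")
  # 20% pool of the 176-nurse registry: 35 nurses, EUR 700,000 to train
  expect_equal(training_cost(nurses_to_train("model2", pcs, 0.20)), 700000)
})

test_that("the four strategy models transform gaps as defined", {
  ids <- c("A", "B")
  Z <- matrix(1, 2, 2, dimnames = list(ids, ids))
  units <- data.frame(id = ids, department = c("D", "D"), beds = c(5L, 5L),
                      patient_group = c("adult", "adult"),
                      specialization_rank = 1:2)
  roster <- matrix(5L, 3, 2, dimnames = list(SHIFT_TYPES_TEST, ids))
  ntp <- matrix(2, 3, 2, dimnames = list(SHIFT_TYPES_TEST, ids))
  registry <- data.frame(group = ids, nurses = c(5L, 5L))
  registry$units <- list("A", "B")
  sys <- care_system(units, roster, ntp, Z, registry, name = "mini")

  s <- staffing_gap(c(A = 2, B = 4), c(A = 5, B = 5))   # e = (-3, -1)
  expect_equal(run_model(0, s, sys)$residual_e, s$e)
  m2 <- run_model(2, s, sys, float = 2L)
  expect_equal(m2$float_deployed, c(A = 2L, B = 0L))
  expect_equal(m2$residual_e, c(A = -1, B = -1))
  expect_equal(m2$M, 0L)
  # degenerate pool: model 3 collapses to model 1
  s2 <- staffing_gap(c(A = 2, B = 7), c(A = 5, B = 5))
  m3 <- run_model(3, s2, sys, float = 0L)
  m1 <- run_model(1, s2, sys)
  expect_equal(m3$moves, m1$moves)
  expect_equal(m3$residual_e, m1$residual_e)
  expect_error(run_model(7, s, sys), "unknown model")
})

test_that("model 1 never understaffs more than model 0; model 3 never more than model 2", {
  set.seed(11)
  ids <- colnames(pcs$skill)
  for (rep in 1:30) {
    e <- stats::setNames(sample(-3:3, 7, replace = TRUE), ids)
    a <- pmax(e, 0) + 5
    s <- staffing_gap(a, a - e)
    short <- function(p) sum(pmin(p$residual_e, 0))
    m0 <- run_model(0, s, pcs); m1 <- run_model(1, s, pcs)
    expect_gte(short(m1), short(m0))
    f <- 2L
    m2 <- run_model(2, s, pcs, float = f)
    m3 <- run_model(3, s, pcs, float = f)
    expect_gte(short(m3), short(m2))
  }
})
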