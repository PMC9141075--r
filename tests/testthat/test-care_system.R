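test_that("packaged fixture reproduces the printed system totals", {
  expect_s3_class(pcs, "care_system")
  expect_equal(sum(pcs$units$beds), 70)
  expect_equal(pcs$units$beds[pcs$units$id == "O1n"], 7)
  expect_equal(unname(rowSums(pcs$roster)),
               c(28, 21, 17))          # day, evening, night
  expect_equal(sum(pcs$roster), 66)    # shifts per day
  expect_equal(sum(pcs$registry$nurses), 176)
  # O1 ratios apply to both sub-units; spot checks against the ratio table
  expect_equal(pcs$ntp["day", "O1a"], 5)
  expect_equal(pcs$ntp["night", "O1n"], 16)
  expect_equal(pcs$ntp["evening", "N3"], 6)
  # O1 roster column split by bed share (7/32 vs 25/32, largest remainder)
  expect_equal(unname(pcs$roster[, "O1n"] + pcs$roster[, "O1a"]), c(6, 5, 2))
  expect_equal(unname(pcs$roster["day", c("O1n", "O1a")]), c(1, 5))
})

test_that("current-layout skill matrix matches the qualification table", {
  Z <- pcs$skill
  expect_equal(Z["N1", "N3"], 1L)
  expect_equal(Z["N3", "N1"], 0L)
  expect_equal(unname(Z["O3", ]), c(0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(unname(Z["N2", ]), c(0L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(Z["N3", "O1n"], 1L)
  expect_equal(Z["O1n", "N3"], 1L)
  expect_true(all(diag(Z) == 1L))
})

test_that("skill matrices follow the specialization order and dominance", {
  Z <- pcs$skill
  u <- pcs$units
  # downward reachability within a department, same patient group:
  # Z[j, i] = 1 exactly when j is at least as specialized as i
  for (j in seq_len(nrow(u))) for (i in seq_len(nrow(u))) {
    if (u$department[j] == u$department[i] &&
        u$patient_group[j] == u$patient_group[i]) {
      expect_equal(Z[u$id[j], u$id[i]],
                   as.integer(u$specialization_rank[j] <= u$specialization_rank[i]),
                   info = paste(u$id[j], "->", u$id[i]))
    }
  }
  Z1 <- derive_skill_matrix("config1_two_departments", u)
  Z2 <- derive_skill_matrix("config2_one_department", u)
  expect_true(all(Z1 >= Z))     # pooled layouts dominate entrywise
  expect_true(all(Z2 >= Z1))
  expect_true(all(Z2 == 1L))
  expect_equal(Z1["N2", "N1"], 1L)
  expect_equal(Z1["N2", "O2"], 0L)
  expect_equal(Z1["N3", "O1n"], 1L)
  expect_error(derive_skill_matrix("layout9"), "arg")
})

test_that("float-pool row extends a skill matrix without a pool column", {
  Z7 <- add_float_row(pcs$skill)
  expect_equal(nrow(Z7), 8L)
  expect_equal(ncol(Z7), 7L)
  expect_true(all(Z7["pool", ] == 1L))
  expect_equal(unclass(Z7)[1:7, ], unclass(pcs$skill)[, ])
})

test_that("training headcounts follow the strategy definitions", {
  expect_equal(nurses_to_train("model1_current", pcs), 0L)
  expect_equal(nurses_to_train("model2", pcs, flex_rate = 0.07), 12L)
  expect_equal(nurses_to_train("model2", pcs, flex_rate = 0.20), 35L)
  expect_equal(nurses_to_train("model2", pcs, flex_rate = 0.40), 70L)
  expect_equal(nurses_to_train("config1_two_departments", pcs), 64L)
  expect_equal(nurses_to_train("config2_one_department", pcs), 176L)
  expect_error(nurses_to_train("model2", pcs, flex_rate = -0.1), "non-negative")
})

test_that("care system serializes and parses back identically", {
  path <- withr::local_tempfile(fileext = ".json")
  write_care_system(pcs, path)
  back <- read_care_system(path)
  expect_equal(back$layout, pcs$layout)
  expect_equal(back$roster, pcs$roster)
  expect_equal(back$ntp, pcs$ntp)
  expect_equal(unclass(back$skill), unclass(pcs$skill))
  expect_equal(back$units$beds, pcs$units$beds)
  expect_equal(back$registry$nurses, pcs$registry$nurses)
  expect_equal(back$registry$group, pcs$registry$group)
})

test_that("skill matrices round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_skill_matrix(pcs$skill, path)
  expect_equal(unclass(read_skill_matrix(path)), unclass(pcs$skill))
})

test_that("constructor rejects malformed systems", {
  bad_units <- pcs$units
  bad_units$beds[1] <- 0
  expect_error(care_system(bad_units, pcs$roster, pcs$ntp, pcs$skill,
                           pcs$registry), "beds > 0")
  bad_Z <- unclass(pcs$skill)
  diag(bad_Z)[2] <- 0L
  expect_error(care_system(pcs$units, pcs$roster, pcs$ntp, bad_Z,
                           pcs$registry), "diagonal")
  bad_rank <- pcs$units
  bad_rank$specialization_rank[2] <- 1L   # duplicates N1's rank
  expect_error(care_system(bad_rank, pcs$roster, pcs$ntp, pcs$skill,
                           pcs$registry), "strict order")
})
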