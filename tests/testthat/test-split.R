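test_that("patient-level split is disjoint for every seed tried", {
  ids <- sprintf("P%03d", 1:37)
  for (seed in 1:20) {
    plan <- splitCohort(ids, 0.8, seed = seed)
    expect_length(intersect(plan@trainIds, plan@testIds), 0)
    expect_setequal(c(plan@trainIds, plan@testIds), ids)
  }
})

test_that("identical inputs and seed give an identical plan", {
  ids <- sprintf("P%03d", 1:10)
  p1 <- splitCohort(ids, 0.8, seed = 9)
  p2 <- splitCohort(ids, 0.8, seed = 9)
  expect_identical(p1@trainIds, p2@trainIds)
  expect_length(p1@trainIds, 8)
  expect_length(p1@testIds, 2)
})

test_that("an 0.8 fraction of 7034 patients yields 5627/1407", {
  plan <- splitCohort(sprintf("P%05d", 1:7034), 0.8, seed = 1)
  expect_length(plan@trainIds, 5627)
  expect_length(plan@testIds, 1407)
})

test_that("degenerate cohorts and fractions are rejected", {
  expect_error(splitCohort("P1", 0.8, 1), "at least 2")
  expect_error(splitCohort(c("P1", "P2"), 1.2, 1), "trainFraction")
  expect_error(splitCohort(c("P1", "P1"), 0.5, 1), "duplicate")
})

test_that("temporally overlapping train/test periods are rejected", {
  ids <- sprintf("P%03d", 1:10)
  expect_error(splitCohort(ids, 0.8, 1, trainPeriod = c(2012L, 2021L),
                           testPeriod = c(2021L, 2022L)), "disjoint")
  plan <- splitCohort(ids, 0.8, 1, trainPeriod = c(2012L, 2021L),
                      testPeriod = c(2022L, 2022L))
  expect_s4_class(plan, "SplitPlan")
})

test_that("filterSamples restricts by patient and target-week period", {
  bench <- defaultBenchmarkCohort(seed = 2, nPatients = 20)
  s <- extractSamples(bench$histories, bench$channels, bench$vocabulary, 52)
  plan <- splitCohort(bench$histories, 0.8, seed = 2,
                      trainPeriod = c(2020L, 2021L),
                      testPeriod = c(2022L, 2022L))
  tr <- filterSamples(s, plan, "train")
  te <- filterSamples(s, plan, "test")
  expect_true(all(tr@patientId %in% plan@trainIds))
  expect_true(all(format(tr@targetWeek, "%Y") %in% c("2020", "2021")))
  expect_true(all(te@patientId %in% plan@testIds))
  expect_true(all(format(te@targetWeek, "%Y") == "2022"))
})

test_that("a SplitPlan survives a JSON round trip", {
  plan <- splitCohort(sprintf("P%03d", 1:15), 0.8, seed = 3,
                      testPeriod = c(2022L, 2022L))
  path <- withr::local_tempfile(fileext = ".json")
  writeSplitPlan(plan, path)
  back <- readSplitPlan(path)
  expect_identical(back@trainIds, plan@trainIds)
  expect_identical(back@testIds, plan@testIds)
  expect_identical(back@testPeriod, plan@testPeriod)
  expect_identical(back@trainPeriod, plan@trainPeriod)
})
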