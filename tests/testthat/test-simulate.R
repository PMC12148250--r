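test_that("the generator is byte-identical under a repeated seed", {
  b1 <- defaultBenchmarkCohort(seed = 4, nPatients = 15)
  b2 <- defaultBenchmarkCohort(seed = 4, nPatients = 15)
  expect_identical(eventTable(b1$histories), eventTable(b2$histories))
  b3 <- defaultBenchmarkCohort(seed = 5, nPatients = 15)
  expect_false(identical(eventTable(b1$histories), eventTable(b3$histories)))
})

test_that("per-visit missingness matches the configured rate", {
  spec <- cohortSpec(nPatients = 120, startYear = 2020, years = 2, seed = 8,
                     missingRate = c(glucose = 0.3))
  hs <- simulateCohort(spec, benchmarkPolicy(noiseRate = 0))
  nVisits <- attr(hs, "visitCount")
  ev <- eventTable(hs)
  nGlu <- sum(ev$channel == "glucose")
  phat <- 1 - nGlu / nVisits
  se <- sqrt(0.3 * 0.7 / nVisits)
  expect_lt(abs(phat - 0.3), 3 * se)   # binomial standard-error check
})

test_that("with zero rule noise the policy is exactly recoverable from the chart", {
  co <- singleRuleCohort(seed = 9, nPatients = 25)
  for (h in co$histories) {
    ev <- h@events
    visits <- unique(ev$date)
    for (d in visits) {
      state <- lastObsBeforeWeek(ev, "hba1c", d)
      gotA <- any(ev$channel == "drug_a" & ev$date == d)
      if (!is.na(state)) {
        expect_equal(gotA, state >= 7.0)
      } else {
        expect_false(gotA)
      }
    }
  }
})

test_that("the default benchmark matches its stated layout", {
  bench <- defaultBenchmarkCohort(seed = 3, nPatients = 40)
  expect_gte(nDrugs(bench$vocabulary), 8)
  expect_lte(nDrugs(bench$vocabulary), 12)
  expect_length(bench$channels@name, 12)
  expect_equal(sum(bench$channels@kind == "numeric"), 10)
  expect_equal(sum(bench$channels@kind == "categorical"), 2)
  # the late-entry drug is never prescribed before its activation year
  ev <- eventTable(bench$histories)
  drift <- ev[ev$channel == "lispro_biosim", ]
  expect_gt(nrow(drift), 0)
  expect_true(all(as.integer(format(drift$date, "%Y")) >= 2021))
})

test_that("generator bookkeeping matches a brute-force recount", {
  bench <- defaultBenchmarkCohort(seed = 7, nPatients = 30)
  ev <- eventTable(bench$histories)
  counts <- attr(bench$histories, "drugCounts")
  recount <- table(factor(ev$channel[ev$channel %in% bench$vocabulary@drugs],
                          levels = bench$vocabulary@drugs))
  expect_equal(unname(counts), as.integer(recount))
})

test_that("every drug in the vocabulary is reachable by some rule", {
  pol <- benchmarkPolicy(driftYear = 2021)
  ruled <- unique(unlist(lapply(pol@rules, `[[`, "drugs")))
  expect_setequal(ruled, benchmarkVocabulary()@drugs)
  expect_error(simulateCohort(
    cohortSpec(nPatients = 2, seed = 1), pol,
    vocabulary = drugVocabulary("something_else")), "outside the vocabulary")
})
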