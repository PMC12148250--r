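ch <- channelSet("hba1c", "numeric")
vb <- drugVocabulary(c("a", "b"))

test_that("one sample per prescription week with prior history", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date(c("2022-01-04",                      # labs only
                     "2022-02-01", "2022-02-03",        # rx week 1
                     "2022-03-01",                      # rx week 2
                     "2022-04-05")),                    # rx week 3
    channel = c("hba1c", "a", "hba1c", "a", "b"),
    value = c("7.1", "1", "7.3", "1", "1")))
  s <- extractSamples(h, ch, vb, 52)
  expect_equal(length(s), 3L)
  expect_equal(s@targetWeek,
               weekMonday(as.Date(c("2022-02-01", "2022-03-01", "2022-04-05"))))
  expect_equal(unname(s@target[, 3]), c(0, 1))
  # input window strictly precedes each target week
  expect_true(all(s@targetWeek - 1 >= s@targetWeek - 7 * s@windowWeeks))
  # week of 2022-02-01: drug "a" prescribed, hba1c 7.3 recorded same week ->
  # neither appears in that sample's own input window
  expect_equal(sum(s@drugHist[, , 1]), 0)
  expect_equal(sum(s@numMask[, , 1]), 1)  # only the January lab
})

test_that("patients without prescriptions yield no samples", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date("2022-01-04"), channel = "hba1c", value = "7.1"))
  expect_equal(length(extractSamples(h, ch, vb)), 0L)
})

test_that("a first-week prescription with no prior history is not a sample", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date(c("2022-01-04", "2022-01-05")),
    channel = c("a", "hba1c"), value = c("1", "7.0")))
  expect_equal(length(extractSamples(h, ch, vb)), 0L)
})

test_that("sample count matches a brute-force event-table recount", {
  bench <- defaultBenchmarkCohort(seed = 5, nPatients = 100)
  s <- extractSamples(bench$histories, bench$channels, bench$vocabulary, 52)
  expect_equal(length(s),
               bruteSampleCount(bench$histories, bench$vocabulary@drugs))
  # every sample target has at least one positive drug
  expect_true(all(colSums(s@target) >= 1))
})

test_that("sample targets match the raw event table drug sets", {
  bench <- defaultBenchmarkCohort(seed = 6, nPatients = 12)
  s <- extractSamples(bench$histories, bench$channels, bench$vocabulary, 52)
  for (i in seq_len(min(length(s), 30))) {
    h <- bench$histories[[s@patientId[i]]]
    m <- s@targetWeek[i]
    inWeek <- h@events$date >= m & h@events$date <= m + 6 &
      h@events$channel %in% bench$vocabulary@drugs
    expect_setequal(bench$vocabulary@drugs[s@target[, i] == 1],
                    unique(h@events$channel[inWeek]))
  }
})

test_that("sampleWindow materializes a consistent SampleWindow", {
  bench <- defaultBenchmarkCohort(seed = 6, nPatients = 6)
  s <- extractSamples(bench$histories, bench$channels, bench$vocabulary, 52)
  sw <- sampleWindow(s, 1)
  expect_s4_class(sw, "SampleWindow")
  expect_true(sum(sw@target) >= 1)
  expect_equal(sw@grid@windowEnd, sw@targetWeek - 1)
  # the materialized grid equals a direct quantization of the raw history
  h <- bench$histories[[s@patientId[1]]]
  g <- quantizeToWeeks(h, bench$channels, bench$vocabulary,
                       sw@targetWeek - 1, 52)
  expect_equal(sw@grid@numValues, g@numValues)
  expect_equal(sw@grid@drugHist, g@drugHist)
})
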