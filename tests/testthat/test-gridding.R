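ch <- channelSet(c("hba1c", "urine_protein"), c("numeric", "categorical"),
                 categories = list(character(0), c("-", "+-", "1+", "2+", "3+")))
vb <- drugVocabulary(c("a", "b"))

test_that("week arithmetic follows the Monday-Sunday convention", {
  expect_equal(weekMonday(as.Date("2022-03-02")), as.Date("2022-02-28"))
  expect_equal(weekMonday(as.Date("2022-02-28")), as.Date("2022-02-28"))
  expect_equal(weekMonday(as.Date("2022-03-06")), as.Date("2022-02-28"))
  expect_equal(snapToSunday(as.Date("2022-03-06")), as.Date("2022-03-06"))
  expect_equal(snapToSunday(as.Date("2022-03-05")), as.Date("2022-02-27"))
  expect_equal(snapToSunday(as.Date("2022-03-07")), as.Date("2022-03-06"))
})

test_that("grid slot count equals ceiling(Y*365/7) for Y in 1..10", {
  expect_equal(vapply(1:10, function(y) gridSpec(y)@weeks, 1L),
               c(53L, 105L, 157L, 209L, 261L, 313L, 365L, 418L, 470L, 522L))
  expect_error(new("GridSpec", years = 1L, weeks = 52L), "ceiling")
})

test_that("within-week numeric values are arithmetic means", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date(c("2022-03-01", "2022-03-03", "2022-02-22")),
    channel = "hba1c", value = c("7.0", "8.0", "6.0")))
  g <- quantizeToWeeks(h, ch, vb, as.Date("2022-03-06"), 4)
  expect_equal(unname(g@numValues["hba1c", 4]), 7.5)    # two measurements averaged
  expect_equal(unname(g@numValues["hba1c", 3]), 6.0)
  expect_true(g@numMask["hba1c", 4])
  expect_false(g@numMask["hba1c", 1])
  expect_true(is.na(g@numValues["hba1c", 1]))   # sentinel under the mask
})

test_that("categorical channels keep the week's last observation", {
  h <- patientHistory("p1", "female", 1950, data.frame(
    date = as.Date(c("2022-03-01", "2022-03-04")),
    channel = "urine_protein", value = c("2+", "1+")))
  g <- quantizeToWeeks(h, ch, vb, as.Date("2022-03-06"), 2)
  expect_equal(unname(g@catValues["urine_protein", 2]), 3L)  # "1+" observed later
  expect_error(quantizeToWeeks(
    patientHistory("p1", "female", 1950, data.frame(
      date = as.Date("2022-03-01"), channel = "urine_protein", value = "9+")),
    ch, vb, as.Date("2022-03-06"), 2), "unknown level")
})

test_that("drug slots flag any prescription in the week", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date(c("2022-03-01", "2022-03-03")),
    channel = c("a", "hba1c"), value = c("1", "7.0")))
  g <- quantizeToWeeks(h, ch, vb, as.Date("2022-03-06"), 2)
  expect_equal(g@drugHist["a", ], c(0, 1))
  expect_equal(g@drugHist["b", ], c(0, 0))
})

test_that("events outside the window are excluded, empty history is all-masked", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date("2022-03-08"), channel = "hba1c", value = "9.0"))
  g <- quantizeToWeeks(h, ch, vb, as.Date("2022-03-06"), 2)
  expect_false(any(g@numMask))
  empty <- patientHistory("p2", "male", 1960,
    data.frame(date = as.Date(character(0)), channel = character(0),
               value = character(0)))
  g2 <- quantizeToWeeks(empty, ch, vb, as.Date("2022-03-06"), 3)
  expect_false(any(g2@numMask))
  expect_true(all(is.na(g2@catValues)))
  expect_true(all(g2@drugHist == 0))
})

test_that("windowEnd must be a Sunday", {
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = as.Date("2022-03-01"), channel = "hba1c", value = "7"))
  expect_error(quantizeToWeeks(h, ch, vb, as.Date("2022-03-05"), 2), "Sunday")
})

test_that("quantization is idempotent on an already weekly-regular history", {
  # one observation per channel per week, placed mid-week
  end <- as.Date("2022-03-06")
  weeks <- 8
  dates <- end - 7 * (weeks:1) + 3
  set.seed(4)
  vals <- round(rnorm(weeks, 7, 1), 3)
  h <- patientHistory("p1", "male", 1960, data.frame(
    date = dates, channel = "hba1c", value = as.character(vals)))
  g <- quantizeToWeeks(h, ch, vb, end, weeks)
  expect_equal(unname(g@numValues["hba1c", ]), vals)
  # re-grid the gridded values: identical
  h2 <- patientHistory("p1", "male", 1960, data.frame(
    date = dates, channel = "hba1c", value = as.character(g@numValues["hba1c", ])))
  g2 <- quantizeToWeeks(h2, ch, vb, end, weeks)
  expect_identical(g@numValues, g2@numValues)
  expect_identical(g@numMask, g2@numMask)
})
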