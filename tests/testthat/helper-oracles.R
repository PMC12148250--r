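# Independent oracles and small fixture builders shared across the suite.

# O(n^2) positive-negative pair count, ties half credit
pairAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# brute-force recount of (patient, prescription-week-with-prior-history)
# pairs straight from a long event table
bruteSampleCount <- function(histories, drugIds) {
  total <- 0L
  for (h in histories) {
    ev <- h@events
    rx <- ev[ev$channel %in% drugIds, , drop = FALSE]
    if (nrow(rx) == 0) next
    mondays <- unique(weekMonday(rx$date))
    for (m in mondays) if (any(ev$date < m)) total <- total + 1L
  }
  total
}

# last observed value of `channel` strictly before the week containing `date`
lastObsBeforeWeek <- function(events, channel, date) {
  m <- weekMonday(date)
  sel <- events$channel == channel & events$date < m
  if (!any(sel)) return(NA_real_)
  as.numeric(events$value[sel][sum(sel)])
}

tinyChannels <- function() {
  channelSet(c("hba1c", "urine_protein"), c("numeric", "categorical"),
             categories = list(character(0), c("-", "+-", "1+", "2+", "3+")))
}

tinyModel <- function(channels = tinyChannels(),
                      vocabulary = drugVocabulary(c("a", "b", "c")),
                      seed = 7L, windowWeeks = 52L) {
  seq2setModel(channels, vocabulary,
               modelConfig("desk", hidden = 16L, encoderLayers = 1L,
                           decoderLayers = 1L, heads = 2L, ffDim = 32L,
                           windowWeeks = windowWeeks),
               seed = seed)
}

# random weekly grid matching tinyChannels()/3 drugs
randomGrid <- function(seed, weeks = 52L, channels = tinyChannels(),
                       vocabulary = drugVocabulary(c("a", "b", "c"))) {
  set.seed(seed)
  numValues <- matrix(NA_real_, 1, weeks, dimnames = list("hba1c", NULL))
  obs <- runif(weeks) < 0.3
  numValues[1, obs] <- rnorm(sum(obs), 7.5, 1.5)
  catValues <- matrix(NA_integer_, 1, weeks,
                      dimnames = list("urine_protein", NULL))
  cobs <- runif(weeks) < 0.2
  catValues[1, cobs] <- sample(1:5, sum(cobs), replace = TRUE)
  drugHist <- matrix(as.numeric(runif(3 * weeks) < 0.1), 3, weeks,
                     dimnames = list(vocabulary@drugs, NULL))
  new("WeeklyGrid", numValues = numValues, numMask = !is.na(numValues),
      catValues = catValues, drugHist = drugHist, sex = sample(1:2, 1),
      age = round(runif(1, 40, 85)), windowEnd = snapToSunday(Sys.Date()),
      channels = channels, vocabulary = vocabulary)
}
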