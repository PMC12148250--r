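#' @include AllClasses.R weeks.R
NULL

#' Quantize an irregular patient history to a weekly grid
#'
#' Collapses irregularly dated events onto Monday-to-Sunday week slots:
#' numeric channels take the arithmetic mean of the week's measurements,
#' categorical channels the week's last observed level, drug channels flag
#' whether the drug was prescribed at least once in the week. Weeks with no
#' observation of a channel are masked missing and carry the `NA` sentinel;
#' nothing is imputed.
#'
#' @param history a [PatientHistory-class].
#' @param channels the [ChannelSet-class] describing the laboratory panel.
#' @param vocabulary the [DrugVocabulary-class].
#' @param windowEnd the Sunday the window ends on (see [snapToSunday()]).
#' @param weeks number of weekly slots, or a [GridSpec-class].
#' @return A [WeeklyGrid-class] with exactly `weeks` slots. Events dated
#'   after `windowEnd` (or before the window start) are excluded; an empty
#'   history yields an all-masked grid.
#' @examples
#' ch <- channelSet("hba1c", "numeric")
#' vb <- drugVocabulary("drug_a")
#' h <- patientHistory("p1", "male", 1960, data.frame(
#'   date = as.Date(c("2022-03-01", "2022-03-03")),
#'   channel = "hba1c", value = c("7.0", "8.0")))
#' g <- quantizeToWeeks(h, ch, vb, windowEnd = as.Date("2022-03-06"), weeks = 4)
#' g@numValues["hba1c", 4]  # 7.5, the within-week mean
#' @export
quantizeToWeeks <- function(history, channels, vocabulary, windowEnd, weeks) {
  if (is(weeks, "GridSpec")) weeks <- weeks@weeks
  weeks <- as.integer(weeks)
  windowEnd <- as.Date(windowEnd)
  if (as.integer(format(windowEnd, "%u")) != 7L)
    stop("windowEnd must be a Sunday; use snapToSunday()")

  numCh <- numericChannels(channels)
  catCh <- categoricalChannels(channels)
  drugIds <- vocabulary@drugs

  numValues <- matrix(NA_real_, length(numCh), weeks,
                      dimnames = list(numCh, NULL))
  catValues <- matrix(NA_integer_, length(catCh), weeks,
                      dimnames = list(catCh, NULL))
  drugHist <- matrix(0, length(drugIds), weeks, dimnames = list(drugIds, NULL))

  ev <- history@events
  if (nrow(ev) > 0) {
    idx <- weekIndex(ev$date, windowEnd, weeks)
    keep <- idx >= 1L & idx <= weeks
    ev <- ev[keep, , drop = FALSE]
    idx <- idx[keep]
    for (ch in numCh) {
      sel <- ev$channel == ch
      if (!any(sel)) next
      v <- as.numeric(ev$value[sel])
      if (any(!is.finite(v))) stop("non-finite value in numeric channel ", ch)
      m <- tapply(v, idx[sel], mean)
      numValues[ch, as.integer(names(m))] <- m
    }
    for (ch in catCh) {
      sel <- ev$channel == ch
      if (!any(sel)) next
      lv <- categoryLevels(channels, ch)
      k <- match(ev$value[sel], lv)
      if (anyNA(k)) stop("unknown level in categorical channel ", ch)
      # events are date-sorted, so the last entry per week wins
      last <- tapply(k, idx[sel], function(x) x[length(x)])
      catValues[ch, as.integer(names(last))] <- last
    }
    for (dg in drugIds) {
      sel <- ev$channel == dg
      if (any(sel)) drugHist[dg, unique(idx[sel])] <- 1
    }
  }

  new("WeeklyGrid",
      numValues = numValues, numMask = !is.na(numValues),
      catValues = catValues, drugHist = drugHist,
      sex = match(history@sex, c("male", "female")),
      age = ageAt(history, windowEnd), windowEnd = windowEnd,
      channels = channels, vocabulary = vocabulary)
}

#' Extract prediction samples from patient histories
#'
#' Emits one sample per calendar week in which the patient was prescribed at
#' least one drug and which is preceded by at least one week of history. Each
#' sample's input is the weekly grid of the `windowWeeks` weeks strictly
#' before the target week; the target is the multi-hot vector of all drugs
#' prescribed in the target week. Deterministic given the history.
#'
#' @param histories a [PatientHistory-class] or a list of them.
#' @param channels the [ChannelSet-class].
#' @param vocabulary the [DrugVocabulary-class].
#' @param windowWeeks input window length; default 52 complete weeks ("past
#'   one year").
#' @return A [SampleSet-class]; patients with no prescription events
#'   contribute no samples.
#' @export
extractSamples <- function(histories, channels, vocabulary, windowWeeks = 52L) {
  if (is(histories, "PatientHistory")) histories <- list(histories)
  windowWeeks <- as.integer(windowWeeks)
  numCh <- numericChannels(channels)
  catCh <- categoricalChannels(channels)
  drugIds <- vocabulary@drugs

  parts <- lapply(histories, function(h)
    .extractOne(h, channels, vocabulary, windowWeeks, numCh, catCh, drugIds))
  parts <- parts[!vapply(parts, is.null, TRUE)]
  n <- sum(vapply(parts, function(p) length(p$age), 1L))

  numValues <- array(NA_real_, c(length(numCh), windowWeeks, n))
  numMask <- array(0, c(length(numCh), windowWeeks, n))
  catValues <- array(0, c(length(catCh), windowWeeks, n))
  drugHist <- array(0, c(length(drugIds), windowWeeks, n))
  target <- matrix(0, length(drugIds), n)
  sex <- integer(n); age <- numeric(n)
  targetWeek <- rep(as.Date(NA), n); patientId <- character(n)

  at <- 0L
  for (p in parts) {
    k <- length(p$age)
    ix <- at + seq_len(k)
    numValues[, , ix] <- p$numValues
    numMask[, , ix] <- p$numMask
    catValues[, , ix] <- p$catValues
    drugHist[, , ix] <- p$drugHist
    target[, ix] <- p$target
    sex[ix] <- p$sex; age[ix] <- p$age
    targetWeek[ix] <- p$targetWeek; patientId[ix] <- p$patientId
    at <- at + k
  }
  dimnames(numValues) <- dimnames(numMask) <- list(numCh, NULL, NULL)
  dimnames(catValues) <- list(catCh, NULL, NULL)
  dimnames(drugHist) <- list(drugIds, NULL, NULL)
  rownames(target) <- drugIds

  new("SampleSet", numValues = numValues, numMask = numMask,
      catValues = catValues, drugHist = drugHist, sex = sex, age = age,
      target = target, targetWeek = targetWeek, patientId = patientId,
      channels = channels, vocabulary = vocabulary, windowWeeks = windowWeeks)
}

## one patient: grid the full history once, then slice 52-week windows
.extractOne <- function(h, channels, vocabulary, windowWeeks, numCh, catCh, drugIds) {
  ev <- h@events
  if (nrow(ev) == 0) return(NULL)
  isRx <- ev$channel %in% drugIds
  if (!any(isRx)) return(NULL)

  rxMondays <- sort(unique(weekMonday(ev$date[isRx])))
  # require >= 1 week of history strictly before the target week
  rxMondays <- rxMondays[vapply(rxMondays,
    function(m) any(ev$date < m), TRUE)]
  if (length(rxMondays) == 0) return(NULL)

  globalEnd <- max(snapToSunday(max(ev$date)), max(rxMondays) - 1L)
  totalWeeks <- as.integer(as.numeric(globalEnd - weekMonday(min(ev$date)) + 1L) %/% 7)
  grid <- quantizeToWeeks(h, channels, vocabulary, globalEnd, totalWeeks)

  k <- length(rxMondays)
  numValues <- array(NA_real_, c(length(numCh), windowWeeks, k))
  numMask <- array(0, c(length(numCh), windowWeeks, k))
  catValues <- array(0, c(length(catCh), windowWeeks, k))
  drugHist <- array(0, c(length(drugIds), windowWeeks, k))
  target <- matrix(0, length(drugIds), k)
  age <- numeric(k)

  for (s in seq_len(k)) {
    m <- rxMondays[s]
    endIdx <- weekIndex(m - 1L, globalEnd, totalWeeks)
    cols <- (endIdx - windowWeeks + 1L):endIdx
    valid <- cols >= 1L
    dst <- which(valid); src <- cols[valid]
    numValues[, dst, s] <- grid@numValues[, src, drop = FALSE]
    numMask[, dst, s] <- grid@numMask[, src, drop = FALSE]
    cv <- grid@catValues[, src, drop = FALSE]
    cv[is.na(cv)] <- 0
    catValues[, dst, s] <- cv
    drugHist[, dst, s] <- grid@drugHist[, src, drop = FALSE]
    inWeek <- isRx & ev$date >= m & ev$date <= m + 6L
    target[unique(match(ev$channel[inWeek], drugIds)), s] <- 1
    age[s] <- ageAt(h, m - 1L)
  }
  list(numValues = numValues, numMask = numMask, catValues = catValues,
       drugHist = drugHist, target = target,
       sex = match(h@sex, c("male", "female")), age = age,
       targetWeek = rxMondays, patientId = rep(h@patientId, k))
}

#' Materialize one sample as a SampleWindow
#'
#' @param set a [SampleSet-class].
#' @param i sample index.
#' @return A [SampleWindow-class] holding the input [WeeklyGrid-class], the
#'   target week and the multi-hot target.
#' @export
sampleWindow <- function(set, i) {
  numValues <- set@numValues[, , i, drop = TRUE]
  if (is.null(dim(numValues)))
    numValues <- matrix(numValues, nrow = dim(set@numValues)[1])
  numMask <- matrix(set@numMask[, , i] > 0.5, nrow = dim(set@numMask)[1])
  catValues <- matrix(as.integer(set@catValues[, , i]),
                      nrow = dim(set@catValues)[1])
  catValues[catValues == 0L] <- NA_integer_
  rownames(numValues) <- rownames(numMask) <- numericChannels(set@channels)
  rownames(catValues) <- categoricalChannels(set@channels)
  drugHist <- matrix(set@drugHist[, , i], nrow = dim(set@drugHist)[1],
                     dimnames = list(set@vocabulary@drugs, NULL))
  grid <- new("WeeklyGrid", numValues = numValues, numMask = numMask,
              catValues = catValues, drugHist = drugHist,
              sex = set@sex[i], age = set@age[i],
              windowEnd = set@targetWeek[i] - 1L,
              channels = set@channels, vocabulary = set@vocabulary)
  tgt <- set@target[, i]
  names(tgt) <- set@vocabulary@drugs
  new("SampleWindow", grid = grid, targetWeek = set@targetWeek[i], target = tgt)
}
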