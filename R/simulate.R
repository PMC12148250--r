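#' @include AllClasses.R weeks.R io.R
NULL

## Synthetic EHR cohorts with a known rule-based prescriber policy.
##
## Each patient carries four latent disease axes (glycemia, lipids, renal,
## liver), each a mean-reverting random walk at weekly resolution. Visits
## occur at random gaps of weeks to months; each visit observes a noisy
## subset of the 12-channel laboratory panel; the prescriber applies ordered
## threshold rules to the patient's chart (the last observed value of each
## channel strictly before the visit week) and prescribes the union of the
## firing rules' drug sets. With zero rule noise the prescribed set is a
## deterministic function of the observable history.

#' The default 12-channel laboratory panel
#'
#' Ten numeric channels (HbA1c, glucose, triacylglycerol, HDL and total
#' cholesterol, urinary albumin-creatinine ratio, creatinine, ALT, AST, GGT)
#' and two ordinal urine dipstick channels with levels -, +-, 1+, 2+, 3+.
#'
#' @return A [ChannelSet-class].
#' @export
defaultChannels <- function() {
  dip <- c("-", "+-", "1+", "2+", "3+")
  channelSet(
    name = c("hba1c", "glucose", "tg", "hdl", "tc", "uacr", "cre", "alt",
             "ast", "ggt", "urine_protein", "urine_glucose"),
    kind = c(rep("numeric", 10), "categorical", "categorical"),
    categories = c(replicate(10, character(0), simplify = FALSE),
                   list(dip, dip)),
    units = c("%", "mg/dL", "mg/dL", "mg/dL", "mg/dL", "mg/gCr", "mg/dL",
              "U/L", "U/L", "U/L", "", ""))
}

.defaultLabNoise <- function() c(
  hba1c = 0.10, glucose = 12, tg = 12, hdl = 4, tc = 10, uacr = 6,
  cre = 0.05, alt = 3, ast = 3, ggt = 5, urine_protein = 0.3,
  urine_glucose = 0.3)

.defaultMissingRate <- function() c(
  hba1c = 0.05, glucose = 0.10, tg = 0.20, hdl = 0.20, tc = 0.20,
  uacr = 0.35, cre = 0.15, alt = 0.20, ast = 0.20, ggt = 0.25,
  urine_protein = 0.30, urine_glucose = 0.30)

## latent -> expected observation; obs adds labNoise on top
.latentToLab <- function(g, l, r, v) list(
  hba1c = g,
  glucose = 60 + 12 * g,
  tg = exp(4.7 + 0.35 * l),
  hdl = 60 - 10 * l,
  tc = 195 + 15 * l,
  uacr = exp(3.3 + 1.0 * r),
  cre = exp(-0.105 + 0.28 * r),
  alt = exp(3.1 + 0.40 * v),
  ast = exp(3.0 + 0.35 * v),
  ggt = exp(3.4 + 0.50 * v))

.labFloor <- c(hba1c = 4, glucose = 40, tg = 20, hdl = 15, tc = 80,
               uacr = 1, cre = 0.2, alt = 3, ast = 3, ggt = 3)

#' Benchmark prescriber policy over ten drug classes
#'
#' Ordered threshold rules on the chart state: stepped glycemia rules
#' (metformin, DPP-4 inhibitor, sulfonylurea, basal insulin), a glucose rule
#' (rapid insulin), renal rules (renally dosed DPP-4 inhibitor on creatinine,
#' SGLT2 inhibitor on albuminuria, GLP-1 receptor agonist on dipstick
#' proteinuria), a lipid rule (pioglitazone on low HDL) and one late-entry
#' biosimilar rule active only from `driftYear` on (emulating a drug whose
#' prescribing starts mid-study).
#'
#' @param driftYear first calendar year in which the late rule is active
#'   (`NA` disables it).
#' @param noiseRate per-visit, per-rule suppression probability.
#' @return A [PrescriberPolicy-class].
#' @export
benchmarkPolicy <- function(driftYear = NA_integer_, noiseRate = 0.03) {
  prescriberPolicy(list(
    policyRule("r_met",    "hba1c",   ">=", 6.8, "metformin"),
    policyRule("r_dpp4",   "hba1c",   ">=", 7.6, "sitagliptin"),
    policyRule("r_su",     "hba1c",   ">=", 8.4, "glimepiride"),
    policyRule("r_basal",  "hba1c",   ">=", 9.3, "insulin_basal"),
    policyRule("r_rapid",  "glucose", ">=", 165, "insulin_rapid"),
    policyRule("r_lina",   "cre",     ">=", 1.15, "linagliptin"),
    policyRule("r_pio",    "hdl",     "<",  47,  "pioglitazone"),
    policyRule("r_sglt2",  "uacr",    ">=", 60,  "empagliflozin"),
    policyRule("r_glp1",   "urine_protein", ">=", 4, "semaglutide"),
    policyRule("r_drift",  "hba1c",   ">=", 8.0, "lispro_biosim",
               activeFrom = driftYear)),
    noiseRate = noiseRate)
}

#' Vocabulary matching [benchmarkPolicy()]
#' @return A [DrugVocabulary-class] of the ten drug classes.
#' @export
benchmarkVocabulary <- function() {
  drugVocabulary(c("metformin", "sitagliptin", "glimepiride", "insulin_basal",
                   "insulin_rapid", "linagliptin", "pioglitazone",
                   "empagliflozin", "semaglutide", "lispro_biosim"))
}

#' Simulate a synthetic EHR cohort
#'
#' @param spec a [CohortSpec-class].
#' @param policy a [PrescriberPolicy-class].
#' @param channels a [ChannelSet-class] (the default panel is assumed for
#'   the latent-to-lab maps).
#' @param vocabulary a [DrugVocabulary-class]; every drug a rule references
#'   must be present.
#' @return Named list of [PatientHistory-class]; attribute `drugCounts`
#'   carries the generator's own per-drug prescription-event bookkeeping,
#'   attribute `visitCount` the total number of visits. Byte-identical for
#'   identical spec and seed.
#' @export
simulateCohort <- function(spec, policy, channels = defaultChannels(),
                           vocabulary = benchmarkVocabulary()) {
  ruleDrugs <- unique(unlist(lapply(policy@rules, `[[`, "drugs")))
  if (!all(ruleDrugs %in% vocabulary@drugs))
    stop("policy references drugs outside the vocabulary")
  labNoise <- .fillNamed(spec@labNoise, .defaultLabNoise(), channels@name)
  missRate <- .fillNamed(spec@missingRate, .defaultMissingRate(), channels@name)

  totalWeeks <- as.integer(ceiling(spec@years * 365 / 7))
  day0 <- weekMonday(as.Date(sprintf("%d-01-07", spec@startYear)))
  numCh <- numericChannels(channels)
  catCh <- categoricalChannels(channels)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec@seed)

  drugCounts <- stats::setNames(integer(length(vocabulary@drugs)),
                                vocabulary@drugs)
  nVisits <- 0L
  histories <- vector("list", spec@nPatients)

  for (i in seq_len(spec@nPatients)) {
    pid <- sprintf("P%04d", i)
    sex <- if (stats::runif(1) < 0.62) "male" else "female"
    age0 <- round(min(90, max(30, stats::rnorm(1, 66, 12))))
    birthYear <- spec@startYear - age0

    mu <- c(g = min(12, max(5.2, stats::rnorm(1, 7.4, 1.3))),
            l = stats::rnorm(1), r = stats::rnorm(1), v = stats::rnorm(1))
    x0 <- mu + stats::rnorm(4, 0, c(0.5, 0.4, 0.3, 0.3))
    kappa <- 0.03
    stepSd <- c(0.06, 0.05, 0.04, 0.04)
    lat <- vapply(1:4, function(k) {
      mu[k] + as.numeric(stats::filter(stepSd[k] * stats::rnorm(totalWeeks),
                                       1 - kappa, "recursive",
                                       init = x0[k] - mu[k]))
    }, numeric(totalWeeks))

    # visit weeks: minimum gap plus a geometric tail
    gapExtra <- spec@visitGapMean - spec@visitGapMin
    w <- sample.int(min(6L, totalWeeks), 1L)
    visitWeeks <- integer(0)
    while (w <= totalWeeks) {
      visitWeeks <- c(visitWeeks, w)
      w <- w + spec@visitGapMin +
        stats::rgeom(1, 1 / (1 + max(0.01, gapExtra)))
    }

    state <- stats::setNames(rep(NA_real_, length(channels@name)), channels@name)
    dates <- character(0); chs <- character(0); vals <- character(0)

    for (vw in visitWeeks) {
      date <- day0 + (vw - 1L) * 7L + sample.int(5L, 1L) - 1L
      year <- as.integer(format(date, "%Y"))

      # prescriber acts on the chart as of the previous week
      rx <- character(0)
      for (r in policy@rules) {
        if (!is.na(r$activeFrom) && year < r$activeFrom) next
        sv <- state[[r$channel]]
        if (is.na(sv)) next
        fire <- if (r$op == ">=") sv >= r$threshold else sv < r$threshold
        if (fire && (policy@noiseRate == 0 ||
                     stats::runif(1) >= policy@noiseRate))
          rx <- c(rx, r$drugs)
      }
      rx <- unique(rx)

      exp_ <- .latentToLab(lat[vw, 1], lat[vw, 2], lat[vw, 3], lat[vw, 4])
      obs <- stats::setNames(rep(NA_real_, length(channels@name)), channels@name)
      for (ch in numCh) {
        if (stats::runif(1) < missRate[[ch]]) next
        obs[[ch]] <- max(.labFloor[[ch]],
                         exp_[[ch]] + stats::rnorm(1, 0, labNoise[[ch]]))
      }
      dip <- c("-", "+-", "1+", "2+", "3+")
      for (ch in catCh) {
        if (stats::runif(1) < missRate[[ch]]) next
        z <- if (ch == "urine_protein")
          lat[vw, 3] + stats::rnorm(1, 0, labNoise[[ch]])
        else (lat[vw, 1] - 7.5) / 1.0 + stats::rnorm(1, 0, labNoise[[ch]])
        cuts <- if (ch == "urine_protein") c(0.6, 1.0, 1.35, 1.7)
                else c(0.0, 0.9, 1.8, 2.7)
        obs[[ch]] <- sum(z >= cuts) + 1
      }

      for (ch in channels@name) {
        if (is.na(obs[[ch]])) next
        dates <- c(dates, format(date))
        chs <- c(chs, ch)
        vals <- c(vals, if (ch %in% numCh) as.character(round(obs[[ch]], 3))
                        else dip[obs[[ch]]])
        state[[ch]] <- obs[[ch]]
      }
      for (dg in rx) {
        dates <- c(dates, format(date))
        chs <- c(chs, dg)
        vals <- c(vals, "1")
        drugCounts[[dg]] <- drugCounts[[dg]] + 1L
      }
      nVisits <- nVisits + 1L
    }

    histories[[i]] <- patientHistory(pid, sex, birthYear,
      data.frame(date = as.Date(dates), channel = chs, value = vals))
  }
  names(histories) <- vapply(histories, function(h) h@patientId, "")
  attr(histories, "drugCounts") <- drugCounts
  attr(histories, "visitCount") <- nVisits
  histories
}

.fillNamed <- function(given, default, names) {
  out <- default[names]
  out[is.na(out)] <- 0
  if (length(given)) out[names(given)] <- given
  out
}

#' The default seeded benchmark cohort
#'
#' A desk-scale cohort: 300 patients over three calendar years (2020-2022)
#' with the 12-channel panel, the ten-drug [benchmarkPolicy()] (rule noise
#' 0.03) and one late-entry drug whose rule activates in 2021. Visits occur
#' every six weeks on average.
#'
#' @param seed generator seed.
#' @param nPatients cohort size (default 300).
#' @return List with elements `histories`, `policy`, `channels`,
#'   `vocabulary`, `spec`.
#' @export
defaultBenchmarkCohort <- function(seed = 1L, nPatients = 300L) {
  spec <- cohortSpec(nPatients = nPatients, startYear = 2020L, years = 3L,
                     seed = seed, visitGapMean = 6, visitGapMin = 2L,
                     driftYear = 2021L)
  policy <- benchmarkPolicy(driftYear = 2021L, noiseRate = 0.03)
  channels <- defaultChannels()
  vocabulary <- benchmarkVocabulary()
  histories <- simulateCohort(spec, policy, channels, vocabulary)
  list(histories = histories, policy = policy, channels = channels,
       vocabulary = vocabulary, spec = spec)
}

#' A noise-free single-rule cohort
#'
#' One numeric channel (HbA1c) and a drug prescribed exactly when the last
#' observed HbA1c before the visit week is at least 7.0; rule noise zero, so
#' the drug set is a deterministic function of the observable history. A
#' second comparator drug is prescribed at every visit with an observed
#' chart, so that every visit anchors a sample and the ruled drug has both
#' classes in any evaluation set.
#'
#' @param seed generator seed.
#' @param nPatients cohort size.
#' @return List with elements `histories`, `policy`, `channels`,
#'   `vocabulary`, `spec`.
#' @export
singleRuleCohort <- function(seed = 1L, nPatients = 160L) {
  channels <- channelSet("hba1c", "numeric", units = "%")
  vocabulary <- drugVocabulary(c("drug_a", "drug_b"))
  policy <- prescriberPolicy(
    list(policyRule("r_a", "hba1c", ">=", 7.0, "drug_a"),
         policyRule("r_base", "hba1c", ">=", 0, "drug_b")), noiseRate = 0)
  spec <- cohortSpec(nPatients = nPatients, startYear = 2021L, years = 2L,
                     seed = seed, visitGapMean = 5, visitGapMin = 2L,
                     labNoise = c(hba1c = 0.1),
                     missingRate = c(hba1c = 0.05))
  histories <- simulateCohort(spec, policy, channels, vocabulary)
  list(histories = histories, policy = policy, channels = channels,
       vocabulary = vocabulary, spec = spec)
}
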