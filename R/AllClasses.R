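#' @import methods
NULL

## ---------------------------------------------------------------- ChannelSet

#' Laboratory channel definitions
#'
#' A `ChannelSet` describes the laboratory panel carried by a cohort: channel
#' names, whether each channel is numeric or categorical, the ordered level
#' labels of categorical channels, and free-text units.
#'
#' @slot name character vector of unique channel identifiers.
#' @slot kind `"numeric"` or `"categorical"`, one per channel.
#' @slot categories list of ordered level labels (empty for numeric channels).
#' @slot units free-text units, one per channel.
#' @export
setClass("ChannelSet",
  representation(name = "character", kind = "character",
                 categories = "list", units = "character"),
  validity = function(object) {
    n <- length(object@name)
    if (anyDuplicated(object@name)) return("channel names must be unique")
    if (length(object@kind) != n || length(object@categories) != n ||
        length(object@units) != n)
      return("slots must have one entry per channel")
    if (!all(object@kind %in% c("numeric", "categorical")))
      return("kind must be 'numeric' or 'categorical'")
    bad <- object@kind == "categorical" &
      vapply(object@categories, length, 1L) == 0L
    if (any(bad)) return("categorical channels need non-empty category levels")
    TRUE
  })

#' Construct a ChannelSet
#'
#' @param name character vector of channel identifiers.
#' @param kind `"numeric"` or `"categorical"` per channel.
#' @param categories list of ordered level labels for categorical channels.
#' @param units optional units per channel.
#' @return A [ChannelSet-class] object.
#' @examples
#' channelSet(c("hba1c", "urine_protein"), c("numeric", "categorical"),
#'            categories = list(character(0), c("-", "+-", "1+", "2+", "3+")))
#' @export
channelSet <- function(name, kind, categories = NULL, units = NULL) {
  n <- length(name)
  if (is.null(categories)) categories <- replicate(n, character(0), simplify = FALSE)
  if (is.null(units)) units <- rep("", n)
  new("ChannelSet", name = as.character(name), kind = as.character(kind),
      categories = categories, units = as.character(units))
}

numericChannels <- function(x) x@name[x@kind == "numeric"]
categoricalChannels <- function(x) x@name[x@kind == "categorical"]
categoryLevels <- function(x, ch) x@categories[[match(ch, x@name)]]

## ------------------------------------------------------------ DrugVocabulary

#' Ordered drug vocabulary
#'
#' The vocabulary fixes the identity and the order of the N drugs; the order
#' defines the unit order of the model's output head. With N drugs the
#' decision space contains all 2^N drug combinations.
#'
#' @slot drugs ordered character vector of unique drug identifiers.
#' @export
setClass("DrugVocabulary", representation(drugs = "character"),
  validity = function(object) {
    if (length(object@drugs) < 1L) return("vocabulary needs at least one drug")
    if (anyDuplicated(object@drugs)) return("drug identifiers must be unique")
    TRUE
  })

#' @param drugs ordered character vector of drug identifiers.
#' @return A [DrugVocabulary-class].
#' @rdname DrugVocabulary-class
#' @export
drugVocabulary <- function(drugs) new("DrugVocabulary", drugs = as.character(drugs))

## ------------------------------------------------------------ PatientHistory

#' All dated observations and prescriptions for one patient
#'
#' Events are stored long: one row per (date, channel, value). Laboratory
#' channels carry the measured value (numeric channels as the printed number,
#' categorical channels as the level label); drug channels carry a
#' prescription flag.
#'
#' @slot patientId patient identifier.
#' @slot sex `"male"` or `"female"`.
#' @slot birthYear year of birth, used to compute age at any date.
#' @slot events data.frame with columns `date` (Date), `channel`, `value`
#'   (character), sorted by date.
#' @export
setClass("PatientHistory",
  representation(patientId = "character", sex = "character",
                 birthYear = "numeric", events = "data.frame"),
  validity = function(object) {
    if (!object@sex %in% c("male", "female")) return("sex must be male/female")
    ev <- object@events
    if (nrow(ev) > 0) {
      if (!all(c("date", "channel", "value") %in% names(ev)))
        return("events need columns date/channel/value")
      if (is.unsorted(ev$date)) return("events must be sorted by date")
      if (any(as.integer(format(ev$date, "%Y")) - object@birthYear < 0))
        return("age at an event would be negative")
    }
    TRUE
  })

#' @param patientId patient identifier.
#' @param sex `"male"` or `"female"`.
#' @param birthYear year of birth.
#' @param events data.frame with columns `date`, `channel`, `value`.
#' @return A [PatientHistory-class].
#' @rdname PatientHistory-class
#' @export
patientHistory <- function(patientId, sex, birthYear, events) {
  events$date <- as.Date(events$date)
  events$value <- as.character(events$value)
  events <- events[order(events$date), c("date", "channel", "value")]
  rownames(events) <- NULL
  new("PatientHistory", patientId = as.character(patientId), sex = sex,
      birthYear = as.numeric(birthYear), events = events)
}

ageAt <- function(history, date) {
  as.integer(format(as.Date(date), "%Y")) - history@birthYear
}

## ------------------------------------------------------------------ GridSpec

#' Weekly grid specification
#'
#' A span of Y years is represented as `ceiling(Y * 365 / 7)` Monday-to-Sunday
#' week slots.
#'
#' @slot years integer number of years Y.
#' @slot weeks slot count, always `ceiling(years * 365 / 7)`.
#' @export
setClass("GridSpec", representation(years = "integer", weeks = "integer"),
  validity = function(object) {
    if (object@years < 1L) return("years must be >= 1")
    if (object@weeks != ceiling(object@years * 365 / 7))
      return("weeks must equal ceiling(years * 365 / 7)")
    TRUE
  })

#' @param years number of years Y (>= 1).
#' @return A [GridSpec-class] with `weeks = ceiling(years * 365 / 7)`.
#' @examples gridSpec(1)@weeks  # 53
#' @rdname GridSpec-class
#' @export
gridSpec <- function(years) {
  years <- as.integer(years)
  new("GridSpec", years = years, weeks = as.integer(ceiling(years * 365 / 7)))
}

## ---------------------------------------------------------------- WeeklyGrid

#' Regular weekly tensor for one observation window
#'
#' Numeric channels hold the within-week arithmetic mean of raw measurements;
#' categorical channels hold the last observed level of the week; drug rows
#' flag any prescription in the week. Missing slots carry `NA` (the reserved
#' non-numeric sentinel) and are flagged in the mask; no value is ever
#' imputed, and model output is invariant to whatever a masked slot stores.
#'
#' @slot numValues numeric matrix, numeric channels x weeks (`NA` = missing).
#' @slot numMask logical matrix, presence indicator per numeric channel/week.
#' @slot catValues integer matrix, categorical channels x weeks; level index
#'   or `NA`.
#' @slot drugHist numeric 0/1 matrix, drugs x weeks.
#' @slot sex 1 = male, 2 = female.
#' @slot age age in years at the end of the window.
#' @slot windowEnd the Sunday the window ends on.
#' @slot channels the [ChannelSet-class] the rows refer to.
#' @slot vocabulary the [DrugVocabulary-class] the drug rows refer to.
#' @export
setClass("WeeklyGrid",
  representation(numValues = "matrix", numMask = "matrix", catValues = "matrix",
                 drugHist = "matrix", sex = "integer", age = "numeric",
                 windowEnd = "Date", channels = "ChannelSet",
                 vocabulary = "DrugVocabulary"),
  validity = function(object) {
    if (any(!object@numMask & !is.na(object@numValues)))
      return("masked numeric slots must hold the NA sentinel")
    if (any(object@numMask & is.na(object@numValues)))
      return("observed numeric slots cannot be NA")
    TRUE
  })

## ----------------------------------------------------------------- SampleSet

#' A set of training/evaluation sample windows
#'
#' Dense container for `extractSamples()` output: one sample per calendar week
#' in which at least one drug was prescribed, anchored at that target week,
#' with the weekly grid of the 52 (by default) preceding weeks as input and
#' the week's drug multi-hot as target. Stored struct-of-arrays so the whole
#' set can be handed to the compiled model in one call.
#'
#' @slot numValues numeric array, channels x weeks x samples (`NA` = missing).
#' @slot numMask numeric 0/1 array of the same shape.
#' @slot catValues numeric array, categorical channels x weeks x samples
#'   (0 = missing, otherwise level index).
#' @slot drugHist numeric 0/1 array, drugs x weeks x samples.
#' @slot sex integer vector (1 = male, 2 = female).
#' @slot age numeric vector, age in years at the end of each input window.
#' @slot target numeric 0/1 matrix, drugs x samples.
#' @slot targetWeek Date vector, the Monday of each target week.
#' @slot patientId character vector.
#' @slot channels,vocabulary the panel and drug vocabulary.
#' @slot windowWeeks input window length in weeks.
#' @export
setClass("SampleSet",
  representation(numValues = "array", numMask = "array", catValues = "array",
                 drugHist = "array", sex = "integer", age = "numeric",
                 target = "matrix", targetWeek = "Date", patientId = "character",
                 channels = "ChannelSet", vocabulary = "DrugVocabulary",
                 windowWeeks = "integer"))

#' One training/evaluation unit
#'
#' @slot grid the input [WeeklyGrid-class] over the weeks preceding the
#'   target week.
#' @slot targetWeek the Monday of the predicted week.
#' @slot target named 0/1 vector over the drug vocabulary (at least one
#'   positive: samples are anchored at prescription events).
#' @export
setClass("SampleWindow",
  representation(grid = "WeeklyGrid", targetWeek = "Date", target = "numeric"),
  validity = function(object) {
    if (sum(object@target) < 1) return("target must contain >= 1 positive drug")
    if (object@grid@windowEnd >= object@targetWeek)
      return("input window must strictly precede the target week")
    TRUE
  })

## ----------------------------------------------------------------- SplitPlan

#' Patient-level train/test split
#'
#' Patients are split between training and testing so that no patient
#' contributes to both sides. Optional calendar periods additionally restrict
#' which target weeks each side may use; when both periods are given they
#' must be disjoint.
#'
#' @slot trainIds,testIds disjoint character vectors of patient ids.
#' @slot trainPeriod,testPeriod integer `c(startYear, endYear)` or
#'   `integer(0)` for no restriction.
#' @slot seed the seed the split was drawn with.
#' @export
setClass("SplitPlan",
  representation(trainIds = "character", testIds = "character",
                 trainPeriod = "integer", testPeriod = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (length(intersect(object@trainIds, object@testIds)) > 0)
      return("train and test patient sets must be disjoint")
    if (length(object@trainPeriod) == 2 && length(object@testPeriod) == 2) {
      if (object@trainPeriod[2] >= object@testPeriod[1] &&
          object@testPeriod[2] >= object@trainPeriod[1])
        return("train and test periods must be disjoint")
    }
    TRUE
  })

## ---------------------------------------------------------------- CohortSpec

#' Synthetic cohort specification
#'
#' @slot nPatients number of patients.
#' @slot startYear first simulated calendar year.
#' @slot years simulated span in years.
#' @slot seed generator seed.
#' @slot visitGapMean mean inter-visit gap in weeks (geometric + minimum).
#' @slot visitGapMin minimum gap in weeks (>= 1 so visits fall in distinct
#'   weeks).
#' @slot labNoise named per-channel measurement noise SD.
#' @slot missingRate named per-channel probability that a visit omits the lab.
#' @slot driftYear calendar year at which late policy rules activate
#'   (`NA` = none).
#' @export
setClass("CohortSpec",
  representation(nPatients = "integer", startYear = "integer", years = "integer",
                 seed = "integer", visitGapMean = "numeric",
                 visitGapMin = "integer", labNoise = "numeric",
                 missingRate = "numeric", driftYear = "integer"),
  validity = function(object) {
    if (object@nPatients < 1L) return("nPatients must be >= 1")
    if (any(object@missingRate < 0 | object@missingRate > 1))
      return("missing rates must lie in [0, 1]")
    if (object@visitGapMin < 1L) return("visitGapMin must be >= 1 week")
    TRUE
  })

#' Construct a CohortSpec
#'
#' @param nPatients,startYear,years,seed cohort size, first calendar year,
#'   span in years and generator seed.
#' @param visitGapMean,visitGapMin inter-visit gap distribution (weeks).
#' @param labNoise,missingRate named per-channel noise SDs and per-visit
#'   missingness probabilities.
#' @param driftYear year at which late policy rules activate, or `NA`.
#' @return A [CohortSpec-class].
#' @export
cohortSpec <- function(nPatients, startYear = 2020L, years = 3L, seed = 1L,
                       visitGapMean = 5, visitGapMin = 2L,
                       labNoise = numeric(0), missingRate = numeric(0),
                       driftYear = NA_integer_) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      startYear = as.integer(startYear), years = as.integer(years),
      seed = as.integer(seed), visitGapMean = visitGapMean,
      visitGapMin = as.integer(visitGapMin), labNoise = labNoise,
      missingRate = missingRate, driftYear = as.integer(driftYear))
}

## ----------------------------------------------------------- PrescriberPolicy

#' Rule-based prescriber policy
#'
#' An ordered list of threshold rules mapping the patient's chart state (the
#' last observed value of each channel strictly before the current week) to a
#' drug set. With `noiseRate = 0` the policy is a deterministic function of
#' that state; otherwise each rule's action is independently suppressed with
#' probability `noiseRate` per visit.
#'
#' Each rule is a list with fields `id`, `channel`, `op` (`">="` or `"<"`; for
#' categorical channels the threshold is a level index), `threshold`, `drugs`
#' (character vector added when the rule fires), and `activeFrom` (calendar
#' year, `NA` = always active).
#'
#' @slot rules ordered list of rules.
#' @slot noiseRate probability in `[0, 1]` that a rule's action is suppressed.
#' @export
setClass("PrescriberPolicy",
  representation(rules = "list", noiseRate = "numeric"),
  validity = function(object) {
    if (object@noiseRate < 0 || object@noiseRate > 1)
      return("noiseRate must lie in [0, 1]")
    need <- c("id", "channel", "op", "threshold", "drugs", "activeFrom")
    for (r in object@rules)
      if (!all(need %in% names(r))) return("rule missing required fields")
    TRUE
  })

#' @param rules ordered list of rules (see class description).
#' @param noiseRate per-visit, per-rule suppression probability.
#' @return A [PrescriberPolicy-class].
#' @rdname PrescriberPolicy-class
#' @export
prescriberPolicy <- function(rules, noiseRate = 0) {
  new("PrescriberPolicy", rules = rules, noiseRate = noiseRate)
}

#' @param id,channel,op,threshold,drugs,activeFrom rule fields.
#' @rdname PrescriberPolicy-class
#' @export
policyRule <- function(id, channel, op, threshold, drugs, activeFrom = NA_integer_) {
  list(id = id, channel = channel, op = op, threshold = threshold,
       drugs = drugs, activeFrom = as.integer(activeFrom))
}

## --------------------------------------------------------------- ModelConfig

#' Transformer architecture configuration
#'
#' The full-scale profile mirrors the reference architecture: hidden width
#' 256, four encoder and four decoder layers with four attention heads, and a
#' 0.5 decision threshold on the per-drug probabilities. The `"desk"` profile
#' is a reduced configuration (hidden 64, 2 + 2 layers) sized for CPU-bound
#' experimentation and the test suite.
#'
#' @slot hidden embedding/hidden width.
#' @slot encoderLayers,decoderLayers layer counts.
#' @slot heads attention heads (must divide `hidden`).
#' @slot ffDim position-wise feed-forward width.
#' @slot windowWeeks input window length (weeks).
#' @slot nDrugs output-head width N (bound to the vocabulary at model
#'   construction; `NA` until then).
#' @slot decisionThreshold probability cutoff for the binary prescription
#'   decision.
#' @slot profile the profile name the config was derived from.
#' @export
setClass("ModelConfig",
  representation(hidden = "integer", encoderLayers = "integer",
                 decoderLayers = "integer", heads = "integer", ffDim = "integer",
                 windowWeeks = "integer", nDrugs = "integer",
                 decisionThreshold = "numeric", profile = "character"),
  validity = function(object) {
    if (object@hidden %% object@heads != 0)
      return("hidden must be divisible by heads")
    if (object@hidden %% 2 != 0)
      return("hidden must be even (sinusoidal positional code pairs)")
    if (object@decisionThreshold <= 0 || object@decisionThreshold >= 1)
      return("decisionThreshold must lie in (0, 1)")
    TRUE
  })

#' @param profile `"paper"` (hidden 256, 4 + 4 layers) or `"desk"`
#'   (hidden 64, 2 + 2 layers).
#' @param hidden,encoderLayers,decoderLayers,heads,ffDim,windowWeeks,nDrugs,decisionThreshold
#'   individual overrides of the profile values.
#' @return A [ModelConfig-class].
#' @examples
#' modelConfig("desk")
#' @rdname ModelConfig-class
#' @export
modelConfig <- function(profile = c("desk", "paper"), hidden = NULL,
                        encoderLayers = NULL, decoderLayers = NULL, heads = NULL,
                        ffDim = NULL, windowWeeks = 52L, nDrugs = NA_integer_,
                        decisionThreshold = 0.5) {
  profile <- match.arg(profile)
  def <- switch(profile,
    paper = list(hidden = 256L, enc = 4L, dec = 4L, heads = 4L, ff = 1024L),
    desk  = list(hidden = 64L,  enc = 2L, dec = 2L, heads = 4L, ff = 128L))
  new("ModelConfig",
      hidden = as.integer(hidden %||% def$hidden),
      encoderLayers = as.integer(encoderLayers %||% def$enc),
      decoderLayers = as.integer(decoderLayers %||% def$dec),
      heads = as.integer(heads %||% def$heads),
      ffDim = as.integer(ffDim %||% def$ff),
      windowWeeks = as.integer(windowWeeks),
      nDrugs = as.integer(nDrugs),
      decisionThreshold = decisionThreshold,
      profile = profile)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --------------------------------------------------------------- TrainConfig

#' Optimization configuration
#'
#' Full-scale defaults follow the reference training recipe (Adam, learning
#' rate 1e-4, batch size 256, 100 epochs). The `"desk"` profile keeps the
#' learning rate but uses smaller batches (32) and desk-scale epoch counts
#' (20 fine-tune; 40 pretrain, chosen so the self-supervised objective
#' approaches the carry-forward baseline) so one CPU suffices.
#'
#' @slot learningRate Adam learning rate.
#' @slot batchSize minibatch size.
#' @slot epochs epoch count.
#' @slot focalGamma focusing exponent of the focal loss.
#' @slot focalAlpha class-balance weight (positive class).
#' @slot alphaWeighting whether the alpha weight is applied.
#' @slot phase `"pretrain"` or `"finetune"`.
#' @slot seed RNG seed for batch order (and any fresh initialization).
#' @slot validationFraction fraction of training patients held out for epoch
#'   checkpoint selection during fine-tuning.
#' @slot freezeEncoder if `TRUE` fine-tuning only updates decoder-side
#'   parameters.
#' @slot beta1,beta2,eps Adam moments/stabilizer.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 epochs = "integer", focalGamma = "numeric",
                 focalAlpha = "numeric", alphaWeighting = "logical",
                 phase = "character", seed = "integer",
                 validationFraction = "numeric", freezeEncoder = "logical",
                 beta1 = "numeric", beta2 = "numeric", eps = "numeric"),
  validity = function(object) {
    if (object@learningRate <= 0) return("learningRate must be > 0")
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@focalGamma < 0) return("focalGamma must be >= 0")
    if (!object@phase %in% c("pretrain", "finetune"))
      return("phase must be pretrain/finetune")
    TRUE
  })

#' @param phase `"pretrain"` or `"finetune"`.
#' @param profile `"desk"` or `"paper"`; sets batch size and epochs.
#' @param learningRate,batchSize,epochs,focalGamma,focalAlpha,alphaWeighting,seed,validationFraction,freezeEncoder
#'   overrides.
#' @return A [TrainConfig-class].
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(phase = c("finetune", "pretrain"),
                        profile = c("desk", "paper"),
                        learningRate = 1e-4, batchSize = NULL, epochs = NULL,
                        focalGamma = 2, focalAlpha = 0.25, alphaWeighting = TRUE,
                        seed = 1L, validationFraction = 0.1,
                        freezeEncoder = FALSE) {
  phase <- match.arg(phase)
  profile <- match.arg(profile)
  def <- switch(profile,
    paper = list(batch = 256L, epochs = 100L),
    desk  = list(batch = 32L, epochs = if (phase == "pretrain") 40L else 20L))
  new("TrainConfig", learningRate = learningRate,
      batchSize = as.integer(batchSize %||% def$batch),
      epochs = as.integer(epochs %||% def$epochs),
      focalGamma = focalGamma, focalAlpha = focalAlpha,
      alphaWeighting = alphaWeighting, phase = phase, seed = as.integer(seed),
      validationFraction = validationFraction, freezeEncoder = freezeEncoder,
      beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

## ------------------------------------------------------------- BootstrapSpec

#' Bootstrap configuration for confidence intervals
#'
#' @slot nResamples number of bootstrap resamples.
#' @slot confidence interval coverage (0.95 for a 95\% CI).
#' @slot resampleUnit `"record"` or `"patient"`.
#' @slot seed RNG seed.
#' @export
setClass("BootstrapSpec",
  representation(nResamples = "integer", confidence = "numeric",
                 resampleUnit = "character", seed = "integer"),
  validity = function(object) {
    if (object@nResamples < 1L) return("nResamples must be >= 1")
    if (object@confidence <= 0 || object@confidence >= 1)
      return("confidence must lie in (0, 1)")
    if (!object@resampleUnit %in% c("record", "patient"))
      return("resampleUnit must be record/patient")
    TRUE
  })

#' @param nResamples,confidence,resampleUnit,seed see slots.
#' @return A [BootstrapSpec-class].
#' @rdname BootstrapSpec-class
#' @export
bootstrapSpec <- function(nResamples = 1000L, confidence = 0.95,
                          resampleUnit = c("record", "patient"), seed = 1L) {
  new("BootstrapSpec", nResamples = as.integer(nResamples),
      confidence = confidence, resampleUnit = match.arg(resampleUnit),
      seed = as.integer(seed))
}

## --------------------------------------------------------------- Seq2SetModel

#' The transformer encoder-decoder model
#'
#' Holds the architecture configuration, the channel panel and drug
#' vocabulary it was built for, and all parameter matrices (including the
#' auxiliary pretraining heads, which the fine-tuning task never uses).
#'
#' @slot config a [ModelConfig-class].
#' @slot channels,vocabulary the data layout the model is bound to.
#' @slot params named list of parameter matrices.
#' @slot pretrained,finetuned training-state flags.
#' @slot history list of per-epoch loss/metric traces accumulated by
#'   [pretrain()] and [finetune()].
#' @export
setClass("Seq2SetModel",
  representation(config = "ModelConfig", channels = "ChannelSet",
                 vocabulary = "DrugVocabulary", params = "list",
                 pretrained = "logical", finetuned = "logical",
                 history = "list"))

#' Encoder output for one sample
#'
#' @slot states matrix of per-position context vectors (positions x hidden);
#'   row 1 is the static sex/age token, rows 2..T+1 the week positions.
#' @slot mask the attention mask actually applied (1 = position attended).
#' @export
setClass("EncoderState", representation(states = "matrix", mask = "numeric"))

#' Per-drug scores and decisions
#'
#' @slot scores named per-drug probabilities in `[0, 1]`.
#' @slot decisions named logicals, `scores >= decisionThreshold`.
#' @slot threshold the decision threshold applied.
#' @export
setClass("DrugScoreVector",
  representation(scores = "numeric", decisions = "logical", threshold = "numeric"),
  validity = function(object) {
    if (any(object@scores < 0 | object@scores > 1))
      return("scores must lie in [0, 1]")
    if (!identical(unname(object@decisions),
                   unname(object@scores >= object@threshold)))
      return("decisions must equal scores >= threshold")
    TRUE
  })

## ------------------------------------------------------------- MetricsReport

#' Evaluation report
#'
#' @slot perDrug data.frame with columns `drug`, `rocAuc`, `accuracy`,
#'   `nPositive` (AUC is `NA` for drugs lacking both classes).
#' @slot microAuc ROC-AUC on the pooled (drug, sample) score/label pairs.
#' @slot macroAuc unweighted mean of per-drug AUCs over computable drugs.
#' @slot excludedDrugs drugs left out of the macro average (no positives or
#'   no negatives in the evaluation set).
#' @slot ci named list of `c(lower, upper)` bootstrap intervals.
#' @slot nSamples,nPatients evaluation set size.
#' @export
setClass("MetricsReport",
  representation(perDrug = "data.frame", microAuc = "numeric",
                 macroAuc = "numeric", excludedDrugs = "character",
                 ci = "list", nSamples = "integer", nPatients = "integer"),
  validity = function(object) {
    aucs <- c(object@microAuc, object@macroAuc,
              object@perDrug$rocAuc[!is.na(object@perDrug$rocAuc)])
    if (any(aucs < 0 | aucs > 1, na.rm = TRUE)) return("AUCs must lie in [0, 1]")
    TRUE
  })

#' Pretraining loss decomposition
#'
#' @slot numeric mean squared error component (observed next-week labs only).
#' @slot categorical focal-loss component (next-week drugs and categorical
#'   labs).
#' @slot total their sum.
#' @export
setClass("LossBreakdown",
  representation(numeric = "numeric", categorical = "numeric", total = "numeric"),
  validity = function(object) {
    if (any(c(object@numeric, object@categorical) < 0))
      return("loss components must be >= 0")
    TRUE
  })
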