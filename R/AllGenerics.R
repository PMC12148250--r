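#' @include AllClasses.R
NULL

#' Drugs in a vocabulary, model or report
#'
#' @param x object carrying a drug vocabulary.
#' @return Character vector of drug identifiers, in output-head order.
#' @export
setGeneric("drugs", function(x) standardGeneric("drugs"))

#' @rdname drugs
#' @export
setMethod("drugs", "DrugVocabulary", function(x) x@drugs)

#' @rdname drugs
#' @export
setMethod("drugs", "Seq2SetModel", function(x) x@vocabulary@drugs)

#' @rdname drugs
#' @export
setMethod("drugs", "SampleSet", function(x) x@vocabulary@drugs)

#' Number of drugs N
#'
#' @param x object carrying a drug vocabulary.
#' @return Integer count.
#' @export
setGeneric("nDrugs", function(x) standardGeneric("nDrugs"))

#' @rdname nDrugs
#' @export
setMethod("nDrugs", "DrugVocabulary", function(x) length(x@drugs))

#' @rdname nDrugs
#' @export
setMethod("nDrugs", "Seq2SetModel", function(x) length(x@vocabulary@drugs))

#' @rdname nDrugs
#' @export
setMethod("nDrugs", "SampleSet", function(x) length(x@vocabulary@drugs))

#' Sample count of a SampleSet
#' @param x a [SampleSet-class].
#' @return Integer number of samples.
#' @export
setMethod("length", "SampleSet", function(x) length(x@age))

#' Subset a SampleSet by sample index
#'
#' @param x a [SampleSet-class].
#' @param i integer or logical index over samples.
#' @param j,...,drop ignored.
#' @return A [SampleSet-class] with the selected samples.
#' @export
setMethod("[", "SampleSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  new("SampleSet",
      numValues = x@numValues[, , i, drop = FALSE],
      numMask = x@numMask[, , i, drop = FALSE],
      catValues = x@catValues[, , i, drop = FALSE],
      drugHist = x@drugHist[, , i, drop = FALSE],
      sex = x@sex[i], age = x@age[i],
      target = x@target[, i, drop = FALSE],
      targetWeek = x@targetWeek[i], patientId = x@patientId[i],
      channels = x@channels, vocabulary = x@vocabulary,
      windowWeeks = x@windowWeeks)
})

#' Patient ids behind a SampleSet
#' @param x a [SampleSet-class].
#' @return Character vector, one entry per sample.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname patientIds
#' @export
setMethod("patientIds", "SampleSet", function(x) x@patientId)

#' Multi-hot targets of a SampleSet
#' @param x a [SampleSet-class].
#' @return 0/1 matrix, drugs x samples.
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname targets
#' @export
setMethod("targets", "SampleSet", function(x) {
  m <- x@target
  rownames(m) <- x@vocabulary@drugs
  m
})

#' Micro-averaged ROC-AUC stored in a report
#' @param x a [MetricsReport-class].
#' @return Numeric scalar.
#' @export
setGeneric("microAvgAuc", function(x) standardGeneric("microAvgAuc"))

#' @rdname microAvgAuc
#' @export
setMethod("microAvgAuc", "MetricsReport", function(x) x@microAuc)

#' Macro-averaged ROC-AUC stored in a report
#' @param x a [MetricsReport-class].
#' @return Numeric scalar.
#' @export
setGeneric("macroAvgAuc", function(x) standardGeneric("macroAvgAuc"))

#' @rdname macroAvgAuc
#' @export
setMethod("macroAvgAuc", "MetricsReport", function(x) x@macroAuc)

#' Per-drug metrics table of a report
#' @param x a [MetricsReport-class].
#' @return data.frame with per-drug ROC-AUC, accuracy and positive counts.
#' @export
setGeneric("perDrugMetrics", function(x) standardGeneric("perDrugMetrics"))

#' @rdname perDrugMetrics
#' @export
setMethod("perDrugMetrics", "MetricsReport", function(x) x@perDrug)

#' Scores slot of a DrugScoreVector
#' @param x a [DrugScoreVector-class].
#' @return Named numeric vector of per-drug probabilities.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname scores
#' @export
setMethod("scores", "DrugScoreVector", function(x) x@scores)

#' Decisions slot of a DrugScoreVector
#' @param x a [DrugScoreVector-class].
#' @return Named logical vector (`scores >= threshold`).
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname decisions
#' @export
setMethod("decisions", "DrugScoreVector", function(x) x@decisions)

## ----------------------------------------------------------------- show

setMethod("show", "ChannelSet", function(object) {
  cat("ChannelSet with", length(object@name), "channels (",
      sum(object@kind == "numeric"), "numeric,",
      sum(object@kind == "categorical"), "categorical )\n")
  cat(" ", paste(object@name, collapse = ", "), "\n")
})

setMethod("show", "DrugVocabulary", function(object) {
  cat("DrugVocabulary with N =", length(object@drugs), "drugs\n")
  cat(" ", paste(object@drugs, collapse = ", "), "\n")
})

setMethod("show", "PatientHistory", function(object) {
  cat("PatientHistory", object@patientId, "(", object@sex,
      ", born", object@birthYear, "):", nrow(object@events), "events")
  if (nrow(object@events) > 0)
    cat(" from", format(min(object@events$date)), "to",
        format(max(object@events$date)))
  cat("\n")
})

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", object@years, "year(s) ->", object@weeks, "weekly slots\n")
})

setMethod("show", "WeeklyGrid", function(object) {
  cat("WeeklyGrid:", ncol(object@numValues), "weeks ending",
      format(object@windowEnd), "\n")
  cat("  observed numeric slots:", sum(object@numMask), "/",
      length(object@numMask), "\n")
})

setMethod("show", "SampleSet", function(object) {
  cat("SampleSet:", length(object), "samples from",
      length(unique(object@patientId)), "patients;",
      object@windowWeeks, "week windows;",
      nDrugs(object), "drugs\n")
})

setMethod("show", "SplitPlan", function(object) {
  fmtp <- function(p) if (length(p) == 2) paste(p, collapse = "-") else "unrestricted"
  cat("SplitPlan:", length(object@trainIds), "train /",
      length(object@testIds), "test patients\n")
  cat("  train period:", fmtp(object@trainPeriod),
      "| test period:", fmtp(object@testPeriod), "\n")
})

setMethod("show", "Seq2SetModel", function(object) {
  cfg <- object@config
  cat("Seq2SetModel (", cfg@profile, "profile ): hidden", cfg@hidden, ",",
      cfg@encoderLayers, "+", cfg@decoderLayers, "layers,", cfg@heads,
      "heads\n")
  cat("  channels:", length(object@channels@name), "| drugs:",
      nDrugs(object), "| window:", cfg@windowWeeks, "weeks\n")
  cat("  pretrained:", object@pretrained, "| finetuned:", object@finetuned, "\n")
})

setMethod("show", "DrugScoreVector", function(object) {
  cat("DrugScoreVector over", length(object@scores), "drugs; positives:",
      sum(object@decisions), "(threshold", object@threshold, ")\n")
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", object@nSamples, "samples /", object@nPatients,
      "patients\n")
  cat(sprintf("  micro ROC-AUC: %.4f | macro ROC-AUC: %.4f\n",
              object@microAuc, object@macroAuc))
  if (length(object@excludedDrugs))
    cat("  excluded from macro:", paste(object@excludedDrugs, collapse = ", "), "\n")
})

setMethod("show", "LossBreakdown", function(object) {
  cat(sprintf("LossBreakdown: numeric %.5f + categorical %.5f = %.5f\n",
              object@numeric, object@categorical, object@total))
})
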