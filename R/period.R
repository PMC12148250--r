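#' @include AllClasses.R train.R evaluate.R split.R
NULL

#' Training-period experiment
#'
#' Trains one model per candidate training period on the same patient-level
#' split and evaluates every model on the same fixed test period, to measure
#' how the recency and length of the training window affect performance
#' (e.g. whether a model trained only on recent prescribing patterns tracks
#' a late-introduced drug better than one trained on a longer history).
#'
#' @param histories list of [PatientHistory-class].
#' @param periods list of `c(startYear, endYear)` training periods.
#' @param testPeriod `c(startYear, endYear)` evaluation period.
#' @param channels,vocabulary cohort layout.
#' @param config a [ModelConfig-class].
#' @param pretrainConfig,finetuneConfig [TrainConfig-class] objects (set
#'   `pretrainConfig = NULL` to skip pretraining).
#' @param families model families to run: `"transformer"` and/or
#'   `"xgboost"`.
#' @param trainFraction,seed patient-level split parameters.
#' @return data.frame with one row per (period, family): micro/macro AUC and
#'   evaluation-set size. Attribute `reports` holds the full
#'   [MetricsReport-class] per row.
#' @export
runPeriodExperiment <- function(histories, periods, testPeriod,
                                channels, vocabulary,
                                config = modelConfig("desk"),
                                pretrainConfig = trainConfig("pretrain"),
                                finetuneConfig = trainConfig("finetune"),
                                families = c("transformer", "xgboost"),
                                trainFraction = 0.8, seed = 1L) {
  families <- match.arg(families, several.ok = TRUE)
  samples <- extractSamples(histories, channels, vocabulary,
                            config@windowWeeks)
  plan <- splitCohort(histories, trainFraction, seed)
  yr <- as.integer(format(samples@targetWeek, "%Y"))
  isTest <- samples@patientId %in% plan@testIds &
    yr >= testPeriod[1] & yr <= testPeriod[2]
  testSamples <- samples[isTest]
  if (length(testSamples) == 0) stop("empty test subset")

  rows <- list(); reports <- list(); keys <- character(0)
  for (p in periods) {
    sel <- samples@patientId %in% plan@trainIds & yr >= p[1] & yr <= p[2]
    trainSamples <- samples[sel]
    if (length(trainSamples) == 0)
      stop("empty training subset for period ", paste(p, collapse = "-"))
    label <- paste(p, collapse = "-")
    if ("transformer" %in% families) {
      model <- seq2setModel(channels, vocabulary, config, seed = seed)
      if (!is.null(pretrainConfig))
        model <- pretrain(model, trainSamples, pretrainConfig)
      model <- finetune(model, trainSamples, finetuneConfig)
      rep <- evaluateModel(model, testSamples)
      keys <- c(keys, paste(label, "transformer"))
      rows[[length(rows) + 1L]] <-
        data.frame(period = label, family = "transformer",
                   microAuc = rep@microAuc, macroAuc = rep@macroAuc,
                   nTrain = length(trainSamples), nTest = length(testSamples))
      reports[[length(reports) + 1L]] <- rep
    }
    if ("xgboost" %in% families) {
      ref <- fitReferenceModel(trainSamples, testSamples, seed = seed)
      keys <- c(keys, paste(label, "xgboost"))
      rows[[length(rows) + 1L]] <-
        data.frame(period = label, family = "xgboost",
                   microAuc = ref$report@microAuc,
                   macroAuc = ref$report@macroAuc,
                   nTrain = length(trainSamples), nTest = length(testSamples))
      reports[[length(reports) + 1L]] <- ref$report
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  names(reports) <- make.unique(keys)   # duplicate periods stay addressable
  attr(out, "reports") <- reports
  out
}
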