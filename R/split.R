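#' @include AllClasses.R
NULL

#' Patient-level cohort split
#'
#' Randomly assigns patients to training or testing so that no patient's
#' records appear on both sides. Optional calendar periods restrict which
#' target weeks each side may contribute (see [filterSamples()]); the
#' reference design pairs a patient-level 80/20 split with temporally
#' disjoint training and test periods.
#'
#' @param histories list of [PatientHistory-class] (or a character vector of
#'   patient ids).
#' @param trainFraction fraction of patients assigned to training (0 < f < 1);
#'   the training side receives `floor(n * trainFraction)` patients, e.g.
#'   5627 of 7034 at 0.8.
#' @param seed RNG seed; identical inputs and seed give an identical plan.
#' @param trainPeriod,testPeriod optional `c(startYear, endYear)`; when both
#'   are given they must be disjoint.
#' @return A [SplitPlan-class].
#' @export
splitCohort <- function(histories, trainFraction = 0.8, seed = 1L,
                        trainPeriod = NULL, testPeriod = NULL) {
  ids <- if (is.character(histories)) histories
         else vapply(histories, function(h) h@patientId, "")
  if (anyDuplicated(ids)) stop("duplicate patient ids")
  n <- length(ids)
  if (n < 2L) stop("cohort must contain at least 2 patients")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  nTrain <- max(1L, min(n - 1L, as.integer(floor(n * trainFraction))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trainIds <- sort(sample(ids, nTrain))
  new("SplitPlan", trainIds = trainIds, testIds = sort(setdiff(ids, trainIds)),
      trainPeriod = as.integer(trainPeriod %||% integer(0)),
      testPeriod = as.integer(testPeriod %||% integer(0)),
      seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Select the samples belonging to one side of a split
#'
#' Keeps the samples of the side's patients and, when the side carries a
#' period restriction, only target weeks whose calendar year falls inside it.
#'
#' @param samples a [SampleSet-class].
#' @param plan a [SplitPlan-class].
#' @param side `"train"` or `"test"`.
#' @return A [SampleSet-class].
#' @export
filterSamples <- function(samples, plan, side = c("train", "test")) {
  side <- match.arg(side)
  ids <- if (side == "train") plan@trainIds else plan@testIds
  period <- if (side == "train") plan@trainPeriod else plan@testPeriod
  keep <- samples@patientId %in% ids
  if (length(period) == 2) {
    yr <- as.integer(format(samples@targetWeek, "%Y"))
    keep <- keep & yr >= period[1] & yr <= period[2]
  }
  samples[keep]
}

#' Serialize / read a SplitPlan as JSON
#'
#' @param plan a [SplitPlan-class].
#' @param path output / input file.
#' @return `readSplitPlan` returns the [SplitPlan-class];
#'   `writeSplitPlan` returns `path` invisibly.
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(list(
    train_patient_ids = plan@trainIds, test_patient_ids = plan@testIds,
    train_period = plan@trainPeriod, test_period = plan@testPeriod,
    seed = plan@seed), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SplitPlan", trainIds = as.character(x$train_patient_ids),
      testIds = as.character(x$test_patient_ids),
      trainPeriod = as.integer(x$train_period),
      testPeriod = as.integer(x$test_period), seed = as.integer(x$seed))
}
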