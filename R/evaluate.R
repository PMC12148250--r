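#' @include AllClasses.R model.R
NULL

#' Rank-based ROC-AUC
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, with ties counted half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`; `NA` with a warning when only one class is
#'   present (the AUC is undefined there).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length")
  labels <- as.integer(labels > 0.5)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("ROC-AUC undefined: labels contain a single class")
    return(NA_real_)
  }
  r <- rank(scores)  # average ranks implement the tie-half convention
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Micro-averaged ROC-AUC
#'
#' Pools all (drug, sample) score/label pairs into one multiset and computes
#' a single rank-based AUC over it, weighting every prediction equally
#' regardless of drug.
#'
#' @param scores samples x drugs score matrix (or vector).
#' @param labels 0/1 matrix of the same shape.
#' @return AUC of the pooled pairs.
#' @export
microAuc <- function(scores, labels) {
  rocAuc(as.numeric(scores), as.numeric(labels))
}

#' Macro-averaged ROC-AUC
#'
#' Computes a per-drug AUC and averages them with equal weight per drug.
#' Drugs lacking both classes in the evaluation set have no defined AUC;
#' they are excluded from the mean and reported in the `excluded` attribute.
#'
#' @param scores samples x drugs score matrix.
#' @param labels 0/1 matrix of the same shape.
#' @return Unweighted mean of the computable per-drug AUCs, with attributes
#'   `perDrug` (named vector) and `excluded` (drug names). Errors if no drug
#'   has a computable AUC.
#' @export
macroAuc <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  per <- vapply(seq_len(ncol(scores)), function(j)
    suppressWarnings(rocAuc(scores[, j], labels[, j])), 1)
  names(per) <- colnames(scores)
  if (all(is.na(per))) stop("no drug has both classes: macro AUC undefined")
  out <- mean(per, na.rm = TRUE)
  attr(out, "perDrug") <- per
  attr(out, "excluded") <- names(per)[is.na(per)]
  out
}

#' Per-drug accuracy
#'
#' Fraction of samples whose binary decision matches the label, per drug.
#'
#' @param decisions logical/0-1 matrix, samples x drugs.
#' @param labels 0/1 matrix of the same shape.
#' @return Named numeric vector of per-drug accuracies.
#' @export
perDrugAccuracy <- function(decisions, labels) {
  decisions <- as.matrix(decisions) > 0.5
  labels <- as.matrix(labels) > 0.5
  acc <- colMeans(decisions == labels)
  names(acc) <- colnames(labels)
  acc
}

#' Percentile bootstrap confidence interval
#'
#' Resamples `data` rows with replacement (at record or patient granularity),
#' evaluates `metricFn` on each resample, and returns the percentile interval
#' at `(1 - confidence)/2` and `(1 + confidence)/2`. Resamples on which the
#' metric is undefined (`NA`) are redrawn; the redraw count is attached as an
#' attribute.
#'
#' @param metricFn function taking a data.frame and returning a scalar.
#' @param data data.frame of records; patient-level resampling requires a
#'   `patient_id` column.
#' @param spec a [BootstrapSpec-class].
#' @return `c(lower, upper)` with attributes `estimate` (point estimate on
#'   the full data) and `redraws`.
#' @export
bootstrapCi <- function(metricFn, data, spec = bootstrapSpec()) {
  est <- metricFn(data)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec@seed)
  pats <- if (spec@resampleUnit == "patient") {
    if (is.null(data$patient_id)) stop("patient resampling needs patient_id")
    split(seq_len(nrow(data)), data$patient_id)
  } else NULL
  vals <- numeric(spec@nResamples)
  redraws <- 0L
  for (b in seq_len(spec@nResamples)) {
    for (try in 1:100) {
      idx <- if (is.null(pats)) {
        sample.int(nrow(data), replace = TRUE)
      } else {
        unlist(pats[sample.int(length(pats), replace = TRUE)], use.names = FALSE)
      }
      v <- suppressWarnings(metricFn(data[idx, , drop = FALSE]))
      if (!is.na(v)) break
      redraws <- redraws + 1L
    }
    if (is.na(v)) stop("metric undefined on 100 consecutive resamples")
    vals[b] <- v
  }
  a <- (1 - spec@confidence) / 2
  ci <- unname(stats::quantile(vals, c(a, 1 - a)))
  attr(ci, "estimate") <- est
  attr(ci, "redraws") <- redraws
  ci
}

#' Evaluate a score matrix against multi-hot targets
#'
#' @param scores samples x drugs probability matrix.
#' @param target drugs x samples 0/1 matrix (as stored in a
#'   [SampleSet-class]).
#' @param patientId per-sample patient ids.
#' @param threshold decision threshold for the accuracy columns.
#' @param bootstrap optional [BootstrapSpec-class]; adds percentile CIs for
#'   the micro and macro AUC.
#' @return A [MetricsReport-class].
#' @export
evaluateScores <- function(scores, target, patientId,
                           threshold = 0.5, bootstrap = NULL) {
  labels <- t(target)
  colnames(labels) <- colnames(scores)
  mac <- macroAuc(scores, labels)
  per <- attr(mac, "perDrug")
  acc <- perDrugAccuracy(scores >= threshold, labels)
  report <- new("MetricsReport",
    perDrug = data.frame(drug = colnames(scores), rocAuc = unname(per),
                         accuracy = unname(acc),
                         nPositive = unname(colSums(labels)),
                         row.names = NULL),
    microAuc = microAuc(scores, labels), macroAuc = as.numeric(mac),
    excludedDrugs = attr(mac, "excluded"), ci = list(),
    nSamples = nrow(scores), nPatients = length(unique(patientId)))
  if (!is.null(bootstrap)) {
    df <- data.frame(i = seq_len(nrow(scores)), patient_id = patientId)
    report@ci <- list(
      microAuc = bootstrapCi(function(d)
        microAuc(scores[d$i, , drop = FALSE], labels[d$i, , drop = FALSE]),
        df, bootstrap),
      macroAuc = bootstrapCi(function(d)
        as.numeric(suppressWarnings(
          macroAuc(scores[d$i, , drop = FALSE], labels[d$i, , drop = FALSE]))),
        df, bootstrap))
  }
  report
}

#' Evaluate a model on a sample set
#'
#' Scores the samples and reports per-drug ROC-AUC and accuracy, micro- and
#' macro-averaged ROC-AUC, and (optionally) bootstrap confidence intervals.
#'
#' @param model a [Seq2SetModel-class].
#' @param samples a [SampleSet-class].
#' @param bootstrap optional [BootstrapSpec-class].
#' @return A [MetricsReport-class].
#' @export
evaluateModel <- function(model, samples, bootstrap = NULL) {
  sc <- predictScores(model, samples)
  evaluateScores(sc, samples@target, samples@patientId,
                 model@config@decisionThreshold, bootstrap)
}

## ------------------------------------------------- gradient-boosted baseline

#' Flatten sample windows into baseline features
#'
#' Per numeric channel: last observed value, window mean and observation
#' count; per categorical channel: last observed level index; per drug:
#' prescription-week count; plus sex and age.
#'
#' @param samples a [SampleSet-class].
#' @return Numeric feature matrix, samples x features (`NA` = never
#'   observed).
#' @export
flattenFeatures <- function(samples) {
  n <- length(samples)
  numCh <- numericChannels(samples@channels)
  catCh <- categoricalChannels(samples@channels)
  lastObs <- function(vals, mask) {
    vapply(seq_len(n), function(i) {
      w <- which(mask[, i] > 0.5)
      if (length(w)) vals[w[length(w)], i] else NA_real_
    }, 1)
  }
  cols <- list(sex = as.numeric(samples@sex), age = samples@age)
  for (ci in seq_along(numCh)) {
    vals <- matrix(samples@numValues[ci, , ], ncol = n)
    mask <- matrix(samples@numMask[ci, , ], ncol = n)
    vm <- vals; vm[mask < 0.5] <- NA
    cols[[paste0(numCh[ci], "_last")]] <- lastObs(vals, mask)
    cols[[paste0(numCh[ci], "_mean")]] <- suppressWarnings(colMeans(vm, na.rm = TRUE))
    cols[[paste0(numCh[ci], "_n")]] <- colSums(mask)
  }
  for (ci in seq_along(catCh)) {
    vals <- matrix(samples@catValues[ci, , ], ncol = n)
    cols[[paste0(catCh[ci], "_last")]] <- lastObs(vals, (vals > 0) * 1)
  }
  dn <- drugs(samples)
  for (j in seq_along(dn))
    cols[[paste0("rx_", dn[j])]] <- colSums(matrix(samples@drugHist[j, , ],
                                                   ncol = n))
  m <- do.call(cbind, cols)
  m[is.nan(m)] <- NA
  m
}

#' Gradient-boosted reference model
#'
#' One-vs-rest gradient-boosted trees (xgboost) per drug on the flattened
#' window features, evaluated on the same splits as the transformer for
#' side-by-side comparison. Drugs without a positive training sample receive
#' a constant score of 0 (recorded in the report's excluded attribute as
#' applicable).
#'
#' @param trainSamples,testSamples [SampleSet-class] splits.
#' @param nrounds,maxDepth,eta boosting parameters.
#' @param threshold decision threshold for accuracies.
#' @param bootstrap optional [BootstrapSpec-class].
#' @param seed RNG seed passed to the booster.
#' @return List with `scores` (test samples x drugs) and `report`
#'   (a [MetricsReport-class]).
#' @export
fitReferenceModel <- function(trainSamples, testSamples, nrounds = 150L,
                              maxDepth = 4L, eta = 0.1, threshold = 0.5,
                              bootstrap = NULL, seed = 1L) {
  xtr <- flattenFeatures(trainSamples)
  xte <- flattenFeatures(testSamples)
  dn <- drugs(trainSamples)
  sc <- matrix(0, nrow(xte), length(dn), dimnames = list(NULL, dn))
  constantDrugs <- character(0)
  for (j in seq_along(dn)) {
    y <- trainSamples@target[j, ]
    if (sum(y) == 0) {
      constantDrugs <- c(constantDrugs, dn[j])
      next
    }
    if (sum(y) == length(y)) {
      sc[, j] <- 1
      constantDrugs <- c(constantDrugs, dn[j])
      next
    }
    booster <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = maxDepth,
                    eta = eta, nthread = 1L, seed = seed),
      data = xgboost::xgb.DMatrix(xtr, label = y, nthread = 1L),
      nrounds = nrounds, verbose = 0)
    sc[, j] <- stats::predict(booster, xgboost::xgb.DMatrix(xte, nthread = 1L))
  }
  if (length(constantDrugs))
    message("constant scores for drugs without both training classes: ",
            paste(constantDrugs, collapse = ", "))
  report <- evaluateScores(sc, testSamples@target, testSamples@patientId,
                           threshold, bootstrap)
  list(scores = sc, report = report)
}

#' Serialize a MetricsReport
#'
#' @param report a [MetricsReport-class].
#' @param path output file; `writeMetricsReport` writes JSON,
#'   `writeMetricsCsv` a per-drug CSV table.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(list(
    micro_auc = report@microAuc, macro_auc = report@macroAuc,
    excluded_drugs = report@excludedDrugs,
    ci = lapply(report@ci, function(x) c(lower = x[1], upper = x[2])),
    n_samples = report@nSamples, n_patients = report@nPatients,
    per_drug = report@perDrug), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname writeMetricsReport
#' @export
writeMetricsCsv <- function(report, path) {
  data.table::fwrite(report@perDrug, path)
  invisible(path)
}
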