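test_that("rank-based ROC-AUC matches hand-computed cases", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(pairAuc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(rocAuc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAuc(rep(0.4, 10), c(rep(1, 4), rep(0, 6))), 0.5)  # all ties
  expect_warning(a <- rocAuc(c(0.2, 0.9), c(1, 1)), "single class")
  expect_true(is.na(a))
  expect_error(rocAuc(1:3, 1:2), "equal length")
})

test_that("rank formulation equals the pairwise oracle on random instances", {
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(4:50, 1)
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # many ties
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_identical(rocAuc(sc, lb), pairAuc(sc, lb))
  }
})

test_that("micro average pools all (drug, sample) pairs", {
  sc <- cbind(a = c(0.9, 0.2, 0.6), b = c(0.1, 0.8, 0.4))
  lb <- cbind(a = c(1, 0, 1), b = c(0, 1, 0))
  # single drug: pooling is the identity
  expect_equal(microAuc(sc[, 1, drop = FALSE], lb[, 1, drop = FALSE]),
               rocAuc(sc[, 1], lb[, 1]))
  # two drugs: equals the pairwise oracle on the concatenation
  expect_equal(microAuc(sc, lb), pairAuc(as.numeric(sc), as.numeric(lb)))
  # label-independent scores stay near 0.5 (permutation null, 3 SEs)
  set.seed(7)
  n <- 4000
  sc2 <- runif(n); lb2 <- rbinom(n, 1, 0.3)
  n1 <- sum(lb2); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(microAuc(sc2, lb2) - 0.5), 3 * se)
})

test_that("macro average weights drugs equally and reports exclusions", {
  sc <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.4, 0.4, 0.4, 0.4))
  lb <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  m <- macroAuc(sc, lb)
  expect_equal(as.numeric(m), (1.0 + 0.5) / 2)   # mean of per-drug AUCs
  # identical data per drug: macro equals micro
  sc2 <- cbind(a = c(0.9, 0.1), b = c(0.9, 0.1))
  lb2 <- cbind(a = c(1, 0), b = c(1, 0))
  expect_equal(as.numeric(macroAuc(sc2, lb2)), microAuc(sc2, lb2))
  # a drug with one class is excluded and named
  lb3 <- cbind(a = c(1, 1, 0, 0), b = rep(1, 4))
  m3 <- macroAuc(sc, lb3)
  expect_equal(as.numeric(m3), 1.0)
  expect_identical(attr(m3, "excluded"), "b")
  expect_error(macroAuc(sc[, 1, drop = FALSE],
                        cbind(a = rep(1, 4))), "macro AUC undefined")
})

test_that("macro equals the mean of independently recomputed per-drug AUCs", {
  set.seed(12)
  sc <- matrix(runif(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  lb <- matrix(rbinom(200, 1, 0.4), 50, 4, dimnames = list(NULL, letters[1:4]))
  m <- macroAuc(sc, lb)
  oracle <- mean(vapply(1:4, function(j) pairAuc(sc[, j], lb[, j]), 1))
  expect_equal(as.numeric(m), oracle)
})

test_that("per-drug accuracy is the fraction of matching decisions", {
  dec <- cbind(a = c(TRUE, TRUE, FALSE), b = c(FALSE, FALSE, FALSE))
  lb <- cbind(a = c(1, 1, 0), b = c(1, 0, 0))
  acc <- perDrugAccuracy(dec, lb)
  expect_equal(unname(acc), c(1, 2 / 3))
  # all-negative decisions on a drug with 10% positives score 0.9
  lb2 <- cbind(a = c(rep(1, 1), rep(0, 9)))
  expect_equal(unname(perDrugAccuracy(matrix(FALSE, 10, 1), lb2)), 0.9)
  # brute-force recount on random data
  set.seed(3)
  d <- matrix(runif(60) > 0.5, 20, 3); l <- matrix(rbinom(60, 1, 0.5), 20, 3)
  expect_equal(unname(perDrugAccuracy(d, l)),
               vapply(1:3, function(j) sum(d[, j] == (l[, j] > 0)) / 20, 1))
})

test_that("bootstrap intervals are seeded, ordered and honest about redraws", {
  set.seed(40)
  df <- data.frame(x = rnorm(40), patient_id = rep(sprintf("P%d", 1:8), 5))
  spec <- bootstrapSpec(nResamples = 200, seed = 4)
  ci1 <- bootstrapCi(function(d) mean(d$x), df, spec)
  ci2 <- bootstrapCi(function(d) mean(d$x), df, spec)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  expect_gte(attr(ci1, "estimate"), ci1[1])
  expect_lte(attr(ci1, "estimate"), ci1[2])
  # constant metric: zero-width interval at the constant
  ci3 <- bootstrapCi(function(d) 0.7, df, spec)
  expect_equal(as.numeric(ci3), c(0.7, 0.7))
  # patient-level resampling requires the id column
  expect_error(bootstrapCi(function(d) mean(d$x), data.frame(x = 1:5),
                           bootstrapSpec(10, resampleUnit = "patient")),
               "patient_id")
  cip <- bootstrapCi(function(d) mean(d$x), df,
                     bootstrapSpec(50, resampleUnit = "patient", seed = 2))
  expect_lte(cip[1], cip[2])
  # undefined resamples are redrawn and counted
  flaky <- function(d) if (nrow(d) %% 2 == 0 && d$x[1] > 0) NA_real_ else mean(d$x)
  ci4 <- bootstrapCi(flaky, df, spec)
  expect_gte(attr(ci4, "redraws"), 0)
})

test_that("evaluateScores assembles a coherent report", {
  set.seed(5)
  sc <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  tgt <- t(matrix(rbinom(60, 1, 0.4), 20, 3))
  rep <- evaluateScores(sc, tgt, rep(sprintf("P%d", 1:4), 5),
                        bootstrap = bootstrapSpec(50, seed = 3))
  expect_s4_class(rep, "MetricsReport")
  expect_equal(rep@nSamples, 20L)
  expect_equal(rep@nPatients, 4L)
  expect_equal(rep@perDrug$drug, c("a", "b", "c"))
  expect_equal(rep@perDrug$nPositive, unname(rowSums(tgt)))
  expect_equal(rep@microAuc, microAuc(sc, t(tgt)))
  expect_length(rep@ci$microAuc, 2)
  # threshold consistency: reported accuracy equals scores >= 0.5 recount
  expect_equal(rep@perDrug$accuracy,
               unname(colMeans((sc >= 0.5) == (t(tgt) > 0.5))))
})

test_that("the gradient-boosted reference mirrors the report interface", {
  co <- singleRuleCohort(seed = 13, nPatients = 30)
  s <- extractSamples(co$histories, co$channels, co$vocabulary, 52)
  plan <- splitCohort(co$histories, 0.8, seed = 13)
  tr <- filterSamples(s, plan, "train"); te <- filterSamples(s, plan, "test")
  X <- flattenFeatures(tr)
  expect_equal(nrow(X), length(tr))   # one feature row per sample
  expect_true(all(c("sex", "age", "hba1c_last", "hba1c_mean", "hba1c_n",
                    "rx_drug_a", "rx_drug_b") %in% colnames(X)))
  ref <- suppressMessages(fitReferenceModel(tr, te, nrounds = 40, seed = 1))
  expect_s4_class(ref$report, "MetricsReport")
  expect_equal(dim(ref$scores), c(length(te), 2L))
  expect_identical(ref$report@perDrug$drug, drugs(te))
  # the single-rule label is a threshold on one feature: trees recover it
  expect_gt(ref$report@perDrug$rocAuc[1], 0.95)
})
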