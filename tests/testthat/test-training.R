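test_that("focal loss reproduces its closed-form scalar cases", {
  # gamma 0, no alpha weighting: plain cross-entropy
  expect_equal(focalLoss(0.5, 1, gamma = 0, alphaWeighting = FALSE), log(2),
               tolerance = 1e-12)
  # perfect prediction drives the loss to zero
  expect_lt(focalLoss(1 - 1e-9, 1, gamma = 2, alphaWeighting = FALSE), 1e-6)
  # gamma 2, p = 0.9, positive target: (1 - 0.9)^2 * (-log 0.9)
  expect_equal(focalLoss(0.9, 1, gamma = 2, alphaWeighting = FALSE),
               0.1^2 * -log(0.9), tolerance = 1e-6)
  expect_equal(0.1^2 * -log(0.9), 0.001054, tolerance = 1e-3)
})

test_that("focal loss with gamma 0 equals binary cross-entropy exactly", {
  set.seed(10)
  p <- runif(500, 0.001, 0.999)
  y <- rbinom(500, 1, 0.3)
  bce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  expect_equal(focalLoss(p, y, gamma = 0, alphaWeighting = FALSE), bce,
               tolerance = 1e-12)
})

test_that("probabilities at 0 and 1 are clamped, not infinite", {
  expect_true(is.finite(focalLoss(c(0, 1), c(1, 0), gamma = 2)))
  expect_error(focalLoss(0.5, c(1, 0)), "same shape")
  expect_error(focalLoss(0.5, 1, gamma = -1), "gamma")
})

co <- singleRuleCohort(seed = 21, nPatients = 12)
s21 <- extractSamples(co$histories, co$channels, co$vocabulary, 52)
tiny <- function(seed = 2) seq2setModel(
  co$channels, co$vocabulary,
  modelConfig("desk", hidden = 16, encoderLayers = 1, decoderLayers = 1,
              heads = 2, ffDim = 32), seed = seed)

test_that("pretraining moves encoder parameters and is seed-deterministic", {
  m0 <- tiny()
  m1 <- pretrain(m0, s21, trainConfig("pretrain", epochs = 2, seed = 5))
  expect_true(m1@pretrained)
  expect_false(identical(m1@params$enc1_Wq, m0@params$enc1_Wq))
  expect_false(identical(m1@params$num_w, m0@params$num_w))
  m2 <- pretrain(m0, s21, trainConfig("pretrain", epochs = 2, seed = 5))
  expect_identical(m1@history$pretrain, m2@history$pretrain)
  expect_identical(m1@params, m2@params)
  expect_error(pretrain(m0, s21[integer(0)]), "empty")
})

test_that("pretraining loss ignores unobserved targets entirely", {
  m <- tiny()
  m@params$num_scale <- matrix(2, 1)   # fixed scale so losses are comparable
  lb1 <- pretrainLoss(m, s21)
  s2 <- s21
  nv <- s2@numValues
  nv[s2@numMask < 0.5] <- 123.4   # junk under the mask
  slot(s2, "numValues", check = FALSE) <- nv
  lb2 <- pretrainLoss(m, s2)
  expect_identical(lb1@numeric, lb2@numeric)
  expect_identical(lb1@categorical, lb2@categorical)
  expect_identical(lb1@total, lb2@total)
  expect_gte(lb1@numeric, 0)
  expect_gte(lb1@categorical, 0)
})

test_that("pretraining beats the carry-forward baseline under noisy labs", {
  # high measurement noise: predicting the next observation rewards
  # smoothing over the history rather than copying the last value
  channels <- channelSet("hba1c", "numeric")
  vocab <- drugVocabulary(c("drug_a", "drug_b"))
  policy <- prescriberPolicy(
    list(policyRule("r_a", "hba1c", ">=", 7, "drug_a"),
         policyRule("r_b", "hba1c", ">=", 0, "drug_b")), noiseRate = 0)
  spec <- cohortSpec(nPatients = 60, startYear = 2021, years = 2, seed = 31,
                     visitGapMean = 4, visitGapMin = 1,
                     labNoise = c(hba1c = 1.0), missingRate = c(hba1c = 0.05))
  hs <- simulateCohort(spec, policy, channels, vocab)
  s <- extractSamples(hs, channels, vocab, 52)
  # carry-forward baseline on the standardized scale the loss uses
  v <- s@numValues[1, , ]; mk <- s@numMask[1, , ]
  sq <- 0; n <- 0
  for (i in seq_len(ncol(v))) {
    w <- which(mk[, i] > 0.5)
    if (length(w) >= 2) { d <- diff(v[w, i]); sq <- sq + sum(d^2); n <- n + length(d) }
  }
  baseline <- sq / n / stats::var(v[mk > 0.5])
  m <- tiny(seed = 4)
  m <- pretrain(m, s, trainConfig("pretrain", epochs = 30, seed = 4))
  expect_lt(tail(m@history$pretrain$numeric, 1), baseline)
})

test_that("fine-tuning reduces the focal loss and checkpoints by validation AUC", {
  m <- tiny()
  m <- finetune(m, s21, trainConfig("finetune", epochs = 8, batchSize = 16,
                                    seed = 6))
  expect_true(m@finetuned)
  tr <- m@history$finetune
  expect_lt(tr$loss[8], tr$loss[1])
  expect_true(all(tr$valAuc >= 0 & tr$valAuc <= 1, na.rm = TRUE))
  expect_true(m@history$bestEpoch %in% 1:8)
  # determinism of the whole loss trace
  m2 <- finetune(tiny(), s21, trainConfig("finetune", epochs = 8,
                                          batchSize = 16, seed = 6))
  expect_identical(tr, m2@history$finetune)
  expect_error(finetune(tiny(), s21, trainConfig("pretrain")), "phase")
})

test_that("fine-tuning works with and without pretraining", {
  mA <- finetune(tiny(), s21, trainConfig("finetune", epochs = 2, seed = 7))
  mB <- finetune(pretrain(tiny(), s21, trainConfig("pretrain", epochs = 2,
                                                   seed = 7)),
                 s21, trainConfig("finetune", epochs = 2, seed = 7))
  expect_s4_class(mA, "Seq2SetModel")
  expect_true(mB@pretrained && mB@finetuned)
  expect_false(identical(predictScores(mA, s21), predictScores(mB, s21)))
})

test_that("freezing the encoder leaves encoder-side parameters untouched", {
  m0 <- tiny()
  m <- finetune(m0, s21, trainConfig("finetune", epochs = 2, seed = 8,
                                     freezeEncoder = TRUE,
                                     validationFraction = 0))
  expect_identical(m@params$enc1_Wq, m0@params$enc1_Wq)
  expect_identical(m@params$drug_emb, m0@params$drug_emb)
  expect_false(identical(m@params$out_W, m0@params$out_W))
})

test_that("model checkpoints survive a save/load round trip", {
  m <- finetune(tiny(), s21, trainConfig("finetune", epochs = 2, seed = 9,
                                         validationFraction = 0))
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  back <- loadModel(path)
  expect_identical(back@params, m@params)
  expect_identical(predictScores(back, s21), predictScores(m, s21))
  suppressWarnings(expect_error(loadModel(withr::local_tempfile(fileext = ".rds"))))
})
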