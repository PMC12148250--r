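mdl <- tinyModel()

test_that("positional codes follow the sinusoidal closed form", {
  pe <- positionalEncoding(0:5, 16)
  expect_equal(pe[1, seq(1, 15, 2)], rep(0, 8))   # sin(0)
  expect_equal(pe[1, seq(2, 16, 2)], rep(1, 8))   # cos(0)
  expect_identical(positionalEncoding(3, 16), positionalEncoding(3, 16))
  # each frequency component repeats with its own period
  d <- 16
  for (i in 0:(d / 2 - 1)) {
    period <- 2 * pi * 10000^(2 * i / d)
    a <- positionalEncoding(2, d)
    b <- positionalEncoding(2 + period, d)
    expect_equal(a[1, 2 * i + 1:2], b[1, 2 * i + 1:2], tolerance = 1e-6)
  }
  expect_error(positionalEncoding(0, 15), "even")
})

test_that("embedding emits hidden-width tokens and masks empty weeks", {
  g <- randomGrid(1)
  emb <- embedInputs(mdl, g)
  expect_equal(dim(emb$tokens), c(53L, 16L))
  expect_length(emb$mask, 53L)
  expect_equal(emb$mask[1], 1)   # static token always attended
  observed <- colSums(g@numMask) + colSums(!is.na(g@catValues)) +
    colSums(g@drugHist)
  expect_equal(emb$mask[-1], as.numeric(observed > 0))
})

test_that("tokens are invariant to values stored at masked slots", {
  g <- randomGrid(2)
  emb1 <- embedInputs(mdl, g)
  g2 <- g
  nv <- g2@numValues
  nv[!g2@numMask] <- 1e6             # arbitrary finite junk under the mask
  slot(g2, "numValues", check = FALSE) <- nv  # bypass the sentinel validity
  emb2 <- embedInputs(mdl, g2)
  expect_identical(emb1$tokens, emb2$tokens)
  expect_identical(emb1$mask, emb2$mask)
})

test_that("encoder ignores masked positions and normalizes attention", {
  g <- randomGrid(3)
  st <- encodeGrid(mdl, g)
  expect_s4_class(st, "EncoderState")
  expect_equal(dim(st@states), c(53L, 16L))
  # direct token-level encode exposes the attention weights
  emb <- embedInputs(mdl, g)
  out <- rxformer:::cpp_encode_tokens(mdl@params, emb$tokens, emb$mask,
                                      rxformer:::modelCfgList(mdl),
                                      FALSE, TRUE)
  for (lw in out$attention) for (P in lw) {
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
    expect_true(all(P[, emb$mask == 0] == 0))  # zero weight on masked keys
  }
  # a single unmasked position: its context depends on that token alone
  mask1 <- c(1, rep(0, 52))
  o1 <- rxformer:::cpp_encode_tokens(mdl@params, emb$tokens, mask1,
                                     rxformer:::modelCfgList(mdl), FALSE, FALSE)
  tok2 <- emb$tokens; tok2[10, ] <- 99
  o2 <- rxformer:::cpp_encode_tokens(mdl@params, tok2, mask1,
                                     rxformer:::modelCfgList(mdl), FALSE, FALSE)
  expect_identical(o1$states[1, ], o2$states[1, ])
  # all-masked input is an explicit error
  expect_error(rxformer:::cpp_encode_tokens(mdl@params, emb$tokens,
                                            rep(0, 53),
                                            rxformer:::modelCfgList(mdl),
                                            FALSE, FALSE),
               "masked")
})

test_that("decoder yields N probabilities thresholded at the configured cutoff", {
  g <- randomGrid(4)
  st <- encodeGrid(mdl, g)
  dsv <- decodeScores(mdl, st, g)
  expect_length(scores(dsv), 3)
  expect_true(all(scores(dsv) >= 0 & scores(dsv) <= 1))
  expect_identical(unname(decisions(dsv)), unname(scores(dsv) >= 0.5))
  # zero-initialized output layer scores exactly 0.5 everywhere
  expect_equal(unname(scores(dsv)), rep(0.5, 3))
  expect_error(new("DrugScoreVector", scores = c(0.51, 0.49),
                   decisions = c(FALSE, FALSE), threshold = 0.5), "decisions")
  ok <- new("DrugScoreVector", scores = c(0.51, 0.49),
            decisions = c(TRUE, FALSE), threshold = 0.5)
  expect_identical(unname(decisions(ok)), c(TRUE, FALSE))
})

test_that("scoring is deterministic and the head imposes no exclusivity", {
  co <- singleRuleCohort(seed = 2, nPatients = 10)
  s <- extractSamples(co$histories, co$channels, co$vocabulary, 52)
  m <- seq2setModel(co$channels, co$vocabulary,
                    modelConfig("desk", hidden = 16, encoderLayers = 1,
                                decoderLayers = 1, heads = 2, ffDim = 32),
                    seed = 3)
  m <- finetune(m, s, trainConfig("finetune", epochs = 30, batchSize = 8,
                                  seed = 3, validationFraction = 0))
  sc1 <- predictScores(m, s)
  sc2 <- predictScores(m, s)
  expect_identical(sc1, sc2)
  # both drugs are prescribed together throughout, so a trained model emits
  # two simultaneous positives: the 2^N combination space is unconstrained
  expect_true(any(rowSums(sc1 >= 0.5) == 2))
})

test_that("drug embeddings are exported per drug at hidden width", {
  emb <- extractDrugEmbeddings(mdl)
  expect_equal(dim(emb), c(3L, 16L))
  expect_identical(rownames(emb), c("a", "b", "c"))
  expect_identical(emb, {
    e <- mdl@params$drug_emb; rownames(e) <- c("a", "b", "c"); e
  })  # untrained model: embeddings equal their initialization
  proj <- projectDrugEmbeddings(emb, "pca")
  expect_equal(dim(proj), c(3L, 2L))
  proj2 <- projectDrugEmbeddings(emb, "mds")
  expect_equal(dim(proj2), c(3L, 2L))
})

test_that("backpropagation matches central finite differences", {
  co <- singleRuleCohort(seed = 5, nPatients = 6)
  s <- extractSamples(co$histories, co$channels, co$vocabulary, 52)
  m <- seq2setModel(co$channels, co$vocabulary,
                    modelConfig("desk", hidden = 8, encoderLayers = 1,
                                decoderLayers = 1, heads = 2, ffDim = 16),
                    seed = 1)
  p <- m@params
  set.seed(2)
  p$out_W <- matrix(rnorm(length(p$out_W), 0, 0.1), nrow(p$out_W))
  tens <- rxformer:::sampleTensors(s[1:3])
  cl <- rxformer:::modelCfgList(m)
  for (mode in c("finetune", "pretrain")) {
    g <- rxformer:::cpp_grad(p, tens, cl, 1:3, mode, 2, 0.25, TRUE)
    lossAt <- function(pp)
      rxformer:::cpp_grad(pp, tens, cl, 1:3, mode, 2, 0.25, TRUE)$loss
    set.seed(3)
    for (nm in sample(setdiff(names(p), c("pe", "num_scale", "num_mu")), 12)) {
      i <- sample(length(p[[nm]]), 1)
      h <- 1e-6
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + h; lp <- lossAt(pp)
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] - h; lm <- lossAt(pp)
      fd <- (lp - lm) / (2 * h)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})
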