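#' @include AllClasses.R tensors.R positional.R
NULL

#' Construct and initialize a Seq2SetModel
#'
#' Builds the transformer encoder-decoder for a given laboratory panel and
#' drug vocabulary. Each data type gets its own embedding: per-channel linear
#' maps for numeric labs, lookup tables for categorical labs and sex, a
#' shared drug-embedding table summed over the week's multi-hot prescription
#' vector, and a linear age embedding carried by a static token. Week tokens
#' receive the fixed sinusoidal positional code; the decoder holds a single
#' learned query combined with the target week's positional code and the
#' static sex/age embedding. The output layer is zero-initialized, so an
#' untrained model scores every drug at exactly 0.5.
#'
#' @param channels a [ChannelSet-class].
#' @param vocabulary a [DrugVocabulary-class].
#' @param config a [ModelConfig-class]; its `nDrugs` is bound to the
#'   vocabulary here.
#' @param seed RNG seed for weight initialization.
#' @return A [Seq2SetModel-class].
#' @export
seq2setModel <- function(channels, vocabulary, config = modelConfig("desk"),
                         seed = 1L) {
  config@nDrugs <- length(vocabulary@drugs)
  d <- config@hidden
  Tn <- config@windowWeeks
  Cn <- sum(channels@kind == "numeric")
  Cc <- sum(channels@kind == "categorical")
  N <- config@nDrugs
  Ks <- vapply(channels@categories[channels@kind == "categorical"], length, 1L)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  gauss <- function(r, c, sd = 0.02) matrix(stats::rnorm(r * c, 0, sd), r, c)
  xavier <- function(fi, fo) {
    lim <- sqrt(6 / (fi + fo))
    matrix(stats::runif(fi * fo, -lim, lim), fi, fo)
  }
  zeros <- function(r, c) matrix(0, r, c)
  ones <- function(r, c) matrix(1, r, c)

  p <- list(
    num_w = gauss(d, max(Cn, 1))[, seq_len(Cn), drop = FALSE],
    num_b = gauss(d, max(Cn, 1))[, seq_len(Cn), drop = FALSE],
    drug_emb = gauss(N, d),
    sex_emb = gauss(2, d),
    age_w = gauss(1, d, 0.005), age_b = zeros(1, d),
    query = gauss(1, d),
    pe = positionalEncoding(0:(Tn + 1), d),
    num_scale = ones(1, max(Cn, 1))[, seq_len(Cn), drop = FALSE],
    num_mu = zeros(1, max(Cn, 1))[, seq_len(Cn), drop = FALSE],
    out_W = zeros(d, N), out_b = zeros(1, N),
    aux_reg_W = gauss(d, max(Cn, 1))[, seq_len(Cn), drop = FALSE],
    aux_reg_b = zeros(1, max(Cn, 1))[, seq_len(Cn), drop = FALSE],
    aux_drug_W = gauss(d, N), aux_drug_b = zeros(1, N),
    dec_lnf_g = ones(1, d), dec_lnf_b = zeros(1, d),
    enc_lnf_g = ones(1, d), enc_lnf_b = zeros(1, d))
  for (ci in seq_len(Cc)) {
    p[[paste0("cat", ci, "_emb")]] <- gauss(Ks[ci], d)
    p[[paste0("aux_cat", ci, "_W")]] <- gauss(d, Ks[ci])
    p[[paste0("aux_cat", ci, "_b")]] <- zeros(1, Ks[ci])
  }
  block <- function(pre, d, ff) {
    b <- list()
    for (w in c("Wq", "Wk", "Wv", "Wo")) b[[paste0(pre, w)]] <- xavier(d, d)
    for (w in c("bq", "bk", "bv", "bo")) b[[paste0(pre, w)]] <- zeros(1, d)
    b[[paste0(pre, "ln1_g")]] <- ones(1, d); b[[paste0(pre, "ln1_b")]] <- zeros(1, d)
    b[[paste0(pre, "ln2_g")]] <- ones(1, d); b[[paste0(pre, "ln2_b")]] <- zeros(1, d)
    b[[paste0(pre, "W1")]] <- xavier(d, ff); b[[paste0(pre, "b1")]] <- zeros(1, ff)
    b[[paste0(pre, "W2")]] <- xavier(ff, d); b[[paste0(pre, "b2")]] <- zeros(1, d)
    b
  }
  for (l in seq_len(config@encoderLayers))
    p <- c(p, block(paste0("enc", l, "_"), d, config@ffDim))
  for (l in seq_len(config@decoderLayers))
    p <- c(p, block(paste0("dec", l, "_"), d, config@ffDim))

  new("Seq2SetModel", config = config, channels = channels,
      vocabulary = vocabulary, params = p, pretrained = FALSE,
      finetuned = FALSE, history = list())
}

#' Embed a weekly grid into model tokens
#'
#' Applies the per-data-type embedding layers and the positional code,
#' yielding one token per week plus a leading static sex/age token, together
#' with the attention mask that flags fully missing weeks. Masked slots are
#' never read, so the token sequence is invariant to the sentinel stored
#' there.
#'
#' @param model a [Seq2SetModel-class].
#' @param grid a [WeeklyGrid-class] matching the model's panel.
#' @return List with elements `tokens` ((weeks + 1) x hidden matrix) and
#'   `mask` (0/1 vector; position 1 is the always-attended static token).
#' @export
embedInputs <- function(model, grid) {
  .checkGrid(model, grid)
  out <- cpp_embed(model@params, gridTensors(grid), modelCfgList(model), 1L)
  list(tokens = out$tokens, mask = as.numeric(out$mask))
}

#' Run the encoder over a weekly grid
#'
#' Stacked masked self-attention blocks; positions flagged missing receive
#' zero attention weight everywhere, so their stored values cannot influence
#' any output.
#'
#' @param model a [Seq2SetModel-class].
#' @param grid a [WeeklyGrid-class].
#' @param causal use causal (autoregressive) masking, as in pretraining.
#' @return An [EncoderState-class].
#' @export
encodeGrid <- function(model, grid, causal = FALSE) {
  .checkGrid(model, grid)
  out <- cpp_encode(model@params, gridTensors(grid), modelCfgList(model), 1L,
                    causal)
  new("EncoderState", states = out$states, mask = as.numeric(out$mask))
}

#' Decode per-drug scores from an encoder state
#'
#' The learned decoder query (combined with the target-week positional code
#' and the sex/age embedding) cross-attends to the encoder state; the N-unit
#' output head applies a sigmoid per drug, yielding independent probabilities
#' thresholded into binary prescription decisions.
#'
#' @param model a [Seq2SetModel-class].
#' @param state an [EncoderState-class].
#' @param grid the [WeeklyGrid-class] the state came from (supplies sex/age).
#' @return A [DrugScoreVector-class].
#' @export
decodeScores <- function(model, state, grid) {
  out <- cpp_decode(model@params, gridTensors(grid), modelCfgList(model), 1L,
                    state@states, state@mask)
  sc <- as.numeric(out$scores)
  names(sc) <- model@vocabulary@drugs
  thr <- model@config@decisionThreshold
  new("DrugScoreVector", scores = sc, decisions = sc >= thr, threshold = thr)
}

#' Score a sample set
#'
#' @param model a [Seq2SetModel-class].
#' @param samples a [SampleSet-class].
#' @return Numeric matrix, samples x drugs, of per-drug probabilities.
#' @export
predictScores <- function(model, samples) {
  .checkCompatible(model, samples)
  if (length(samples) == 0) stop("empty sample set")
  sc <- cpp_score(model@params, sampleTensors(samples), modelCfgList(model))
  colnames(sc) <- model@vocabulary@drugs
  sc
}

.checkGrid <- function(model, grid) {
  if (!identical(model@channels@name, grid@channels@name))
    stop("grid and model use different channel panels")
  if (!identical(model@vocabulary@drugs, grid@vocabulary@drugs))
    stop("grid and model use different drug vocabularies")
  if (ncol(grid@numValues) != model@config@windowWeeks)
    stop("grid week count does not match the model configuration")
}

#' Extract the learned drug-embedding table
#'
#' Returns the shared drug-embedding rows (width = hidden dimension), keyed
#' by drug id, for inspection or 2D projection.
#'
#' @param model a [Seq2SetModel-class].
#' @return Numeric matrix, drugs x hidden.
#' @export
extractDrugEmbeddings <- function(model) {
  emb <- model@params$drug_emb
  rownames(emb) <- model@vocabulary@drugs
  emb
}

#' Project drug embeddings to two dimensions
#'
#' Delegates to classical projection methods (principal components or
#' classical multidimensional scaling); the package only owns the embedding
#' export.
#'
#' @param embeddings matrix from [extractDrugEmbeddings()].
#' @param method `"pca"` or `"mds"`.
#' @return Matrix, drugs x 2.
#' @export
projectDrugEmbeddings <- function(embeddings, method = c("pca", "mds")) {
  method <- match.arg(method)
  out <- switch(method,
    pca = stats::prcomp(embeddings, center = TRUE)$x[, 1:2, drop = FALSE],
    mds = stats::cmdscale(stats::dist(embeddings), k = 2))
  rownames(out) <- rownames(embeddings)
  colnames(out) <- c("dim1", "dim2")
  out
}

#' Export drug embeddings as CSV
#'
#' @param model a [Seq2SetModel-class].
#' @param path output CSV (`drug_id`, `v1` ... `v_hidden`).
#' @return `path`, invisibly.
#' @export
writeDrugEmbeddings <- function(model, path) {
  emb <- extractDrugEmbeddings(model)
  df <- data.frame(drug_id = rownames(emb), emb, row.names = NULL)
  names(df)[-1] <- paste0("v", seq_len(ncol(emb)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full configuration, channel panel, vocabulary and
#' training history alongside the parameters.
#'
#' @param model a [Seq2SetModel-class].
#' @param path checkpoint file.
#' @return `loadModel` returns the [Seq2SetModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "Seq2SetModel")) stop("not a Seq2SetModel checkpoint")
  model
}
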