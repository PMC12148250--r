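#' @include AllClasses.R model.R tensors.R
NULL

#' Focal loss
#'
#' Mean over elements of `-alpha_t (1 - p_t)^gamma log(p_t)`, where `p_t` is
#' the predicted probability of the true class and `alpha_t` the
#' class-balance weight (`alpha` for positives, `1 - alpha` for negatives).
#' With `gamma = 0` and alpha weighting disabled this is exactly binary
#' cross-entropy. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the
#' logarithm.
#'
#' @param probabilities predicted probabilities in (0, 1).
#' @param targets binary targets of the same shape.
#' @param gamma focusing exponent (>= 0); default 2.
#' @param alpha positive-class weight; default 0.25.
#' @param alphaWeighting apply the alpha weight (`FALSE` gives unweighted
#'   focal loss).
#' @return Scalar mean loss.
#' @examples
#' focalLoss(0.5, 1, gamma = 0, alphaWeighting = FALSE)  # log(2)
#' @export
focalLoss <- function(probabilities, targets, gamma = 2, alpha = 0.25,
                      alphaWeighting = TRUE) {
  if (length(probabilities) != length(targets))
    stop("probabilities and targets must have the same shape")
  if (gamma < 0) stop("gamma must be >= 0")
  pt <- ifelse(targets > 0.5, probabilities, 1 - probabilities)
  pt <- pmin(pmax(pt, 1e-7), 1 - 1e-7)
  at <- if (alphaWeighting) ifelse(targets > 0.5, alpha, 1 - alpha) else 1
  mean(-at * (1 - pt)^gamma * log(pt))
}

.trainTcfg <- function(config, mode, perm, val) {
  list(mode = mode, lr = config@learningRate, beta1 = config@beta1,
       beta2 = config@beta2, eps = config@eps, epochs = config@epochs,
       batch = config@batchSize, gamma = config@focalGamma,
       alpha = config@focalAlpha, alpha_on = config@alphaWeighting,
       freeze_encoder = config@freezeEncoder, perm = perm, val = val)
}

.permMatrix <- function(idx, epochs, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  matrix(vapply(seq_len(epochs), function(e) sample(idx), integer(length(idx))),
         ncol = epochs)
}

#' Self-supervised pretraining
#'
#' Optimizes the encoder (and embeddings) on the task of predicting the next
#' week from the past: auxiliary per-channel regression heads predict week
#' t+1 laboratory values (mean squared error on standardized residuals,
#' restricted to observed targets) and auxiliary classification heads predict
#' week t+1 drug sets and categorical levels (focal loss), under causal
#' attention masking so position t sees only weeks up to t. The auxiliary
#' heads are not used by the fine-tuned prediction task.
#'
#' @param model a [Seq2SetModel-class].
#' @param samples a [SampleSet-class] of training windows.
#' @param config a [TrainConfig-class] with `phase = "pretrain"`.
#' @return The updated model; `model@history$pretrain` holds the per-epoch
#'   loss trace.
#' @export
pretrain <- function(model, samples, config = trainConfig("pretrain")) {
  .checkCompatible(model, samples)
  if (length(samples) == 0) stop("empty sample set")
  if (config@phase != "pretrain") stop("config phase must be 'pretrain'")
  # per-channel mean/SD for the standardized regression targets, frozen
  # into the model (inputs themselves stay raw)
  Cn <- sum(model@channels@kind == "numeric")
  if (Cn > 0) {
    st <- vapply(seq_len(Cn), function(ci) {
      v <- samples@numValues[ci, , ][samples@numMask[ci, , ] > 0.5]
      s <- stats::sd(v)
      c(if (length(v)) mean(v) else 0, if (!is.finite(s) || s < 1e-3) 1 else s)
    }, numeric(2))
    model@params$num_mu <- matrix(st[1, ], 1)
    model@params$num_scale <- matrix(st[2, ], 1)
  }
  perm <- .permMatrix(seq_len(length(samples)), config@epochs, config@seed)
  out <- cpp_train(model@params, sampleTensors(samples), modelCfgList(model),
                   .trainTcfg(config, "pretrain", perm, integer(0)))
  model@params <- out$params
  model@pretrained <- TRUE
  model@history$pretrain <- data.frame(
    epoch = seq_len(config@epochs), numeric = out$numeric_loss,
    categorical = out$categorical_loss,
    total = out$numeric_loss + out$categorical_loss)
  model
}

#' Supervised fine-tuning
#'
#' Optimizes the full model (decoder cross-attention included, unless
#' `freezeEncoder`) with the focal loss on the target-week drug multi-hot.
#' A patient-level validation slice of the training samples
#' (`validationFraction`) selects the checkpoint epoch by micro-averaged
#' ROC-AUC.
#'
#' @param model a [Seq2SetModel-class] (optionally pretrained).
#' @param samples a [SampleSet-class] of training windows.
#' @param config a [TrainConfig-class] with `phase = "finetune"`.
#' @return The updated model; `model@history$finetune` holds the loss and
#'   validation-AUC traces and the selected epoch.
#' @export
finetune <- function(model, samples, config = trainConfig("finetune")) {
  .checkCompatible(model, samples)
  if (length(samples) == 0) stop("empty sample set")
  if (config@phase != "finetune") stop("config phase must be 'finetune'")

  pats <- unique(samples@patientId)
  valIdx <- integer(0)
  trainIdx <- seq_len(length(samples))
  if (config@validationFraction > 0 && length(pats) >= 5) {
    old <- .Random.seed_save()
    set.seed(config@seed + 1L)
    nv <- max(1L, floor(length(pats) * config@validationFraction))
    valPats <- sample(pats, nv)
    .Random.seed_restore(old)
    valIdx <- which(samples@patientId %in% valPats)
    trainIdx <- setdiff(trainIdx, valIdx)
  }
  perm <- .permMatrix(trainIdx, config@epochs, config@seed)
  out <- cpp_train(model@params, sampleTensors(samples), modelCfgList(model),
                   .trainTcfg(config, "finetune", perm, as.integer(valIdx)))
  model@params <- out$params
  model@finetuned <- TRUE
  model@history$finetune <- data.frame(
    epoch = seq_len(config@epochs), loss = out$loss,
    valAuc = if (length(out$val_auc)) out$val_auc else NA_real_)
  model@history$bestEpoch <- out$best_epoch
  model
}

#' Pretraining loss of a model on a sample set
#'
#' Evaluates the self-supervised objective without updating parameters.
#' Unobserved targets contribute nothing: altering values at masked slots
#' leaves the breakdown unchanged.
#'
#' @param model a [Seq2SetModel-class].
#' @param samples a [SampleSet-class].
#' @param config a [TrainConfig-class] supplying the focal parameters.
#' @return A [LossBreakdown-class].
#' @export
pretrainLoss <- function(model, samples, config = trainConfig("pretrain")) {
  .checkCompatible(model, samples)
  if (length(samples) == 0) stop("empty sample set")
  out <- cpp_grad(model@params, sampleTensors(samples), modelCfgList(model),
                  seq_len(length(samples)), "pretrain", config@focalGamma,
                  config@focalAlpha, config@alphaWeighting)
  new("LossBreakdown", numeric = out$numeric, categorical = out$categorical,
      total = out$numeric + out$categorical)
}
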