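#' @include AllClasses.R gridding.R
NULL

## Bridge between the S4 containers and the compiled model core: dense
## arrays, 0/1 masks, and the per-week attention mask (a week is attended
## iff anything at all was observed in it).

sampleTensors <- function(set) {
  nm <- set@numMask
  cv <- set@catValues
  dh <- set@drugHist
  obs <- colSums(nm, dims = 1) + colSums(cv > 0, dims = 1) +
    colSums(dh > 0.5, dims = 1)
  if (length(dim(obs)) != 2) obs <- matrix(obs, nrow = set@windowWeeks)
  list(numv = unname(set@numValues), numm = unname(nm),
       catv = unname(cv), drugs = unname(dh),
       weekmask = (obs > 0) * 1,
       sex = as.numeric(set@sex), age = as.numeric(set@age),
       target = unname(set@target))
}

## WeeklyGrid -> single-sample tensor list (target all-zero placeholder)
gridTensors <- function(grid) {
  nv <- grid@numValues
  nm <- grid@numMask * 1
  cv <- grid@catValues
  cv[is.na(cv)] <- 0L
  dh <- grid@drugHist
  T <- ncol(nv)
  obs <- colSums(nm) + colSums(cv > 0) + colSums(dh > 0.5)
  list(numv = array(unname(nv), c(nrow(nv), T, 1)),
       numm = array(unname(nm), c(nrow(nm), T, 1)),
       catv = array(unname(cv), c(nrow(cv), T, 1)),
       drugs = array(unname(dh), c(nrow(dh), T, 1)),
       weekmask = matrix((obs > 0) * 1, T, 1),
       sex = as.numeric(grid@sex), age = as.numeric(grid@age),
       target = matrix(0, nrow(dh), 1))
}

modelCfgList <- function(model) {
  ch <- model@channels
  list(hidden = model@config@hidden, heads = model@config@heads,
       encoderLayers = model@config@encoderLayers,
       decoderLayers = model@config@decoderLayers,
       ffDim = model@config@ffDim, windowWeeks = model@config@windowWeeks,
       nNumeric = sum(ch@kind == "numeric"),
       nCategorical = sum(ch@kind == "categorical"),
       nDrugs = model@config@nDrugs,
       catLevels = vapply(ch@categories[ch@kind == "categorical"], length, 1L))
}

.checkCompatible <- function(model, set) {
  if (!identical(model@channels@name, set@channels@name))
    stop("sample set and model use different channel panels")
  if (!identical(model@vocabulary@drugs, set@vocabulary@drugs))
    stop("sample set and model use different drug vocabularies")
  if (set@windowWeeks != model@config@windowWeeks)
    stop("sample window length does not match the model configuration")
}
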