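---
title: "Predicting next-prescribed drug sets from irregular EHR series: models and methods"
author: "rxformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting next-prescribed drug sets from irregular EHR series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Outpatients with diabetes accumulate irregularly spaced electronic-health-record
(EHR) events: laboratory panels measured at some visits and not others,
prescriptions issued at a subset of visits, and static demographics. The task
addressed here is *next-prescription drug-set prediction*: given one year of a
patient's history (labs, prior drugs, age, sex), emit a probability for each of
N drugs that it will be prescribed at the next prescription event. With N drugs
the decision space contains all 2^N combinations, so the problem is treated as
N simultaneous binary classifications rather than a single multiclass choice —
the output head places no mutual-exclusion constraint on the drugs.

## Data model: weekly quantization and the attention mask

Irregular event streams are quantized to Monday–Sunday weeks. A span of Y years
becomes `ceiling(Y * 365 / 7)` weekly slots; within a week, numeric laboratory
channels take the arithmetic mean of that week's measurements, categorical
channels take the week's *last* observed level (averaging level labels is
undefined), and each drug channel flags whether the drug was prescribed at
least once. Weeks with no observation of a channel are *missing*: they carry a
reserved non-numeric sentinel (`NA`) and a mask bit, and nothing is ever
imputed. No normalization, interpolation, outlier removal, or dimensionality
reduction is applied to the inputs; a z-score option exists for completeness
but is off by default and unused everywhere in this package.

Missingness is consumed by the model as an *attention mask*: a week in which
nothing at all was observed is excluded from every attention computation, so
the value stored in a masked slot cannot influence any output. This is tested
end to end: perturbing masked slots with arbitrary finite junk leaves all
scores bit-identical.

Prediction samples are anchored at prescription events: one sample per calendar
week in which at least one drug was prescribed, provided at least one earlier
week of history exists. The input is the weekly grid of the 52 complete weeks
strictly before the target week — the target week's own same-day labs are
excluded, resolving an ambiguity in "the past one year" in favor of a strictly
causal window. The target is the multi-hot vector of all drugs prescribed in
the target week.

## Architecture

The model is a transformer encoder–decoder operating on one token per week
plus one static token:

* **Embeddings.** Each data type has its own embedding: a per-channel linear
  map (`value * w_c + b_c`) for numeric labs, lookup tables for categorical
  labs and sex, a shared drug-embedding table summed over the week's multi-hot
  prescription vector, and a linear age embedding. All channel embeddings of a
  week are summed into a single composite token (keeping the sequence at 52
  positions); an alternative channel-per-token layout was considered and
  rejected for its 12-fold sequence-length cost. Sex and age form a static
  token prepended to the sequence *and* are added to the decoder query; how the static covariates enter a
  sequence model is an open choice, and supplying them on both sides lets
  either pathway be used.
* **Positional code.** The fixed sinusoidal code
  `sin/cos(p / 10000^(2i/d))` is added to week tokens; it is deterministic and
  parameter-free.
* **Encoder.** Stacked pre-norm self-attention blocks (masked as above;
  bidirectional during fine-tuning, causal during pretraining) followed by a
  position-wise feed-forward network (ReLU). Pre-norm was chosen over post-norm
  for optimization stability at small batch counts.
* **Decoder.** A single learned query token, combined with the target week's
  positional code and the static sex/age embedding, cross-attends to the
  encoder states through stacked blocks. Self-attention over a single query
  token is a degenerate linear map, so decoder blocks contain cross-attention
  and feed-forward sublayers only. The output layer has N sigmoid units —
  independent per-drug probabilities — thresholded at 0.5 into prescription
  decisions. The output layer is zero-initialized, so an untrained model
  scores every drug at exactly 0.5.
* **Profiles.** The full-scale profile is hidden width 256 with four encoder
  and four decoder layers and four heads; the `"desk"` profile (hidden 64,
  2 + 2 layers, four heads, feed-forward width 128) is the configuration used
  throughout the test suite and the benchmark, sized for a single CPU.

Drug-history embeddings and the output head are deliberately *untied*; the
embedding table is exportable per drug for inspection and 2D projection
(delegated to classical PCA/MDS — the package owns only the export surface).

## Training

Training is two-phase, both phases using Adam (learning rate 1e-4, β =
0.9/0.999) without dropout or weight decay; determinism was preferred over
regularization at these scales, and all randomness (initialization, batch
order, validation slice) derives from user-supplied seeds.

**Self-supervised pretraining** optimizes the encoder and embeddings under
causal masking on targets derived from the data itself: from each observed
week position, predict each numeric channel's *next observed* value, each
categorical channel's next observed level, and the drug set of the next visit
week. Two points deserve emphasis:

* *Next observed, not next week.* With realistic inter-visit gaps of weeks to
  months, the literally adjacent week is almost always empty; a literal t+1
  target makes the numeric objective vacuous and teaches the drug head to
  predict the empty set. Predicting the next *observation* restores the
  intended task.
* *Standardized regression targets.* Raw laboratory scales differ by two
  orders of magnitude (HbA1c ≈ 7, glucose ≈ 150). The regression heads
  therefore predict `(y - mean_c) / sd_c`, with per-channel statistics
  computed from the training samples and frozen into the checkpoint. At a
  desk-scale Adam budget a raw-scale head cannot even traverse the distance
  to a channel's mean, leaving the objective unconverged. The *inputs* remain
  raw.

The numeric loss is mean squared error restricted to observed targets;
unobserved targets contribute exactly nothing. Drug and categorical targets
use the focal loss. The desk pretraining length (40 epochs) was chosen so the
numeric objective approaches the carry-forward baseline (predict next = last
observed), which is the point of the phase: an encoder that can reproduce the
chart state at every position. The auxiliary heads are discarded by the
fine-tuned task.

**Supervised fine-tuning** optimizes the full model (a freeze-encoder switch exists,
default off, for experiments that restrict the supervised phase to the
decoder side) with the focal loss on the target
multi-hot,

&nbsp;&nbsp;&nbsp;&nbsp;`FL(p_t) = -alpha_t (1 - p_t)^gamma log(p_t)`,

with the loss's original recommended settings γ = 2 and α = 0.25, both
exposed in `trainConfig()`. With γ = 0 and alpha weighting off the
implementation reduces to binary cross-entropy to machine precision, which the
suite asserts. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before
logarithms. A patient-level slice of 10% of the training patients is held out
each run; the checkpoint is the epoch with the best validation micro ROC-AUC.
Full-scale defaults are batch 256 / 100 epochs; the desk profile uses batch 32
(≈ 150 updates per epoch on the benchmark) and 20 epochs.

## The synthetic cohort generator

No hospital data ships with this package; a seeded generator provides cohorts
whose ground truth is known by construction. Each patient carries four latent
disease axes (glycemia, lipids, renal, liver), each a mean-reverting random
walk at weekly resolution (reversion 0.03/week toward a patient-specific mean,
e.g. HbA1c means drawn from N(7.4, 1.3²), a realistic dispersion for a
diabetes outpatient population). Visits arrive at random gaps (minimum 2
weeks plus a geometric tail, mean 6 weeks in the benchmark); each visit
observes a noisy subset of a 12-channel panel (10 numeric channels modeled on
HbA1c, glucose, lipids, renal and liver labs; 2 ordinal urine dipstick
channels thresholded from latent values), with per-channel missingness
(HbA1c nearly always measured, albuminuria often skipped).

The prescriber is an ordered list of threshold rules evaluated against the
*chart*: the last observed value of each channel strictly before the visit
week. This has two consequences chosen deliberately. First, labels inherit
measurement noise realistically (the prescriber reacts to the measured, not
the true, value). Second, with rule noise zero the prescribed set is a
deterministic function of the observable 52-week window, so the Bayes-optimal
predictor is the policy itself and a sufficiently trained model's ROC-AUC
approaches 1 — the property the acceptance suite exercises. The benchmark
policy covers stepped glycemia rules, a glucose rule, renal, albuminuria and
dipstick-proteinuria rules, a lipid rule, and one late-entry biosimilar rule
active only from a drift year (2021 of the 2020–2022 span), emulating a drug
whose prescribing begins mid-study; benchmark rule noise is 3% per rule-visit
(suppression), leaving a small irreducible label noise.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: pharmacodynamics (prescriptions do not feed back into
the latent state), contraindications and drug–drug constraints, clinical
inertia and guideline hysteresis (real prescribing is smoother around
thresholds than hard rules), coding errors, and inter-prescriber variation.
Real-data performance claims require real data.

## Evaluation

Per-drug ROC-AUC uses the rank (Mann–Whitney) formulation with ties counted
half, asserted exactly equal to an O(n²) pair-counting oracle. The
micro average pools every (drug, sample) score/label pair — each prediction
weighted equally; the macro average is the unweighted mean of per-drug AUCs
over drugs with both classes present in the evaluation set. Drugs lacking a
class have no defined AUC and are excluded from the macro mean but named in
the report; single-class inputs to `rocAuc()` yield `NA` with a warning rather
than a silent number. Accuracy is the plain fraction of correct thresholded
decisions per drug.

Confidence intervals use the percentile bootstrap: 1000 resamples by default,
record-level resampling by default (patient-level available, since either
granularity is defensible), seeded, with undefined resamples redrawn and
counted. Coverage is checked by simulation (95% intervals cover a known mean
in ≈95% of 200 replications).

The reference model is one-vs-rest gradient-boosted trees (xgboost) on
flattened window features: per numeric channel the last value, window mean and
observation count; per categorical channel the last level; per drug the
prescription-week count; plus sex and age. The flattening recipe is this package's own design decision. The period-experiment runner trains one model per candidate
training period on a shared patient-level split and evaluates all of them on
one fixed later test period, to probe whether recent prescribing
patterns beat longer histories for late-introduced drugs.

## Numerical choices and problem sizes

Layer-norm ε is 1e-5; attention masking uses an additive −1e30 before the
softmax; focal probabilities are clamped at 1e-7. All PRNG use flows through
R's seed; the compiled core contains no random source, so identical seeds give
identical checkpoints and loss traces on a machine. The test suite runs the
benchmark at its default size (300 patients, 3 years, ~6,000 samples, ten
drugs) with the desk profile; the policy-recovery check uses 160 patients over
2 years; unit tests use reduced layouts (hidden 16, 1 + 1 layers). These sizes
are the package's chosen desk-scale study conditions; the full-scale profile
values (hidden 256, 4 + 4 layers, batch 256, 100 epochs) are preserved as the
documented configuration for hospital-scale data.

## Known limitations

* The desk-scale transformer approximates hard policy thresholds with smooth
  functions; samples whose chart state sits within measurement noise of a rule
  threshold are the dominant error source (near-ceiling but not perfect AUC).
* The bootstrap is percentile-based; BCa corrections are not implemented.
* Checkpoints serialize with `saveRDS()` and are not portable across package
  versions with different parameter layouts.
* The CLI covers the documented pipeline but not distributed or multi-device
  training, hyperparameter search, or deployment surfaces.
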