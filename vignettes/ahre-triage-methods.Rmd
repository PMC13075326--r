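---
title: "Methods: classifying and triaging atrial high-rate episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and triaging atrial high-rate episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Implanted pacemakers and defibrillators transmit atrial high-rate
episodes (AHREs) whenever the device suspects fast atrial activity.
Each episode carries two intracardiac electrogram (EGM) channels —
atrial and ventricular — plus a marker train of device-annotated sensed
events. A human reviewer must decide whether the episode shows true
atrial tachycardia or fibrillation (AT/AF), lead noise, or far-field
oversensing (FFO: the ventricular R wave leaking into the atrial channel
and being double-counted). `ahretriage` implements an automated triage
pipeline for this three-class problem: a small one-dimensional residual
network is trained per hospital fold, the fold models are combined by
soft voting, and only predictions whose top ensemble probability clears
a threshold are auto-handled, the rest being returned to the human
queue. The operating target is asymmetric: near-perfect sensitivity for
AT/AF (missing it risks an untreated stroke-associated arrhythmia),
while noise/FFO mistakes mainly cost review time.

## Episode representation and preprocessing

Every episode is reduced to a fixed grid of 1280 samples per channel
(10 s at 128 Hz). Longer recordings keep their last ten seconds — the
segment immediately preceding device detection is the clinically
informative one — and shorter recordings are zero-padded at the
beginning. Episodes lacking a ventricular channel carry an explicit
all-zero channel and a flag. Markers are binarized onto the same grid at
`round(t * 128)`, relative to the retained window; times falling outside
the window are dropped.

Two preprocessing choices were open and are resolved as follows:

* **Normalization.** Each channel is divided by its maximum absolute
  value (all-zero channels stay zero). Max-absolute scaling is
  scale-free (device gain does not matter), preserves waveform shape
  exactly, and is idempotent. It is applied after padding; zero padding
  cannot change the maximum, so the order is immaterial.
* **Markers.** The marker train is stored (both as a 0/1 vector and as
  typed events) but is *not* an input to the classifier, which sees only
  the two EGM channels. The markers serve the simulator and rendering.

## The synthetic cohort generator

The study conditions this package emulates involve proprietary
multi-center device data, so the generator is a first-class module: it
must reproduce the *statistical structure* that drives the protocol,
not the biophysics of cardiac tissue.

Waveforms are built from a biphasic spike kernel (first derivative of a
Gaussian, width 8–20 ms), which at 128 Hz yields the sharp two-lobed
deflections characteristic of near-field EGM spikes. Per class:

* **Sinus** (pretraining only): regular atrial activations at 50–90 bpm,
  each conducted after a 120–200 ms AV delay to a ventricular spike.
* **AT/AF**: atrial rate 180–350 bpm. The AF mode draws i.i.d. uniform
  cycle lengths and per-deflection amplitudes in [0.3, 0.7] — the
  simplest mechanism that produces "irregularly irregular" structure —
  while the AT mode is fast and regular. The ventricular response is a
  thinned (conduction probability 0.35), jittered, refractory-limited
  (350 ms) subsample of the atrial events.
* **Noise**: an underlying sinus-like rhythm plus one to three bursts of
  band-limited 30–60 Hz contamination (FFT-masked white noise, tapered
  edges) on the atrial channel, with spurious atrial markers inside
  bursts.
* **FFO**: sinus rhythm plus an attenuated (20–60% amplitude), broader
  (double width) copy of each ventricular activation added to the
  *atrial* channel at a per-episode lag of 0–80 ms, with double-counted
  atrial markers.

Identity structure: one root seed fans out hierarchically
(center → patient → episode) so cohorts are bit-reproducible and stable
under insertion of new centers. Each center draws a morphology
(amplitude scale, kernel width factor, noise band center) applied to all
its patients — this is the center-specific sampling bias that the
ensemble is meant to absorb. Per-patient AHRE episode counts are
`1 + NegBin(size = 1.1, mu = 10)`; under the default class mixture
(AT/AF 0.70, noise 0.22, FFO 0.08) this puts the median AT/AF burden per
patient (among patients with at least one) at six, with a long right
tail. The negative-binomial parameters were calibrated once against
that median and frozen; the median is stable at roster sizes in the
thousands, while at one or two hundred patients a fixed-seed draw can
land on five or seven — sampling noise of a median, which is why the
calibration check in the test suite uses a 1920-patient counts-only
roster (`simulate_patient_plan()` draws rosters without rendering
signals). Five percent of non-FFO episodes omit the ventricular channel,
exercising the zeros path. A `hard_mode` flag narrows the
amplitude/frequency gaps between classes for robustness experiments;
the default configuration is deliberately learnable.

What the generator does **not** emulate: real noise morphologies beyond
band-limited bursts, device sensing/blanking behaviour, pathological
conduction patterns, or inter-patient waveform diversity beyond scale
and width jitter. Passing the end-to-end tests therefore demonstrates
that the pipeline machinery (splitting, pretraining, transfer,
augmentation, ensembling, thresholding) is correct and learnable on
data with the study's structure — it says nothing about performance on
real device data.

## Augmentation

Five operators, all channel-coherent (the same window/offset on both
channels, preserving atrial–ventricular timing except where the
transformation intends otherwise): blanking a random 2 s window;
per-channel amplitude scaling by independent Uniform[0.4, 1.2] factors;
amplitude inversion; temporal shifting by Uniform[0.4, 1.5] s in a
random direction with zero-fill; and swapping the two 5 s halves.
Every noise and FFO episode contributes one copy per technique (a
five-fold enlargement of the minority classes); a disjoint 4% of AT/AF
episodes per technique (20% in total, sampled without replacement)
contributes one copy each. Copies supplement their originals, carry
provenance (source episode, technique), and are used only for 3-class
training — never for pretraining, validation, or testing. Markers on
copies are left untouched since they are not a model input.

## Architecture and training

The classifier is a deliberately small residual network (~59k
parameters at the defaults):

* **Stem**: convolution (kernel 7, stride 2, F = 32 filters) → batch
  norm → ReLU → max pool (window 3, stride 2), compressing 1280 samples
  to a 320-point feature signal.
* **Residual layers**: two layers of two blocks. Layer 1 keeps 32
  channels with identity shortcuts; layer 2 doubles to 64 channels and
  halves time (stride-2 first convolution, 1x1 projection shortcut) —
  canonical ResNet staging. Block kernels are 3.
* **Head**: global average pooling → dense(64, ReLU) → dense(softmax).

Exact filter counts and kernel sizes were an open choice; the defaults
above fit a ten-layer budget (stem + eight block convolutions + output)
and are all exposed in `model_spec()`. The engine itself — im2col
convolutions multiplied through BLAS with compiled gather/scatter
kernels, exact manual backpropagation (verified against numerical
differentiation to ~1e-9 relative error in the test suite), Adam — is
part of the package, keeping the training loop fully inspectable.

Training (per `train_config()`): categorical focal loss
`FL = -mean(alpha_t (1 - p_t)^gamma log p_t)` with gamma = 2 and uniform
class weights (both exposed; probabilities clipped at 1e-7), Adam at
learning rate 0.001, batch size 64, at most 50 epochs with early
stopping after 5 epochs without improvement, and checkpoint selection by
the validation **class-weighted F2-score**: per-class one-vs-rest
`F2 = 5PR/(4P+R)` averaged with weights equal to the normalized class
supports, which emphasizes the majority AT/AF class; a per-class F2
that is undefined (no true and no predicted positives) contributes
zero. Each fold first **pretrains** a two-class model (sinus vs AT/AF)
on unaugmented data, then transfers every weight except the output
layer into the three-class model.

## Protocol

Folds are defined at the *center* level so each test set comes from
hospitals unseen in training. Mirroring the multi-center design: the
largest cross-validation center is split into two patient-stratified
halves and the two smallest are merged, yielding one group per fold
(four groups from four CV centers); a designated external center is
excluded entirely and used only for ensemble evaluation. Within each
fold the pooled trainval episodes are split 80/20 at the patient level
with greedy class stratification ("class rectification" is read as the
class stratification named alongside it). Patients are atomic, so both
splits are best-effort with measured tolerances (the suite checks the
halves agree within 10 percentage points per class and the train
fraction lands in [0.75, 0.85]). A class carried by a single patient is
forced into training with a warning. Patient leakage between any
training pool (including pretraining sinus sources and augmentation
sources) and the fold's validation/test sets is a hard error checked
before training starts.

## Ensemble, triage, and evaluation

The four fold models are combined by **soft voting** (element-wise mean
of probability rows); the ensemble prediction is the argmax, with ties
broken toward AT/AF, then noise, then FFO — the clinically conservative
priority. An episode is **retained** iff its top probability is at least
the threshold τ (τ ∈ {none, 0.90, 0.95}); with continuous probabilities
the choice of ≥ versus > is measure-zero. Coverage (retained/total) is
the fraction of the review workload removed from humans; the error rate
among retained episodes is the cost of that automation.

Metrics are standard one-vs-rest: precision TP/(TP+FP), recall
TP/(TP+FN), specificity TN/(TN+FP), F2 = 5PR/(4P+R), reported in
percent. Undefined ratios are reported as missing, never silently as
zero. (A unit test documents that the printed-formula variant that swaps
the FN/FP denominators of precision and recall differs from these
standard definitions, which are the ones implemented.)

Patient-level uncertainty uses a **bootstrap**: B = 1000 iterations,
patients resampled with replacement, one episode per class the patient
possesses drawn per iteration — this preserves class balance and gives
the minority classes enough patients. Point estimate = mean over
iterations (the plug-in estimate is also reported; the paper-style
convention was open); CI = 2.5/97.5 percentiles.

## Saliency

Grad-CAM++ attribution targets the final residual block's activation
(standard practice for coarse maps). Because only global average
pooling and the dense head follow that layer, the gradient of a class
logit with respect to the feature map has an exact closed form, which
the implementation uses. Channel weights follow the usual
first/second/third-order gradient ratio with ReLU rectification of both
the gradients and the weighted sum, giving a nonnegative temporal map
at feature resolution (160 points at the defaults) that is linearly
interpolated to the 1280-sample grid. One temporal map is shared across
both input channels (1D class-activation maps aggregate feature
channels, not input channels); ensemble maps min-max normalize each
member (a constant map normalizes to zeros by convention) and average.

## Numerical and design notes

* Probability clipping at 1e-7 in losses; batch-norm epsilon 1e-5,
  momentum 0.9 on running statistics; He initialization.
* Argmax ties: AT/AF > noise > FFO. Threshold comparison: `>=`.
* Augmented copies may exceed [-1, 1] after scaling — they are training
  inputs, not stored episodes, and the record invariant applies to
  preprocessed episodes.
* Storage: signals in Parquet (full-precision doubles, cross-language,
  streamable) keyed by episode id; identity in a plain-CSV manifest
  (`episode_id, patient_id, center_id, label, has_ventricular`);
  ground-truth event logs in CSV with 17-significant-digit times so the
  round trip is lossless.
* Reproducibility: all randomness descends from one root seed through
  named substreams (`derive_seed()`); training is deterministic for a
  fixed seed and thread count; evaluation mode is deterministic
  always.

## Problem sizes used in the checks

The end-to-end check trains the fourfold ensemble on the default
cohort (five centers, 169 patients, ~1750 episodes of which ~590 are
sinus) at reduced epochs — one pretraining and at most three training
epochs with patience one — which is enough for the separable default
conditions (every fold reaches its best validation F2 by the second
epoch at these sizes); the toy learnability check uses 90 episodes of 256 samples
and the full 50-epoch budget; the generator calibration check uses a
1920-patient counts-only roster; the bootstrap checks use B in the
hundreds to 1000. These sizes are the package's own choices balancing
coverage against a fast default test run.

## Known limitations

* The generator's waveform realism is intentionally minimal; class
  separability at the defaults is higher than in real device data, so
  absolute performance numbers on synthetic cohorts do not transfer.
* The engine is CPU-only and single-threaded apart from BLAS; it is
  sized for the ~59k-parameter default network, not for large-scale
  architecture search.
* Calibration of predicted probabilities is out of scope (thresholds
  act on raw softmax outputs).
* The bootstrap treats episodes within a patient-class cell as
  exchangeable; temporal drift within a patient is not modeled.
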