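---
title: "Six-class motor-imagery EEG classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six-class motor-imagery EEG classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mieegnet)
```

## The problem

In the HaLT (hand, leg, tongue) interaction paradigm, a subject wearing a
19-electrode 10--20 EEG montage is cued to imagine one of six movements —
left hand, right hand, a passive state, left leg, tongue, right leg — for
about one second per trial, while the scalp potential is recorded at
200 Hz through a 0.53--70 Hz analogue passband.  A brain--computer
interface built on these signals must answer two questions:

1. **Which electrodes carry discriminative information?**  Processing a
   small discriminant channel subset (DCS) instead of all 19 electrodes
   shrinks the model and the per-trial latency, which is what makes
   embedded deployment practical.
2. **How should the retained channels be classified?**  The package uses a
   compact convolutional network of the EEGNet family, small enough that
   its complete parameter inventory is counted in the hundreds.

This package implements the full pipeline — session I/O, epoching, two
channel-selection strategies, the network, and a cross-validation
harness — together with a synthetic-session generator that plants a known
ground truth, so every stage can be validated end to end without access
to the benchmark recordings.

## Trial extraction

Recordings arrive as a continuous `samples x channels` matrix with a
per-sample marker stream (0 = no task, 1--6 = active task in paradigm
order).  One trial is cut per maximal run of a constant nonzero code.
Each ~1 s task (200 samples) is trimmed by 15 samples on each side,
yielding the 170-sample (0.85 s) analysis window; trimming suppresses
cue-onset and cue-offset artifacts.  Where inside the task the window
sits is a convention of this package (symmetric trim); the recording
paradigm itself does not prescribe it.  Runs shorter than
`window_len + 2*trim` are skipped and counted, so
`emitted + skipped = total task runs` always holds.  Marker codes
outside 1--6 (the benchmark's service codes such as 91/92/99) are treated
as "no task".

## The classifier

The network stacks three convolution stages, each followed by batch
normalisation:

* a **temporal convolution** — `F1 = 4` bias-free filters of length 4
  applied along time with "same" padding (16 parameters).  With a
  4-sample kernel at 200 Hz these act as short FIR filters;
* a **depthwise spatial convolution** across all `k` input channels with
  depth multiplier `D = 4` (one spatial filter per temporal filter and
  depth index; `16k` parameters — 96 for `k = 6`, 128 for `k = 8`),
  collapsing the channel axis;
* a **separable convolution** — a depthwise temporal convolution of
  length 16 on the 16 maps followed by `F2 = 16` pointwise (1x1) mixing
  filters (256 + 256 = 512 parameters).

ELU activations follow the second and third batch norms, each followed by
average pooling (widths 4 then 8, floor division: 170 -> 42 -> 5) and
dropout.  The flattened 80-dimensional feature vector feeds a dense
softmax layer over the six classes (486 parameters including bias).
`audit_parameters()` reproduces this inventory layer by layer; batch-norm
entries count 4 per feature map (scale, offset, and the two running
statistics), which is the convention under which the table above is
exact.

```{r}
audit_parameters(eegnet_config(chans = 8))
```

Several kernel hyperparameters are not stated outright by the
architecture tables this reconstruction follows; they are forced by the
parameter counts: 16 temporal-conv parameters with four bias-free filters
force `kern_length = 4`; 512 separable parameters with 16 maps force a
16-sample depthwise kernel and 16 pointwise filters; pooling widths 4 and
8 are forced by the 170 -> 42 -> 5 shape sequence; and only bias-free
convolutions make all counts consistent.  One published shape row
(`(None, 1, 42, 64)` after the third batch norm) contradicts the 16-map
separable stage; we read the 64 as that layer's parameter count and keep
16 maps.  Dropout (rate 0.25, spatial by default) is the cross-subject
default of the original EEGNet publication; the source architecture is
silent on it, so both rate and type are configurable.  No max-norm weight
constraint is applied.

### Training

Training minimises categorical cross-entropy with the Nadam optimiser
(the standard bias-corrected Nesterov--Adam formulation, without the
momentum warm-up schedule some frameworks add; `beta1 = 0.9`,
`beta2 = 0.999`, `eps = 1e-7`).  Two recipes are provided as constants:

* **channel-ranking stage** (`arbc_train_config()`): 2000 epochs, batch
  330, rate 0.001, constant;
* **processing stage** (`processing_train_config()`): 1500 epochs, batch
  330, rate 0.0001, with a triangular cyclical learning rate between
  1e-6 and 5e-2.

The cyclical schedule (`clr_schedule()`) rises linearly from `base_lr`
to `max_lr` over `step_size` iterations and falls back over the next
`step_size`.  The cycle bounds are fixed by the recipe; the half-period
is not, so the package defaults to 8 epochs' worth of iterations
(configurable).  Batch-norm uses `eps = 1e-3` and running-statistic
momentum 0.99 (training normalises with biased batch moments; inference
uses the running estimates).  Weight initialisation, shuffling and
dropout masks all draw from R's RNG under the training seed, and the
numerical core is single-threaded, so a fixed
`(data, config, train_config)` triple reproduces the fitted weights
bit for bit.  No early stopping or validation-split monitoring is
applied inside folds.

## Channel selection

### Accuracy-rating-based selection (ARbC)

`arbc_rank()` trains the single-channel variant of the network
(`chans = 1`, `F1 = F2 = D = 4`) on each electrode separately, under
stratified k-fold cross-validation on the pooled all-subject trials, and
ranks electrodes by mean fold accuracy.  `arbc_select()` takes the top
`n`; when electrodes are tied at the cut boundary (equal accuracy at
one-decimal printing precision, the precision at which such ties are
reported), each tied candidate is appended to the already-selected
channels and scored by subset-level CV accuracy, the higher subset
winning; any residual tie falls back to montage order.  This mirrors how
a boundary tie between two electrodes with identical single-channel
accuracy is settled in practice.

### Mutual-information grouping (CMIbA)

Each channel's pooled amplitude samples are binned into 32 equal-width
histogram bins over their own range ("occurrence probability" read
literally; the estimator is not otherwise prescribed).  Entropies and
divergences are reported in bits; selection only uses their ordering,
which is base-invariant.  For a channel pair, the joint 32x32 occupancy
table gives the mutual information as the Kullback--Leibler divergence of
the joint from the product of its own marginals; deriving marginals from
the joint makes `I(X, X) = H(X)` exact and keeps `I >= 0` without any
smoothing inside the MI computation (marginal estimates used on their own
apply additive smoothing `eps = 1e-10` to the counts).  All
`C(19, 2) = 171` pairs are evaluated on the pooled all-subject data.

The grouping rule — "combine pairs of nonzero shared entropy with the
remaining channels until a group of n is formed" — is under-specified as
stated, so the package fixes a deterministic greedy realisation: seed the
group with the highest-MI pair, then repeatedly add the channel with the
largest summed MI to the current group, stopping at `n`; ties break
toward the lower channel index.  Whether shared information should be
maximised or minimised within the group is arguable; the package
maximises by default (channels that co-express the class signal share
information) and exposes `objective = "min"` as the alternative.
Distributions are estimated on fully pooled samples rather than per
trial, the simpler of the two readings.

## Evaluation

`cross_validate()` partitions trials into k = 10 stratified folds
(greedy least-loaded assignment: fold sizes differ by at most one, class
proportions by at most one trial), trains a fresh model per fold and
aggregates a six-class confusion matrix.  The published accuracy metric
is stated in binary TP/TN form; for six classes the harness reports
`100 * trace / total` (micro-averaged correctness, the multi-class
generalisation) and additionally exposes the binary form per class
one-vs-rest.  Stratification is the package's choice; an unstratified
mode exists.  A per-subject mode splits by subject tag before CV,
matching subject-dependent evaluation; the pooled mode mixes all
subjects.  `measure_latency()` reports wall-clock single-trial inference
statistics with a hardware descriptor; timings are machine-bound and
only sanity properties are ever asserted.

## The synthetic generator

`synthetic_spec()` fixes the study conditions used throughout the
package's validation:

| parameter | default | meaning |
|---|---|---|
| channels / rate | 19 @ 200 Hz | montage and rate of the recordings |
| run / gap | 200 / 60 samples | 1 s task, rest gap (>= 50) |
| trials per class | 20 | desk-scale session |
| background | pink noise, slope 1, RMS 10 uV | 1/f EEG-like floor |
| common mode | 2 uV slow drift | shared reference/drift component |
| informative map | C3, Cz, C4, P3, Pz, P4 for every class | planted clique |
| class bands | 8--12, 12--16, --, 16--20, 20--24, 24--28 Hz | passive class flat |
| snr | 4 | class-signal power / noise power on informative channels |

During a class-c run, one sinusoid with random frequency inside class c's
band and random phase is added *coherently* to all informative channels
(amplitude `noise_rms * sqrt(2 * snr)`, ~28 uV at the defaults).
Coherence is what makes the clique recoverable by mutual information;
the class-specific bands are what make single channels classifiable.
The passive class injects nothing and is recognisable by absence.  All
values sit inside the 0.53--70 Hz recording passband and at
physiologically plausible microvolt scales, but deliberately exaggerate
separability: real motor-imagery rhythms are weaker, non-sinusoidal,
subject-variable and spatially smeared by volume conduction.  Passing
recovery and accuracy checks on this generator therefore validates the
*implementation* — estimators, selectors, network, harness — not
real-data performance, whose published levels (83.7% per subject on the
benchmark) require the external recordings.

Determinism: each subject's session derives its RNG stream from
`(seed, subject_index)`, so regeneration is byte-identical.

## Problem sizes used in the validation studies

The package's own studies are sized for a single CPU: selector-recovery
runs use 10 seeds of the default spec (120 trials) with a desk-scale
ranking profile (`arbc_desk_profile()`: 30 epochs, 2 folds, batch 20,
rate 0.005) — calibrated once on pilot separation runs and then frozen —
and the classifier study uses 120 trials/class with 50-epoch training per
fold.  The full-scale recipes (2000/1500 epochs, 10-fold, batch 330)
remain the package defaults for real use.

## Numerical choices and degenerate inputs

* Histogram of a constant signal: a unit-width bin range is substituted;
  the estimate is a point mass with zero entropy (not an error).
* `kld(p, q)` requires `q > 0` wherever `p > 0` and errors otherwise;
  `0 log 0 = 0` throughout.
* An all-zero pairwise MI matrix aborts grouping with a "no
  discriminative structure" error rather than returning an arbitrary
  subset.
* Pooling drops the incomplete tail group (floor division), as the shape
  sequence requires.
* Softmax is computed shift-invariantly; prediction ties break toward
  the lowest class code.
* Channel-name matching is case-insensitive and keeps the legacy
  T3/T4/T5/T6 labels verbatim.
* The MAT-file layer implements the v5 subset the HaLT layout needs
  (numeric/char/cell/struct, compressed elements on read) and
  round-trips sessions exactly; it interoperates with `scipy.io` in both
  directions (checked in the test suite).

## Known limitations

* No EDF/BDF input, streaming acquisition, or artifact-removal
  algorithms (hardware filtering is assumed upstream).
* Selection operates once on pooled all-subject data; no per-subject
  re-selection.
* The backend is CPU-only; embedded-deployment concerns (quantisation,
  board latency) are out of scope.
* Published benchmark accuracies are shipped as reference constants
  (`halt_reference()`) for comparison and are never asserted against
  computed output, since the external dataset is not redistributable
  with the package.
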