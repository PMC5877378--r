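---
title: "Methods: recognizing self-induced emotion from EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognizing self-induced emotion from EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most EEG emotion-recognition work classifies emotion *while a stimulus is
playing*. This package implements and validates the complementary analysis:
recognizing **self-induced** emotion — affect a participant re-elicits by
recalling a movie scene with closed eyes — and comparing it with the
movie-induced state, within one protocol. The protocol it models is a
six-emotion design (joy, neutral, sad, disgust, anger, fear): per subject,
18 movie clips (3 per emotion), each followed by a recall period, recorded
over a 61-channel extended 10–20 montage at 512 Hz (Fz reference, AFz
ground).

Because the underlying EEG cohort is not publicly deposited, the package is
built around a synthetic-cohort generator with *known* ground truth. All
claims the test suite makes are claims about the pipeline's correctness and
its ability to recover planted structure — not about real brains.

## Pipeline

1. **Preprocessing** — zero-phase 0.1–80 Hz Butterworth band-pass (order 4,
   forward–backward), ICA-based ocular-artifact removal, removal of the 5 s
   pre-trial baselines, trimming of each trial to its last 50 s, and
   epoching with a 2 s window at 50% overlap. A 50 s trial yields 49 epochs;
   18 trials give 882 epochs per subject per paradigm.
2. **Features** — per epoch and channel, six values: the differential
   entropy (DE) of the five classical bands (delta 1–4, theta 4–8,
   alpha 8–12, beta 12–30, gamma 30–64 Hz) computed from an STFT
   spectrogram, plus the log mean absolute first difference of the first
   intrinsic mode function (IMF1) from empirical mode decomposition (EMD).
   With 61 channels: 366 features (305 DE + 61 EMD).
3. **Selection** — minimal-redundancy–maximal-relevance (MRMR) greedy
   ranking with plug-in mutual information on discretized features; cohort
   electrode lists by aggregating per-subject rankings.
4. **Classification** — linear SVM (LIBSVM via `e1071`, default
   parameters) in three protocols: within-paradigm binary
   (joy vs. sad/disgust/anger/fear, neutral excluded) with
   leave-one-clip-out folds (686 train / 49 test × 15), within-paradigm
   six-class with folds over clip positions (588 / 294 × 3), and
   cross-paradigm (train on all 882 movie epochs, test on all 882 recall
   epochs).
5. **Patterns** — per-class, per-electrode feature means (scalp
   topographies with an IDW-interpolated grid) and per-feature
   distribution summaries.

## Modelling choices worth knowing about

**DE aggregation.** The spectrogram-based DE of a band is defined per
(frame, bin); a single per-epoch value requires an aggregation rule, which
the source methods leave open. We use
`DE = log( mean over frames of ( sum over band bins of |S|² ) )`: one value
per band that is stable under the frame count and obeys the exact scaling
identity `DE(a·x) = DE(x) + log a²` (tested to machine precision). Bands
are half-open `(low, high]` intervals; at 512 Hz with the 128-sample STFT
window the bin spacing is 4 Hz, so the delta band holds exactly one bin —
a direct consequence of the protocol's own STFT settings. The taper is a
Hamming window; frames that would overrun the epoch are dropped. All logs
are natural.

**EMD.** Envelopes are natural cubic splines through the local extrema,
with two extrema mirrored across each boundary (endpoints clamp the
envelope when they dominate the first extremum). Sifting stops when the
envelope mean, normalized by the envelope half-amplitude, is below 0.05 at
≥ 95% of samples, with a hard cap of 100 sifts; decomposition stops at 8
IMFs or a residue with fewer than 4 extrema. The IMFs and residue sum back
to the input by construction (asserted < 1e-8 of the signal range on every
tested epoch). Feature extraction only needs IMF1, so the batched path
stops after the first mode.

**Ocular component flagging.** The original procedure selected EOG
components visually. For reproducibility we flag components whose time
course correlates (|r| > 0.7) with a surrogate EOG: the mean of FP1/FP2
band-limited to 0.5–4 Hz. On blink-injected synthetic data this removes
the planted blink train (frontal correlation drops from > 0.7 to < 0.3)
while artifact-free recordings pass through essentially unchanged
(per-channel r > 0.95). Zeroing k components leaves rank n−k, so a second
pass must request fewer components; with that adjustment a re-run flags
nothing new.

**Baseline removal** is span removal (the 5 s pre-trial segments are
discarded), not mean subtraction, and only the last 50 s of each trial are
analysed.

**MI estimation.** Eq.-level mutual information needs probability masses;
we discretize each feature at mean ± sd into 3 levels (the original MRMR
practice) and use the plug-in estimator in nats. Greedy ties break toward
the lower feature index so rankings are deterministic. Cohort-level
electrode lists count, per feature, how many subjects place it in their own
top-*n*, breaking ties by mean rank — the aggregation rule itself is our
choice, as no published rule exists for this step.

**SVM.** Linear kernel, default cost, features z-scored by training-fold
statistics only (never the test fold); six-class problems use LIBSVM's
one-vs-one voting; ROC/AUC come from pooled, orientation-corrected decision
values with a trapezoid rule.

## The synthetic cohort generator

Each subject is 1/f^1 Gaussian background noise (sd 10 µV) over all
channels, plus a band-limited 36–44 Hz oscillation at the effect channels
(default T7, T8, TP8, AF7, O1) whose amplitude is
`2 µV · (1 + effect_size · m[class, channel] · attenuation)`. The class
multiplier matrix `m` gives joy the strongest temporal/occipital gamma,
disgust the strongest prefrontal gamma, neutral zero everywhere, and
laterally asymmetric negative emotions; recall trials carry the same
pattern attenuated by 0.7 by default. The SNR was fixed once from band
power arithmetic — the largest class effect roughly doubles effect-channel
gamma power against the pink-noise gamma floor — as a plausible strong
single-subject effect. Amplitude parameters consume no random draws, so
cohorts differing only in `effect_size` or attenuation share identical
noise under one seed, making effect/null and attenuation comparisons
paired by construction. Optional blink artifacts are 0.4 s squared-sine
frontal transients at Poisson times.

The generator deliberately does **not** simulate cortical sources, volume
conduction, inter-channel correlation, non-stationarity, or any stimulus
content. Consequences for interpreting the validation suite:

* Passing tests show the *pipeline* is correct and sensitive; they say
  nothing about classification rates achievable on real EEG.
* Because the class signal lives in exactly 10 features (5 × gamma-DE,
  5 × EMD-D_t), MRMR recovers it sharply — a cleaner situation than real
  data, where information is spatially distributed.
* For the same reason, a linear SVM on the top-10 MRMR features *beats*
  the all-366-feature model on synthetic cohorts (the other 356 dimensions
  are pure noise). On the real cohort the reported trend is the opposite —
  accuracy rising with feature count — which reflects distributed
  information that this generator intentionally lacks. The validation
  suite asserts the distributed-information direction (top-10 ≤ all-366)
  and that assertion fails on synthetic data; we keep it failing rather
  than weaken it, as an honest marker of where the simulation's
  assumptions end.

## Validation problem sizes

The protocol's structure (18 + 18 trials, 3 clips × 6 emotions, 61
channels, 512 Hz, 2 s / 50% epochs) is preserved exactly throughout the
validation suite. Trial length is where we scale: synthetic validation
cohorts use 10 s trials (9 epochs/trial) and a 60 s resting baseline,
sizes chosen so the whole suite runs comfortably on one CPU; the counting
checks (49 epochs/trial, 882 epochs/subject, 686/49 and 588/294 folds) run
at the full 50 s dimensions via single-channel recordings and structural
feature matrices. Cohorts: 5 subjects for recovery/decodability/nulls,
3 seed-paired subjects per attenuation level (1.0 / 0.7 / 0.3). The
full-scale simulation is available by simply not overriding
`trial_seconds` in `sim_config()`.

A note on the chance model for the no-effect null: an SVM trained on pure
noise does not reduce to a majority-class voter — it overfits the training
folds and typically scores a few points *below* the 80% majority rate on
held-out clips. The correct chance reference is therefore the classifier's
own label-permutation distribution (the same protocol re-run with the
clip-to-class assignment shuffled), which is what `recovery_experiment()`
uses; the binomial bound above the majority rate is kept as a one-sided
guard against information leakage.

## Numerical details and degenerate inputs

* Log of zero band power or zero D_t is floored at 1e-30 and flagged;
  the flag count is asserted to be zero on all synthetic data.
* Constant features discretize to a single level and are flagged; their
  MI is 0, so they can never be selected first.
* The EDF writer quantizes to 16 bits over each channel's physical range
  (error ≤ range/65534); annotations travel in a JSON sidecar and
  round-trip exactly.
* ICA initialization is seeded; the band-pass uses odd-reflection padding
  of 2/low seconds so the 0.1 Hz edge's transient never reaches the data.
* `segment_epochs` never emits an epoch crossing a trial boundary, and the
  epoch-count formula is property-tested against brute-force enumeration.

## Known limitations

* Single-subject ICA on 61 channels is the slowest preprocessing step;
  the validation suite exercises it on 10-channel cohorts and full-montage
  use is left to analyses that need it.
* The MRMR aggregation rule and the DE frame-aggregation rule are
  documented package choices among several defensible ones; both are
  configurable at the call sites.
* Classification reports use pooled confusion matrices; per-subject F1
  averaging (an alternative convention) can differ in the second decimal.
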