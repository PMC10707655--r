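---
title: "Methods: frame-level bleeding detection and alert escalation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frame-level bleeding detection and alert escalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During robot-assisted laparoscopic procedures, bleeding is one of the most
frequent intraoperative adverse events, and recognising it quickly is
hard precisely when it matters most. `bleedwatch` implements a complete,
self-contained pipeline for anticipating bleeding from endoscopic video at
the frame level: a multi-task convolutional network scores each frame for
the presence of blood accumulation, a causal low-pass filter stabilises
that noisy per-frame confidence, and a parking-sensor style escalation
turns repeated faint detections into a graded warning that crosses a
significance threshold *before* frank bleeding, when the scene shows
precursor oozing. An evaluation suite compares machine alerts with human
annotations.

Everything runs on synthetic surgical scenes produced by the package's own
seeded generator, so the full pipeline is trainable and testable on a desk
machine without any clinical data.

## The multi-task network

The model is a U-Net variant with two output branches sharing one
contracting path:

* **Shared encoder.** Per level: two 3x3 same-padding convolutions with
  ReLU, then 2x2 max pooling; channel counts multiply per level
  (default x2). The default desk-scale configuration is 64x64x3 input,
  depth 3, 16 base channels, giving a 128-channel 8x8 bottleneck and
  about 0.49 M parameters. The canonical 64-to-1024-channel depth-4
  U-Net is reachable through `net_config()`, but the smaller default is
  the configuration the package's tests and acceptance runs use, chosen
  so a full 30-epoch training run fits in minutes on one CPU core.
* **Segmentation branch.** The standard expansive path: 2x2
  transposed-convolution up-sampling, concatenation with the matching
  encoder feature map (skip connection), two 3x3 convolutions per level,
  and a 1x1 convolution with sigmoid producing a per-pixel instrument
  probability map at input resolution. Same-padding is used throughout
  (the original crop-and-copy variant would shrink the map), which is the
  dominant modern convention and keeps mask comparison trivial.
* **Classification branch.** Global average pooling of the bottleneck
  feature map, one hidden dense stage (default width 64, ReLU), and a
  2-way softmax: class 0 "no blood accumulation", class 1 "blood
  accumulation". Feeding the head from the pooled bottleneck is a
  deliberate design interpretation: the shared features that segment
  instruments are also what the event detector consumes.

The engine (forward and backward passes) is implemented in the package's
own C++ code as im2col + GEMM in single precision, with gradients verified
against central finite differences in the test suite. Batch normalisation
is deliberately absent; ReLU, max pooling and transposed-convolution
up-sampling are the standard choices.

## Training

The loss is the unweighted multi-task sum

    loss = seg_loss + cls_loss

where `seg_loss` is the *pixel-mean* binary cross-entropy of the
segmentation map against the instrument mask and `cls_loss` the
cross-entropy of the 2-way head (both in nats). The mean (rather than
pixel-sum) convention is a documented choice; it keeps the two components
on comparable scales without introducing explicit weights. Probabilities
are clamped to `[1e-7, 1 - 1e-7]` inside both cross-entropies so reported
losses are finite and reproducible.

Event-detection quality is summarised as

    Classification Accuracy = #correct_predictions / #samples

plus the same ratio restricted to each class. The optimiser is Adam
(1e-3, batch 16) — unstated upstream, standard for small U-Nets, and
configurable. The validation split is 80/20 stratified by class. Model
selection is by epoch: `train_network()` records per-epoch training losses
and validation accuracies and returns the weights at `selection_epoch`
(default the final epoch; the package's standard runs train 30 epochs and
select epoch 30). Runs are reproducible given the seed: weight
initialisation, the split and shuffling all derive from explicit seeds,
and the engine is deterministic in single-threaded execution.

## The synthetic scene generator

The generator emulates the three ingredients the pipeline needs:

* **Background**: a tissue-toned base colour with smooth, seeded
  luminance texture and per-pixel Gaussian noise (sigma = 0.02).
* **Instruments**: 2 (default) bright, low-saturation capsules of random
  orientation and length that drift slowly over time — elongated proxies
  for laparoscopic tools, the binary segmentation target.
* **Blood accumulation**: a cluster of dark-red ellipses (red channel
  0.5-0.8, green/blue <= 0.25) whose *visible* (non-occluded) pixel area
  defines the frame label: class 1 iff the area reaches 1% of the frame.
  The 1% floor makes labels unambiguous and the thresholding testable;
  the label is always recomputed from the rendered area, so content and
  label cannot disagree.

Temporal scenarios add a precursor phase: from `precursor_onset_s` the
blob appears in 2-frame bursts every ~300 ms, mostly below the labelling
area (faint oozing), briefly above it (every fourth burst), and from
`bleed_onset_s` it is persistent, supra-threshold and growing at
`blob_growth_rate` (default 40 px^2/s). This reproduces the
clinically-motivated pattern that repeated low-confidence detections
precede a frank bleed. In the iid training sets
(`make_frame_dataset()`), class-0 frames contain no blood at all:
keeping the desk-scale task cleanly separable is what the class
separability invariant (a one-dimensional colour heuristic must reach
>95% accuracy) guarantees, and sub-threshold blobs appear only in the
temporal sequences where the area rule labels them 0.

What the generator does **not** emulate: specular highlights, smoke,
camera motion blur, depth, anatomical variability, or photo-realistic
tissue. Passing tests on these scenes therefore demonstrates that the
implementation is correct and that the pipeline's logic behaves as
specified — not that the network would reach the same accuracy on real
surgical video, where the reported figures act as context, not as a
claim this package can verify.

## Filtering and alert escalation

The per-frame class-1 confidence is a highly perturbed signal. It is
stabilised with a causal digital Butterworth low-pass filter (default
cutoff 5 Hz, order 2, sample rate = video fps, default 25): unit DC gain,
-3 dB at the cutoff, monotone roll-off. Only a single forward pass is
used — no zero-phase forward-backward filtering — because the engine must
run on live streams. The filter's order is a documented choice (order 2
is the smallest with a useful roll-off); since the delay of "a 5 Hz
Butterworth" is not derivable without an order and sample rate, the
`filter_spec` *measures* its nominal delay from the 50% crossing of its
unit-step response instead of asserting a figure.

The warning level `w` in `[0, 1]` escalates like a parking sensor.
A sample whose filtered confidence reaches `detection_floor` (default
0.30) is a *possible bleeding occurrence*. While occurrences keep
recurring — no silence longer than `persistence_gap_ms` (default 400 ms,
covering the ~300 ms oozing cadence) — the level rises by
`dt / escalation_window`; when they cease it decays at `decay_rate`
(default 0.5/s). Sustained full confidence therefore saturates the level
in exactly one escalation window (default 2200 ms, the midpoint of the
2100-2300 ms escalation time frame). Two design points deserve
emphasis:

* **Occurrences are dichotomic above the floor.** An early design used a
  confidence-weighted leaky integrator (`w += alpha * max(0, p - floor) * dt`
  with `alpha` calibrated to the same saturation condition), but under the
  default floor and decay a 2-frame burst at confidence ~0.6 contributes
  ~0.016 of warning while the ~220 ms inter-burst silence decays ~0.11, so
  faint oozing could never escalate — contradicting the intended
  behaviour that repeated detections *even with a small confidence
  percentage* announce a bleed. Counting occurrences dichotomically above
  the floor preserves both the saturation calibration and the early
  warning.
* **The significance threshold applies to the warning level**, not to the
  raw network confidence (the convention is ambiguous in the source
  material); the default 0.94 is the midpoint of the conventional 93-95%
  band. Events are recorded dichotomically: one event per upward
  crossing, onset at the first sample at or above threshold.

Consequences verified by the test suite: no alert can ever fire on a
signal that stays below the detection floor; the warning is invariant to
prepended silence; a clean step alerts within one escalation window plus
a few filter time constants; and on precursor traces whose oozing starts
6 s before the sustained phase, the alert precedes the frank bleed by a
median of more than 3 s.

## Evaluation machinery

* **Event matching** (`match_events()`): greedy nearest-in-time
  one-to-one matching of machine events to human annotations within a
  tolerance (default +/- 10 s — bleeding episodes are sparse relative to
  this window in prostatectomy video). Matched pairs are true positives
  with `delta_s = machine - human`; unmatched machine events are false
  positives, unmatched human events false negatives.
* **Delta statistics** (`delta_stats()`): median and IQR with type-7
  (linear-interpolation) quantiles — no quartile rule is mandated
  upstream, so the R default is used and frozen by an oracle test.
  Negative deltas mean the machine was earlier; `lead_median_s = -median`
  is reported alongside to keep the sign unambiguous.
* **KDE** (`kde_density()`): exact Gaussian-mixture evaluation on a
  regular grid (event logs are tens of points, so no binned FFT
  approximation is needed), Silverman's rule bandwidth by default, with a
  flagged fixed-bandwidth fallback for zero-variance data.
* **MCA** (`mca()`): indicator-matrix multiple correspondence analysis
  built directly on the SVD of the standardised residuals of
  `P = Z / sum(Z)`. Principal inertias are squared singular values and
  sum to `(J - Q) / Q` exactly (checked to 1e-10); for two variables the
  inertias are `(1 +/- s) / 2` for each classical-CA singular value `s`
  of the contingency table, which the tests verify against a brute-force
  CA oracle. Variables are summarised per dimension by their squared
  correlations (discrimination measures, eta^2 of the individual scores
  against the variable), whose per-dimension mean equals the principal
  inertia — an identity the tests also exercise. No Benzecri/Greenacre
  inertia correction is applied by default (none is mandated); the
  Benzecri adjustment is available as an option.

## Numerical and degenerate-input choices

* Cross-entropy clamp 1e-7; engine arithmetic float32 with losses
  accumulated in double; loss additivity `total = seg + cls` is exact by
  construction.
* Butterworth design via the bilinear transform (the `signal` package),
  which places the -3 dB point exactly at the requested cutoff.
* Zero-variance KDE input falls back to bandwidth 0.1 with a warning;
  single-category MCA variables are dropped with a warning; empty
  datasets, zero-sample accuracy, out-of-range render times and
  fps/filter mismatches raise classed validation errors.
* All randomness flows from explicit seeds through small derived
  substreams; nothing reads or perturbs the caller's RNG state
  permanently.

## Problem sizes used by the standard runs

The package's standard desk-scale study conditions — used by its tests
and by `scripts/acceptance.R` — are: 500 balanced 64x64 frames (400
train / 100 validation), the default depth-3/base-16 network, 30 epochs
of Adam at 1e-3 with batch 16; and 50 synthetic confidence traces at
25 fps with oozing bursts starting 6 s before a sustained plateau for
the alert-lead measurement. These sizes were chosen once as the smallest
configuration on which the behaviours of interest are stable.

## Known limitations

* Synthetic scenes are far easier than surgical video; accuracies
  measured here are upper bounds in spirit, floors only in the test
  sense.
* The network is frame-independent: no temporal architecture, no
  severity grading, no bleeding-source localisation, and single-class
  instrument segmentation only.
* The alert engine's persistence gap introduces one extra tunable not
  present in the original behavioural description; its default (400 ms)
  is tied to the oozing cadence and documented above.
* MCA is exploratory; the package draws no inferential conclusions from
  it.
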