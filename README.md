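# bleedwatch

Frame-level detection and *anticipation* of intraoperative bleeding in
endoscopic video, for surgical data-science researchers and engineers who
want a fully reproducible, self-contained reference pipeline.

Intraoperative bleeding is among the most frequent adverse events in
robot-assisted laparoscopy, and the raw output of a per-frame classifier
is far too jittery to alarm on directly. `bleedwatch` implements the
complete chain:

1. **Multi-task U-Net.** A shared contracting path feeds two branches: a
   segmentation decoder (with skip connections) that delineates surgical
   instruments, and a classification head off the bottleneck (global
   average pooling → dense → softmax) that labels each frame *blood
   accumulation present/absent*. Training minimises the unweighted
   multi-task loss
   `loss = seg_loss + cls_loss`,
   with `seg_loss` the pixel-mean binary cross-entropy of the instrument
   mask and `cls_loss` the cross-entropy of the 2-way head; accuracy is
   reported as `#correct_predictions / #samples`, overall and per class.
   The forward/backward engine is the package's own C++ (im2col + GEMM),
   so no deep-learning framework is required.
2. **Alert engine.** The per-frame bleeding confidence `p(t)` is passed
   through a causal digital Butterworth low-pass filter (default 5 Hz
   cutoff, order 2) and escalated, parking-sensor style, into a warning
   level `w(t) ∈ [0, 1]`: while supra-floor detections keep recurring,
   `w` rises so that persistent detections saturate it in one escalation
   window (default 2200 ms); when they stop, it decays (0.5/s). Upward
   crossings of the significance threshold (default 0.94, midpoint of
   the 93–95% band) are recorded as dichotomic bleeding events. Repeated
   *faint* oozing detections therefore raise an alert seconds before the
   frank bleed.
3. **Evaluation suite.** Greedy nearest-in-time matching of machine
   events to human annotations (TP/FP/FN and `delta = machine − human`),
   median/IQR delta statistics, exact Gaussian KDE of the deltas, and a
   from-scratch indicator-matrix Multiple Correspondence Analysis
   (principal inertias = squared singular values, total `(J − Q)/Q`;
   variable squared correlations as discrimination measures).
4. **Synthetic scene generator.** Seeded 64×64 surgical scenes — textured
   tissue background, bright elongated instruments, dark-red blood blobs
   whose visible area defines the label — including temporal scenarios
   where brief sub-threshold "oozing" bursts precede a sustained
   bleeding phase. Everything downstream is trainable and testable
   without clinical data.

## Worked example

Escalate a noisy confidence trace whose faint precursor bursts start at
t = 4 s and whose frank bleed plateaus from t = 10 s:

```r
library(bleedwatch)

set.seed(1)
fps <- 25
t <- (0:(16 * fps - 1)) / fps
p <- runif(length(t), 0, 0.1)                     # baseline jitter
burst <- t >= 4 & t < 10 & (floor((t - 4) * fps) %% 8) < 2
p[burst] <- runif(sum(burst), 0.5, 0.7)           # 2-frame bursts / ~300 ms
p[t >= 10] <- runif(sum(t >= 10), 0.97, 1)        # sustained bleed

spec <- design_butterworth(cutoff_hz = 5, sample_rate_hz = fps, order = 2)
trace <- update_warning(lowpass_filter(probability_series(p, fps), spec),
                        alert_config())
trace
#> Alert trace: 400 samples at 25 fps, 1 significant event(s)
#>   onsets (s): 6.08
```

The alert fires at 6.08 s — 3.92 s before the sustained bleeding phase —
because the oozing bursts keep the escalation running. Comparing such
machine events against human annotations:

```r
machine <- event_log(c(6.08, 130.4, 310.0), "machine")
human   <- event_log(c(10.0, 132.0, 305.5, 420.0), "human")
res <- match_events(machine, human, tolerance_s = 10)
c(tp = res$tp, fp = res$fp, fn = res$fn)
#> tp fp fn
#>  3  0  1
delta_stats(res)[c("median_s", "iqr_s", "lead_median_s")]
#> $median_s
#> [1] -1.6
#>
#> $iqr_s
#> [1] 4.21
#>
#> $lead_median_s
#> [1] 1.6
```

A negative median delta means the machine detected bleeding earlier than
the human reviewer (here by 1.6 s in the median). Training the network on
generated scenes is one call each:

```r
ds  <- make_frame_dataset(500, size = 64, seed = 2024)
net <- build_network(net_config(), seed = 1)      # 64×64, depth 3, base 16
fit <- train_network(net, list(train = ds[1:400], val = ds[401:500]),
                     train_config(epochs = 30, rng_seed = 7))
```

`fit$history` then holds per-epoch training losses and validation
event-detection accuracies, and `fit$network` the epoch-30 weights.

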