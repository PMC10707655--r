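# Shared fixtures: everything is generated in code at test time.

tiny_net_config <- function() {
  net_config(input_size = 16, depth = 2, base_channels = 4, hidden_units = 8)
}

tiny_dataset <- function(n = 12, seed = 11) {
  make_frame_dataset(n, size = 16, seed = seed)
}

# Confidence trace with uniform baseline noise, 2-frame oozing bursts every
# ~300 ms through the precursor window, then a sustained high plateau.
precursor_trace <- function(seed, precursor_s = 4, plateau_s = 10,
                            duration_s = 16, fps = 25,
                            burst_lo = 0.5, burst_hi = 0.7) {
  set.seed(seed)
  n <- round(duration_s * fps)
  t <- (seq_len(n) - 1) / fps
  p <- runif(n, 0, 0.1)
  per <- round(0.3 * fps)
  k <- floor((t - precursor_s) * fps + 1e-9)
  in_burst <- t >= precursor_s & t < plateau_s & (k %% per) < 2
  p[in_burst] <- runif(sum(in_burst), burst_lo, burst_hi)
  p[t >= plateau_s] <- runif(sum(t >= plateau_s), 0.97, 1.0)
  probability_series(p, fps)
}

# Align column signs of A to those of B (singular vectors are defined up
# to sign).
abs_align <- function(A, B) {
  for (j in seq_len(ncol(A))) {
    if (sum(A[, j] * B[, j]) < 0) A[, j] <- -A[, j]
  }
  A
}

# Build an alert_trace around an externally supplied warning curve, for
# exercising event extraction in isolation.
manual_trace <- function(warning, fps = 25, t0 = 0) {
  structure(list(
    filtered = probability_series(rep(0, length(warning)), fps, t0),
    warning_level = warning, events = NULL
  ), class = "alert_trace")
}
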