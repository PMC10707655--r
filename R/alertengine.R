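#' Per-frame bleeding-confidence series
#'
#' A uniformly sampled sequence of bleeding probabilities with frame-rate
#' metadata.
#'
#' @param values Numeric vector in `[0, 1]`.
#' @param fps Sampling rate in frames/second (> 0).
#' @param t0 Time of the first sample in seconds.
#' @return A `probability_series` list.
#' @export
probability_series <- function(values, fps, t0 = 0) {
  if (!is.numeric(values) || any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop_validation("values must lie in [0, 1]")
  }
  if (!is.numeric(fps) || fps <= 0) stop_validation("fps must be > 0")
  structure(list(values = pmin(pmax(as.numeric(values), 0), 1),
                 fps = fps, t0 = t0),
            class = "probability_series")
}

series_times <- function(series) {
  series$t0 + (seq_along(series$values) - 1) / series$fps
}

#' Design a causal digital Butterworth low-pass filter
#'
#' Maximally flat low-pass design (via the bilinear transform): unit DC
#' gain, magnitude 1/sqrt(2) at the cutoff, monotonically non-increasing
#' magnitude with frequency. The nominal group delay is *measured* from
#' the 50% crossing of the filter's unit-step response rather than
#' asserted.
#'
#' @param cutoff_hz Cutoff frequency in Hz (default 5).
#' @param sample_rate_hz Sampling rate in Hz; the cutoff must lie below
#'   the Nyquist frequency `sample_rate_hz / 2`.
#' @param order Filter order (>= 1; default 2).
#' @return A `filter_spec` list with transfer-function coefficients `b`,
#'   `a` and the measured `nominal_delay_ms`.
#' @examples
#' spec <- design_butterworth(5, 25, 2)
#' butter_response(spec, 5)  # ~0.7071
#' @export
design_butterworth <- function(cutoff_hz = 5, sample_rate_hz = 25, order = 2) {
  if (order < 1) stop_validation("order must be >= 1")
  if (cutoff_hz <= 0 || cutoff_hz >= sample_rate_hz / 2) {
    stop_validation("cutoff (%g Hz) must lie in (0, Nyquist = %g Hz)",
                    cutoff_hz, sample_rate_hz / 2)
  }
  bt <- signal::butter(order, cutoff_hz / (sample_rate_hz / 2), type = "low")
  spec <- structure(list(cutoff_hz = cutoff_hz,
                         sample_rate_hz = sample_rate_hz,
                         order = as.integer(order),
                         b = as.numeric(bt$b), a = as.numeric(bt$a),
                         nominal_delay_ms = NA_real_),
                    class = "filter_spec")
  spec$nominal_delay_ms <- step_delay_ms(spec)
  spec
}

# 50% crossing time of the unit-step response, linearly interpolated.
step_delay_ms <- function(spec, horizon_s = 2) {
  n <- max(16L, ceiling(horizon_s * spec$sample_rate_hz))
  y <- as.numeric(signal::filter(spec$b, spec$a, rep(1, n)))
  k <- which(y >= 0.5)[1]
  if (is.na(k)) return(NA_real_)
  frac <- if (k > 1) (0.5 - y[k - 1]) / (y[k] - y[k - 1]) else 0.5 / y[k]
  1000 * ((k - 1 + ifelse(k > 1, frac, frac - 1)) / spec$sample_rate_hz)
}

#' Magnitude response of a designed filter
#'
#' @param spec A `filter_spec`.
#' @param freq_hz Frequencies (Hz) at which to evaluate `|H(f)|`.
#' @return Numeric vector of magnitudes.
#' @export
butter_response <- function(spec, freq_hz) {
  vapply(freq_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / spec$sample_rate_hz)
    num <- sum(spec$b * z^(seq_along(spec$b) - 1))
    den <- sum(spec$a * z^(seq_along(spec$a) - 1))
    Mod(num / den)
  }, numeric(1))
}

#' Causally low-pass filter a confidence series
#'
#' Applies the designed filter in a single causal pass (the output at
#' time t uses inputs at times <= t only; no zero-phase forward-backward
#' smoothing, so the engine can run on live streams). The output is
#' clamped back to `[0, 1]`.
#'
#' @param series A [probability_series()].
#' @param spec A [design_butterworth()] filter whose sample rate matches
#'   the series' fps.
#' @return The filtered `probability_series`.
#' @export
lowpass_filter <- function(series, spec) {
  stopifnot(inherits(series, "probability_series"),
            inherits(spec, "filter_spec"))
  if (abs(series$fps - spec$sample_rate_hz) > 1e-9) {
    stop_validation("series fps (%g) does not match filter sample rate (%g)",
                    series$fps, spec$sample_rate_hz)
  }
  y <- as.numeric(signal::filter(spec$b, spec$a, series$values))
  probability_series(pmin(pmax(y, 0), 1), series$fps, series$t0)
}

#' Alert-escalation configuration
#'
#' Parameters of the parking-sensor style warning logic: any filtered
#' confidence at or above `detection_floor` counts as a "possible bleeding
#' occurrence"; while such occurrences keep recurring (no silence longer
#' than `persistence_gap_ms`), the warning level rises linearly so that
#' persistent detections saturate it in exactly `escalation_window_ms`;
#' once occurrences stop, the level decays at `decay_rate`. A warning
#' level at or above `significant_threshold` is significant bleeding.
#'
#' @param escalation_window_ms Time for persistent detections to saturate
#'   the warning level (default 2200 ms; the escalation time frame is
#'   approximately 2100-2300 ms).
#' @param detection_floor Minimum filtered confidence counted as a
#'   detection (default 0.30).
#' @param significant_threshold Warning level declared significant
#'   bleeding, in `[0.93, 0.95]` by convention (default 0.94, the band
#'   midpoint).
#' @param decay_rate Warning-level decay in units/second when detections
#'   cease (default 0.5/s).
#' @param persistence_gap_ms Maximum silence between detections for the
#'   escalation to continue (default 400 ms, covering the ~300 ms repeat
#'   cadence of pre-bleed oozing).
#' @return An `alert_config` list.
#' @export
alert_config <- function(escalation_window_ms = 2200, detection_floor = 0.30,
                         significant_threshold = 0.94, decay_rate = 0.5,
                         persistence_gap_ms = 400) {
  if (!(detection_floor > 0 && detection_floor < significant_threshold &&
        significant_threshold <= 1)) {
    stop_validation("need 0 < detection_floor < significant_threshold <= 1")
  }
  if (escalation_window_ms <= 0 || persistence_gap_ms <= 0 || decay_rate < 0) {
    stop_validation("window, gap and decay must be positive")
  }
  structure(list(escalation_window_ms = escalation_window_ms,
                 detection_floor = detection_floor,
                 significant_threshold = significant_threshold,
                 decay_rate = decay_rate,
                 persistence_gap_ms = persistence_gap_ms),
            class = "alert_config")
}

#' Escalate filtered confidences into a warning level
#'
#' Implements the parking-sensor escalation: the warning level is a
#' bounded accumulation of recurring supra-floor detections. At each
#' sample, if a detection occurred within the trailing persistence gap,
#' the level rises by `dt / escalation_window`; otherwise it decays by
#' `decay_rate * dt`. The level is clipped to `[0, 1]`, is monotone
#' non-decreasing while detections persist, and saturates in exactly one
#' escalation window under sustained full confidence. Detections are
#' deliberately dichotomic above the floor: occurrences count even with a
#' small confidence percentage, which is what lets repeated faint oozing
#' escalate ahead of a frank bleeding event.
#'
#' @param filtered A filtered [probability_series()].
#' @param cfg An [alert_config()].
#' @return An `alert_trace` list: `filtered`, `warning_level` (numeric in
#'   `[0, 1]`), `events` (data frame from [detect_events()]).
#' @export
update_warning <- function(filtered, cfg = alert_config()) {
  stopifnot(inherits(filtered, "probability_series"),
            inherits(cfg, "alert_config"))
  v <- filtered$values
  dt <- 1 / filtered$fps
  rise <- dt / (cfg$escalation_window_ms / 1000)
  gap_s <- cfg$persistence_gap_ms / 1000
  w <- numeric(length(v))
  level <- 0
  last_det <- -Inf
  for (i in seq_along(v)) {
    t <- (i - 1) * dt
    if (v[i] >= cfg$detection_floor) last_det <- t
    if (t - last_det <= gap_s) {
      level <- min(1, level + rise)
    } else {
      level <- max(0, level - cfg$decay_rate * dt)
    }
    w[i] <- level
  }
  trace <- structure(list(filtered = filtered, warning_level = w,
                          events = NULL),
                     class = "alert_trace")
  trace$events <- detect_events(trace, cfg)
  trace
}

#' Extract dichotomic bleeding events from a warning trace
#'
#' One event per upward crossing of the significant-bleeding threshold:
#' the onset is the first sample at or above the threshold after having
#' been below it. Events are recorded dichotomically (flag = 1).
#'
#' @param trace An `alert_trace` from [update_warning()].
#' @param cfg An [alert_config()].
#' @return Data frame with columns `onset_s` (strictly increasing) and
#'   `flag` (always 1).
#' @export
detect_events <- function(trace, cfg = alert_config()) {
  stopifnot(inherits(trace, "alert_trace"))
  w <- trace$warning_level
  times <- series_times(trace$filtered)
  above <- w >= cfg$significant_threshold
  onset_idx <- which(above & !c(FALSE, above[-length(above)]))
  data.frame(onset_s = times[onset_idx],
             flag = rep(1L, length(onset_idx)))
}

#' @export
print.alert_trace <- function(x, ...) {
  cat(sprintf("Alert trace: %d samples at %g fps, %d significant event(s)\n",
              length(x$warning_level), x$filtered$fps, nrow(x$events)))
  if (nrow(x$events) > 0) {
    cat("  onsets (s):", paste(sprintf("%.2f", x$events$onset_s),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.alert_trace <- function(x, ...) {
  times <- series_times(x$filtered)
  plot(times, x$filtered$values, type = "l", col = "grey50",
       xlab = "time (s)", ylab = "confidence / warning level", ylim = c(0, 1),
       main = "Bleeding confidence and escalated warning")
  graphics::lines(times, x$warning_level, col = "firebrick", lwd = 2)
  if (nrow(x$events) > 0) {
    graphics::abline(v = x$events$onset_s, lty = 2, col = "firebrick")
  }
  invisible(x)
}
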