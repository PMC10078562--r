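#' Respiration filter settings
#'
#' Linear-phase FIR band-pass design used on breathing traces: passband
#' 0.5-1 Hz, 8000 coefficients, designed at the 100 Hz working rate. The
#' acquisition software's `Q = 0.70700` has no standard FIR meaning and is
#' carried as metadata only; the filter is fully determined by the cutoffs,
#' tap count and rate.
#'
#' @param low_cut,high_cut passband edges, Hz (0 < low < high < rate/2).
#' @param n_coefficients FIR order (taps - 1; default 8000).
#' @param design_rate sampling rate the filter is designed for, Hz.
#' @param q_metadata carried but unused.
#' @return an object of class `filter_settings`.
#' @export
filter_settings <- function(low_cut = 0.5, high_cut = 1.0,
                            n_coefficients = 8000, design_rate = 100,
                            q_metadata = 0.707) {
  .cop_assert(low_cut > 0 && low_cut < high_cut &&
                high_cut < design_rate / 2,
              "copstab_config_error",
              "need 0 < low_cut < high_cut < design_rate/2")
  .cop_assert(n_coefficients >= 2, "copstab_config_error",
              "n_coefficients must be >= 2")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 n_coefficients = as.integer(n_coefficients),
                 design_rate = design_rate, q_metadata = q_metadata),
            class = "filter_settings")
}

#' Breathing-rate detector settings
#'
#' Positive-peak detector configuration: baseline smoothing window, a
#' hysteresis (noise-rejection) threshold expressed as a fraction of the
#' peak-to-peak range, and physiological rate bounds used to discard
#' implausible breath-to-breath intervals.
#'
#' @param baseline_window_ms baseline smoothing window, milliseconds.
#' @param noise_rejection hysteresis threshold as a fraction of the
#'   peak-to-peak range (0-1).
#' @param min_rate,max_rate admissible breathing rates, breaths/min.
#' @return an object of class `rate_detector_settings`.
#' @export
rate_detector_settings <- function(baseline_window_ms = 25,
                                   noise_rejection = 0.05,
                                   min_rate = 6, max_rate = 20) {
  .cop_assert(noise_rejection > 0 && noise_rejection < 1,
              "copstab_config_error", "noise_rejection must be in (0,1)")
  .cop_assert(min_rate > 0 && min_rate < max_rate, "copstab_config_error",
              "need 0 < min_rate < max_rate")
  .cop_assert(baseline_window_ms > 0, "copstab_config_error",
              "baseline_window_ms must be > 0")
  structure(list(baseline_window_ms = baseline_window_ms,
                 noise_rejection = noise_rejection,
                 min_rate = min_rate, max_rate = max_rate),
            class = "rate_detector_settings")
}

# centered moving average with edge replication; exact on constants
.smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L || length(x) <= width) return(x)
  half <- width %/% 2
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[
    (half + 1):(half + length(x))]
}

#' Resample (downsample) a respiration signal
#'
#' Anti-alias low-pass filtering (zero-phase, linear-phase FIR run forward
#' and backward) followed by interpolation onto the target grid. Duration
#' is preserved to within one output sample. Upsampling is not supported.
#'
#' @param signal a [resp_signal()].
#' @param target_rate new sampling rate, Hz (<= original rate).
#' @return a [resp_signal()] at `target_rate`.
#' @export
resample_signal <- function(signal, target_rate) {
  validate_resp_signal(signal)
  fs <- signal$sampling_rate
  .cop_assert(target_rate <= fs, "copstab_config_error",
              "upsampling (%g -> %g Hz) is unsupported", fs, target_rate)
  x <- signal$samples
  if (target_rate < fs) {
    # anti-alias at 90% of the new Nyquist; the symmetric FIR kernel is
    # applied as one centered convolution (zero phase by symmetry) with
    # edge-replicated padding, normalized to exactly unit DC gain
    order <- max(64L, 10L * as.integer(ceiling(fs / target_rate)))
    if (order %% 2 == 1) order <- order + 1L
    h <- as.numeric(signal::fir1(order, 0.9 * target_rate / fs,
                                 type = "low"))
    h <- h / sum(h)
    half <- order %/% 2
    xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
    x <- as.numeric(stats::filter(xp, h, sides = 2))[
      (half + 1):(half + length(x))]
  }
  n_out <- round(length(signal$samples) * target_rate / fs)
  t_out <- (seq_len(n_out) - 1) / target_rate
  t_in <- (seq_along(x) - 1) / fs
  y <- stats::approx(t_in, x, xout = pmin(t_out, max(t_in)))$y
  resp_signal(samples = y, sampling_rate = target_rate,
              condition = signal$condition, phase = signal$phase,
              window_bounds = signal$window_bounds)
}

#' FIR band-pass filter a respiration signal
#'
#' Applies the linear-phase FIR band-pass of [filter_settings()] with full
#' group-delay compensation, so the output is time-aligned with the input
#' and has the same length. The `n/2` samples at each end are influenced by
#' zero padding and are flagged via the `edge_samples` attribute.
#'
#' @param signal a [resp_signal()] at the design rate.
#' @param settings a [filter_settings()].
#' @return a band-passed [resp_signal()] (attribute `edge_samples` gives
#'   the per-end transient length in samples).
#' @export
fir_bandpass <- function(signal, settings = filter_settings()) {
  validate_resp_signal(signal)
  .cop_assert(abs(signal$sampling_rate - settings$design_rate) < 1e-9,
              "copstab_config_error",
              "signal at %g Hz but filter designed for %g Hz",
              signal$sampling_rate, settings$design_rate)
  n <- length(signal$samples)
  .cop_assert(n > settings$n_coefficients, "copstab_length_error",
              "signal (%d samples) shorter than the %d-tap filter",
              n, settings$n_coefficients + 1)
  nyq <- settings$design_rate / 2
  h <- as.numeric(signal::fir1(settings$n_coefficients,
                               c(settings$low_cut, settings$high_cut) / nyq,
                               type = "pass"))
  gd <- settings$n_coefficients %/% 2   # linear phase: constant group delay
  y_full <- signal::fftfilt(h, c(signal$samples, rep(0, gd)))
  y <- y_full[(gd + 1):(gd + n)]
  out <- resp_signal(samples = y, sampling_rate = signal$sampling_rate,
                     condition = signal$condition, phase = signal$phase,
                     window_bounds = signal$window_bounds)
  attr(out, "edge_samples") <- gd
  attr(out, "filtered") <- TRUE
  out
}

#' Estimate breathing rate in a balance window
#'
#' Positive-peak detection with a hysteresis threshold equal to
#' `noise_rejection` times the peak-to-peak range inside the window, on a
#' baseline-smoothed copy of the signal. Inter-peak intervals outside the
#' admissible band `[60/max_rate, 60/min_rate]` seconds are discarded; the
#' rate is `60 / mean(retained intervals)`. Fewer than two detected peaks,
#' or no retained interval, raises an undefined-rate error rather than
#' returning zero. The estimate is invariant to amplitude scaling because
#' the threshold is range-relative.
#'
#' The estimator expects the resampled trace, not the band-passed one: a
#' signal band-limited to 0.5-1 Hz oscillates at least every 2 s and so
#' cannot present one peak per breath at physiological rates (0.1-0.33
#' Hz); its fundamental is in the filter's stopband. See the methods
#' vignette for the full argument.
#'
#' @param signal a [resample_signal()]-processed [resp_signal()].
#' @param settings a [rate_detector_settings()].
#' @param window `c(start, end)` seconds inside the record.
#' @return breathing rate in breaths/min.
#' @export
estimate_breathing_rate <- function(signal,
                                    settings = rate_detector_settings(),
                                    window = NULL) {
  validate_resp_signal(signal)
  fs <- signal$sampling_rate
  n <- length(signal$samples)
  if (is.null(window)) window <- c(0, n / fs)
  .cop_assert(window[1] >= 0 && window[2] <= n / fs + 1e-9 &&
                window[1] < window[2],
              "copstab_config_error", "window outside record")
  i0 <- max(1L, floor(window[1] * fs) + 1L)
  i1 <- min(n, ceiling(window[2] * fs))
  y <- .smooth_ma(signal$samples[i0:i1],
                  round(settings$baseline_window_ms / 1000 * fs))
  p2p <- diff(range(y))
  .cop_assert(p2p > 0, "copstab_rate_error",
              "flat signal in window: rate undefined")
  delta <- settings$noise_rejection * p2p
  # alternating-extrema hysteresis walk; record positive peaks only
  peaks <- integer(0)
  cmax <- y[1]; imax <- 1L
  cmin <- y[1]
  rising <- TRUE
  for (i in seq_along(y)) {
    v <- y[i]
    if (rising) {
      if (v > cmax) { cmax <- v; imax <- i }
      if (cmax - v >= delta) {       # confirmed local maximum
        peaks <- c(peaks, imax)
        rising <- FALSE
        cmin <- v
      }
    } else {
      if (v < cmin) cmin <- v
      if (v - cmin >= delta) {       # confirmed local minimum
        rising <- TRUE
        cmax <- v; imax <- i
      }
    }
  }
  if (length(peaks) < 2) {
    .cop_error("copstab_rate_error",
               "fewer than 2 suprathreshold peaks: rate undefined")
  }
  intervals <- diff(peaks) / fs
  lo <- 60 / settings$max_rate
  hi <- 60 / settings$min_rate
  kept <- intervals[intervals >= lo & intervals <= hi]
  if (length(kept) == 0) {
    .cop_error("copstab_rate_error",
               "no inter-peak interval inside %g-%g breaths/min: rate undefined",
               settings$min_rate, settings$max_rate)
  }
  60 / mean(kept)
}

#' Preprocess a raw respiration trace
#'
#' Convenience wrapper chaining [resample_signal()] to the filter design
#' rate and [fir_bandpass()]. Note that the band-passed output isolates
#' the 0.5-1 Hz band and is not the input for
#' [estimate_breathing_rate()], which runs on the resampled trace.
#'
#' @param signal a raw [resp_signal()].
#' @param settings a [filter_settings()].
#' @return a preprocessed [resp_signal()].
#' @export
preprocess_resp <- function(signal, settings = filter_settings()) {
  fir_bandpass(resample_signal(signal, settings$design_rate), settings)
}
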