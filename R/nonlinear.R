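#' Embedding specification
#'
#' Delay and dimension for state-space reconstruction of a scalar series by
#' the method of time delays.
#'
#' @param delay_T time delay in samples (>= 1).
#' @param dimension_dE embedding dimension (>= 1).
#' @param direction optional sway-direction label (`"ML"` or `"AP"`).
#' @return an object of class `embedding_spec`.
#' @export
embedding_spec <- function(delay_T, dimension_dE, direction = NA_character_) {
  .cop_assert(delay_T >= 1 && delay_T == round(delay_T),
              "copstab_config_error", "delay_T must be an integer >= 1")
  .cop_assert(dimension_dE >= 1 && dimension_dE == round(dimension_dE),
              "copstab_config_error", "dimension_dE must be an integer >= 1")
  structure(list(delay_T = as.integer(delay_T),
                 dimension_dE = as.integer(dimension_dE),
                 direction = direction),
            class = "embedding_spec")
}

#' Average mutual information and first-minimum delay
#'
#' Estimates the average mutual information AMI(tau) between a series and
#' its lag-tau copy from a joint equal-width histogram (`n_bins` bins per
#' margin, nats), for tau = 0..`max_lag`, and selects the embedding delay
#' as the first interior minimum: the smallest tau >= 1 with
#' `AMI(tau) < AMI(tau-1)` and `AMI(tau) <= AMI(tau+1)`.
#'
#' Two guarded fallbacks (reported in `method`): if the series carries no
#' lag-1 dependence (`AMI(1) < 0.1 AMI(0)`, as for white noise) a minimum
#' location is meaningless and the 1/e rule is used directly; the 1/e rule
#' returns the first tau with `AMI(tau) < AMI(1)/e`, and if that never
#' happens, `max_lag` with `method = "max_lag"`.
#'
#' @param series numeric scalar series (non-constant).
#' @param max_lag largest lag evaluated, samples.
#' @param n_bins histogram bins per margin (>= 4; default 64).
#' @return list with `lags`, `ami` (nats), `first_minimum` (samples) and
#'   `method` (`"interior_minimum"`, `"one_over_e"` or `"max_lag"`).
#' @export
average_mutual_information <- function(series, max_lag, n_bins = 64) {
  series <- as.numeric(series)
  .cop_assert(all(is.finite(series)), "copstab_data_error",
              "series must be finite")
  .cop_assert(n_bins >= 4, "copstab_config_error", "n_bins must be >= 4")
  .cop_assert(max_lag >= 1 && max_lag < length(series) - 1,
              "copstab_config_error", "max_lag out of range")
  rng <- range(series)
  .cop_assert(diff(rng) > 0, "copstab_degenerate_error",
              "constant series has a degenerate amplitude distribution")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(series, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  n <- length(series)
  ami <- vapply(0:max_lag, function(tau) {
    b1 <- bin[seq_len(n - tau)]
    b2 <- bin[(1 + tau):n]
    joint <- tabulate((b1 - 1L) * n_bins + b2, nbins = n_bins * n_bins)
    joint <- joint / sum(joint)
    px <- tabulate(b1, nbins = n_bins) / length(b1)
    py <- tabulate(b2, nbins = n_bins) / length(b2)
    prod_p <- as.numeric(outer(px, py))
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / prod_p[nz]))
  }, numeric(1))
  # Minimum detection runs on a lightly smoothed copy (3-point moving
  # average): the raw histogram AMI carries bin-boundary fine structure
  # that would otherwise trigger spurious interior minima well before the
  # true valley. The returned curve is the raw one.
  a <- ami  # index shift: a[tau + 1] == AMI(tau)
  sm <- as.numeric(stats::filter(c(a[1], a, a[length(a)]),
                                 rep(1 / 3, 3), sides = 2))[
                                   2:(length(a) + 1)]
  first_min <- NA_integer_
  method <- "interior_minimum"
  if (a[2] >= 0.1 * a[1]) {
    for (tau in 1:(max_lag - 1)) {
      if (sm[tau + 1] < sm[tau] && sm[tau + 1] <= sm[tau + 2]) {
        first_min <- tau
        break
      }
    }
  }
  if (is.na(first_min)) {
    method <- "one_over_e"
    below <- which(a[-1] < a[2] / exp(1))
    if (length(below) > 0) {
      first_min <- below[1]
    } else {
      first_min <- max_lag
      method <- "max_lag"
    }
  }
  list(lags = 0:max_lag, ami = ami, first_minimum = as.integer(first_min),
       method = method)
}

#' Global false nearest neighbors
#'
#' Kennel-style selection of the embedding dimension: for each candidate
#' dimension d, the fraction of nearest-neighbor pairs whose distance is
#' inflated by more than `r_tol` (or pushed beyond `a_tol` times the series
#' standard deviation) when the (d+1)-th delay coordinate is added. The
#' chosen dimension is the smallest d with fraction below `threshold`; if
#' no dimension qualifies (as for noise, which has no finite embedding),
#' `max_dim` is returned with `saturated = TRUE`.
#'
#' @param series numeric scalar series.
#' @param delay_T embedding delay in samples.
#' @param max_dim largest dimension tested.
#' @param r_tol distance-inflation ratio (Kennel's first criterion).
#' @param a_tol loneliness ratio relative to the series scale (second
#'   criterion).
#' @param threshold acceptable false-neighbor fraction.
#' @param theiler temporal exclusion window for neighbor candidates,
#'   samples.
#' @return list with `fnn_fraction` (per dimension 1..max_dim),
#'   `chosen_dE` and `saturated`.
#' @export
false_nearest_neighbors <- function(series, delay_T, max_dim = 10,
                                    r_tol = 15, a_tol = 2,
                                    threshold = 0.01, theiler = 0) {
  series <- as.numeric(series)
  .cop_assert(length(series) > (max_dim + 1) * delay_T + 10,
              "copstab_length_error",
              "series too short to embed at max_dim")
  scale <- sd(series)
  .cop_assert(scale > 0, "copstab_degenerate_error", "constant series")
  frac <- .fnn_fractions_cpp(series, as.integer(delay_T),
                             as.integer(max_dim), r_tol, a_tol, scale,
                             as.integer(theiler))
  ok <- which(!is.na(frac) & frac < threshold)
  if (length(ok) > 0) {
    list(fnn_fraction = frac, chosen_dE = as.integer(ok[1]),
         saturated = FALSE)
  } else {
    list(fnn_fraction = frac, chosen_dE = as.integer(max_dim),
         saturated = TRUE)
  }
}

#' Delay embedding
#'
#' Reconstructs state-space points
#' `X(t) = [x(t), x(t+T), ..., x(t + (dE-1) T)]` from a scalar series; the
#' result has `M = N - (dE - 1) T` rows.
#'
#' @param series numeric scalar series.
#' @param spec an [embedding_spec()].
#' @return numeric matrix with `M` rows and `dE` columns.
#' @export
delay_embed <- function(series, spec) {
  series <- as.numeric(series)
  T <- spec$delay_T
  dE <- spec$dimension_dE
  N <- length(series)
  M <- N - (dE - 1) * T
  .cop_assert(M >= 1, "copstab_length_error",
              "series of length %d too short for dE=%d, T=%d", N, dE, T)
  out <- matrix(0, nrow = M, ncol = dE)
  for (m in seq_len(dE)) {
    out[, m] <- series[(1 + (m - 1) * T):((m - 1) * T + M)]
  }
  out
}

#' Mean period of a series
#'
#' Reciprocal of the power-weighted mean frequency of the one-sided
#' periodogram (DC excluded). Used as the temporal (Theiler) exclusion
#' window when searching nearest neighbors.
#'
#' @param series numeric scalar series (length >= 64).
#' @param sampling_rate sampling rate, Hz.
#' @return mean period in seconds.
#' @export
mean_period <- function(series, sampling_rate) {
  series <- as.numeric(series)
  .cop_assert(length(series) >= 64, "copstab_length_error",
              "need >= 64 samples for a spectral mean period")
  n <- length(series)
  spec <- Mod(fft(series - mean(series)))^2
  k <- seq_len(floor(n / 2))        # positive frequencies, DC excluded
  freqs <- k * sampling_rate / n
  power <- spec[k + 1]
  tot <- sum(power)
  .cop_assert(tot > 0, "copstab_degenerate_error",
              "zero spectral power (constant series)")
  1 / (sum(power * freqs) / tot)
}

#' Rosenstein largest-Lyapunov-exponent divergence curve
#'
#' For every point of the delay-embedded series the nearest neighbor with
#' temporal separation greater than the mean period of the signal is found;
#' `d_j(i)` is the Euclidean distance between the pair i steps later, and
#' the curve value at time `i / fs` is the mean of `ln d_j(i)` over all
#' pairs still inside the series. The largest Lyapunov exponent is the
#' ordinary-least-squares slope of the curve over `fit_window` (inclusive),
#' in 1/s; a larger exponent means faster divergence of neighboring
#' trajectories, i.e. lower local dynamic stability.
#'
#' @param series numeric scalar series.
#' @param spec an [embedding_spec()].
#' @param sampling_rate samples per second (use 1 for map iterations).
#' @param track_time how long pairs are tracked, seconds.
#' @param fit_window `c(lo, hi)` in seconds; the slope uses all curve
#'   samples with `lo <= t <= hi`.
#' @param theiler temporal exclusion window in samples; defaults to the
#'   [mean_period()] of the series converted to samples.
#' @return an object of class `divergence_curve`: `times`,
#'   `mean_log_divergence`, `n_pairs`, `fit_window`, `slope` (the LyE,
#'   1/s), `intercept`, `delay_T`, `dimension_dE`.
#' @export
rosenstein_lye <- function(series, spec, sampling_rate,
                           track_time = 1.0, fit_window = c(0, 0.75),
                           theiler = NULL) {
  .cop_assert(track_time >= fit_window[2], "copstab_config_error",
              "track_time must cover the fit window")
  emb <- delay_embed(series, spec)
  .cop_assert(nrow(emb) >= 100, "copstab_length_error",
              "embedded point count %d < 100", nrow(emb))
  if (is.null(theiler)) {
    theiler <- round(mean_period(series, sampling_rate) * sampling_rate)
  }
  theiler <- max(1L, min(as.integer(theiler), nrow(emb) - 2L))
  nn <- .nn_theiler_cpp(emb, theiler)
  ksteps <- as.integer(round(track_time * sampling_rate))
  curve <- .divergence_curve_cpp(emb, nn$index, ksteps)
  .cop_assert(curve$n_pairs[1] > 0, "copstab_degenerate_error",
              "all neighbor pairs excluded (zero initial distances)")
  times <- (0:ksteps) / sampling_rate
  sel <- times >= fit_window[1] & times <= fit_window[2] &
    !is.na(curve$mean_log)
  .cop_assert(sum(sel) >= 2, "copstab_degenerate_error",
              "fewer than 2 curve samples inside the fit window")
  fit <- stats::lm.fit(cbind(1, times[sel]), curve$mean_log[sel])
  structure(list(times = times,
                 mean_log_divergence = curve$mean_log,
                 n_pairs = curve$n_pairs,
                 fit_window = fit_window,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 delay_T = spec$delay_T,
                 dimension_dE = spec$dimension_dE,
                 theiler = theiler),
            class = "divergence_curve")
}

#' @export
print.divergence_curve <- function(x, ...) {
  cat(sprintf("<divergence_curve> T=%d dE=%d: LyE = %.4f 1/s (fit %g-%g s, %d pairs)\n",
              x$delay_T, x$dimension_dE, x$slope, x$fit_window[1],
              x$fit_window[2], x$n_pairs[1]))
  invisible(x)
}

#' Local dynamic stability of one COP trial
#'
#' Full per-trial stability analysis of one sway direction: the embedding
#' delay is selected per trial from the first minimum of the average mutual
#' information of that direction's coordinate, the embedding dimension is
#' fixed (default 6) or chosen by false nearest neighbors when
#' `fixed_dE = "AUTO"`, and the Rosenstein divergence curve is fitted over
#' 0-0.75 s.
#'
#' @param trial a [cop_trial()].
#' @param direction `"AP"` (anterior-posterior, y) or `"ML"`
#'   (medio-lateral, x).
#' @param fixed_dE embedding dimension, or `"AUTO"` for FNN selection.
#' @param ami_max_lag,ami_bins AMI settings for delay selection.
#' @param track_time,fit_window passed to [rosenstein_lye()].
#' @return list with `spec` (the [embedding_spec()] used), `curve` (the
#'   [rosenstein_lye()] result) and `lye` (the slope, 1/s).
#' @export
trial_lye <- function(trial, direction = c("AP", "ML"), fixed_dE = 6,
                      ami_max_lag = 150, ami_bins = 16,
                      track_time = 1.0, fit_window = c(0, 0.75)) {
  validate_cop_trial(trial)
  direction <- match.arg(direction)
  series <- if (direction == "AP") trial$y else trial$x
  max_lag <- min(ami_max_lag, length(series) %/% 4)
  ami <- average_mutual_information(series, max_lag = max_lag,
                                    n_bins = ami_bins)
  delay <- max(1L, ami$first_minimum)
  if (identical(fixed_dE, "AUTO")) {
    fnn <- false_nearest_neighbors(series, delay)
    dE <- fnn$chosen_dE
  } else {
    dE <- as.integer(fixed_dE)
  }
  # keep the embedding feasible for short trials / large AMI delays
  max_delay <- max(1L, (length(series) - 100L) %/% max(1L, dE - 1L))
  delay <- min(delay, max_delay)
  spec <- embedding_spec(delay, dE, direction)
  curve <- rosenstein_lye(series, spec, trial$sampling_rate,
                          track_time = track_time, fit_window = fit_window)
  list(spec = spec, curve = curve, lye = curve$slope)
}
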