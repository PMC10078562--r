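#' Simulation configuration for a synthetic inhalation-challenge cohort
#'
#' Builds and validates the configuration driving [simulate_cohort()]. The
#' defaults emulate the study design the package targets: 10 subjects, two
#' inhalation types (normal air vs 7.5% CO2-enriched air), balance trials at
#' 5, 10 and 15 minutes of the inhalation period plus a post-inhalation
#' block, five 30-s quiet-standing repetitions per block, COP sampled at
#' 50 Hz (1500 samples, i.e. 1499 increments per trial).
#'
#' The per-axis COP model is a mean-reverting (Ornstein-Uhlenbeck) process
#' plus a chaotic component (Lorenz first coordinate, standardized) whose
#' amplitude is `chaos_blend_gain` times the stationary standard deviation
#' of the mean-reverting part, all multiplied by a log-normal
#' subject-level multiplier. The diffusion scale `ou_noise_scale` controls
#' sway path length; the (dimensionless) chaotic blend ratio controls
#' local dynamic stability. Expressing the blend relative to the postural
#' noise amplitude keeps the two dials orthogonal: raising the diffusion
#' under one condition does not dilute its injected stability effect.
#'
#' @param n_subjects number of subjects (default 10).
#' @param inhalation_types character vector of condition labels.
#' @param timepoints character vector of inhalation-time labels.
#' @param reps_per_timepoint repetitions per design cell (default 5).
#' @param trial_duration trial length in seconds (default 30).
#' @param cop_sampling_rate COP sampling rate in Hz (default 50).
#' @param ou_reversion mean-reversion rate of the sway process, 1/s.
#' @param ou_noise_scale named numeric, diffusion scale in mm/sqrt(s) per
#'   inhalation type.
#' @param chaos_blend_gain named numeric per inhalation type: amplitude of
#'   the chaotic component as a ratio of the stationary mean-reverting
#'   amplitude (dimensionless).
#' @param subject_sd standard deviation (log scale) of the between-subject
#'   log-normal multiplier.
#' @param resp_rate_mean named list (one entry per inhalation type) of named
#'   numerics with elements `DURING` and `POST`: mean breathing rate in
#'   breaths/min per condition and phase.
#' @param resp_noise relative cycle-length/amplitude jitter of the simulated
#'   respiration traces.
#' @param seed root integer seed; every trial's RNG stream is derived from
#'   it deterministically.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 10,
                              inhalation_types = c("AIR", "CO2"),
                              timepoints = c("T5", "T10", "T15", "POST"),
                              reps_per_timepoint = 5,
                              trial_duration = 30,
                              cop_sampling_rate = 50,
                              ou_reversion = 1.0,
                              ou_noise_scale = c(AIR = 1.5, CO2 = 1.8),
                              chaos_blend_gain = c(AIR = 0.8, CO2 = 1.6),
                              subject_sd = 0.15,
                              resp_rate_mean = list(
                                AIR = c(DURING = 12.10, POST = 10.96),
                                CO2 = c(DURING = 15.00, POST = 10.71)),
                              resp_noise = 0.05,
                              seed = 20221006) {
  cfg <- structure(list(
    n_subjects = n_subjects,
    inhalation_types = as.character(inhalation_types),
    timepoints = as.character(timepoints),
    reps_per_timepoint = reps_per_timepoint,
    trial_duration = trial_duration,
    cop_sampling_rate = cop_sampling_rate,
    ou_reversion = ou_reversion,
    ou_noise_scale = ou_noise_scale,
    chaos_blend_gain = chaos_blend_gain,
    subject_sd = subject_sd,
    resp_rate_mean = resp_rate_mean,
    resp_noise = resp_noise,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname simulation_config
#' @param config object to validate.
#' @export
validate_sim_config <- function(config) {
  .cop_assert(inherits(config, "sim_config"), "copstab_config_error",
              "not a sim_config object")
  with(config, {
    .cop_assert(is.numeric(n_subjects) && n_subjects >= 1,
                "copstab_config_error", "n_subjects must be >= 1")
    .cop_assert(is.numeric(reps_per_timepoint) && reps_per_timepoint >= 1,
                "copstab_config_error", "reps_per_timepoint must be >= 1")
    .cop_assert(length(inhalation_types) >= 1 &&
                  !anyDuplicated(inhalation_types),
                "copstab_config_error", "inhalation_types must be unique labels")
    .cop_assert(length(timepoints) >= 1 && !anyDuplicated(timepoints),
                "copstab_config_error", "timepoints must be unique labels")
    .cop_assert(is.numeric(trial_duration) && trial_duration > 0,
                "copstab_config_error", "trial_duration must be > 0")
    .cop_assert(is.numeric(cop_sampling_rate) && cop_sampling_rate > 0,
                "copstab_config_error", "cop_sampling_rate must be > 0")
    .cop_assert(is.numeric(ou_reversion) && ou_reversion > 0,
                "copstab_config_error", "ou_reversion must be > 0")
    .cop_assert(all(ou_noise_scale >= 0) && all(chaos_blend_gain >= 0),
                "copstab_config_error", "noise scales must be >= 0")
    .cop_assert(is.numeric(subject_sd) && subject_sd >= 0,
                "copstab_config_error", "subject_sd must be >= 0")
    .cop_assert(is.numeric(resp_noise) && resp_noise >= 0,
                "copstab_config_error", "resp_noise must be >= 0")
    for (fld in c("ou_noise_scale", "chaos_blend_gain", "resp_rate_mean")) {
      keys <- names(config[[fld]])
      .cop_assert(all(inhalation_types %in% keys), "copstab_config_error",
                  "%s must have an entry for every inhalation type", fld)
    }
    for (ty in inhalation_types) {
      .cop_assert(all(c("DURING", "POST") %in% names(resp_rate_mean[[ty]])),
                  "copstab_config_error",
                  "resp_rate_mean[[%s]] needs DURING and POST entries", ty)
    }
    .cop_assert(is.numeric(seed) && seed == round(seed),
                "copstab_config_error", "seed must be an integer")
  })
  config
}

.subject_ids <- function(config) {
  sprintf("S%02d", seq_len(config$n_subjects))
}

.subject_multiplier <- function(config, subject_index) {
  .with_seed(.mix_seed(config$seed, 7L, subject_index),
             rlnorm(1, meanlog = 0, sdlog = config$subject_sd))
}

.design_index <- function(config, subject, inhalation_type, timepoint) {
  ids <- .subject_ids(config)
  if (is.numeric(subject)) subject <- ids[subject]
  si <- match(subject, ids)
  ti <- match(inhalation_type, config$inhalation_types)
  pi <- match(timepoint, config$timepoints)
  .cop_assert(!is.na(si), "copstab_design_error", "unknown subject '%s'", subject)
  .cop_assert(!is.na(ti), "copstab_design_error",
              "unknown inhalation type '%s'", inhalation_type)
  .cop_assert(!is.na(pi), "copstab_design_error",
              "unknown timepoint '%s'", timepoint)
  list(subject = ids[si], si = si, ti = ti, pi = pi)
}

# exact discretization of dX = -theta X dt + sigma dW
.ou_series <- function(n, dt, theta, sigma) {
  a <- exp(-theta * dt)
  step_sd <- sigma * sqrt((1 - a^2) / (2 * theta))
  as.numeric(stats::filter(rnorm(n, 0, step_sd), a, method = "recursive"))
}

# Standardized Lorenz first coordinate, random initial state, for blending.
# 0.04 time units per sample (2 tu/s at 50 Hz) places the chaotic
# divergence (about 1.8 nats/s) inside the 0-0.75 s fit window of the
# stability stage, so the blend ratio acts as an effective stability dial.
.chaos_component <- function(n) {
  x0 <- runif(3, c(-15, -15, 10), c(15, 15, 40))
  n_trans <- 300L
  xyz <- .lorenz_rk4_cpp(10, 28, 8 / 3, 0.04, n + n_trans,
                         x0[1], x0[2], x0[3])
  x <- xyz[(n_trans + 1):(n_trans + n), 1]
  (x - mean(x)) / max(sd(x), .Machine$double.eps)
}

#' Simulate one quiet-standing COP trial
#'
#' Generates a two-axis COP recording under the generative model described
#' in [simulation_config()]. The trial is a pure function of
#' `(config$seed, subject, inhalation_type, timepoint, rep, seed_offset)`.
#'
#' @param config a [simulation_config()] object.
#' @param subject subject id (e.g. `"S01"`) or index.
#' @param inhalation_type,timepoint design labels (members of the config's
#'   design sets).
#' @param rep repetition number within the timepoint block.
#' @param seed_offset extra integer folded into the trial seed (used to
#'   produce independent replicate cohorts).
#' @return a [cop_trial()] object.
#' @export
simulate_cop_trial <- function(config, subject, inhalation_type, timepoint,
                               rep = 1L, seed_offset = 0L) {
  validate_sim_config(config)
  ix <- .design_index(config, subject, inhalation_type, timepoint)
  n <- round(config$trial_duration * config$cop_sampling_rate)
  .cop_assert(n >= 2, "copstab_config_error",
              "trial duration x sampling rate must give >= 2 samples")
  dt <- 1 / config$cop_sampling_rate
  sigma <- config$ou_noise_scale[[inhalation_type]]
  gain <- config$chaos_blend_gain[[inhalation_type]]
  mult <- .subject_multiplier(config, ix$si)
  trial_seed <- .mix_seed(config$seed, 11L, ix$si, ix$ti, ix$pi, rep,
                          seed_offset)
  ou_stat_sd <- sigma / sqrt(2 * config$ou_reversion)
  xy <- .with_seed(trial_seed, {
    lapply(1:2, function(axis) {
      ou <- .ou_series(n, dt, config$ou_reversion, sigma)
      ch <- if (gain > 0) gain * ou_stat_sd * .chaos_component(n)
            else numeric(n)
      mult * (ou + ch)
    })
  })
  cop_trial(subject = ix$subject, inhalation_type = inhalation_type,
            timepoint = timepoint, rep = rep,
            sampling_rate = config$cop_sampling_rate,
            x = xy[[1]], y = xy[[2]])
}

#' Simulate a full balanced cohort
#'
#' Generates every trial of the balanced design
#' `n_subjects x inhalation_types x timepoints x reps_per_timepoint`, and a
#' ground-truth table recording each cell's generating parameters for
#' parameter-recovery tests.
#'
#' @inheritParams simulate_cop_trial
#' @param seed_offset integer folded into every trial seed.
#' @return list with elements `trials` (list of [cop_trial()] objects) and
#'   `truth` (data.frame of generating parameters per subject x type x
#'   timepoint cell).
#' @export
simulate_cohort <- function(config = simulation_config(), seed_offset = 0L) {
  validate_sim_config(config)
  ids <- .subject_ids(config)
  design <- expand.grid(rep = seq_len(config$reps_per_timepoint),
                        timepoint = config$timepoints,
                        inhalation_type = config$inhalation_types,
                        subject = ids,
                        stringsAsFactors = FALSE)
  trials <- lapply(seq_len(nrow(design)), function(i) {
    simulate_cop_trial(config, design$subject[i], design$inhalation_type[i],
                       design$timepoint[i], design$rep[i], seed_offset)
  })
  cells <- unique(design[c("subject", "inhalation_type", "timepoint")])
  truth <- data.frame(
    subject = cells$subject,
    inhalation_type = cells$inhalation_type,
    timepoint = cells$timepoint,
    ou_noise_scale = unname(unlist(
      config$ou_noise_scale[cells$inhalation_type])),
    chaos_blend_gain = unname(unlist(
      config$chaos_blend_gain[cells$inhalation_type])),
    subject_multiplier = vapply(
      match(cells$subject, ids),
      function(si) .subject_multiplier(config, si), numeric(1)),
    stringsAsFactors = FALSE
  )
  list(trials = trials, truth = truth)
}

#' Simulate a respiration trace
#'
#' Quasi-periodic respiration-transducer-like voltage trace with mean cycle
#' rate `rate_bpm`. Cycle lengths and cycle amplitudes are jittered by the
#' relative `noise` level; `noise = 0` gives an exactly periodic unit sine,
#' so a 12 breaths/min, 60-s trace contains exactly 12 full cycles.
#'
#' @param rate_bpm mean breathing rate, breaths per minute (> 0).
#' @param duration trace length, seconds.
#' @param sampling_rate sampling rate, Hz (default 2000, the acquisition
#'   rate the preprocessing stage expects).
#' @param noise relative jitter of cycle length and amplitude (>= 0).
#' @param seed integer seed; the trace is a pure function of its arguments.
#' @param condition,phase optional labels carried on the result.
#' @return a [resp_signal()] object.
#' @export
simulate_resp_signal <- function(rate_bpm, duration, sampling_rate = 2000,
                                 noise = 0, seed = 1L,
                                 condition = "AIR", phase = "DURING") {
  .cop_assert(rate_bpm > 0, "copstab_config_error", "rate_bpm must be > 0")
  .cop_assert(duration > 0 && sampling_rate > 0, "copstab_config_error",
              "duration and sampling_rate must be > 0")
  n <- round(duration * sampling_rate)
  t <- (seq_len(n) - 1) / sampling_rate
  mean_cycle <- 60 / rate_bpm
  samples <- .with_seed(seed, {
    n_cycles <- ceiling(duration / mean_cycle) + 3L
    lens <- mean_cycle * pmax(0.2, 1 + noise * rnorm(n_cycles))
    amps <- pmax(0.2, 1 + noise * rnorm(n_cycles))
    edges <- c(0, cumsum(lens))
    k <- findInterval(t, edges, rightmost.closed = FALSE)
    # piecewise-linear phase: one unit per breath cycle
    phase_t <- (k - 1) + (t - edges[k]) / lens[k]
    amps[k] * sin(2 * pi * phase_t)
  })
  resp_signal(samples = samples, sampling_rate = sampling_rate,
              condition = condition, phase = phase)
}

#' Deterministic chaotic fixtures
#'
#' Defines a logistic-map or Lorenz-system fixture used to validate the
#' Lyapunov stage against an independent oracle.
#'
#' @param system `"LOGISTIC"` or `"LORENZ"`.
#' @param parameters named list: logistic needs `r` and `x0` in (0,1);
#'   Lorenz needs `sigma`, `rho`, `beta`, `dt` and optionally `x0`, `y0`,
#'   `z0` (defaults 1, 1, 20).
#' @param n_samples samples to return after discarding the transient.
#' @param transient_discard leading samples discarded.
#' @return an object of class `chaotic_fixture`.
#' @export
chaotic_fixture <- function(system = c("LOGISTIC", "LORENZ"),
                            parameters = list(), n_samples = 10000L,
                            transient_discard = 1000L) {
  system <- match.arg(system)
  defaults <- if (system == "LOGISTIC") {
    list(r = 4, x0 = 0.2)
  } else {
    list(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.01,
         x0 = 1, y0 = 1, z0 = 20)
  }
  parameters <- utils::modifyList(defaults, parameters)
  .cop_assert(n_samples > transient_discard, "copstab_config_error",
              "n_samples must exceed transient_discard")
  if (system == "LOGISTIC") {
    .cop_assert(parameters$x0 > 0 && parameters$x0 < 1,
                "copstab_config_error", "logistic x0 must be in (0,1)")
  } else {
    .cop_assert(parameters$dt > 0, "copstab_config_error", "dt must be > 0")
  }
  structure(list(system = system, parameters = parameters,
                 n_samples = as.integer(n_samples),
                 transient_discard = as.integer(transient_discard)),
            class = "chaotic_fixture")
}

#' Scalar series of a chaotic fixture
#'
#' Iterates the logistic map (x <- r x (1 - x)) or integrates the Lorenz
#' equations with fixed-step RK4 and returns the first coordinate, after
#' discarding the transient. Bit-identical across reruns for fixed
#' parameters.
#'
#' @param fixture a [chaotic_fixture()].
#' @return numeric series of length `n_samples - transient_discard`.
#' @export
chaotic_fixture_series <- function(fixture) {
  .cop_assert(inherits(fixture, "chaotic_fixture"), "copstab_config_error",
              "not a chaotic_fixture")
  p <- fixture$parameters
  n_tot <- fixture$n_samples
  n_keep <- n_tot - fixture$transient_discard
  if (fixture$system == "LOGISTIC") {
    x <- numeric(n_tot)
    xi <- p$x0
    for (i in seq_len(n_tot)) {
      xi <- p$r * xi * (1 - xi)
      if (!is.finite(xi)) .cop_error("copstab_numeric_error",
                                     "logistic iteration diverged at step %d", i)
      x[i] <- xi
    }
    x[(fixture$transient_discard + 1):n_tot]
  } else {
    xyz <- .lorenz_rk4_cpp(p$sigma, p$rho, p$beta, p$dt, n_tot,
                           p$x0, p$y0, p$z0)
    xyz[(fixture$transient_discard + 1):n_tot, 1]
  }
}

#' Independent largest-Lyapunov-exponent oracle
#'
#' Computes the largest Lyapunov exponent of a fixture by a route entirely
#' independent of the divergence-curve (Rosenstein) estimator: for the
#' logistic map, the orbit average of `ln |r (1 - 2x)|` (the exact
#' derivative formula); for the Lorenz system, the Benettin tangent-space
#' method with per-step renormalization (its own self-contained integrator).
#'
#' @param fixture a [chaotic_fixture()].
#' @param n_steps integration steps for the Benettin method (Lorenz only).
#' @return largest exponent in 1/iteration (logistic) or 1/time-unit
#'   (Lorenz).
#' @export
lyapunov_oracle <- function(fixture, n_steps = 2e6) {
  .cop_assert(inherits(fixture, "chaotic_fixture"), "copstab_config_error",
              "not a chaotic_fixture")
  p <- fixture$parameters
  if (fixture$system == "LOGISTIC") {
    x <- chaotic_fixture_series(fixture)
    mean(log(abs(p$r * (1 - 2 * x))))
  } else {
    .benettin_lorenz_cpp(p$sigma, p$rho, p$beta, 0.002,
                         as.integer(n_steps), 50000L, p$x0, p$y0, p$z0)
  }
}
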