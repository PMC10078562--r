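# shared fixture builders (all generated in code; no stored data)

# cohort table for a 2 x 4 within design with a compound-symmetric subject
# effect and no condition effects; draws from the current RNG stream
null_cohort_table <- function(n_subjects = 10, subject_sd = 1) {
  tab <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                     inhalation_type = c("AIR", "CO2"),
                     inhalation_time = c("T5", "T10", "T15", "POST"),
                     stringsAsFactors = FALSE)
  tab$outcome <- "y"
  tab$value <- rnorm(nrow(tab)) +
    rep(rnorm(n_subjects, sd = subject_sd), length.out = nrow(tab))
  tab
}

# small, fast simulation configuration for pipeline plumbing tests
small_config <- function(...) {
  simulation_config(n_subjects = 4, reps_per_timepoint = 2,
                    trial_duration = 15, ...)
}

# sine observed in measurement noise: the regime in which the histogram
# AMI resolves the quarter-period delay
noisy_sine <- function(n = 50000, period = 100, noise_sd = 0.2, seed = 42) {
  set.seed(seed)
  sin(2 * pi * seq_len(n) / period) + rnorm(n, 0, noise_sd)
}

logistic_fixture <- function(r = 4, n = 11000) {
  chaotic_fixture("LOGISTIC", list(r = r, x0 = 0.2), n_samples = n,
                  transient_discard = 1000)
}

lorenz_fixture <- function(n = 31000, dt = 0.01) {
  chaotic_fixture("LORENZ", list(dt = dt), n_samples = n,
                  transient_discard = 1000)
}

expect_cop_error <- function(expr, class) {
  expect_error(expr, class = class)
}
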