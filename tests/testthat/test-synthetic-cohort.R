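test_that("trial simulation is a pure function of seed and design labels", {
  cfg <- small_config()
  a <- simulate_cop_trial(cfg, "S01", "CO2", "T10", 2)
  b <- simulate_cop_trial(cfg, "S01", "CO2", "T10", 2)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  d <- simulate_cop_trial(cfg, "S01", "CO2", "T10", 1)
  expect_false(identical(a$x, d$x))
  # duration x rate samples per axis
  cfg30 <- simulation_config()
  tr <- simulate_cop_trial(cfg30, "S01", "AIR", "T5", 1)
  expect_length(tr$x, 1500)
  expect_length(tr$y, 1500)
  expect_cop_error(simulate_cop_trial(cfg, "S01", "HELIUM", "T5", 1),
                   "copstab_design_error")
  expect_cop_error(simulate_cop_trial(cfg, "S99", "AIR", "T5", 1),
                   "copstab_design_error")
})

test_that("a higher diffusion scale under CO2 lengthens the mean sway path", {
  # 200 replicate trials per condition; no chaotic blend so that only the
  # diffusion dial differs
  cfg <- simulation_config(n_subjects = 1, ou_noise_scale = c(AIR = 1.5, CO2 = 1.8),
                           chaos_blend_gain = c(AIR = 0, CO2 = 0))
  paths <- sapply(1:200, function(k) {
    c(compute_sway_paths(
        simulate_cop_trial(cfg, 1, "AIR", "T5", 1, seed_offset = k))$total_path,
      compute_sway_paths(
        simulate_cop_trial(cfg, 1, "CO2", "T5", 1, seed_offset = k))$total_path)
  })
  expect_gt(mean(paths[2, ]), mean(paths[1, ]))
})

test_that("mean sway path is non-decreasing in the diffusion scale", {
  cfg_for <- function(s) simulation_config(
    n_subjects = 1, ou_noise_scale = c(AIR = s, CO2 = s),
    chaos_blend_gain = c(AIR = 0, CO2 = 0))
  means <- sapply(c(1.0, 1.5, 2.2), function(s) {
    cfg <- cfg_for(s)
    mean(sapply(1:100, function(k) compute_sway_paths(
      simulate_cop_trial(cfg, 1, "AIR", "T5", 1, seed_offset = k))$total_path))
  })
  expect_true(all(diff(means) >= 0))
})

test_that("cohorts are balanced with every design cell exactly once", {
  cfg <- small_config()
  co <- simulate_cohort(cfg)
  expect_length(co$trials, 4 * 2 * 4 * 2)
  labs <- sapply(co$trials, function(tr)
    paste(tr$subject, tr$inhalation_type, tr$timepoint, tr$rep))
  expect_equal(anyDuplicated(labs), 0L)
  counts <- table(sapply(co$trials, function(tr)
    paste(tr$subject, tr$inhalation_type, tr$timepoint)))
  expect_true(all(counts == cfg$reps_per_timepoint))
  # ground truth covers each cell with its generating parameters
  expect_equal(nrow(co$truth), 4 * 2 * 4)
  expect_setequal(unique(co$truth$ou_noise_scale),
                  unname(cfg$ou_noise_scale))
  # default design size
  expect_equal(simulation_config()$n_subjects *
                 length(simulation_config()$inhalation_types) *
                 length(simulation_config()$timepoints) *
                 simulation_config()$reps_per_timepoint, 400)
})

test_that("null cohorts keep the sway-path ANOVA near its nominal size", {
  # identical generating parameters across conditions; full pipeline from
  # trials to the repeated-measures test on total path
  cfg <- simulation_config(n_subjects = 10, reps_per_timepoint = 1,
                           ou_noise_scale = c(AIR = 1.5, CO2 = 1.5),
                           chaos_blend_gain = c(AIR = 0, CO2 = 0))
  n_cohorts <- 400
  rej <- logical(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    co <- simulate_cohort(cfg, seed_offset = k)
    rows <- lapply(co$trials, function(tr) {
      data.frame(subject = tr$subject, inhalation_type = tr$inhalation_type,
                 timepoint = tr$timepoint, rep = tr$rep,
                 total_path = compute_sway_paths(tr)$total_path)
    })
    tab <- aggregate_trials(do.call(rbind, rows), "total_path")
    res <- rm_anova_2way(tab, "total_path", alpha = 0)
    rej[k] <- res$effects$p_uncorrected[1] < 0.05
  }
  half_width <- 1.96 * sqrt(0.05 * 0.95 / n_cohorts)
  expect_gt(mean(rej), 0.05 - half_width)
  expect_lt(mean(rej), 0.05 + half_width)
})

test_that("respiration traces are reproducible with the nominal cycle count", {
  s <- simulate_resp_signal(12, 60, 500, noise = 0)
  # noiseless: exactly 12 full cycles in 60 s; signal ends where it began
  zero_up <- sum(diff(sign(s$samples)) > 0)
  expect_equal(zero_up, 12)
  s2 <- simulate_resp_signal(14, 30, 500, noise = 0.1, seed = 5)
  s3 <- simulate_resp_signal(14, 30, 500, noise = 0.1, seed = 5)
  expect_identical(s2$samples, s3$samples)
  expect_cop_error(simulate_resp_signal(-2, 30, 500), "copstab_config_error")
})

test_that("chaotic fixtures stay on their attractors and rerun bit-identically", {
  lf <- logistic_fixture(r = 4, n = 3000)
  x <- chaotic_fixture_series(lf)
  expect_true(all(x >= 0 & x <= 1))
  expect_identical(x, chaotic_fixture_series(lf))
  lo <- lorenz_fixture(n = 6000)
  y <- chaotic_fixture_series(lo)
  expect_true(all(abs(y) < 25))
  expect_identical(y, chaotic_fixture_series(lo))
  expect_cop_error(chaotic_fixture("LOGISTIC", list(x0 = 1.5)),
                   "copstab_config_error")
  expect_cop_error(
    chaotic_fixture("LOGISTIC", n_samples = 100, transient_discard = 200),
    "copstab_config_error")
})

test_that("the tangent-space oracle matches known Lyapunov exponents", {
  # logistic r = 4: closed form ln 2 per iteration
  expect_equal(lyapunov_oracle(logistic_fixture(r = 4)), log(2),
               tolerance = 1e-3)
  # stable period-2 orbit at r = 3.2: negative exponent
  expect_lt(lyapunov_oracle(logistic_fixture(r = 3.2, n = 6000)), 0)
  # Lorenz at canonical parameters: about 0.91 nats per time unit
  lam <- lyapunov_oracle(lorenz_fixture(n = 2000), n_steps = 2e6)
  expect_equal(lam, 0.906, tolerance = 0.02)
})
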