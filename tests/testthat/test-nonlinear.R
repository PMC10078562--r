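test_that("delay embedding indexes lagged copies correctly", {
  x <- 1:10
  emb <- delay_embed(x, embedding_spec(2, 3))
  expect_equal(dim(emb), c(6, 3))
  expect_equal(emb[1, ], c(1, 3, 5))
  expect_equal(emb[6, ], c(6, 8, 10))
  expect_equal(delay_embed(x, embedding_spec(3, 1))[, 1], x)
  # point-count formula over random valid (N, T, dE)
  set.seed(3)
  for (i in 1:20) {
    N <- sample(50:400, 1); T <- sample(1:10, 1); dE <- sample(1:6, 1)
    if (N - (dE - 1) * T < 1) next
    expect_equal(nrow(delay_embed(rnorm(N), embedding_spec(T, dE))),
                 N - (dE - 1) * T)
  }
  expect_cop_error(delay_embed(1:10, embedding_spec(5, 4)),
                   "copstab_length_error")
})

test_that("AMI peaks at lag zero and flags independent series", {
  s <- noisy_sine(n = 20000)
  res <- average_mutual_information(s, max_lag = 40)
  expect_true(all(res$ami[1] >= res$ami[-1]))  # self-information maximal
  set.seed(8)
  nz <- runif(1e5)
  rn <- average_mutual_information(nz, max_lag = 20)
  expect_true(all(rn$ami[-1] <= 0.05))
  expect_true(rn$method %in% c("one_over_e", "max_lag"))
  expect_cop_error(average_mutual_information(rep(2, 1000), 10),
                   "copstab_degenerate_error")
})

test_that("AMI first minimum recovers the quarter period of a noisy tone", {
  s <- noisy_sine(n = 50000, period = 100, noise_sd = 0.2, seed = 42)
  res <- average_mutual_information(s, max_lag = 60)
  expect_gte(res$first_minimum, 24)
  expect_lte(res$first_minimum, 26)
  expect_identical(res$method, "interior_minimum")
})

test_that("false nearest neighbors selects the attractor dimension", {
  # planar limit cycle: two delay coordinates suffice
  s <- sin(2 * pi * (1:5000) / 100)
  fs <- false_nearest_neighbors(s, 25, max_dim = 6)
  expect_equal(fs$chosen_dE, 2L)
  expect_false(fs$saturated)
  # Lorenz flow embeds at three
  x <- chaotic_fixture_series(lorenz_fixture(n = 9000))
  delay <- average_mutual_information(x, 100)$first_minimum
  fl <- false_nearest_neighbors(x, delay, max_dim = 6)
  expect_equal(fl$chosen_dE, 3L)
  # noise has no finite embedding: saturation flag
  set.seed(12)
  fn <- false_nearest_neighbors(rnorm(3000), 1, max_dim = 8)
  expect_true(fn$saturated)
  expect_equal(fn$chosen_dE, 8L)
})

test_that("mean period matches spectral expectations", {
  fs <- 50
  t <- (0:499) / fs
  expect_equal(mean_period(sin(2 * pi * 1 * t), fs), 1.0, tolerance = 1e-9)
  mix <- sin(2 * pi * 1 * t) + sin(2 * pi * 2 * t)
  expect_equal(mean_period(mix, fs), 1 / 1.5, tolerance = 1e-9)
  set.seed(4)
  wn <- mean(replicate(20, mean_period(rnorm(4096), fs)))
  expect_equal(wn, 4 / fs, tolerance = 0.05)
  expect_cop_error(mean_period(rep(1, 100), fs), "copstab_degenerate_error")
})

test_that("the divergence slope recovers the logistic-map exponent", {
  x <- chaotic_fixture_series(logistic_fixture(r = 4))
  cv <- rosenstein_lye(x, embedding_spec(1, 2), sampling_rate = 1,
                       track_time = 10, fit_window = c(0, 6))
  expect_equal(cv$slope, log(2), tolerance = 0.05 * log(2))
  # curve rises monotonically over the fit window
  sel <- cv$times <= 6
  expect_true(all(diff(cv$mean_log_divergence[sel]) > 0))
  expect_true(all(diff(cv$n_pairs) <= 0))
})

test_that("the divergence slope matches the tangent-space oracle on Lorenz", {
  fx <- lorenz_fixture(n = 31000)
  x <- chaotic_fixture_series(fx)
  delay <- average_mutual_information(x, 100)$first_minimum
  cv <- rosenstein_lye(x, embedding_spec(delay, 3), sampling_rate = 100,
                       track_time = 4, fit_window = c(1, 3.5))
  oracle <- lyapunov_oracle(fx)
  expect_lt(abs(cv$slope - oracle) / oracle, 0.15)
  sel <- cv$times >= 1 & cv$times <= 3.5
  incs <- diff(cv$mean_log_divergence[sel])
  expect_gt(mean(incs > 0), 0.8)   # rising through the fit region
})

test_that("a damped noisy oscillator shows no exponential divergence", {
  set.seed(7)
  f <- 1.3; fs <- 100; zeta <- 0.3
  w <- 2 * pi * f / fs
  a1 <- 2 * exp(-zeta * w) * cos(w * sqrt(1 - zeta^2))
  a2 <- -exp(-2 * zeta * w)
  y <- as.numeric(stats::filter(rnorm(30000), c(a1, a2),
                                method = "recursive"))
  delay <- average_mutual_information(y, 100)$first_minimum
  cv <- rosenstein_lye(y, embedding_spec(delay, 3), sampling_rate = 100,
                       track_time = 4, fit_window = c(1, 3.5))
  expect_lt(abs(cv$slope), 0.05 * 0.906)
})

test_that("amplitude scaling shifts the curve by log c but not the slope", {
  x <- chaotic_fixture_series(logistic_fixture(n = 4000))
  spec <- embedding_spec(1, 2)
  cv1 <- rosenstein_lye(x, spec, 1, track_time = 8, fit_window = c(0, 5))
  cc <- 37.5
  cv2 <- rosenstein_lye(cc * x, spec, 1, track_time = 8,
                        fit_window = c(0, 5))
  expect_equal(cv2$slope, cv1$slope, tolerance = 1e-6)
  expect_equal(cv2$mean_log_divergence - cv1$mean_log_divergence,
               rep(log(cc), length(cv1$times)), tolerance = 1e-9)
})

test_that("per-trial analysis is deterministic and feasibility-capped", {
  cfg <- small_config()
  tr <- simulate_cop_trial(cfg, "S02", "CO2", "T15", 1)
  r1 <- trial_lye(tr, "AP")
  r2 <- trial_lye(tr, "AP")
  expect_identical(r1$curve$mean_log_divergence,
                   r2$curve$mean_log_divergence)
  expect_identical(r1$spec, r2$spec)
  expect_equal(r1$spec$dimension_dE, 6L)
  # delay of order tens of samples in the simulated sway regime
  expect_gte(r1$spec$delay_T, 2L)
  expect_lte(r1$spec$delay_T, 100L)
})
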