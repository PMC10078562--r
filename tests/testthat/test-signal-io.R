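test_that("COP trial files round-trip at full precision", {
  cfg <- small_config()
  tr <- simulate_cop_trial(cfg, "S03", "CO2", "POST", 2)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cop_trial(tr, f)
  back <- read_cop_trial(f)
  expect_identical(back$x, tr$x)
  expect_identical(back$y, tr$y)
  expect_identical(back$subject, tr$subject)
  expect_identical(back$timepoint, tr$timepoint)
  expect_equal(back$sampling_rate, tr$sampling_rate)
})

test_that("malformed COP files are rejected, never coerced", {
  cfg <- small_config()
  tr <- simulate_cop_trial(cfg, "S01", "AIR", "T5", 1)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cop_trial(tr, f)
  lines <- readLines(f)

  # a gap in the time column, named by row
  bad <- lines
  row <- 40L  # 34th data row
  parts <- strsplit(bad[row], ",")[[1]]
  parts[1] <- as.character(as.numeric(parts[1]) + 0.01)
  bad[row] <- paste(parts, collapse = ",")
  writeLines(bad, f)
  err <- tryCatch(read_cop_trial(f), error = function(e) e)
  expect_s3_class(err, "copstab_format_error")
  expect_match(conditionMessage(err), "row")

  # declared rate inconsistent with the time grid
  bad <- lines
  bad[grepl("sampling_rate_hz", bad)] <- "# sampling_rate_hz: 200"
  writeLines(bad, f)
  expect_cop_error(read_cop_trial(f), "copstab_format_error")

  # wrong header
  bad <- lines
  bad[7] <- "time_s,x_mm,y_mm"
  writeLines(bad, f)
  expect_cop_error(read_cop_trial(f), "copstab_format_error")

  # non-finite coordinate
  bad <- lines
  parts <- strsplit(bad[20], ",")[[1]]
  parts[2] <- "NaN"
  bad[20] <- paste(parts, collapse = ",")
  writeLines(bad, f)
  expect_cop_error(read_cop_trial(f), "copstab_data_error")
})

test_that("respiration files round-trip with windows and labels", {
  sig <- simulate_resp_signal(13, 20, 100, noise = 0.05, seed = 3,
                              condition = "CO2", phase = "POST")
  sig$window_bounds <- list(c(2, 12), c(14, 19))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_resp_signal(sig, f)
  back <- read_resp_signal(f)
  expect_identical(back$samples, sig$samples)
  expect_identical(back$condition, "CO2")
  expect_identical(back$phase, "POST")
  expect_equal(back$window_bounds, sig$window_bounds)
  expect_cop_error(
    resp_signal(1:100, 100, window_bounds = list(c(0, 5))),
    "copstab_data_error")
})

test_that("JSON configuration loading fills defaults and rejects junk", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines("{}", f)
  cfg <- load_config(f)
  expect_s3_class(cfg$simulation, "sim_config")
  expect_equal(cfg$simulation$n_subjects, 10)
  expect_equal(cfg$analysis$fixed_dE, 6)
  expect_equal(cfg$analysis$fit_window, c(0, 0.75))

  writeLines('{"simulation": {"cop_sampling_rate": -1}}', f)
  expect_cop_error(load_config(f), "copstab_config_error")
  writeLines('{"simulation": {"bogus_key": 3}}', f)
  err <- tryCatch(load_config(f), error = function(e) e)
  expect_s3_class(err, "copstab_config_error")
  expect_match(conditionMessage(err), "bogus_key")
  writeLines('{"frobnicate": {}}', f)
  expect_cop_error(load_config(f), "copstab_config_error")

  # load -> dump -> load is idempotent
  writeLines('{"simulation": {"n_subjects": 6, "seed": 99}}', f)
  c1 <- load_config(f)
  f2 <- tempfile(fileext = ".json")
  on.exit(unlink(f2), add = TRUE)
  dump_config(c1, f2)
  c2 <- load_config(f2)
  expect_equal(unclass(c2$simulation), unclass(c1$simulation))
  expect_equal(c2$analysis, c1$analysis)
})

test_that("results tables serialize deterministically and refuse emptiness", {
  set.seed(21)
  tab <- null_cohort_table(8)
  res <- rm_anova_2way(tab, "y", alpha = 0.9)  # force pairwise rows
  corr <- change_correlation(rnorm(8), rnorm(8))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(f1, f2)))
  write_results_table(list(y = res), list(air_t5_t10 = corr), f1)
  write_results_table(list(y = res), list(air_t5_t10 = corr), f2)
  expect_identical(readLines(f1), readLines(f2))
  got <- utils::read.delim(f1)
  expect_equal(ncol(got), 7)
  expect_true(any(grepl("^cor:", got$effect)))
  expect_cop_error(write_results_table(list(), list(), f1),
                   "copstab_data_error")
})
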