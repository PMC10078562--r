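test_that("outlier screening removes only values beyond the z cut", {
  v <- setNames(c(rep(70, 9), 150), sprintf("S%02d", 1:10))
  scr <- screen_outliers(v)          # z of the odd subject ~ 2.85
  expect_identical(scr$removed, "S10")
  expect_length(scr$retained, 9)

  same <- setNames(rep(5, 6), letters[1:6])
  s2 <- screen_outliers(same)
  expect_length(s2$removed, 0)
  expect_true(s2$flagged_zero_sd)

  # a value at exactly the cut is retained (strict inequality)
  set.seed(41)
  vals <- setNames(rnorm(10), sprintf("P%d", 1:10))
  zmax <- max(abs(screen_outliers(vals, z_cut = 99)$z))
  expect_length(screen_outliers(vals, z_cut = zmax)$removed, 0)
  expect_gte(length(screen_outliers(vals, z_cut = zmax - 1e-9)$removed), 1)
})

test_that("trial aggregation averages repetitions per design cell", {
  df <- expand.grid(subject = "S01", inhalation_type = "AIR",
                    timepoint = "T5", rep = 1:5,
                    stringsAsFactors = FALSE)
  df$total_path <- 1:5
  agg <- aggregate_trials(df, "total_path")
  expect_equal(agg$value, 3)
  expect_equal(agg$n_reps, 5L)

  cfg <- small_config()
  co <- simulate_cohort(cfg)
  rows <- do.call(rbind, lapply(co$trials, function(tr)
    data.frame(subject = tr$subject, inhalation_type = tr$inhalation_type,
               timepoint = tr$timepoint, rep = tr$rep,
               total_path = compute_sway_paths(tr)$total_path)))
  agg2 <- aggregate_trials(rows, "total_path")
  expect_equal(nrow(agg2), 4 * 2 * 4)
  # one missing rep still aggregates, with the count recorded
  agg3 <- aggregate_trials(rows[-1, ], "total_path")
  expect_equal(sort(unique(agg3$n_reps)), c(1L, 2L))
  # an empty cell aborts with the cell named
  drop <- rows[!(rows$subject == "S01" & rows$timepoint == "T5" &
                   rows$inhalation_type == "AIR"), ]
  err <- tryCatch(aggregate_trials(drop, "total_path"),
                  error = function(e) e)
  expect_s3_class(err, "copstab_missing_cell_error")
  expect_match(conditionMessage(err), "S01")
})

test_that("the within-subject decomposition matches aov exactly", {
  set.seed(31)
  for (i in 1:3) {
    tab <- null_cohort_table(8)
    tab$value <- tab$value + ifelse(tab$inhalation_type == "CO2", 0.4, 0)
    res <- rm_anova_2way(tab, "y")
    d <- transform(tab, subject = factor(subject),
                   A = factor(inhalation_type), B = factor(inhalation_time))
    fit <- summary(aov(value ~ A * B + Error(subject / (A * B)), data = d))
    f_aov <- c(fit[["Error: subject:A"]][[1]]$`F value`[1],
               fit[["Error: subject:B"]][[1]]$`F value`[1],
               fit[["Error: subject:A:B"]][[1]]$`F value`[1])
    expect_equal(res$effects$F, f_aov, tolerance = 1e-10)
    # internal identity eta_p2 = F df1 / (F df1 + df2)
    with(res$effects, expect_equal(
      eta_p2, F * df1 / (F * df1 + df2), tolerance = 1e-12))
  }
})

test_that("two-level factors reduce to the squared paired t statistic", {
  set.seed(32)
  tab <- null_cohort_table(10)
  res <- rm_anova_2way(tab, "y")
  m_sa <- with(tab, tapply(value, list(subject, inhalation_type), mean))
  tt <- t.test(m_sa[, 1], m_sa[, 2], paired = TRUE)
  expect_equal(res$effects$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$effects$epsilon_GG[1], 1)
})

test_that("zero between-condition differences give F = 0 and eta = 0", {
  tab <- expand.grid(subject = sprintf("S%d", 1:6),
                     inhalation_type = c("AIR", "CO2"),
                     inhalation_time = c("T5", "T10"),
                     stringsAsFactors = FALSE)
  tab$outcome <- "y"
  tab$value <- rep(1:6, 4)   # subject differences only
  res <- rm_anova_2way(tab, "y")
  expect_equal(res$effects$F, rep(0, 3))
  expect_equal(res$effects$eta_p2, rep(0, 3))
  expect_equal(res$effects$p, rep(1, 3))
})

test_that("Greenhouse-Geisser epsilon hits its closed-form anchors", {
  set.seed(33)
  expect_equal(greenhouse_geisser_epsilon(matrix(rnorm(24), 12, 2)), 1)
  # rank-one covariance at k = 4 attains the lower bound 1/3
  rank1 <- rnorm(12) %*% t(c(1, 2, 3, 4)) + 3
  expect_equal(greenhouse_geisser_epsilon(rank1), 1 / 3, tolerance = 1e-12)
  # compound symmetry: sphericity holds, epsilon near 1 at large n
  cs <- matrix(rnorm(4 * 2000), 2000, 4) + rnorm(2000)
  expect_gt(greenhouse_geisser_epsilon(cs), 0.98)
  # degenerate covariance flagged at the lower bound
  eps <- greenhouse_geisser_epsilon(matrix(5, 10, 4))
  expect_equal(as.numeric(eps), 1 / 3)
  expect_true(attr(eps, "flagged"))
})

test_that("ANOVA sums of squares are shift invariant", {
  set.seed(34)
  tab <- null_cohort_table(7)
  r1 <- rm_anova_2way(tab, "y")
  tab2 <- tab; tab2$value <- tab2$value + 123.456
  r2 <- rm_anova_2way(tab2, "y")
  expect_equal(r1$effects$SS_effect, r2$effects$SS_effect)
  expect_equal(r1$effects$SS_error, r2$effects$SS_error)
  expect_equal(r1$effects$F, r2$effects$F)
})

test_that("partial eta squared reproduces published effect-size identities", {
  expect_equal(round(partial_eta_squared(18.90, 1, 9), 2), 0.68)
  expect_equal(round(partial_eta_squared(33.98, 1, 8), 2), 0.81)
  expect_equal(partial_eta_squared(0, 1, 9), 0)
})

test_that("Bonferroni families adjust and cap pairwise p-values", {
  set.seed(35)
  tab <- null_cohort_table(9)
  pw_time <- bonferroni_pairwise(tab, "y", "inhalation_time")
  expect_equal(nrow(pw_time), 6)        # 4 levels -> 6 pairs
  expect_equal(pw_time$p_bonferroni, pmin(1, 6 * pw_time$p_raw))
  pw_int <- bonferroni_pairwise(tab, "y", "type:time")
  expect_equal(nrow(pw_int), 4)         # type contrast at each time
  pw_type <- bonferroni_pairwise(tab, "y", "inhalation_type")
  expect_equal(nrow(pw_type), 1)        # m = 1: p unchanged
  expect_equal(pw_type$p_bonferroni, pw_type$p_raw)
})

test_that("change-score correlations carry one-tailed p and Evans bands", {
  cc <- change_correlation(c(1, 2, 3), c(2, 4, 6))
  expect_equal(cc$r, 1)
  expect_identical(cc$band, "very strong")
  expect_equal(cc$p, 0)
  expect_identical(evans_band(-0.57), "moderate")
  expect_identical(evans_band(0.02), "very weak")
  expect_identical(evans_band(0.26), "weak")
  expect_identical(evans_band(-0.62), "strong")
  # one-tailed p in the observed direction: r = -.57 at n = 10 -> ~.04
  set.seed(36)
  xs <- scale(rnorm(10))[, 1]
  es <- scale(resid(lm(rnorm(10) ~ xs)))[, 1]
  y <- -0.57 * xs + sqrt(1 - 0.57^2) * es
  cc2 <- change_correlation(xs, y)
  expect_equal(cc2$r, -0.57, tolerance = 1e-10)
  expect_equal(cc2$p, pt(0.57 * sqrt(8 / (1 - 0.57^2)), 8,
                         lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(round(cc2$p, 2), 0.04)
  expect_cop_error(change_correlation(rep(1, 5), rnorm(5)),
                   "copstab_degenerate_error")
})

test_that("rejection of the type effect grows with the injected multiplier", {
  base <- 1.5
  rates <- sapply(c(1.0, 1.05, 1.2), function(mult) {
    cfg <- simulation_config(n_subjects = 8, reps_per_timepoint = 1,
                             ou_noise_scale = c(AIR = base,
                                                CO2 = base * mult),
                             chaos_blend_gain = c(AIR = 0, CO2 = 0))
    mean(sapply(1:60, function(k) {
      co <- simulate_cohort(cfg, seed_offset = 10000 + k)
      rows <- do.call(rbind, lapply(co$trials, function(tr)
        data.frame(subject = tr$subject,
                   inhalation_type = tr$inhalation_type,
                   timepoint = tr$timepoint, rep = tr$rep,
                   total_path = compute_sway_paths(tr)$total_path)))
      tab <- aggregate_trials(rows, "total_path")
      rm_anova_2way(tab, "total_path", alpha = 0)$effects$p_uncorrected[1] < 0.05
    }))
  })
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})
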