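#' Screen per-subject outliers
#'
#' Single-pass z-score screening: subjects whose value deviates from the
#' sample mean by strictly more than `z_cut` sample standard deviations are
#' removed (a value at exactly `z_cut` SD is retained). With zero standard
#' deviation nothing is removed and the result is flagged.
#'
#' @param values named numeric vector, one value per subject.
#' @param z_cut removal threshold in standard deviations (default 2.5).
#' @return list with `retained` (named values), `removed` (names), `z`
#'   (z-scores) and `flagged_zero_sd`.
#' @export
screen_outliers <- function(values, z_cut = 2.5) {
  .cop_assert(length(values) >= 3, "copstab_data_error",
              "need at least 3 subjects to screen outliers")
  .cop_assert(!is.null(names(values)), "copstab_data_error",
              "values must be named by subject")
  s <- sd(values)
  if (s == 0) {
    return(list(retained = values, removed = character(0),
                z = setNames(rep(0, length(values)), names(values)),
                flagged_zero_sd = TRUE))
  }
  z <- (values - mean(values)) / s
  out <- abs(z) > z_cut
  list(retained = values[!out], removed = names(values)[out], z = z,
       flagged_zero_sd = FALSE)
}

#' Aggregate per-trial metrics into a cohort table
#'
#' Averages the repetitions of each subject x inhalation-type x
#' inhalation-time cell for every outcome column, yielding the long-format
#' cohort table consumed by [rm_anova_2way()]. A design cell with no trial
#' raises a missing-cell error naming the cell.
#'
#' @param metrics data.frame with columns `subject`, `inhalation_type`,
#'   `timepoint` (or `inhalation_time`) and the outcome columns.
#' @param outcomes character vector of outcome column names.
#' @return data.frame with columns `subject`, `inhalation_type`,
#'   `inhalation_time`, `outcome`, `value`, `n_reps`.
#' @export
aggregate_trials <- function(metrics, outcomes) {
  if (!"inhalation_time" %in% names(metrics) &&
      "timepoint" %in% names(metrics)) {
    metrics$inhalation_time <- metrics$timepoint
  }
  for (col in c("subject", "inhalation_type", "inhalation_time")) {
    .cop_assert(col %in% names(metrics), "copstab_data_error",
                "metrics lacks column '%s'", col)
  }
  .cop_assert(all(outcomes %in% names(metrics)), "copstab_data_error",
              "missing outcome column(s): %s",
              paste(setdiff(outcomes, names(metrics)), collapse = ", "))
  subjects <- unique(metrics$subject)
  types <- unique(metrics$inhalation_type)
  times <- unique(metrics$inhalation_time)
  full <- expand.grid(subject = subjects, inhalation_type = types,
                      inhalation_time = times, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(full)), function(i) {
    sel <- metrics$subject == full$subject[i] &
      metrics$inhalation_type == full$inhalation_type[i] &
      metrics$inhalation_time == full$inhalation_time[i]
    if (!any(sel)) {
      .cop_error("copstab_missing_cell_error",
                 "no trial for cell (%s, %s, %s)", full$subject[i],
                 full$inhalation_type[i], full$inhalation_time[i])
    }
    do.call(rbind, lapply(outcomes, function(oc) {
      data.frame(subject = full$subject[i],
                 inhalation_type = full$inhalation_type[i],
                 inhalation_time = full$inhalation_time[i],
                 outcome = oc, value = mean(metrics[[oc]][sel]),
                 n_reps = sum(sel), stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

# orthonormal contrast matrix (k x (k-1)) for a k-level within factor
.orthonormal_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  sweep(cm, 2, sqrt(colSums(cm^2)), "/")
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-violation correction factor estimated from the covariance of
#' the orthonormalized contrasts of a subject x level matrix:
#' `eps = tr(S)^2 / ((k-1) * sum(S^2))`, clipped to `[1/(k-1), 1]`. For a
#' 2-level factor epsilon is exactly 1; a rank-one contrast covariance
#' attains the lower bound `1/(k-1)`. A singular (all-zero) covariance with
#' k > 2 returns the lower bound with attribute `flagged = TRUE`.
#'
#' @param cell_matrix numeric matrix, subjects in rows, factor levels in
#'   columns (k >= 2).
#' @return epsilon in `[1/(k-1), 1]`.
#' @export
greenhouse_geisser_epsilon <- function(cell_matrix) {
  cell_matrix <- as.matrix(cell_matrix)
  k <- ncol(cell_matrix)
  .cop_assert(k >= 2, "copstab_data_error", "need k >= 2 levels")
  .gg_eps(cell_matrix %*% .orthonormal_contrasts(k), k - 1)
}

# eps from an n x df matrix of orthonormal contrast scores
.gg_eps <- function(scores, df) {
  if (df == 1) return(1)
  S <- stats::cov(scores)
  denom <- df * sum(S^2)
  if (denom <= 0 || !is.finite(denom)) {
    eps <- 1 / df
    attr(eps, "flagged") <- TRUE
    return(eps)
  }
  min(1, max(1 / df, sum(diag(S))^2 / denom))
}

#' Partial eta squared from an F statistic
#'
#' `eta_p2 = F * df1 / (F * df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)` for a repeated-measures effect.
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return partial eta squared in `[0, 1]`.
#' @export
partial_eta_squared <- function(F, df1, df2) {
  .cop_assert(all(F >= 0) && all(df1 > 0) && all(df2 > 0),
              "copstab_data_error", "need F >= 0 and positive dfs")
  F * df1 / (F * df1 + df2)
}

# pivot the long cohort table into a subject x type x time array
.cohort_array <- function(table, outcome) {
  tab <- table[table$outcome == outcome, , drop = FALSE]
  .cop_assert(nrow(tab) > 0, "copstab_data_error",
              "no rows for outcome '%s'", outcome)
  subjects <- unique(tab$subject)
  types <- unique(tab$inhalation_type)
  times <- unique(tab$inhalation_time)
  y <- array(NA_real_, dim = c(length(subjects), length(types),
                               length(times)),
             dimnames = list(subjects, types, times))
  idx <- cbind(match(tab$subject, subjects),
               match(tab$inhalation_type, types),
               match(tab$inhalation_time, times))
  y[idx] <- tab$value
  if (anyNA(y)) {
    miss <- which(is.na(y), arr.ind = TRUE)[1, ]
    .cop_error("copstab_missing_cell_error", "missing cell (%s, %s, %s)",
               subjects[miss[1]], types[miss[2]], times[miss[3]])
  }
  y
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject decomposition of a complete crossed
#' subject x inhalation-type x inhalation-time design with one value per
#' cell: each effect (type, time, type:time) is tested against its own
#' effect-by-subject interaction. Greenhouse-Geisser epsilon is estimated
#' from the orthonormalized contrast covariance and applied to the degrees
#' of freedom whenever the effect has more than one numerator df; raw and
#' corrected results are both reported. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. Pairwise Bonferroni comparisons
#' are attached for effects significant at `alpha`.
#'
#' @param table long cohort table (see [aggregate_trials()]).
#' @param outcome outcome label to analyze.
#' @param alpha significance level used to decide which effects get
#'   pairwise follow-ups (default 0.05).
#' @return an object of class `anova_rm2`: list with `outcome`, `effects`
#'   (one row per effect) and `pairwise`.
#' @export
rm_anova_2way <- function(table, outcome, alpha = 0.05) {
  y <- .cohort_array(table, outcome)
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  .cop_assert(n >= 2 && a >= 2 && b >= 2, "copstab_data_error",
              "need >= 2 subjects and >= 2 levels per factor")
  grand <- mean(y)
  m_s <- apply(y, 1, mean)
  m_a <- apply(y, 2, mean)
  m_b <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean)
  m_sb <- apply(y, c(1, 3), mean)
  m_ab <- apply(y, c(2, 3), mean)
  ss_a <- n * b * sum((m_a - grand)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  resid <- y
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b)) {
    resid[i, j, k] <- y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - grand
  }
  ss_abs <- sum(resid^2)
  Ca <- .orthonormal_contrasts(a)
  Cb <- .orthonormal_contrasts(b)
  # cell matrix, type-major then time, to match kronecker(Ca, Cb)
  cells <- matrix(NA_real_, n, a * b)
  for (j in seq_len(a)) for (k in seq_len(b)) {
    cells[, (j - 1) * b + k] <- y[, j, k]
  }
  eff <- data.frame(
    effect = c("inhalation_type", "inhalation_time", "type:time"),
    SS_effect = c(ss_a, ss_b, ss_ab),
    SS_error = c(ss_as, ss_bs, ss_abs),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1),
            (a - 1) * (b - 1) * (n - 1)),
    stringsAsFactors = FALSE
  )
  eff$epsilon_GG <- c(
    as.numeric(.gg_eps(m_sa %*% Ca, a - 1)),
    as.numeric(.gg_eps(m_sb %*% Cb, b - 1)),
    as.numeric(.gg_eps(cells %*% kronecker(Ca, Cb), (a - 1) * (b - 1))))
  eff$df1_corr <- eff$df1 * eff$epsilon_GG
  eff$df2_corr <- eff$df2 * eff$epsilon_GG
  ms_eff <- eff$SS_effect / eff$df1
  ms_err <- eff$SS_error / eff$df2
  if (any(ms_err == 0 & eff$SS_effect > 0)) {
    .cop_error("copstab_degenerate_error", "zero error variance: F undefined")
  }
  eff$F <- ifelse(eff$SS_effect == 0, 0, ms_eff / ms_err)
  eff$p_uncorrected <- ifelse(eff$F == 0, 1,
                              pf(eff$F, eff$df1, eff$df2,
                                 lower.tail = FALSE))
  eff$p_GG <- ifelse(eff$F == 0, 1,
                     pf(eff$F, eff$df1_corr, eff$df2_corr,
                        lower.tail = FALSE))
  # GG applied only where sphericity is estimable (df1 > 1)
  eff$p <- ifelse(eff$df1 > 1, eff$p_GG, eff$p_uncorrected)
  eff$eta_p2 <- ifelse(eff$SS_effect + eff$SS_error == 0, 0,
                       eff$SS_effect / (eff$SS_effect + eff$SS_error))
  pairwise <- do.call(rbind, lapply(which(eff$p < alpha), function(i) {
    bonferroni_pairwise(table, outcome = outcome, effect = eff$effect[i])
  }))
  structure(list(outcome = outcome, effects = eff, pairwise = pairwise,
                 n_subjects = n, alpha = alpha),
            class = "anova_rm2")
}

#' @export
print.anova_rm2 <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA: %s (n = %d)\n", x$outcome,
              x$n_subjects))
  ef <- x$effects
  for (i in seq_len(nrow(ef))) {
    cat(sprintf("  %-16s F(%.2f, %.2f) = %.3f, p = %.4f, eta_p2 = %.3f (eps_GG = %.3f)\n",
                ef$effect[i],
                if (ef$df1[i] > 1) ef$df1_corr[i] else ef$df1[i],
                if (ef$df1[i] > 1) ef$df2_corr[i] else ef$df2[i],
                ef$F[i], ef$p[i], ef$eta_p2[i], ef$epsilon_GG[i]))
  }
  if (!is.null(x$pairwise) && nrow(x$pairwise) > 0) {
    cat(sprintf("  %d Bonferroni pairwise comparison(s)\n",
                nrow(x$pairwise)))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests on within-subject differences for one effect of the
#' 2-way within design, with Bonferroni adjustment
#' `p_adj = min(1, m * p_raw)` where m is the family size: all level pairs
#' for a main effect; for the type:time interaction, the between-type
#' contrast at each time level (one comparison per time level).
#'
#' @param table long cohort table.
#' @param outcome outcome label.
#' @param effect `"inhalation_type"`, `"inhalation_time"` or
#'   `"type:time"`.
#' @return data.frame of comparisons with raw and adjusted p-values.
#' @export
bonferroni_pairwise <- function(table, outcome, effect) {
  y <- .cohort_array(table, outcome)
  n <- dim(y)[1]
  types <- dimnames(y)[[2]]
  times <- dimnames(y)[[3]]
  paired_row <- function(label, l1, l2, d) {
    tt <- stats::t.test(d)
    data.frame(effect = label, level_1 = l1, level_2 = l2,
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  if (effect == "inhalation_type") {
    m_sa <- apply(y, c(1, 2), mean)
    for (p in utils::combn(seq_along(types), 2, simplify = FALSE)) {
      rows[[length(rows) + 1]] <-
        paired_row(effect, types[p[1]], types[p[2]],
                   m_sa[, p[1]] - m_sa[, p[2]])
    }
  } else if (effect == "inhalation_time") {
    m_sb <- apply(y, c(1, 3), mean)
    for (p in utils::combn(seq_along(times), 2, simplify = FALSE)) {
      rows[[length(rows) + 1]] <-
        paired_row(effect, times[p[1]], times[p[2]],
                   m_sb[, p[1]] - m_sb[, p[2]])
    }
  } else if (effect == "type:time") {
    for (k in seq_along(times)) {
      for (p in utils::combn(seq_along(types), 2, simplify = FALSE)) {
        rows[[length(rows) + 1]] <-
          paired_row(effect, paste0(types[p[1]], "@", times[k]),
                     paste0(types[p[2]], "@", times[k]),
                     y[, p[1], k] - y[, p[2], k])
      }
    }
  } else {
    .cop_error("copstab_config_error", "unknown effect '%s'", effect)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, nrow(out) * out$p_raw)
  out
}

#' Evans strength band for a correlation
#'
#' Maps `|r|` to the descriptive bands .00-.19 "very weak", .20-.39
#' "weak", .40-.59 "moderate", .60-.79 "strong", .80-1.0 "very strong".
#'
#' @param r correlation coefficient in `[-1, 1]`.
#' @return band label.
#' @export
evans_band <- function(r) {
  .cop_assert(abs(r) <= 1 + 1e-12, "copstab_data_error", "|r| must be <= 1")
  as.character(cut(abs(r), breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                   labels = c("very weak", "weak", "moderate", "strong",
                              "very strong"),
                   right = FALSE))
}

#' Pearson correlation of change scores
#'
#' Pearson r between two vectors of paired change scores with a one-tailed
#' p-value (in the direction of the observed r) and the Evans strength
#' band of `|r|`.
#'
#' @param x_changes,y_changes numeric vectors of equal length (>= 3) of
#'   paired deltas.
#' @return an object of class `correlation_result`: `r`, `n`, `t`, `p`
#'   (one-tailed), `band`.
#' @export
change_correlation <- function(x_changes, y_changes) {
  .cop_assert(length(x_changes) == length(y_changes),
              "copstab_data_error", "change vectors must be paired")
  n <- length(x_changes)
  .cop_assert(n >= 3, "copstab_data_error", "need >= 3 paired deltas")
  .cop_assert(sd(x_changes) > 0 && sd(y_changes) > 0,
              "copstab_degenerate_error",
              "zero variance: correlation undefined")
  r <- cor(x_changes, y_changes)
  if (abs(r) >= 1) {
    t <- Inf * sign(r)
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  structure(list(r = r, n = n, t = t, p = p, band = evans_band(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r(%d) = %.3f, one-tailed p = %.4f (%s)\n", x$n - 2, x$r,
              x$p, x$band))
  invisible(x)
}
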