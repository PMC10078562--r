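#' COP trial container
#'
#' One quiet-standing centre-of-pressure recording: two planar coordinate
#' series (x = medio-lateral, y = anterior-posterior, both in millimetres)
#' at a fixed sampling rate, plus its design labels.
#'
#' @param subject subject id.
#' @param inhalation_type,timepoint design labels.
#' @param rep repetition number.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param x,y numeric coordinate series of equal length (>= 2), finite.
#' @return an object of class `cop_trial`.
#' @export
cop_trial <- function(subject, inhalation_type, timepoint, rep,
                      sampling_rate, x, y) {
  trial <- structure(list(subject = as.character(subject),
                          inhalation_type = as.character(inhalation_type),
                          timepoint = as.character(timepoint),
                          rep = as.integer(rep),
                          sampling_rate = sampling_rate,
                          x = as.numeric(x), y = as.numeric(y)),
                     class = "cop_trial")
  validate_cop_trial(trial)
}

#' @rdname cop_trial
#' @param trial object to validate.
#' @export
validate_cop_trial <- function(trial) {
  .cop_assert(inherits(trial, "cop_trial"), "copstab_data_error",
              "not a cop_trial object")
  .cop_assert(length(trial$x) == length(trial$y), "copstab_data_error",
              "x and y must have equal length")
  .cop_assert(length(trial$x) >= 2, "copstab_data_error",
              "a trial needs at least 2 samples")
  .cop_assert(all(is.finite(trial$x)) && all(is.finite(trial$y)),
              "copstab_data_error", "non-finite COP coordinate value")
  .cop_assert(is.numeric(trial$sampling_rate) && trial$sampling_rate > 0,
              "copstab_data_error", "sampling_rate must be > 0")
  trial
}

#' @export
print.cop_trial <- function(x, ...) {
  cat(sprintf("<cop_trial> %s %s %s rep %d: %d samples @ %g Hz\n",
              x$subject, x$inhalation_type, x$timepoint, x$rep,
              length(x$x), x$sampling_rate))
  invisible(x)
}

#' Respiration signal container
#'
#' @param samples voltage series (arbitrary units), non-empty.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param condition inhalation-type label.
#' @param phase `"DURING"` or `"POST"` (inhalation phase).
#' @param window_bounds optional list of `c(start, end)` balance windows in
#'   seconds, all inside the record.
#' @return an object of class `resp_signal`.
#' @export
resp_signal <- function(samples, sampling_rate, condition = "AIR",
                        phase = "DURING", window_bounds = NULL) {
  sig <- structure(list(samples = as.numeric(samples),
                        sampling_rate = sampling_rate,
                        condition = as.character(condition),
                        phase = as.character(phase),
                        window_bounds = window_bounds),
                   class = "resp_signal")
  validate_resp_signal(sig)
}

#' @rdname resp_signal
#' @param signal object to validate.
#' @export
validate_resp_signal <- function(signal) {
  .cop_assert(inherits(signal, "resp_signal"), "copstab_data_error",
              "not a resp_signal object")
  .cop_assert(length(signal$samples) > 0, "copstab_data_error",
              "empty respiration signal")
  .cop_assert(is.numeric(signal$sampling_rate) && signal$sampling_rate > 0,
              "copstab_data_error", "sampling_rate must be > 0")
  dur <- length(signal$samples) / signal$sampling_rate
  for (w in signal$window_bounds) {
    .cop_assert(length(w) == 2 && w[1] >= 0 && w[2] <= dur + 1e-9 &&
                  w[1] < w[2],
                "copstab_data_error",
                "window [%g, %g] outside record of %g s", w[1], w[2], dur)
  }
  signal
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$condition, x$phase, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

.num_fmt <- function(v) sprintf("%.17g", v)

#' Write a COP trial file
#'
#' Plain-text CSV with a leading `#`-comment metadata block and columns
#' `time_s, cop_x_mm, cop_y_mm`. Values are written at full double
#' precision so write-then-read is the identity.
#'
#' @param trial a [cop_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cop_trial <- function(trial, path) {
  validate_cop_trial(trial)
  n <- length(trial$x)
  t <- (seq_len(n) - 1) / trial$sampling_rate
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# cop_trial",
    paste0("# subject: ", trial$subject),
    paste0("# inhalation_type: ", trial$inhalation_type),
    paste0("# timepoint: ", trial$timepoint),
    paste0("# rep: ", trial$rep),
    paste0("# sampling_rate_hz: ", .num_fmt(trial$sampling_rate)),
    "time_s,cop_x_mm,cop_y_mm",
    paste(.num_fmt(t), .num_fmt(trial$x), .num_fmt(trial$y), sep = ",")
  ), con)
  invisible(path)
}

.read_meta_block <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines,
                   regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", meta_lines))
  kv <- Filter(function(m) length(m) == 3, kv)
  setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
}

#' Read a COP trial file
#'
#' Reads and validates a file written by [write_cop_trial()] (or any file
#' in the same dialect). The header must be exactly
#' `time_s,cop_x_mm,cop_y_mm`; the time column must be uniformly spaced,
#' consistent with the declared sampling rate to within 1e-6 s, and all
#' coordinates finite. Malformed input is rejected, never coerced.
#'
#' @param path file path.
#' @return a [cop_trial()].
#' @export
read_cop_trial <- function(path) {
  .cop_assert(file.exists(path), "copstab_format_error",
              "no such file: %s", path)
  lines <- readLines(path)
  meta <- .read_meta_block(lines)
  for (key in c("subject", "inhalation_type", "timepoint", "rep",
                "sampling_rate_hz")) {
    .cop_assert(key %in% names(meta), "copstab_format_error",
                "missing metadata '%s' in %s", key, path)
  }
  body <- lines[!grepl("^#", lines)]
  .cop_assert(length(body) >= 2, "copstab_format_error",
              "no data rows in %s", path)
  .cop_assert(identical(body[1], "time_s,cop_x_mm,cop_y_mm"),
              "copstab_format_error",
              "bad header '%s' (expected time_s,cop_x_mm,cop_y_mm)", body[1])
  dat <- read.csv(text = body, header = TRUE)
  .cop_assert(identical(names(dat), c("time_s", "cop_x_mm", "cop_y_mm")),
              "copstab_format_error", "bad column set in %s", path)
  .cop_assert(all(vapply(dat, is.numeric, logical(1))) &&
                all(is.finite(as.matrix(dat))),
              "copstab_data_error", "non-finite value in %s", path)
  rate <- as.numeric(meta$sampling_rate_hz)
  dt <- 1 / rate
  gaps <- abs(diff(dat$time_s) - dt)
  if (any(gaps > 1e-6)) {
    bad <- which(gaps > 1e-6)[1] + 1
    .cop_error("copstab_format_error",
               "non-uniform time column in %s: first bad row %d (t = %g)",
               path, bad, dat$time_s[bad])
  }
  cop_trial(subject = meta$subject, inhalation_type = meta$inhalation_type,
            timepoint = meta$timepoint, rep = as.integer(meta$rep),
            sampling_rate = rate, x = dat$cop_x_mm, y = dat$cop_y_mm)
}

#' Write / read respiration signal files
#'
#' Same dialect as the COP files: `#`-comment metadata then
#' `time_s,resp_v` columns at full precision.
#'
#' @param signal a [resp_signal()].
#' @param path file path.
#' @return `path` invisibly ([write_resp_signal()]), or a [resp_signal()]
#'   ([read_resp_signal()]).
#' @export
write_resp_signal <- function(signal, path) {
  validate_resp_signal(signal)
  n <- length(signal$samples)
  t <- (seq_len(n) - 1) / signal$sampling_rate
  wb <- if (is.null(signal$window_bounds)) "" else
    paste(vapply(signal$window_bounds,
                 function(w) paste(.num_fmt(w), collapse = ":"), ""),
          collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# resp_signal",
    paste0("# condition: ", signal$condition),
    paste0("# phase: ", signal$phase),
    paste0("# sampling_rate_hz: ", .num_fmt(signal$sampling_rate)),
    paste0("# windows: ", wb),
    "time_s,resp_v",
    paste(.num_fmt(t), .num_fmt(signal$samples), sep = ",")
  ), con)
  invisible(path)
}

#' @rdname write_resp_signal
#' @export
read_resp_signal <- function(path) {
  .cop_assert(file.exists(path), "copstab_format_error",
              "no such file: %s", path)
  lines <- readLines(path)
  meta <- .read_meta_block(lines)
  for (key in c("condition", "phase", "sampling_rate_hz")) {
    .cop_assert(key %in% names(meta), "copstab_format_error",
                "missing metadata '%s' in %s", key, path)
  }
  body <- lines[!grepl("^#", lines)]
  .cop_assert(length(body) >= 2 && identical(body[1], "time_s,resp_v"),
              "copstab_format_error", "bad header in %s", path)
  dat <- read.csv(text = body, header = TRUE)
  .cop_assert(all(is.finite(as.matrix(dat))), "copstab_data_error",
              "non-finite value in %s", path)
  wb <- NULL
  if (!is.null(meta$windows) && nzchar(meta$windows)) {
    wb <- lapply(strsplit(meta$windows, ";", fixed = TRUE)[[1]],
                 function(s) as.numeric(strsplit(s, ":", fixed = TRUE)[[1]]))
  }
  resp_signal(samples = dat$resp_v,
              sampling_rate = as.numeric(meta$sampling_rate_hz),
              condition = meta$condition, phase = meta$phase,
              window_bounds = wb)
}

# ---------------------------------------------------------------------------
# configuration files

.analysis_defaults <- function() {
  list(fixed_dE = 6, fit_window = c(0, 0.75), track_time = 1.0,
       ami_max_lag = 150, ami_bins = 16, alpha = 0.05, z_cut = 2.5,
       resp_filter = list(low_cut = 0.5, high_cut = 1.0,
                          n_coefficients = 8000, design_rate = 100,
                          q_metadata = 0.707),
       resp_detector = list(baseline_window_ms = 25, noise_rejection = 0.05,
                            min_rate = 6, max_rate = 20))
}

#' Load a run configuration from JSON
#'
#' Reads a JSON object with (optionally) a `simulation` block of
#' [simulation_config()] fields and an `analysis` block of analysis
#' settings (embedding dimension, fit window, AMI settings, alpha, outlier
#' cut, respiration filter/detector settings). Unknown keys anywhere are
#' rejected; missing keys are filled with defaults; an empty object yields
#' the full default configuration.
#'
#' @param path JSON file path.
#' @return list with elements `simulation` (a `sim_config`) and `analysis`.
#' @export
load_config <- function(path) {
  .cop_assert(file.exists(path), "copstab_config_error",
              "no such file: %s", path)
  raw <- jsonlite::fromJSON(readChar(path, file.size(path)),
                            simplifyVector = TRUE)
  .cop_assert(is.list(raw), "copstab_config_error",
              "config must be a JSON object")
  unknown_top <- setdiff(names(raw), c("simulation", "analysis"))
  .cop_assert(length(unknown_top) == 0, "copstab_config_error",
              "unknown config keys: %s", paste(unknown_top, collapse = ", "))
  sim_raw <- if (is.null(raw$simulation)) list() else raw$simulation
  sim_formals <- names(formals(simulation_config))
  unknown_sim <- setdiff(names(sim_raw), sim_formals)
  .cop_assert(length(unknown_sim) == 0, "copstab_config_error",
              "unknown simulation keys: %s",
              paste(unknown_sim, collapse = ", "))
  if (!is.null(sim_raw$ou_noise_scale))
    sim_raw$ou_noise_scale <- unlist(sim_raw$ou_noise_scale)
  if (!is.null(sim_raw$chaos_blend_gain))
    sim_raw$chaos_blend_gain <- unlist(sim_raw$chaos_blend_gain)
  if (!is.null(sim_raw$resp_rate_mean))
    sim_raw$resp_rate_mean <- lapply(sim_raw$resp_rate_mean, unlist)
  sim <- do.call(simulation_config, sim_raw)
  ana <- .analysis_defaults()
  ana_raw <- if (is.null(raw$analysis)) list() else raw$analysis
  unknown_ana <- setdiff(names(ana_raw), names(ana))
  .cop_assert(length(unknown_ana) == 0, "copstab_config_error",
              "unknown analysis keys: %s",
              paste(unknown_ana, collapse = ", "))
  ana <- utils::modifyList(ana, ana_raw)
  .cop_assert(ana$alpha > 0 && ana$alpha < 1, "copstab_config_error",
              "alpha must be in (0,1)")
  .cop_assert(length(ana$fit_window) == 2 &&
                ana$fit_window[1] < ana$fit_window[2],
              "copstab_config_error", "fit_window must be (lo, hi)")
  list(simulation = sim, analysis = ana)
}

#' @rdname load_config
#' @param config a list as returned by [load_config()].
#' @export
dump_config <- function(config, path) {
  sim <- config$simulation
  out <- list(simulation = unclass(sim), analysis = config$analysis)
  out$simulation$ou_noise_scale <- as.list(sim$ou_noise_scale)
  out$simulation$chaos_blend_gain <- as.list(sim$chaos_blend_gain)
  out$simulation$resp_rate_mean <- lapply(sim$resp_rate_mean, as.list)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# results tables

.fmt_cell <- function(v) {
  if (is.na(v)) return("NA")
  if (is.character(v)) return(v)
  sprintf("%.10g", v)
}

#' Write the combined results table
#'
#' Serializes ANOVA results (effects + pairwise comparisons) and
#' change-score correlations into one deterministic TSV with columns
#' `effect, df1, df2, F_or_r, p, eta_p2_or_band, epsilon_GG`. Re-running on
#' identical input yields a byte-identical file.
#'
#' @param anova_results named list of [rm_anova_2way()] results (names are
#'   outcome labels).
#' @param correlation_results optional named list of [change_correlation()]
#'   results.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(anova_results, correlation_results = list(),
                                path) {
  .cop_assert(length(anova_results) + length(correlation_results) > 0,
              "copstab_data_error", "refusing to write an empty results table")
  rows <- list()
  add <- function(effect, df1, df2, stat, p, eta_band, eps) {
    rows[[length(rows) + 1]] <<-
      paste(effect, .fmt_cell(df1), .fmt_cell(df2), .fmt_cell(stat),
            .fmt_cell(p), .fmt_cell(eta_band), .fmt_cell(eps), sep = "\t")
  }
  for (nm in names(anova_results)) {
    res <- anova_results[[nm]]
    ef <- res$effects
    for (i in seq_len(nrow(ef))) {
      add(paste0(nm, ":", ef$effect[i]), ef$df1[i], ef$df2[i], ef$F[i],
          ef$p[i], ef$eta_p2[i], ef$epsilon_GG[i])
    }
    pw <- res$pairwise
    if (!is.null(pw) && nrow(pw) > 0) {
      for (i in seq_len(nrow(pw))) {
        add(paste0(nm, ":", pw$effect[i], ":", pw$level_1[i], "-",
                   pw$level_2[i]),
            NA, pw$df[i], pw$t[i], pw$p_bonferroni[i], NA, NA)
      }
    }
  }
  for (nm in names(correlation_results)) {
    cr <- correlation_results[[nm]]
    add(paste0("cor:", nm), NA, cr$n - 2, cr$r, cr$p, cr$band, NA)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("effect", "df1", "df2", "F_or_r", "p",
                     "eta_p2_or_band", "epsilon_GG", sep = "\t"),
               unlist(rows)), con)
  invisible(path)
}
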