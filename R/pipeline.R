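#' @keywords internal
#' @noRd
.resolve_config <- function(config, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  if (inherits(config, "sim_config")) {
    config <- list(simulation = config, analysis = .analysis_defaults())
  }
  .cop_assert(is.list(config) && inherits(config$simulation, "sim_config"),
              "copstab_config_error", "cannot interpret config argument")
  if (is.null(config$analysis)) config$analysis <- .analysis_defaults()
  if (!is.null(seed)) config$simulation$seed <- seed
  validate_sim_config(config$simulation)
  config
}

.phase_of <- function(timepoint, timepoints) {
  post_label <- if ("POST" %in% timepoints) "POST" else
    timepoints[length(timepoints)]
  ifelse(timepoint == post_label, "POST", "DURING")
}

#' Pipeline stages
#'
#' The pipeline is decomposed into stages that exchange plain-text files
#' under a run directory: `trials/` (COP trial CSVs), `truth.tsv`,
#' `sway.tsv`, `lye.tsv`, `br.tsv`, `results.tsv`, `descriptives.tsv`,
#' `manifest.json` and `log.txt`. Each stage consumes and produces only its
#' declared files, so the command-line subcommands can re-run them in
#' isolation.
#'
#' @param config configuration (path to a JSON file, a `sim_config`, or a
#'   [load_config()] list).
#' @param out_dir run directory.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config, out_dir) {
  cfg <- .resolve_config(config)
  dir.create(file.path(out_dir, "trials"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- simulate_cohort(cfg$simulation)
  for (tr in cohort$trials) {
    f <- sprintf("%s_%s_%s_r%02d.csv", tr$subject, tr$inhalation_type,
                 tr$timepoint, tr$rep)
    write_cop_trial(tr, file.path(out_dir, "trials", f))
  }
  utils::write.table(cohort$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dump_config(cfg, file.path(out_dir, "config_echo.json"))
  invisible(cohort)
}

#' @rdname pipeline_stages
#' @export
stage_sway <- function(out_dir) {
  out <- compute_sway_batch(file.path(out_dir, "trials"),
                            out_tsv = file.path(out_dir, "sway.tsv"))
  invisible(out)
}

#' @rdname pipeline_stages
#' @param analysis analysis-settings list (see [load_config()]).
#' @export
stage_lye <- function(out_dir, analysis = .analysis_defaults()) {
  files <- sort(list.files(file.path(out_dir, "trials"),
                           pattern = "\\.csv$", full.names = TRUE))
  .cop_assert(length(files) > 0, "copstab_format_error",
              "no trial files under %s/trials", out_dir)
  rows <- lapply(files, function(f) {
    tr <- read_cop_trial(f)
    do.call(rbind, lapply(c("ML", "AP"), function(dir) {
      res <- trial_lye(tr, direction = dir, fixed_dE = analysis$fixed_dE,
                       ami_max_lag = analysis$ami_max_lag,
                       ami_bins = analysis$ami_bins,
                       track_time = analysis$track_time,
                       fit_window = analysis$fit_window)
      data.frame(subject = tr$subject, inhalation_type = tr$inhalation_type,
                 timepoint = tr$timepoint, rep = tr$rep, direction = dir,
                 delay_T = res$spec$delay_T,
                 dimension_dE = res$spec$dimension_dE,
                 lye = res$lye, n_pairs = res$curve$n_pairs[1],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(out_dir, "lye.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

# simulated respiration trace length: a 30-s balance window plus margin
.resp_duration <- function(analysis) 40

#' @rdname pipeline_stages
#' @param mode `"SIMULATE"` (generate respiration traces from the config)
#'   or `"FROM_FILES"` (read `resp/<subject>_<type>_<timepoint>.csv`; if no
#'   `resp/` directory exists the stage is skipped and the breathing-rate
#'   analyses are omitted downstream).
#' @export
stage_resp <- function(config, out_dir, analysis = .analysis_defaults(),
                       mode = "SIMULATE") {
  cfg <- .resolve_config(config)
  sim <- cfg$simulation
  if (mode == "FROM_FILES" && !dir.exists(file.path(out_dir, "resp"))) {
    return(invisible(NULL))
  }
  fset <- do.call(filter_settings,
                  analysis$resp_filter[setdiff(names(analysis$resp_filter),
                                               character(0))])
  dset <- rate_detector_settings(
    baseline_window_ms = analysis$resp_detector$baseline_window_ms,
    noise_rejection = analysis$resp_detector$noise_rejection,
    min_rate = analysis$resp_detector$min_rate,
    max_rate = analysis$resp_detector$max_rate)
  ids <- .subject_ids(sim)
  design <- expand.grid(timepoint = sim$timepoints,
                        inhalation_type = sim$inhalation_types,
                        subject = ids, stringsAsFactors = FALSE)
  dur <- .resp_duration(analysis)
  window <- c(dur / 2 - 15, dur / 2 + 15)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    sub <- design$subject[i]; ty <- design$inhalation_type[i]
    tp <- design$timepoint[i]
    phase <- .phase_of(tp, sim$timepoints)
    if (mode == "FROM_FILES") {
      f <- file.path(out_dir, "resp", sprintf("%s_%s_%s.csv", sub, ty, tp))
      .cop_assert(file.exists(f), "copstab_missing_cell_error",
                  "no respiration file for cell (%s, %s, %s)", sub, ty, tp)
      raw <- read_resp_signal(f)
    } else {
      si <- match(sub, ids)
      ti <- match(ty, sim$inhalation_types)
      pi <- match(tp, sim$timepoints)
      rate_seed <- .mix_seed(sim$seed, 13L, si, ti, pi)
      base <- sim$resp_rate_mean[[ty]][[phase]]
      rate <- .with_seed(rate_seed,
                         min(19, max(7, base * exp(rnorm(1, 0, 0.06)))))
      raw <- simulate_resp_signal(rate, duration = dur,
                                  sampling_rate = 2000,
                                  noise = sim$resp_noise,
                                  seed = .mix_seed(sim$seed, 17L, si, ti, pi),
                                  condition = ty, phase = phase)
    }
    res <- resample_signal(raw, fset$design_rate)
    est <- estimate_breathing_rate(res, dset, window = window)
    data.frame(subject = sub, inhalation_type = ty, timepoint = tp,
               phase = phase, rate_bpm = est, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(out_dir, "br.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

.read_tsv <- function(path) {
  .cop_assert(file.exists(path), "copstab_format_error",
              "missing stage output %s (run the earlier stage first)", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.descriptives <- function(table) {
  agg <- aggregate(value ~ outcome + inhalation_type + inhalation_time,
                   data = table,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- data.frame(agg[1:3], mean = agg$value[, "mean"],
                    sd = agg$value[, "sd"], n = agg$value[, "n"],
                    stringsAsFactors = FALSE)
  out[order(out$outcome, out$inhalation_type, out$inhalation_time), ]
}

#' @rdname pipeline_stages
#' @param side_table optional data.frame of pre-tabulated cell-level
#'   outcomes (columns `subject`, `inhalation_type`, `inhalation_time`,
#'   `outcome`, `value`), e.g. manually measured heart rate; analyzed
#'   identically to the computed outcomes.
#' @export
stage_stats <- function(out_dir, analysis = .analysis_defaults(),
                        side_table = NULL) {
  sway <- .read_tsv(file.path(out_dir, "sway.tsv"))
  lye <- .read_tsv(file.path(out_dir, "lye.tsv"))
  have_br <- file.exists(file.path(out_dir, "br.tsv"))
  br <- if (have_br) .read_tsv(file.path(out_dir, "br.tsv")) else NULL
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (!have_br) note("no br.tsv: breathing-rate analyses omitted")

  keys <- c("subject", "inhalation_type", "timepoint", "rep")
  lye_ml <- lye[lye$direction == "ML", c(keys, "lye")]
  names(lye_ml)[5] <- "lye_ml"
  lye_ap <- lye[lye$direction == "AP", c(keys, "lye")]
  names(lye_ap)[5] <- "lye_ap"
  lye_wide <- merge(lye_ml, lye_ap, by = keys)
  trial_metrics <- merge(sway, lye_wide,
                         by = c("subject", "inhalation_type", "timepoint",
                                "rep"))
  table_sway <- aggregate_trials(trial_metrics,
                                 c("total_path", "ml_path", "ap_path",
                                   "lye_ml", "lye_ap"))

  # BR: per-timepoint rates feed the correlations; the ANOVA contrasts the
  # mean of the during-inhalation windows against the post window
  cohort_table <- table_sway
  if (have_br) {
    br$inhalation_time <- br$phase
    br_during <- aggregate(rate_bpm ~ subject + inhalation_type,
                           data = br[br$phase == "DURING", ], FUN = mean)
    br_post <- br[br$phase == "POST",
                  c("subject", "inhalation_type", "rate_bpm")]
    br_cells <- rbind(
      data.frame(br_during[c("subject", "inhalation_type")],
                 inhalation_time = "DURING", outcome = "br",
                 value = br_during$rate_bpm,
                 n_reps = length(unique(br$timepoint[br$phase == "DURING"]))),
      data.frame(br_post[c("subject", "inhalation_type")],
                 inhalation_time = "POST", outcome = "br",
                 value = br_post$rate_bpm, n_reps = 1L))
    cohort_table <- rbind(cohort_table, br_cells)
  }
  if (!is.null(side_table)) {
    side_table$n_reps <- side_table$n_reps %||% 1L
    cohort_table <- rbind(cohort_table,
                          side_table[names(cohort_table)])
  }

  # outlier screening per outcome on subject-level means, single pass
  screened <- list()
  for (oc in unique(cohort_table$outcome)) {
    tab <- cohort_table[cohort_table$outcome == oc, ]
    subj_means <- tapply(tab$value, tab$subject, mean)
    scr <- screen_outliers(setNames(as.numeric(subj_means),
                                    names(subj_means)),
                           z_cut = analysis$z_cut)
    if (length(scr$removed) > 0) {
      note("outcome %s: removed subject(s) %s (>%.1f SD)", oc,
           paste(scr$removed, collapse = ", "), analysis$z_cut)
      tab <- tab[!tab$subject %in% scr$removed, ]
    }
    screened[[oc]] <- tab
  }

  anovas <- lapply(screened, function(tab) {
    rm_anova_2way(tab, outcome = tab$outcome[1], alpha = analysis$alpha)
  })
  for (nm in names(anovas)) {
    ef <- anovas[[nm]]$effects
    note("anova %s: eps_GG applied to %s", nm,
         paste(ef$effect[ef$df1 > 1], collapse = ", "))
  }

  # change-score correlations: BR change vs total-path change between
  # consecutive timepoints, per condition
  correlations <- list()
  tp_levels <- unique(sway$timepoint)
  path_tab <- screened[["total_path"]]
  br_tp <- br
  for (ty in if (have_br) unique(sway$inhalation_type) else character(0)) {
    for (i in seq_len(length(tp_levels) - 1)) {
      t1 <- tp_levels[i]; t2 <- tp_levels[i + 1]
      subs <- sort(unique(path_tab$subject))
      getv <- function(tab, vcol, tp) {
        sel <- tab$inhalation_type == ty & tab[[if ("timepoint" %in%
          names(tab)) "timepoint" else "inhalation_time"]] == tp
        setNames(tab[[vcol]][sel], tab$subject[sel])[subs]
      }
      d_path <- getv(path_tab, "value", t2) - getv(path_tab, "value", t1)
      d_br <- getv(br_tp, "rate_bpm", t2) - getv(br_tp, "rate_bpm", t1)
      ok <- complete.cases(d_path, d_br)
      lab <- sprintf("%s:br_change_vs_path_change:%s-%s", ty, t1, t2)
      correlations[[lab]] <- change_correlation(d_br[ok], d_path[ok])
    }
  }

  desc <- .descriptives(cohort_table)
  utils::write.table(format(desc, digits = 10, trim = TRUE),
                     file.path(out_dir, "descriptives.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_results_table(anovas, correlations,
                      file.path(out_dir, "results.tsv"))
  writeLines(log_lines, file.path(out_dir, "stats_log.txt"))
  invisible(list(anovas = anovas, correlations = correlations,
                 cohort_table = cohort_table, descriptives = desc,
                 log = log_lines))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> sway metrics -> local dynamic stability ->
#' respiration rates -> repeated-measures statistics -> report as one
#' reproducible run. In `SIMULATE` mode the cohort is generated from the
#' configuration; in `FROM_FILES` mode COP trials are read from
#' `out_dir/trials/` and respiration traces from `out_dir/resp/`. All
#' stages after generation are seed-free, so a rerun with the same config
#' and seed reproduces `results.tsv` and `descriptives.tsv` byte for byte.
#'
#' @param config configuration (JSON path, `sim_config`, or
#'   [load_config()] list).
#' @param out_dir run directory (created if needed).
#' @param mode `"SIMULATE"` or `"FROM_FILES"`.
#' @param seed optional override of the config seed.
#' @param side_table optional pre-tabulated outcome table (see
#'   [stage_stats()]).
#' @return list with `manifest`, `anovas`, `correlations`,
#'   `cohort_table`, `descriptives`.
#' @export
run_pipeline <- function(config, out_dir,
                         mode = c("SIMULATE", "FROM_FILES"), seed = NULL,
                         side_table = NULL) {
  mode <- match.arg(mode)
  cfg <- .resolve_config(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "SIMULATE") {
    stage_simulate(cfg, out_dir)
  } else {
    .cop_assert(dir.exists(file.path(out_dir, "trials")),
                "copstab_format_error",
                "FROM_FILES mode needs %s/trials", out_dir)
    dump_config(cfg, file.path(out_dir, "config_echo.json"))
  }
  stage_sway(out_dir)
  stage_lye(out_dir, cfg$analysis)
  stage_resp(cfg, out_dir, cfg$analysis, mode = mode)
  stats_out <- stage_stats(out_dir, cfg$analysis, side_table = side_table)
  outputs <- c("truth.tsv", "sway.tsv", "lye.tsv", "br.tsv", "results.tsv",
               "descriptives.tsv", "stats_log.txt", "config_echo.json")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest <- list(
    package_version = as.character(utils::packageVersion("copstab")),
    seed = cfg$simulation$seed,
    mode = mode,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = jsonlite::fromJSON(file.path(out_dir, "config_echo.json"),
                                simplifyVector = TRUE),
    digests = as.list(tools::md5sum(file.path(out_dir, outputs)))
  )
  names(manifest$digests) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(manifest = manifest), stats_out))
}
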