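#' Sway path lengths of a COP trial
#'
#' Cumulative distance travelled by the centre of pressure over the trial:
#' the medio-lateral path is the sum of absolute x-increments
#' `sum |X[i+1] - X[i]|`, the anterior-posterior path the sum of absolute
#' y-increments, and the total path the sum of planar increment lengths
#' `sum sqrt((dX)^2 + (dY)^2)`, all over `n = length - 1` increments.
#' COP series are used unfiltered; the function refuses trials that carry a
#' `filtered` attribute, since any smoothing stage would bias the path
#' length downwards.
#'
#' @param trial a [cop_trial()] (at least 2 samples).
#' @return an object of class `sway_metrics`: list with `ml_path`,
#'   `ap_path`, `total_path` (mm) and `n_increments`.
#' @export
compute_sway_paths <- function(trial) {
  validate_cop_trial(trial)
  .cop_assert(!isTRUE(attr(trial, "filtered")), "copstab_data_error",
              "sway paths must be computed on unfiltered COP")
  dx <- diff(trial$x)
  dy <- diff(trial$y)
  m <- structure(list(ml_path = sum(abs(dx)),
                      ap_path = sum(abs(dy)),
                      total_path = sum(sqrt(dx^2 + dy^2)),
                      n_increments = length(dx)),
                 class = "sway_metrics")
  stopifnot(m$total_path >= max(m$ml_path, m$ap_path) - 1e-9,
            m$total_path <= m$ml_path + m$ap_path + 1e-9)
  m
}

#' @export
print.sway_metrics <- function(x, ...) {
  cat(sprintf("<sway_metrics> ML %.2f mm, AP %.2f mm, total %.2f mm (%d increments)\n",
              x$ml_path, x$ap_path, x$total_path, x$n_increments))
  invisible(x)
}

#' Batch sway metrics over a directory of trial files
#'
#' Reads every `*.csv` COP trial in `dir` and returns one metrics row per
#' trial; optionally writes the table as TSV.
#'
#' @param dir directory containing [write_cop_trial()] files.
#' @param out_tsv optional output TSV path.
#' @return data.frame with design labels and the three path lengths.
#' @export
compute_sway_batch <- function(dir, out_tsv = NULL) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  .cop_assert(length(files) > 0, "copstab_format_error",
              "no .csv trial files in %s", dir)
  rows <- lapply(files, function(f) {
    tr <- read_cop_trial(f)
    m <- compute_sway_paths(tr)
    data.frame(subject = tr$subject, inhalation_type = tr$inhalation_type,
               timepoint = tr$timepoint, rep = tr$rep,
               ml_path = m$ml_path, ap_path = m$ap_path,
               total_path = m$total_path, n_increments = m$n_increments,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
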