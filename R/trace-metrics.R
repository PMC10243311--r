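# Per-scan metric set: marked/actual BPM statistics, BPM range, amplitude
# statistics, peak/trough ranges, and the marked-vs-actual / GUI differences,
# plus the central CSV audit log.

#' Per-interval breathing rate
#'
#' One breathing "phase" is the half-cycle between an adjacent peak and
#' trough, so the rate for a gap of `dt` seconds is `30 / dt` breaths per
#' minute. A full-cycle variant (same-kind extremum to the next, `60 / dt`)
#' is available via `cycle = "full"`.
#'
#' @param extrema an `extremum_series` with at least 2 rows.
#' @param cycle `"half"` (default) or `"full"`.
#' @return numeric vector of BPM values, one per interval.
#' @export
interval_bpm <- function(extrema, cycle = c("half", "full")) {
  cycle <- match.arg(cycle)
  if (nrow(extrema) < 2) abort_insufficient("need at least 2 extrema for interval BPM")
  if (cycle == "half") {
    30 / diff(extrema$time)
  } else {
    if (nrow(extrema) < 3) abort_insufficient("need at least 3 extrema for full-cycle BPM")
    60 / (extrema$time[-(1:2)] - extrema$time[seq_len(nrow(extrema) - 2)])
  }
}

#' Low-level trace-metrics constructor
#'
#' Builds a `trace_metrics` object from already-computed values; useful for
#' what-if tolerance evaluation. [compute_metrics()] is the normal route.
#'
#' All rates are breaths/min, all lengths cm. `peak_level_sd` /
#' `trough_level_sd` are the standard deviations of the individual peak and
#' trough levels over the scan (the inputs to [voluming_error()], there in
#' mm).
#'
#' @param ... named metric fields; unspecified fields default to `NA`.
#' @return list of class `trace_metrics`.
#' @export
trace_metrics <- function(...) {
  fields <- c("gui_bpm", "marked_bpm_mean", "marked_bpm_sd", "actual_bpm_mean",
              "actual_bpm_sd", "bpm_min", "bpm_max", "marked_bpm_min",
              "marked_bpm_max", "amplitude_mean", "amplitude_sd", "peak_range",
              "trough_range", "peak_level_sd", "trough_level_sd",
              "n_cycles_marked", "n_cycles_actual", "max_invalid_gap_s")
  out <- stats::setNames(as.list(rep(NA_real_, length(fields))), fields)
  dots <- list(...)
  unknown <- setdiff(names(dots), fields)
  if (length(unknown)) abort_config(sprintf("unknown metric field(s): %s",
                                            paste(unknown, collapse = ", ")))
  out[names(dots)] <- dots
  structure(out, class = "trace_metrics")
}

sample_sd <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_

#' Compute the per-scan metric set
#'
#' Mirrors the application results panel: marked and actual breathing rates
#' are means of per-half-cycle BPM with their sample standard deviations
#' (n - 1); the breathing-rate range is the min/max over the actual
#' intervals; per-half-cycle amplitude is half the absolute peak-to-trough
#' excursion, reported as mean and sample SD; peak (trough) range is the
#' spread between the tallest and lowest peak (trough).
#'
#' @param trace a [breathing_trace()].
#' @param marked vendor-marked `extremum_series`, or `NULL` when the trace
#'   carries no marks (marked metrics come back `NA`).
#' @param detected algorithmically detected `extremum_series`.
#' @param gui_bpm the breathing frequency shown on the vendor user interface
#'   (breaths/min), as entered by the operator; `NA` when unknown.
#' @return a [trace_metrics()] object.
#' @export
compute_metrics <- function(trace, marked, detected, gui_bpm = NA_real_) {
  if (is.null(detected) || nrow(detected) < 2) {
    abort_insufficient("detected series too short to compute metrics")
  }
  assert_alternating(detected)
  act_ib <- interval_bpm(detected)
  amp <- abs(diff(detected$amplitude)) / 2
  peaks <- detected$amplitude[detected$kind == "peak"]
  troughs <- detected$amplitude[detected$kind == "trough"]

  mk <- list(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
             n = NA_real_)
  if (!is.null(marked) && nrow(marked) >= 2) {
    assert_alternating(marked)
    mk_ib <- interval_bpm(marked)
    mk <- list(mean = mean(mk_ib), sd = sample_sd(mk_ib),
               min = min(mk_ib), max = max(mk_ib),
               n = sum(marked$kind == "peak"))
  }

  inv <- !trace$samples$valid
  max_gap <- 0
  if (any(inv)) {
    r <- rle(inv)
    max_gap <- max(r$lengths[r$values]) / trace$header$samples_per_second
  }

  trace_metrics(
    gui_bpm = gui_bpm,
    marked_bpm_mean = mk$mean, marked_bpm_sd = mk$sd,
    marked_bpm_min = mk$min, marked_bpm_max = mk$max,
    actual_bpm_mean = mean(act_ib), actual_bpm_sd = sample_sd(act_ib),
    bpm_min = min(act_ib), bpm_max = max(act_ib),
    amplitude_mean = mean(amp), amplitude_sd = sample_sd(amp),
    peak_range = if (length(peaks)) max(peaks) - min(peaks) else NA_real_,
    trough_range = if (length(troughs)) max(troughs) - min(troughs) else NA_real_,
    peak_level_sd = sample_sd(peaks), trough_level_sd = sample_sd(troughs),
    n_cycles_marked = mk$n,
    n_cycles_actual = sum(detected$kind == "peak"),
    max_invalid_gap_s = max_gap)
}

#' @export
print.trace_metrics <- function(x, ...) {
  f <- function(v, d = 2) if (is.na(v)) "--" else formatC(v, digits = d, format = "f")
  cat("Breathing-trace metrics\n")
  cat(sprintf("  GUI BPM:            %s\n", f(x$gui_bpm, 1)))
  cat(sprintf("  Marked BPM:         %s +/- %s  (%s cycles)\n",
              f(x$marked_bpm_mean, 1), f(x$marked_bpm_sd, 1), f(x$n_cycles_marked, 0)))
  cat(sprintf("  Actual BPM:         %s +/- %s  (%s cycles)\n",
              f(x$actual_bpm_mean, 1), f(x$actual_bpm_sd, 1), f(x$n_cycles_actual, 0)))
  cat(sprintf("  BPM range (actual): %s - %s\n", f(x$bpm_min, 1), f(x$bpm_max, 1)))
  cat(sprintf("  Amplitude:          %s +/- %s cm\n",
              f(x$amplitude_mean), f(x$amplitude_sd)))
  cat(sprintf("  Peak range:         %s cm | trough range: %s cm\n",
              f(x$peak_range), f(x$trough_range)))
  if (!is.na(x$max_invalid_gap_s) && x$max_invalid_gap_s > 0) {
    cat(sprintf("  Longest invalid-data gap: %.2f s\n", x$max_invalid_gap_s))
  }
  invisible(x)
}

#' Method-difference percentages for one scan
#'
#' Percent differences between the GUI, marked, and actual breathing-rate
#' estimates for one scan. Denominators: `marked_vs_gui_pct =
#' (marked - gui)/gui * 100`, `actual_vs_gui_pct = (actual - gui)/gui * 100`,
#' `actual_vs_marked_pct = (actual - marked)/marked * 100`, and
#' `sd_marked_vs_actual_pct` is the difference of relative SDs
#' `(marked CV - actual CV) * 100` (positive when the vendor marks imply more
#' breathing-rate variability than the signal shows).
#'
#' @param metrics a [trace_metrics()] object with `gui_bpm > 0`.
#' @return list of class `metric_diffs`.
#' @export
compute_diffs <- function(metrics) {
  g <- metrics$gui_bpm
  if (is.na(g) || g <= 0) {
    qa_abort("gui_bpm must be a positive number to compute method differences",
             "breathqa_undefined_metric")
  }
  if (is.na(metrics$actual_bpm_mean) || metrics$actual_bpm_mean <= 0) {
    qa_abort("actual BPM mean undefined", "breathqa_undefined_metric")
  }
  m <- metrics$marked_bpm_mean
  a <- metrics$actual_bpm_mean
  cv <- function(s, mu) if (is.na(s) || is.na(mu) || mu == 0) NA_real_ else s / mu
  structure(list(
    marked_vs_gui_pct = if (is.na(m)) NA_real_ else (m - g) / g * 100,
    actual_vs_gui_pct = (a - g) / g * 100,
    actual_vs_marked_pct = if (is.na(m) || m == 0) NA_real_ else (a - m) / m * 100,
    sd_marked_vs_actual_pct =
      (cv(metrics$marked_bpm_sd, m) - cv(metrics$actual_bpm_sd, a)) * 100),
    class = "metric_diffs")
}

#' @export
print.metric_diffs <- function(x, ...) {
  f <- function(v) if (is.na(v)) "--" else sprintf("%+.1f%%", v)
  cat("Method differences (this scan)\n")
  cat(sprintf("  marked vs GUI BPM:      %s\n", f(x$marked_vs_gui_pct)))
  cat(sprintf("  actual vs GUI BPM:      %s\n", f(x$actual_vs_gui_pct)))
  cat(sprintf("  actual vs marked BPM:   %s\n", f(x$actual_vs_marked_pct)))
  cat(sprintf("  relative-SD difference: %s\n", f(x$sd_marked_vs_actual_pct)))
  invisible(x)
}

# audit log -----------------------------------------------------------------

AUDIT_SCHEMA_VERSION <- 1L

audit_log_columns <- function() {
  c("schema_version", "tool_version", "file", "file_md5", "config_md5",
    "gui_bpm", "marked_bpm_mean", "marked_bpm_sd", "actual_bpm_mean",
    "actual_bpm_sd", "bpm_min", "bpm_max", "amplitude_mean", "amplitude_sd",
    "peak_range", "trough_range", "peak_level_sd", "trough_level_sd",
    "n_cycles_marked", "n_cycles_actual", "max_invalid_gap_s",
    "marked_vs_gui_pct", "actual_vs_gui_pct", "actual_vs_marked_pct",
    "sd_marked_vs_actual_pct", "qa_overall", "qa_failed")
}

#' Build one audit record from a scan's results
#'
#' @param metrics a [trace_metrics()] object.
#' @param diffs a [compute_diffs()] result, or `NULL`.
#' @param qa a [qa_evaluate()] result, or `NULL`.
#' @param file source trace path recorded for provenance ("" if unknown).
#' @param config_md5 hash of the configuration in force ("" if unknown).
#' @return one-row data frame in the stable audit-log column order.
#' @export
audit_record <- function(metrics, diffs = NULL, qa = NULL, file = "",
                         config_md5 = "") {
  file_md5 <- if (nzchar(file) && file.exists(file)) {
    unname(tools::md5sum(file))
  } else ""
  failed <- if (!is.null(qa)) {
    paste(qa$checks$metric[!qa$checks$pass], collapse = ";")
  } else ""
  rec <- data.frame(
    schema_version = AUDIT_SCHEMA_VERSION,
    tool_version = as.character(utils::packageVersion("breathqa")),
    file = file, file_md5 = file_md5, config_md5 = config_md5,
    gui_bpm = metrics$gui_bpm,
    marked_bpm_mean = metrics$marked_bpm_mean, marked_bpm_sd = metrics$marked_bpm_sd,
    actual_bpm_mean = metrics$actual_bpm_mean, actual_bpm_sd = metrics$actual_bpm_sd,
    bpm_min = metrics$bpm_min, bpm_max = metrics$bpm_max,
    amplitude_mean = metrics$amplitude_mean, amplitude_sd = metrics$amplitude_sd,
    peak_range = metrics$peak_range, trough_range = metrics$trough_range,
    peak_level_sd = metrics$peak_level_sd, trough_level_sd = metrics$trough_level_sd,
    n_cycles_marked = metrics$n_cycles_marked,
    n_cycles_actual = metrics$n_cycles_actual,
    max_invalid_gap_s = metrics$max_invalid_gap_s,
    marked_vs_gui_pct = if (is.null(diffs)) NA_real_ else diffs$marked_vs_gui_pct,
    actual_vs_gui_pct = if (is.null(diffs)) NA_real_ else diffs$actual_vs_gui_pct,
    actual_vs_marked_pct = if (is.null(diffs)) NA_real_ else diffs$actual_vs_marked_pct,
    sd_marked_vs_actual_pct = if (is.null(diffs)) NA_real_ else diffs$sd_marked_vs_actual_pct,
    qa_overall = if (is.null(qa)) "" else if (qa$overall) "pass" else "fail",
    qa_failed = failed,
    stringsAsFactors = FALSE)
  rec[, audit_log_columns()]
}

#' Append one record to the central audit CSV log
#'
#' The header row is written once; the column order is stable and versioned
#' through the `schema_version` column.
#'
#' @param record one-row data frame from [audit_record()].
#' @param path audit-log CSV path.
#' @return `path`, invisibly.
#' @export
append_audit_record <- function(record, path) {
  new <- !file.exists(path)
  utils::write.table(record, path, append = !new, sep = ",",
                     col.names = new, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a central audit CSV log
#'
#' @param path audit-log CSV path.
#' @return data frame of audit records.
#' @export
read_audit_log <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("audit log not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
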