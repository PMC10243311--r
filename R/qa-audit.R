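# Per-scan QA: compare the metric set against configurable tolerances and
# emit a pass/fail report with per-metric reasons.

#' QA tolerance configuration
#'
#' Defaults are the 1-SD cohort statistics of the default study conditions:
#' marked-vs-actual mean-BPM difference 9.6%, relative-SD difference 18.4%,
#' within-scan amplitude CV 17%, within-scan BPM CV 18%, and a 1 s ceiling on
#' invalid-data gaps. The GUI-BPM comparison is advisory only (a note, not a
#' failure) since a +/- 20% spread is normal; `gui_advisory_pct` sets that
#' threshold.
#'
#' @param max_marked_vs_actual_bpm_pct tolerance on `|actual_vs_marked_pct|`.
#' @param max_sd_diff_pct tolerance on `|sd_marked_vs_actual_pct|`.
#' @param max_amplitude_cv_pct tolerance on the within-scan amplitude CV (%).
#' @param max_bpm_cv_pct tolerance on the within-scan actual-BPM CV (%).
#' @param max_invalid_gap_s tolerance on the longest invalid-data gap (s).
#' @param gui_advisory_pct advisory threshold on `|marked_vs_gui_pct|`.
#' @return list of class `tolerance_config`.
#' @export
tolerance_config <- function(max_marked_vs_actual_bpm_pct = 9.6,
                             max_sd_diff_pct = 18.4,
                             max_amplitude_cv_pct = 17,
                             max_bpm_cv_pct = 18,
                             max_invalid_gap_s = 1,
                             gui_advisory_pct = 20.1) {
  cfg <- list(max_marked_vs_actual_bpm_pct = max_marked_vs_actual_bpm_pct,
              max_sd_diff_pct = max_sd_diff_pct,
              max_amplitude_cv_pct = max_amplitude_cv_pct,
              max_bpm_cv_pct = max_bpm_cv_pct,
              max_invalid_gap_s = max_invalid_gap_s,
              gui_advisory_pct = gui_advisory_pct)
  for (nm in names(cfg)) stopifnot_scalar_num(cfg[[nm]], nm, positive = TRUE)
  structure(cfg, class = "tolerance_config")
}

#' Evaluate a scan against QA tolerances
#'
#' Each gated metric is compared on absolute value against its tolerance; a
#' single exceedance fails the scan. An undefined required metric is recorded
#' as a failure with reason "unanalyzable". The GUI-BPM comparison only adds
#' an advisory note.
#'
#' @param metrics a [trace_metrics()] object.
#' @param diffs a [compute_diffs()] result (or `NULL`; the marked-vs-actual
#'   checks are then unanalyzable).
#' @param config a [tolerance_config()].
#' @return list of class `qa_result`: `checks` (data frame `metric`, `value`,
#'   `tolerance`, `pass`, `reason`), `overall` (logical), `notes`.
#' @export
qa_evaluate <- function(metrics, diffs = NULL, config = tolerance_config()) {
  if (!inherits(metrics, "trace_metrics")) abort_config("'metrics' must be a trace_metrics")
  cv_pct <- function(s, m) {
    if (!is.finite(s) || !is.finite(m) || m == 0) NA_real_ else 100 * abs(s / m)
  }
  vals <- c(
    bpm_marked_vs_actual_pct =
      if (is.null(diffs)) NA_real_ else abs(diffs$actual_vs_marked_pct),
    bpm_sd_diff_pct =
      if (is.null(diffs)) NA_real_ else abs(diffs$sd_marked_vs_actual_pct),
    amplitude_cv_pct = cv_pct(metrics$amplitude_sd, metrics$amplitude_mean),
    bpm_cv_pct = cv_pct(metrics$actual_bpm_sd, metrics$actual_bpm_mean),
    invalid_gap_s = metrics$max_invalid_gap_s)
  tols <- c(bpm_marked_vs_actual_pct = config$max_marked_vs_actual_bpm_pct,
            bpm_sd_diff_pct = config$max_sd_diff_pct,
            amplitude_cv_pct = config$max_amplitude_cv_pct,
            bpm_cv_pct = config$max_bpm_cv_pct,
            invalid_gap_s = config$max_invalid_gap_s)
  pass <- !is.na(vals) & vals <= tols
  reason <- ifelse(is.na(vals), "unanalyzable",
                   ifelse(pass, "within tolerance", "exceeds tolerance"))
  checks <- data.frame(metric = names(vals), value = unname(vals),
                       tolerance = unname(tols), pass = unname(pass),
                       reason = unname(reason), stringsAsFactors = FALSE)
  notes <- character()
  if (!is.null(diffs) && is.finite(diffs$marked_vs_gui_pct) &&
      abs(diffs$marked_vs_gui_pct) > config$gui_advisory_pct) {
    notes <- c(notes, sprintf(
      "advisory: marked BPM differs from GUI BPM by %+.1f%% (advisory threshold %.1f%%)",
      diffs$marked_vs_gui_pct, config$gui_advisory_pct))
  }
  structure(list(checks = checks, overall = all(checks$pass), notes = notes),
            class = "qa_result")
}

#' @export
print.qa_result <- function(x, ...) {
  cat(sprintf("QA result: %s\n", if (x$overall) "PASS" else "FAIL"))
  print.data.frame(x$checks, row.names = FALSE, digits = 4)
  for (n in x$notes) cat(" ", n, "\n")
  invisible(x)
}

#' Render a QA report
#'
#' Deterministic, stable-ordered human-readable report with failing metrics
#' listed first. When `path` is given the text is written there and a
#' machine-readable JSON twin is written alongside (`<path>.json`).
#'
#' @param result a [qa_evaluate()] result.
#' @param metrics the [trace_metrics()] the result was computed from.
#' @param path optional output file path.
#' @return character vector of report lines, invisibly.
#' @export
render_report <- function(result, metrics, path = NULL) {
  ck <- result$checks[order(result$checks$pass, result$checks$metric), ]
  fmt <- function(v) ifelse(is.na(v), "--", sprintf("%.2f", v))
  lines <- c(
    sprintf("BREATHING TRACE QA REPORT: %s", if (result$overall) "PASS" else "FAIL"),
    "",
    sprintf("%-28s %10s %10s  %s", "metric", "value", "tolerance", "status"),
    sprintf("%-28s %10s %10s  %s", ck$metric, fmt(ck$value), fmt(ck$tolerance),
            ifelse(ck$pass, "pass", paste0("FAIL (", ck$reason, ")"))),
    "",
    "Scan metrics:",
    sprintf("  GUI BPM %s | marked BPM %s +/- %s | actual BPM %s +/- %s",
            fmt(metrics$gui_bpm), fmt(metrics$marked_bpm_mean),
            fmt(metrics$marked_bpm_sd), fmt(metrics$actual_bpm_mean),
            fmt(metrics$actual_bpm_sd)),
    sprintf("  BPM range %s - %s | amplitude %s +/- %s cm",
            fmt(metrics$bpm_min), fmt(metrics$bpm_max),
            fmt(metrics$amplitude_mean), fmt(metrics$amplitude_sd)),
    sprintf("  peak range %s cm | trough range %s cm",
            fmt(metrics$peak_range), fmt(metrics$trough_range)))
  if (length(result$notes)) lines <- c(lines, "", result$notes)
  if (!is.null(path)) {
    writeLines(lines, path)
    jsonlite::write_json(
      list(overall = if (result$overall) "pass" else "fail",
           checks = result$checks, notes = result$notes,
           metrics = unclass(metrics)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = 10, na = "null")
  }
  invisible(lines)
}
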