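# The central per-scan entry point: parse -> detect -> metrics -> diffs ->
# QA evaluation, returned as one classed object.

#' Audit one breathing trace
#'
#' Runs the full per-scan pipeline: the trace is parsed (VXP or DAT by file
#' extension) or taken as given, vendor marks and algorithmic extrema are
#' extracted, the per-scan metric set and method differences are computed,
#' and the scan is evaluated against the QA tolerances.
#'
#' @param x path to a `.vxp` / `.dat` file, or a [breathing_trace()].
#' @param gui_bpm breathing rate shown on the vendor GUI, breaths/min (`NA`
#'   allowed: method-vs-GUI differences are then undefined).
#' @param detection a [detection_config()].
#' @param tolerances a [tolerance_config()].
#' @param orient polarity handling passed to [read_vxp()].
#' @return object of class `breath_audit`: list with `trace`, `marked`
#'   (`NULL` when the trace carries fewer than 2 marks), `detected`,
#'   `metrics`, `diffs` (`NULL` without a usable `gui_bpm`), `qa`, `source`,
#'   and `call`.
#' @export
#' @examples
#' gen <- generate_trace(trace_spec(duration = 60, seed = 7))
#' a <- audit_trace(gen$trace, gui_bpm = 15)
#' print(a)
audit_trace <- function(x, gui_bpm = NA_real_,
                        detection = detection_config(),
                        tolerances = tolerance_config(),
                        orient = "auto") {
  src <- ""
  if (is.character(x)) {
    src <- x
    ext <- tolower(tools::file_ext(x))
    x <- if (ext == "dat") read_dat(x) else read_vxp(x, orient = orient)
  }
  if (!inherits(x, "breathing_trace")) {
    abort_config("'x' must be a file path or a breathing_trace")
  }
  marked <- tryCatch(marked_extrema(x),
                     breathqa_insufficient_error = function(e) NULL)
  detected <- detect_extrema(x, detection)
  metrics <- compute_metrics(x, marked, detected, gui_bpm = gui_bpm)
  diffs <- tryCatch(compute_diffs(metrics),
                    breathqa_undefined_metric = function(e) NULL)
  qa <- qa_evaluate(metrics, diffs, tolerances)
  structure(list(trace = x, marked = marked, detected = detected,
                 metrics = metrics, diffs = diffs, qa = qa,
                 source = src, call = match.call()),
            class = "breath_audit")
}

#' @export
print.breath_audit <- function(x, ...) {
  cat(sprintf("<breath_audit>%s %s\n",
              if (nzchar(x$source)) paste0(" ", basename(x$source)) else "",
              if (x$qa$overall) "PASS" else "FAIL"))
  cat(sprintf("  actual %.1f +/- %.1f BPM | marked %s | amplitude %.2f +/- %.2f cm\n",
              x$metrics$actual_bpm_mean, x$metrics$actual_bpm_sd,
              if (is.na(x$metrics$marked_bpm_mean)) "--" else
                sprintf("%.1f +/- %.1f BPM", x$metrics$marked_bpm_mean,
                        x$metrics$marked_bpm_sd),
              x$metrics$amplitude_mean, x$metrics$amplitude_sd))
  failing <- x$qa$checks$metric[!x$qa$checks$pass]
  if (length(failing)) cat("  failing:", paste(failing, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.breath_audit <- function(object, ...) {
  print(object$metrics)
  if (!is.null(object$diffs)) print(object$diffs)
  print(object$qa)
  invisible(object)
}

#' Plot an audited breathing trace
#'
#' Amplitude versus time with detected extrema in purple and vendor marks in
#' black, mirroring the application's trace panel.
#'
#' @param x a `breath_audit` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.breath_audit <- function(x, ...) {
  s <- x$trace$samples
  graphics::plot(s$time, s$amplitude, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "amplitude (cm)",
                 main = if (nzchar(x$source)) basename(x$source) else "breathing trace",
                 ...)
  graphics::points(x$detected$time, x$detected$amplitude, col = "purple",
                   pch = 19, cex = 0.8)
  if (!is.null(x$marked)) {
    graphics::points(x$marked$time, x$marked$amplitude, col = "black",
                     pch = 4, cex = 1.1)
  }
  graphics::legend("topright", legend = c("detected", "marked"),
                   col = c("purple", "black"), pch = c(19, 4), bty = "n")
  invisible(x)
}
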