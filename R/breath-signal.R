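# Smoothing of the surrogate amplitude signal and independent location of
# "actual" breathing peaks and troughs, ignoring fluctuations that do not
# contribute to the breathing cycle.

#' Extrema detection configuration
#'
#' @param smoothing_window moving-average window in seconds. Default 0.25 s:
#'   short enough to leave 6--24 BPM breathing essentially unattenuated while
#'   suppressing sensor noise.
#' @param min_half_period minimum peak-to-trough separation in seconds.
#'   Default 0.5 s, i.e. a 60 BPM physiological ceiling.
#' @param min_excursion_fraction candidate peak--trough excursions below this
#'   fraction of the median excursion are rejected as non-breathing
#'   fluctuations. Default 0.2.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(smoothing_window = 0.25, min_half_period = 0.5,
                             min_excursion_fraction = 0.2) {
  stopifnot_scalar_num(smoothing_window, "smoothing_window", positive = TRUE)
  stopifnot_scalar_num(min_half_period, "min_half_period", positive = TRUE)
  stopifnot_scalar_num(min_excursion_fraction, "min_excursion_fraction", positive = TRUE)
  if (min_excursion_fraction >= 1) {
    abort_config("'min_excursion_fraction' must be < 1")
  }
  structure(list(smoothing_window = smoothing_window,
                 min_half_period = min_half_period,
                 min_excursion_fraction = min_excursion_fraction),
            class = "detection_config")
}

#' Centered moving-average smoothing
#'
#' Averages over valid samples in a centered window; near the trace edges the
#' window shrinks. Invalid samples neither contribute to nor receive a value
#' from their neighbours' windows (they come back as the mean of the valid
#' samples around them, or `NA` when none are in reach).
#'
#' @param trace a [breathing_trace()].
#' @param window window length in seconds; must span at least 2 sample
#'   intervals.
#' @return numeric vector of smoothed amplitudes, same length as the trace.
#' @export
smooth_trace <- function(trace, window = 0.25) {
  fs <- trace$header$samples_per_second
  if (!is.numeric(window) || length(window) != 1 || window * fs < 2) {
    abort_config("smoothing window must span at least 2 sample intervals")
  }
  a <- trace$samples$amplitude
  v <- trace$samples$valid & is.finite(a)
  k <- max(1L, as.integer(floor(window * fs / 2)))
  n <- length(a)
  x <- ifelse(v, a, 0)
  cs <- c(0, cumsum(x))
  cn <- c(0, cumsum(as.numeric(v)))
  lo <- pmax(1L, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

new_extremum_series <- function(index, time, amplitude, kind, source) {
  structure(data.frame(index = as.integer(index), time = time,
                       amplitude = amplitude, kind = kind, source = source,
                       stringsAsFactors = FALSE),
            class = c("extremum_series", "data.frame"))
}

# Merge consecutive same-kind extrema, keeping the most extreme (first on
# ties); restores strict peak/trough alternation.
merge_alternate <- function(df) {
  repeat {
    if (nrow(df) < 2) return(df)
    same <- which(df$kind[-1] == df$kind[-nrow(df)])
    if (!length(same)) return(df)
    j <- same[1]
    a1 <- df$amplitude[j]; a2 <- df$amplitude[j + 1]
    drop <- if (df$kind[j] == "peak") {
      if (a2 > a1) j else j + 1L        # first wins ties
    } else {
      if (a2 < a1) j else j + 1L
    }
    df <- df[-drop, , drop = FALSE]
  }
}

assert_alternating <- function(series) {
  if (nrow(series) >= 2) {
    stopifnot(all(series$kind[-1] != series$kind[-nrow(series)]),
              all(diff(series$time) > 0))
  }
  invisible(series)
}

#' Detect breathing extrema in a trace
#'
#' Locates the actual breathing peaks and troughs of the amplitude signal:
#' the signal is moving-average smoothed, strict turning points of the
#' smoothed signal are collected (the first sample of a flat extremum wins),
#' strict alternation is enforced by keeping the most extreme of any
#' same-kind run, and adjacent peak--trough pairs whose excursion falls below
#' `min_excursion_fraction` of the median excursion or whose separation is
#' shorter than `min_half_period` are removed, weakest first. Each surviving
#' extremum is finally refined to the most extreme raw (unsmoothed) sample
#' within half a smoothing window, so reported times and amplitudes come from
#' the recorded signal itself.
#'
#' @param trace a [breathing_trace()].
#' @param config a [detection_config()].
#' @return an `extremum_series` data frame (`index`, `time`, `amplitude`,
#'   `kind`, `source = "detected"`) with strictly alternating kinds.
#' @export
detect_extrema <- function(trace, config = detection_config()) {
  fs <- trace$header$samples_per_second
  ys <- smooth_trace(trace, config$smoothing_window)
  v <- trace$samples$valid & is.finite(ys)
  idx <- which(v)
  if (length(idx) < 3) abort_insufficient("too few valid samples to detect breathing")
  y <- ys[idx]
  d <- diff(y)
  nz <- which(d != 0)
  if (length(nz) < 2) abort_insufficient("no breathing cycle found (flat signal)")
  ss <- sign(d[nz])
  turn <- which(ss[-length(ss)] != ss[-1])
  if (!length(turn)) abort_insufficient("no breathing cycle found (monotone signal)")
  pos <- nz[turn] + 1L  # first sample of any plateau at the turn
  kind <- ifelse(ss[turn] > 0, "peak", "trough")

  df <- data.frame(index = idx[pos], time = trace$samples$time[idx[pos]],
                   amplitude = y[pos], kind = kind, stringsAsFactors = FALSE)
  df <- merge_alternate(df)

  # excursion / half-period filter; median frozen from the initial candidates
  if (nrow(df) >= 2) {
    med <- stats::median(abs(diff(df$amplitude)))
    repeat {
      if (nrow(df) < 2) break
      exc <- abs(diff(df$amplitude))
      gap <- diff(df$time)
      bad <- which(exc < config$min_excursion_fraction * med |
                     gap < config$min_half_period)
      if (!length(bad)) break
      j <- bad[which.min(exc[bad])]
      df <- merge_alternate(df[-c(j, j + 1L), , drop = FALSE])
    }
  }
  if (nrow(df) < 2) abort_insufficient("fewer than 2 breathing extrema retained")

  # refine each extremum against the raw signal within half a window
  k <- max(1L, as.integer(floor(config$smoothing_window * fs / 2)))
  a <- trace$samples$amplitude
  vraw <- trace$samples$valid & is.finite(a)
  n <- length(a)
  ref <- vapply(seq_len(nrow(df)), function(i) {
    win <- max(1L, df$index[i] - k):min(n, df$index[i] + k)
    win <- win[vraw[win]]
    if (!length(win)) return(df$index[i])
    if (df$kind[i] == "peak") win[which.max(a[win])] else win[which.min(a[win])]
  }, integer(1))
  df$index <- ref
  df$time <- trace$samples$time[ref]
  df$amplitude <- a[ref]
  df <- df[!duplicated(df$index), , drop = FALSE]
  df <- merge_alternate(df[order(df$time), , drop = FALSE])
  if (nrow(df) < 2) abort_insufficient("fewer than 2 breathing extrema retained")

  assert_alternating(new_extremum_series(df$index, df$time, df$amplitude,
                                         df$kind, "detected"))
}

#' Extract vendor-marked extrema from a trace
#'
#' Converts the file's P marks to peaks and Z marks to troughs at the marked
#' samples' times and amplitudes. Runs of consecutive same-kind marks are
#' resolved by keeping the more extreme one (a note is attached as the
#' `"merged"` attribute).
#'
#' @param trace a [breathing_trace()].
#' @return an `extremum_series` with `source = "marked"`.
#' @export
marked_extrema <- function(trace) {
  s <- trace$samples
  im <- which(s$mark != "none")
  if (length(im) < 2) abort_insufficient("fewer than 2 vendor marks in trace")
  df <- data.frame(index = im, time = s$time[im], amplitude = s$amplitude[im],
                   kind = ifelse(s$mark[im] == "P", "peak", "trough"),
                   stringsAsFactors = FALSE)
  n0 <- nrow(df)
  df <- merge_alternate(df)
  if (nrow(df) < 2) abort_insufficient("fewer than 2 alternating vendor marks")
  out <- assert_alternating(new_extremum_series(df$index, df$time, df$amplitude,
                                                df$kind, "marked"))
  attr(out, "merged") <- n0 - nrow(df)
  out
}

#' @export
print.extremum_series <- function(x, ...) {
  cat(sprintf("<extremum_series> %d extrema (%d peaks, %d troughs), source=%s\n",
              nrow(x), sum(x$kind == "peak"), sum(x$kind == "trough"),
              x$source[1] %||% "?"))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
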