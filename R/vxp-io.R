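# Reading and writing Varian RPM/RGSC VXP breathing-trace files, plus a
# minimal legacy two-column DAT dialect.
#
# The VXP dialect implemented here is a key=value header block
# (CRC, Version, Data_layout, Patient_ID, Date, Total_study_time,
# Samples_per_second, Scale_factor) followed by a `[Data]` marker and
# comma-separated rows ordered per Data_layout. Unknown header keys are
# preserved verbatim so a parse -> serialize round trip is lossless.

VXP_KNOWN_KEYS <- c("CRC", "Version", "Data_layout", "Patient_ID", "Date",
                    "Total_study_time", "Samples_per_second", "Scale_factor")

#' Construct a VXP header
#'
#' @param samples_per_second sampling rate in Hz (> 0).
#' @param scale_factor dimensionless divisor mapping raw file amplitude to cm
#'   (> 0).
#' @param version,patient_id,date,crc header text fields, kept verbatim.
#' @param total_study_time trace duration in seconds (defaults to last
#'   timestamp on read).
#' @param data_layout ordered character vector naming the data columns; must
#'   contain at least `"amplitude"`, `"timestamp"` and `"mark"`.
#' @param extra named character vector of unknown header keys preserved
#'   verbatim.
#' @param inverted logical; `TRUE` when the amplitude polarity was flipped on
#'   read so that peaks correspond to inhalation (see [read_vxp()]).
#' @return a list of class `vxp_header`.
#' @export
vxp_header <- function(samples_per_second, scale_factor = 1000,
                       version = "1.7", patient_id = "anonymous", date = "",
                       total_study_time = NA_real_,
                       data_layout = c("amplitude", "phase", "timestamp",
                                       "validflag", "ttlin", "mark", "ttlout"),
                       crc = "0000", extra = character(), inverted = FALSE) {
  stopifnot_scalar_num(samples_per_second, "samples_per_second", positive = TRUE)
  stopifnot_scalar_num(scale_factor, "scale_factor", positive = TRUE)
  missing_cols <- setdiff(c("amplitude", "timestamp", "mark"), data_layout)
  if (length(missing_cols)) {
    abort_format(sprintf("data_layout lacks required column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  structure(list(version = version, data_layout = data_layout,
                 patient_id = patient_id, date = date,
                 total_study_time = total_study_time,
                 samples_per_second = samples_per_second,
                 scale_factor = scale_factor, crc = crc,
                 extra = extra, inverted = isTRUE(inverted)),
            class = "vxp_header")
}

#' Construct a breathing trace
#'
#' A breathing trace couples a [vxp_header()] with a sample table holding
#' `time` (s from trace start), `amplitude` (cm, physical), `phase` (radians,
#' may be `NA`), `valid` (logical) and `mark` (one of `"none"`, `"P"`, `"Z"`).
#'
#' @param header a `vxp_header`.
#' @param samples data frame with columns `time`, `amplitude`, and optionally
#'   `phase`, `valid`, `mark` (defaulted when absent).
#' @return object of class `breathing_trace`.
#' @export
breathing_trace <- function(header, samples) {
  if (!inherits(header, "vxp_header")) abort_config("'header' must be a vxp_header")
  samples <- as.data.frame(samples)
  if (is.null(samples$phase)) samples$phase <- NA_real_
  if (is.null(samples$valid)) samples$valid <- TRUE
  if (is.null(samples$mark)) samples$mark <- "none"
  samples$mark[is.na(samples$mark) | samples$mark == ""] <- "none"
  bad_mark <- setdiff(unique(samples$mark), c("none", "P", "Z"))
  if (length(bad_mark)) {
    abort_format(sprintf("unknown mark value(s): %s", paste(bad_mark, collapse = ", ")))
  }
  if (nrow(samples) < 2L) abort_data("a breathing trace needs at least 2 samples")
  dup <- which(diff(samples$time) <= 0)
  if (length(dup)) {
    abort_data(sprintf("timestamps not strictly increasing at sample %d", dup[1] + 1L),
               index = dup[1] + 1L)
  }
  samples <- samples[, c("time", "amplitude", "phase", "valid", "mark")]
  rownames(samples) <- NULL
  structure(list(header = header, samples = samples), class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<breathing_trace> %d samples @ %g Hz (%.1f s)\n",
              n, x$header$samples_per_second, x$samples$time[n]))
  marks <- table(factor(x$samples$mark, levels = c("P", "Z")))
  cat(sprintf("  marks: %d P, %d Z | amplitude range [%.3f, %.3f] cm%s\n",
              marks[["P"]], marks[["Z"]],
              min(x$samples$amplitude), max(x$samples$amplitude),
              if (x$header$inverted) " | polarity inverted on read" else ""))
  invisible(x)
}

parse_header_num <- function(vals, key) {
  if (!key %in% names(vals)) abort_format(sprintf("missing header key '%s'", key))
  x <- suppressWarnings(as.numeric(vals[[key]]))
  if (is.na(x)) abort_format(sprintf("garbled header key '%s': %s", key, vals[[key]]))
  x
}

#' Read a VXP breathing-trace file
#'
#' Parses the key=value header and the comma-separated data section, converts
#' raw amplitudes to cm (raw / `Scale_factor`), timestamps from integer
#' milliseconds to seconds, and attaches the vendor P (peak) / Z (trough)
#' marks to their samples.
#'
#' RPM conventions can record inhalation as decreasing amplitude. With
#' `orient = "auto"` the polarity is detected per file: when the mean
#' amplitude at P-marked samples falls below the mean at Z-marked samples the
#' signal is viewed inverted (sign flipped, flag recorded in the header).
#'
#' @param path path to a VXP file.
#' @param orient `"auto"` (default), `"none"`, or `"invert"`.
#' @return a [breathing_trace()].
#' @export
read_vxp <- function(path, orient = c("auto", "none", "invert")) {
  orient <- match.arg(orient)
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  marker <- which(trimws(lines) == "[Data]")
  if (!length(marker)) abort_format("missing [Data] section marker")
  marker <- marker[1]
  head_lines <- trimws(lines[seq_len(marker - 1L)])
  head_lines <- head_lines[nzchar(head_lines)]
  kv <- regmatches(head_lines, regexpr("=", head_lines), invert = TRUE)
  ok <- vapply(kv, length, 1L) == 2L
  if (any(!ok)) abort_format(sprintf("garbled header line: %s", head_lines[!ok][1]))
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  val_or <- function(key, default = "") {
    if (key %in% names(vals)) vals[[key]] else default
  }

  sps <- parse_header_num(vals, "Samples_per_second")
  scale <- parse_header_num(vals, "Scale_factor")
  if (!"Data_layout" %in% names(vals)) abort_format("missing header key 'Data_layout'")
  layout <- trimws(strsplit(vals[["Data_layout"]], ",", fixed = TRUE)[[1]])
  tst <- if ("Total_study_time" %in% names(vals)) {
    parse_header_num(vals, "Total_study_time")
  } else NA_real_
  extra <- vals[setdiff(names(vals), VXP_KNOWN_KEYS)]

  data_lines <- lines[-seq_len(marker)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (!length(data_lines)) qa_abort("empty data section",
                                 c("breathqa_empty_trace", "breathqa_data_error"))

  parts <- strsplit(data_lines, ",", fixed = TRUE)
  # trailing empty fields are dropped by strsplit; pad rows that end in ","
  nf <- lengths(parts)
  short_tail <- nf == length(layout) - 1L & endsWith(data_lines, ",")
  parts[short_tail] <- lapply(parts[short_tail], function(p) c(p, ""))
  nf <- lengths(parts)
  if (any(nf != length(layout))) {
    bad <- which(nf != length(layout))[1]
    abort_format(sprintf("data row %d has %d fields, expected %d per Data_layout",
                         bad, nf[bad], length(layout)))
  }
  m <- matrix(unlist(parts, use.names = FALSE), ncol = length(layout), byrow = TRUE)
  colnames(m) <- layout

  raw_amp <- suppressWarnings(as.numeric(m[, "amplitude"]))
  ts_ms <- suppressWarnings(as.numeric(m[, "timestamp"]))
  if (anyNA(raw_amp)) {
    abort_format(sprintf("non-numeric amplitude at data row %d", which(is.na(raw_amp))[1]))
  }
  if (anyNA(ts_ms)) {
    abort_format(sprintf("non-numeric timestamp at data row %d", which(is.na(ts_ms))[1]))
  }
  mark <- trimws(m[, "mark"])
  phase <- if ("phase" %in% layout) {
    suppressWarnings(as.numeric(m[, "phase"]))
  } else NA_real_
  valid <- if ("validflag" %in% layout) {
    trimws(m[, "validflag"]) == "1"
  } else TRUE

  header <- vxp_header(samples_per_second = sps, scale_factor = scale,
                       version = val_or("Version"),
                       patient_id = val_or("Patient_ID"),
                       date = val_or("Date"),
                       total_study_time = tst, data_layout = layout,
                       crc = val_or("CRC"), extra = extra)
  trace <- breathing_trace(header, data.frame(
    time = ts_ms / 1000, amplitude = raw_amp / scale,
    phase = phase, valid = valid, mark = mark,
    stringsAsFactors = FALSE))
  if (is.na(trace$header$total_study_time)) {
    trace$header$total_study_time <- max(trace$samples$time)
  }

  flip <- switch(orient,
    none = FALSE,
    invert = TRUE,
    auto = {
      p <- trace$samples$amplitude[trace$samples$mark == "P"]
      z <- trace$samples$amplitude[trace$samples$mark == "Z"]
      length(p) > 0 && length(z) > 0 && mean(p) < mean(z)
    })
  if (flip) {
    trace$samples$amplitude <- -trace$samples$amplitude
    trace$header$inverted <- TRUE
  }
  trace
}

#' Write a breathing trace to a VXP file
#'
#' Emits a file that [read_vxp()] parses back to an identical trace (header
#' fields, timestamps, amplitudes within one raw unit / scale factor, and
#' marks). Amplitudes inverted on read are written back in the original file
#' polarity.
#'
#' @param trace a [breathing_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vxp <- function(trace, path) {
  if (!inherits(trace, "breathing_trace")) abort_config("'trace' must be a breathing_trace")
  h <- trace$header
  s <- trace$samples
  amp <- s$amplitude
  if (h$inverted) amp <- -amp
  raw <- amp * h$scale_factor

  cols <- lapply(h$data_layout, function(col) {
    switch(col,
      amplitude = sprintf("%.4f", raw),
      phase = ifelse(is.na(s$phase), "", sprintf("%.6f", s$phase)),
      timestamp = sprintf("%d", as.integer(round(s$time * 1000))),
      validflag = ifelse(s$valid, "1", "0"),
      mark = ifelse(s$mark == "none", "", s$mark),
      rep("0", nrow(s)))  # ttlin/ttlout and any other columns
  })
  rows <- do.call(paste, c(cols, sep = ","))

  hdr <- c(sprintf("CRC=%s", h$crc),
           sprintf("Version=%s", h$version),
           sprintf("Data_layout=%s", paste(h$data_layout, collapse = ",")),
           sprintf("Patient_ID=%s", h$patient_id),
           sprintf("Date=%s", h$date),
           sprintf("Total_study_time=%g",
                   if (is.na(h$total_study_time)) max(s$time) else h$total_study_time),
           sprintf("Samples_per_second=%g", h$samples_per_second),
           sprintf("Scale_factor=%g", h$scale_factor))
  if (length(h$extra)) hdr <- c(hdr, sprintf("%s=%s", names(h$extra), h$extra))

  res <- tryCatch(writeLines(c(hdr, "[Data]", rows), path),
                  error = function(e) abort_io(sprintf("cannot write '%s': %s",
                                                       path, conditionMessage(e))))
  invisible(path)
}

#' Read a legacy two-column DAT trace
#'
#' Compatibility shim for much older systems: a two-column comma-separated
#' text file of `time_s,amplitude_cm`. The resulting trace carries no vendor
#' marks and no phase channel.
#'
#' @param path path to the DAT file.
#' @return a [breathing_trace()].
#' @export
read_dat <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) qa_abort("empty DAT file", c("breathqa_empty_trace", "breathqa_data_error"))
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1]
    abort_format(sprintf("DAT row %d has %d fields, expected 2", bad, nf[bad]))
  }
  tt <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  aa <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(tt) || anyNA(aa)) {
    abort_format(sprintf("non-numeric DAT value at row %d", which(is.na(tt) | is.na(aa))[1]))
  }
  sps <- 1 / stats::median(diff(tt))
  header <- vxp_header(samples_per_second = sps, scale_factor = 1,
                       version = "DAT", total_study_time = max(tt),
                       data_layout = c("timestamp", "amplitude", "mark"))
  breathing_trace(header, data.frame(time = tt, amplitude = aa,
                                     stringsAsFactors = FALSE))
}

#' Write a legacy two-column DAT trace
#'
#' @param trace a [breathing_trace()]; marks and phase are not representable
#'   in this dialect and are dropped.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(trace, path) {
  s <- trace$samples
  writeLines(sprintf("%.6f,%.6f", s$time, s$amplitude), path)
  invisible(path)
}
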