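# Synthetic breathing traces: piecewise half-cosine waveforms with
# controllable per-cycle period variability, peak/trough level variability,
# baseline drift, sensor noise, and mark-placement error. The generator is
# the test substrate for every other module; its ground truth is returned
# alongside each trace.

#' Synthetic trace specification
#'
#' Defaults encode the study conditions this package simulates: 120 s scans
#' sampled at 25 Hz, 15 breaths/min with a within-scan BPM coefficient of
#' variation of 0.18, a 0.3 cm mean amplitude (peak +0.3 / trough -0.3 cm)
#' with peak/trough level SDs of 0.072 cm (within-scan amplitude CV near
#' 17%), a 0.01 cm-per-cycle baseline random walk, 0.001 cm additive sensor
#' noise (marker-tracking precision scale), per-mark time jitter of 0.41 s
#' with a per-scan systematic period error of SD 7.6% (jointly calibrated so
#' a default cohort reproduces a marked-vs-actual mean-BPM difference SD near
#' 9.6% and a relative-SD difference spread near 18.4%), and a 2% mark-miss
#' probability.
#'
#' @param duration trace length in seconds (> 0).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param bpm_mean mean breathing rate, breaths/min (> 0).
#' @param bpm_cv per-half-cycle breathing-rate CV (fraction, >= 0).
#' @param peak_level_mean,trough_level_mean mean inhale/exhale levels in cm
#'   (`peak_level_mean > trough_level_mean`).
#' @param peak_level_sd,trough_level_sd per-breath level SDs in cm (>= 0).
#' @param drift_sd_per_cycle baseline random-walk step SD per full cycle, cm.
#' @param noise_sd additive Gaussian sensor noise SD, cm.
#' @param mark_time_jitter_sd SD of the per-mark placement time error, s.
#' @param mark_period_error_sd SD of the per-scan systematic relative period
#'   error of the marking system (fraction): the whole mark sequence for a
#'   scan is stretched by one factor `1 + delta`, emulating the predictive
#'   filter assigning phase with a consistent per-scan bias.
#' @param mark_miss_prob probability a true extremum gets no mark, in `[0, 1)`.
#' @param seed integer seed; all randomness flows from it through named
#'   streams (periods, levels, noise, marks), so identical seeds give
#'   identical traces.
#' @return list of class `trace_spec`.
#' @export
trace_spec <- function(duration = 120, sample_rate = 25, bpm_mean = 15,
                       bpm_cv = 0.18, peak_level_mean = 0.3,
                       trough_level_mean = -0.3, peak_level_sd = 0.072,
                       trough_level_sd = 0.072, drift_sd_per_cycle = 0.01,
                       noise_sd = 0.001, mark_time_jitter_sd = 0.41,
                       mark_period_error_sd = 0.076, mark_miss_prob = 0.02,
                       seed = 1L) {
  stopifnot_scalar_num(duration, "duration", positive = TRUE)
  stopifnot_scalar_num(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar_num(bpm_mean, "bpm_mean", positive = TRUE)
  for (nm in c("bpm_cv", "peak_level_sd", "trough_level_sd",
               "drift_sd_per_cycle", "noise_sd", "mark_time_jitter_sd",
               "mark_period_error_sd")) {
    stopifnot_scalar_num(get(nm), nm, nonneg = TRUE)
  }
  stopifnot_scalar_num(mark_miss_prob, "mark_miss_prob", nonneg = TRUE)
  if (mark_miss_prob >= 1) abort_config("'mark_miss_prob' must be < 1")
  if (peak_level_mean <= trough_level_mean) {
    abort_config("'peak_level_mean' must exceed 'trough_level_mean'")
  }
  structure(list(duration = duration, sample_rate = sample_rate,
                 bpm_mean = bpm_mean, bpm_cv = bpm_cv,
                 peak_level_mean = peak_level_mean,
                 trough_level_mean = trough_level_mean,
                 peak_level_sd = peak_level_sd,
                 trough_level_sd = trough_level_sd,
                 drift_sd_per_cycle = drift_sd_per_cycle,
                 noise_sd = noise_sd,
                 mark_time_jitter_sd = mark_time_jitter_sd,
                 mark_period_error_sd = mark_period_error_sd,
                 mark_miss_prob = mark_miss_prob,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

# truncated-normal draws by rejection, deterministic under the caller's seed
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi) {
      qa_abort("degenerate spec: fixed value outside feasible range",
               "breathqa_spec_error")
    }
    return(rep(mean, n))
  }
  p_ok <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  if (p_ok < 0.5) {
    qa_abort(sprintf(
      "infeasible spec: only %.0f%% of draws from N(%g, %g) fall in [%g, %g]",
      100 * p_ok, mean, sd, lo, hi), "breathqa_spec_error")
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

MIN_HALF_PERIOD_S <- 0.5  # shared floor with detection_config()$min_half_period
MIN_MARK_SEP_S <- 0.2     # refractory separation between successive marks

#' Generate a synthetic breathing trace with ground truth
#'
#' Per-half-cycle breathing rates are drawn as Normal(`bpm_mean`,
#' `bpm_cv * bpm_mean`), truncated so half-cycles stay in `[0.5, 15]` s; the
#' corresponding extremum times receive peak/trough levels drawn per spec
#' plus a baseline random walk, and successive extrema are joined by
#' half-cosine segments. Additive Gaussian noise is applied afterwards.
#' Ground-truth extrema are snapped to the most extreme noiseless sample near
#' each true extremum (what the sampled trace actually shows); marks are
#' placed at those samples, perturbed by time jitter, and dropped with the
#' miss probability.
#'
#' @param spec a [trace_spec()].
#' @param patient_id text recorded in the VXP header.
#' @return list with `trace` (a [breathing_trace()]) and `truth` (an
#'   `extremum_series` with `source = "truth"`).
#' @export
generate_trace <- function(spec, patient_id = "synthetic") {
  if (!inherits(spec, "trace_spec")) abort_config("'spec' must be a trace_spec")
  fs <- spec$sample_rate
  dur <- spec$duration
  th_mean <- 30 / spec$bpm_mean
  if (th_mean < MIN_HALF_PERIOD_S) {
    qa_abort("infeasible spec: mean half-cycle shorter than the 0.5 s floor",
             "breathqa_spec_error")
  }
  n_half <- ceiling(dur / th_mean * 1.6) + 8L

  half_periods <- with_stream(spec$seed, "periods", {
    bpm <- rtruncnorm(n_half, spec$bpm_mean, spec$bpm_cv * spec$bpm_mean,
                      lo = 2, hi = 30 / MIN_HALF_PERIOD_S)
    list(hp = 30 / bpm, offset = stats::runif(1, 0.2, 0.8))
  })
  hp <- half_periods$hp
  # first (virtual) extremum sits before t = 0 so the trace starts mid-slope
  e_time <- -half_periods$offset * hp[1] + c(0, cumsum(hp))
  keep <- which(e_time < dur + 2 * th_mean)
  e_time <- e_time[keep]
  n_e <- length(e_time)
  if (n_e < 4) qa_abort("infeasible spec: trace too short for one breath",
                        "breathqa_spec_error")
  kind <- rep(c("trough", "peak"), length.out = n_e)

  levels <- with_stream(spec$seed, "levels", {
    lev <- ifelse(kind == "peak",
                  stats::rnorm(n_e, spec$peak_level_mean, spec$peak_level_sd),
                  stats::rnorm(n_e, spec$trough_level_mean, spec$trough_level_sd))
    drift <- cumsum(stats::rnorm(n_e, 0, spec$drift_sd_per_cycle / sqrt(2)))
    lev + drift
  })

  n <- as.integer(floor(dur * fs))
  t_ms <- round((seq_len(n) - 1) * 1000 / fs)
  t <- t_ms / 1000

  seg <- findInterval(t, e_time)
  seg[seg < 1] <- 1L
  seg[seg >= n_e] <- n_e - 1L
  s <- (t - e_time[seg]) / (e_time[seg + 1L] - e_time[seg])
  clean <- levels[seg] + (levels[seg + 1L] - levels[seg]) * (1 - cos(pi * s)) / 2

  noise <- if (spec$noise_sd > 0) {
    with_stream(spec$seed, "noise", stats::rnorm(n, 0, spec$noise_sd))
  } else 0
  amp <- clean + noise

  # ground truth: interior extrema snapped to the most extreme noiseless sample
  interior <- which(e_time >= 0 & e_time <= t[n])
  snap <- vapply(interior, function(k) {
    i0 <- as.integer(round(e_time[k] * fs)) + 1L
    i0 <- min(n, max(1L, i0))
    win <- max(1L, i0 - 2L):min(n, i0 + 2L)
    if (kind[k] == "peak") win[which.max(clean[win])] else win[which.min(clean[win])]
  }, integer(1))
  truth <- merge_alternate(data.frame(
    index = snap, time = t[snap], amplitude = clean[snap],
    kind = kind[interior], stringsAsFactors = FALSE))
  truth <- new_extremum_series(truth$index, truth$time, truth$amplitude,
                               truth$kind, "truth")

  # marks: truth positions, jittered and thinned
  mark <- rep("none", n)
  if (nrow(truth) > 0) {
    mk <- with_stream(spec$seed, "marks", {
      delta <- stats::rnorm(1, 0, spec$mark_period_error_sd)
      tt <- truth$time[1] + (truth$time - truth$time[1]) * (1 + delta)
      tt <- tt + stats::rnorm(nrow(truth), 0, spec$mark_time_jitter_sd)
      miss <- stats::runif(nrow(truth)) < spec$mark_miss_prob
      data.frame(time = tt, kind = truth$kind, miss = miss,
                 stringsAsFactors = FALSE)
    })
    mk <- mk[!mk$miss, , drop = FALSE]
    if (nrow(mk)) {
      mk$index <- pmin(n, pmax(1L, as.integer(round(mk$time * fs)) + 1L))
      mk <- mk[order(mk$index), , drop = FALSE]
      mk <- mk[!duplicated(mk$index), , drop = FALSE]
      # marking systems have a refractory separation: jittered marks landing
      # within MIN_MARK_SEP_S of the previous kept mark are dropped (the
      # separation sits below the 0.5 s half-period floor, so unjittered
      # marks are never affected)
      keep <- rep(TRUE, nrow(mk))
      last_t <- (mk$index[1] - 1L) / fs
      for (j in seq_len(nrow(mk))[-1]) {
        if ((mk$index[j] - 1L) / fs - last_t < MIN_MARK_SEP_S) {
          keep[j] <- FALSE
        } else {
          last_t <- (mk$index[j] - 1L) / fs
        }
      }
      mk <- mk[keep, , drop = FALSE]
      mark[mk$index] <- ifelse(mk$kind == "peak", "P", "Z")
    }
  }

  # recorded phase channel: 0 at each peak, advancing to 2*pi at the next
  pk_t <- e_time[kind == "peak"]
  phase <- rep(NA_real_, n)
  if (length(pk_t) >= 2) {
    pseg <- findInterval(t, pk_t)
    inb <- pseg >= 1 & pseg < length(pk_t)
    phase[inb] <- 2 * pi * (t[inb] - pk_t[pseg[inb]]) /
      (pk_t[pseg[inb] + 1L] - pk_t[pseg[inb]])
  }

  header <- vxp_header(samples_per_second = fs, scale_factor = 1000,
                       patient_id = patient_id, date = "20230101",
                       total_study_time = dur)
  trace <- breathing_trace(header, data.frame(
    time = t, amplitude = amp, phase = phase, valid = TRUE, mark = mark,
    stringsAsFactors = FALSE))
  list(trace = trace, truth = truth)
}

#' Generate a synthetic cohort of VXP files
#'
#' Draws one breathing rate per patient from a cohort Gaussian (default
#' Normal(15, 4.6) BPM truncated at 4), generates each trace with
#' [generate_trace()], writes the VXP files, and records the true parameters
#' per scan in a `manifest.csv` for recovery tests.
#'
#' @param n number of patients (>= 1).
#' @param out_dir output directory (created if needed).
#' @param seed master seed for the cohort.
#' @param bpm_cohort_mean,bpm_cohort_sd cohort distribution of per-patient
#'   mean BPM.
#' @param bpm_floor lower truncation of the cohort distribution, BPM.
#' @param overrides named list of [trace_spec()] fields overriding the
#'   defaults for every patient.
#' @return invisibly, a list with `manifest` (data frame), `files`, `dir`.
#' @export
generate_cohort <- function(n, out_dir, seed = 1L, bpm_cohort_mean = 15,
                            bpm_cohort_sd = 4.6, bpm_floor = 4,
                            overrides = list()) {
  if (n < 1) abort_config("'n' must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bpm <- with_stream(seed, "cohort",
                     rtruncnorm(n, bpm_cohort_mean, bpm_cohort_sd,
                                lo = bpm_floor, hi = 50))
  rows <- vector("list", n)
  files <- character(n)
  for (i in seq_len(n)) {
    args <- utils::modifyList(
      list(bpm_mean = bpm[i], seed = stream_seed(seed, sprintf("patient-%d", i))),
      overrides)
    sp <- do.call(trace_spec, args)
    gen <- generate_trace(sp, patient_id = sprintf("synthetic-%04d", i))
    files[i] <- file.path(out_dir, sprintf("trace_%04d.vxp", i))
    write_vxp(gen$trace, files[i])
    tb <- interval_bpm(gen$truth)
    rows[[i]] <- data.frame(
      id = i, file = basename(files[i]), seed = sp$seed,
      bpm_mean_spec = bpm[i], bpm_realized = mean(tb),
      bpm_cv_realized = stats::sd(tb) / mean(tb),
      amplitude_realized = mean(abs(diff(gen$truth$amplitude)) / 2),
      n_extrema = nrow(gen$truth), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(manifest = manifest, files = files, dir = out_dir))
}
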