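# Fixtures and independent oracles built in code at test time.

# Pure cosine breathing trace: peaks at t = 0, T, 2T, ... (T = 60/bpm s).
make_cosine_trace <- function(duration = 60, fs = 25, bpm = 15,
                              peak = 0.5, trough = -0.5,
                              mark_extrema = FALSE,
                              ripple_frac = 0, ripple_mult = 5) {
  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  f <- bpm / 60
  mid <- (peak + trough) / 2
  amp <- (peak - trough) / 2
  a <- mid + amp * cos(2 * pi * f * t)
  if (ripple_frac > 0) {
    a <- a + ripple_frac * (peak - trough) * cos(2 * pi * f * ripple_mult * t)
  }
  mark <- rep("none", n)
  if (mark_extrema) {
    T_full <- 1 / f
    pk_t <- seq(0, duration, by = T_full)
    tr_t <- seq(T_full / 2, duration, by = T_full)
    pk_i <- round(pk_t * fs) + 1
    tr_i <- round(tr_t * fs) + 1
    mark[pk_i[pk_i >= 2 & pk_i <= n - 1]] <- "P"
    mark[tr_i[tr_i >= 2 & tr_i <= n - 1]] <- "Z"
  }
  breathing_trace(vxp_header(samples_per_second = fs, scale_factor = 1000),
                  data.frame(time = t, amplitude = a, mark = mark,
                             stringsAsFactors = FALSE))
}

# Independent brute-force oracle: strict local extrema of the *unsmoothed*
# signal (plateau: first sample wins), alternation by keeping the more
# extreme of any same-kind run, then the same excursion / half-period filter
# semantics re-derived with plain loops.
oracle_extrema <- function(trace, config = detection_config()) {
  a <- trace$samples$amplitude
  tt <- trace$samples$time
  n <- length(a)
  pos <- integer(0)
  kind <- character(0)
  for (i in 2:(n - 1)) {
    if (a[i] == a[i - 1]) next  # not the first sample of a plateau
    r <- i + 1
    while (r <= n && a[r] == a[i]) r <- r + 1
    if (r > n) next
    if (a[i] > a[i - 1] && a[i] > a[r]) {
      pos <- c(pos, i); kind <- c(kind, "peak")
    } else if (a[i] < a[i - 1] && a[i] < a[r]) {
      pos <- c(pos, i); kind <- c(kind, "trough")
    }
  }
  merge_runs <- function(pos, kind) {
    repeat {
      if (length(pos) < 2) return(list(pos = pos, kind = kind))
      changed <- FALSE
      for (j in seq_len(length(pos) - 1)) {
        if (kind[j] == kind[j + 1]) {
          better_second <- if (kind[j] == "peak") a[pos[j + 1]] > a[pos[j]]
                           else a[pos[j + 1]] < a[pos[j]]
          drop <- if (better_second) j else j + 1
          pos <- pos[-drop]; kind <- kind[-drop]
          changed <- TRUE
          break
        }
      }
      if (!changed) return(list(pos = pos, kind = kind))
    }
  }
  m <- merge_runs(pos, kind)
  pos <- m$pos; kind <- m$kind
  if (length(pos) >= 2) {
    med <- stats::median(abs(diff(a[pos])))
    repeat {
      if (length(pos) < 2) break
      exc <- abs(diff(a[pos]))
      gap <- diff(tt[pos])
      bad <- which(exc < config$min_excursion_fraction * med |
                     gap < config$min_half_period)
      if (!length(bad)) break
      j <- bad[which.min(exc[bad])]
      pos <- pos[-c(j, j + 1)]; kind <- kind[-c(j, j + 1)]
      m <- merge_runs(pos, kind)
      pos <- m$pos; kind <- m$kind
    }
  }
  data.frame(index = pos, kind = kind, stringsAsFactors = FALSE)
}

# Printed reference grid for the displacement table at a 19% phase shift
# (rows: amplitudes 0.25..3.00 cm; columns: phases 0%..90%).
reference_displacement_grid <- function() {
  matrix(c(
    0.1, 0.3, 0.3, 0.2, 0.0, -0.1, -0.3, -0.3, -0.2,  0.0,
    0.3, 0.5, 0.5, 0.3, 0.0, -0.3, -0.5, -0.5, -0.3,  0.0,
    0.4, 0.8, 0.8, 0.5, 0.0, -0.4, -0.8, -0.8, -0.5,  0.0,
    0.6, 1.0, 1.1, 0.7, 0.1, -0.6, -1.0, -1.1, -0.7, -0.1,
    0.7, 1.3, 1.3, 0.9, 0.1, -0.7, -1.3, -1.3, -0.9, -0.1,
    0.9, 1.5, 1.6, 1.0, 0.1, -0.9, -1.5, -1.6, -1.0, -0.1,
    1.0, 1.8, 1.8, 1.2, 0.1, -1.0, -1.8, -1.8, -1.2, -0.1,
    1.2, 2.0, 2.1, 1.4, 0.1, -1.2, -2.0, -2.1, -1.4, -0.1,
    1.3, 2.3, 2.4, 1.5, 0.1, -1.3, -2.3, -2.4, -1.5, -0.1,
    1.5, 2.6, 2.6, 1.7, 0.1, -1.5, -2.6, -2.6, -1.7, -0.1,
    1.6, 2.8, 2.9, 1.9, 0.2, -1.6, -2.8, -2.9, -1.9, -0.2,
    1.8, 3.1, 3.2, 2.1, 0.2, -1.8, -3.1, -3.2, -2.1, -0.2),
    nrow = 12, byrow = TRUE)
}

# Spec for a trace with no stochastic components at all.
zero_var_spec <- function(duration = 60, bpm = 15, seed = 1) {
  trace_spec(duration = duration, bpm_mean = bpm, bpm_cv = 0,
             peak_level_sd = 0, trough_level_sd = 0, drift_sd_per_cycle = 0,
             noise_sd = 0, mark_time_jitter_sd = 0, mark_period_error_sd = 0,
             mark_miss_prob = 0, seed = seed)
}

# A well-behaved breathing scan: realistic but comfortably inside tolerances.
clean_spec <- function(seed = 1, duration = 120) {
  trace_spec(duration = duration, bpm_cv = 0.06, peak_level_sd = 0.02,
             trough_level_sd = 0.02, drift_sd_per_cycle = 0.002,
             mark_time_jitter_sd = 0.05, mark_period_error_sd = 0,
             mark_miss_prob = 0, seed = seed)
}
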