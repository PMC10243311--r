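mini_trace <- function(n = 50, fs = 25) {
  breathing_trace(vxp_header(fs),
                  data.frame(time = (0:(n - 1)) / fs,
                             amplitude = cos(2 * pi * (0:(n - 1)) / fs / 4)))
}

series_from <- function(time, amplitude, kind) {
  structure(data.frame(index = seq_along(time), time = time,
                       amplitude = amplitude, kind = kind,
                       source = "detected", stringsAsFactors = FALSE),
            class = c("extremum_series", "data.frame"))
}

test_that("per-interval BPM is 30 over the half-cycle gap", {
  s <- series_from(c(0, 2), c(0.5, -0.5), c("peak", "trough"))
  expect_equal(interval_bpm(s), 15)
  s3 <- series_from(c(0, 2, 4, 6), c(0.5, -0.5, 0.5, -0.5),
                    c("peak", "trough", "peak", "trough"))
  expect_equal(interval_bpm(s3), c(15, 15, 15))
  expect_equal(sd(interval_bpm(s3)), 0)
  expect_equal(interval_bpm(s3, cycle = "full"), c(15, 15))
})

test_that("generator periods are recovered by interval_bpm at 100 cycles", {
  sp <- trace_spec(duration = 410, bpm_mean = 15, seed = 99)  # > 100 cycles
  gen <- generate_trace(sp)
  b <- interval_bpm(detect_extrema(gen$trace))
  expect_gt(length(b), 190)
  expect_lt(abs(mean(b) - 15) / 15, 0.02)
})

test_that("a perfect cosine yields textbook metrics", {
  tr <- make_cosine_trace(duration = 60, peak = 0.5, trough = -0.5, bpm = 15,
                          mark_extrema = TRUE)
  det <- detect_extrema(tr)
  mk <- marked_extrema(tr)
  m <- compute_metrics(tr, mk, det, gui_bpm = 15)
  expect_equal(m$amplitude_mean, 0.5, tolerance = 1e-3)
  expect_equal(m$amplitude_sd, 0, tolerance = 1e-3)
  expect_equal(m$peak_range, 0, tolerance = 1e-3)
  expect_equal(m$trough_range, 0, tolerance = 1e-3)
  expect_equal(m$actual_bpm_mean, 15, tolerance = 0.01)
  expect_true(m$bpm_min <= m$actual_bpm_mean && m$actual_bpm_mean <= m$bpm_max)
})

test_that("peak range and per-phase amplitudes follow their definitions", {
  s <- series_from(c(0, 2, 4), c(0.6, 0, 0.4), c("peak", "trough", "peak"))
  m <- compute_metrics(mini_trace(), NULL, s, gui_bpm = 15)
  expect_equal(m$peak_range, 0.2)
  expect_equal(m$amplitude_mean, mean(c(0.3, 0.2)))
  expect_equal(m$amplitude_sd, sd(c(0.3, 0.2)))
  expect_true(is.na(m$marked_bpm_mean))
})

test_that("generator amplitude CV near 17% is recovered over 50 cycles", {
  sp <- trace_spec(duration = 210, seed = 55)  # ~52 cycles at 15 BPM
  gen <- generate_trace(sp)
  det <- detect_extrema(gen$trace)
  m <- compute_metrics(gen$trace, NULL, det)
  expect_lt(abs(m$amplitude_sd / m$amplitude_mean - 0.17), 0.04)
})

test_that("method differences follow their formulas", {
  m <- trace_metrics(gui_bpm = 15, marked_bpm_mean = 15, marked_bpm_sd = 1,
                     actual_bpm_mean = 15, actual_bpm_sd = 1)
  d <- compute_diffs(m)
  expect_equal(d$marked_vs_gui_pct, 0)
  expect_equal(d$actual_vs_marked_pct, 0)
  expect_equal(d$sd_marked_vs_actual_pct, 0)

  m2 <- trace_metrics(gui_bpm = 15, marked_bpm_mean = 12, marked_bpm_sd = 2,
                      actual_bpm_mean = 14, actual_bpm_sd = 1)
  d2 <- compute_diffs(m2)
  expect_equal(d2$marked_vs_gui_pct, -20)
  expect_equal(d2$actual_vs_marked_pct, (14 - 12) / 12 * 100)
  expect_equal(d2$sd_marked_vs_actual_pct, (2 / 12 - 1 / 14) * 100)

  expect_error(compute_diffs(trace_metrics(actual_bpm_mean = 15)),
               class = "breathqa_undefined_metric")
})

test_that("mark jitter inflates the marked relative SD", {
  sp <- trace_spec(duration = 120, mark_time_jitter_sd = 0.4,
                   mark_period_error_sd = 0, mark_miss_prob = 0, seed = 17)
  gen <- generate_trace(sp)
  a <- audit_trace(gen$trace, gui_bpm = 15)
  expect_gt(a$diffs$sd_marked_vs_actual_pct, 0)
})

test_that("marks coinciding with detected extrema give identical metrics", {
  gen <- generate_trace(zero_var_spec(seed = 31))
  det <- detect_extrema(gen$trace)
  mk <- marked_extrema(gen$trace)
  m <- compute_metrics(gen$trace, mk, det, gui_bpm = 15)
  expect_equal(m$marked_bpm_mean, m$actual_bpm_mean)
  expect_equal(m$marked_bpm_sd, m$actual_bpm_sd)
  d <- compute_diffs(m)
  expect_equal(d$actual_vs_marked_pct, 0)
  expect_equal(d$sd_marked_vs_actual_pct, 0)
})

test_that("metrics are scale-equivariant in amplitude and time", {
  gen <- generate_trace(trace_spec(duration = 60, noise_sd = 0, seed = 77))
  tr <- gen$trace
  det <- detect_extrema(tr)
  m <- compute_metrics(tr, NULL, det)

  k <- 2.5
  scaled <- tr
  scaled$samples$amplitude <- tr$samples$amplitude * k
  ms <- compute_metrics(scaled, NULL, detect_extrema(scaled))
  expect_equal(ms$amplitude_mean, k * m$amplitude_mean, tolerance = 1e-6)
  expect_equal(ms$amplitude_sd, k * m$amplitude_sd, tolerance = 1e-6)
  expect_equal(ms$peak_range, k * m$peak_range, tolerance = 1e-6)
  expect_equal(ms$trough_range, k * m$trough_range, tolerance = 1e-6)
  expect_equal(ms$actual_bpm_mean, m$actual_bpm_mean, tolerance = 1e-6)
  expect_equal(ms$actual_bpm_sd, m$actual_bpm_sd, tolerance = 1e-6)

  kt <- 2
  dilated <- breathing_trace(
    vxp_header(samples_per_second = tr$header$samples_per_second / kt,
               scale_factor = tr$header$scale_factor),
    data.frame(time = tr$samples$time * kt, amplitude = tr$samples$amplitude,
               mark = tr$samples$mark))
  md <- compute_metrics(dilated, NULL,
                        detect_extrema(dilated,
                                       detection_config(smoothing_window = 0.5)))
  expect_equal(md$actual_bpm_mean, m$actual_bpm_mean / kt, tolerance = 0.01)
  expect_equal(md$bpm_min, m$bpm_min / kt, tolerance = 0.01)
  expect_equal(md$amplitude_mean, m$amplitude_mean, tolerance = 0.01)
})

test_that("BPM and amplitude estimates are unbiased over 100 synthetic scans", {
  res <- generate_cohort(100, withr::local_tempdir(), seed = 2024,
                         overrides = list(duration = 60))
  rel_bpm <- rel_amp <- numeric(100)
  for (i in 1:100) {
    a <- audit_trace(res$files[i])
    rel_bpm[i] <- a$metrics$actual_bpm_mean / res$manifest$bpm_realized[i] - 1
    rel_amp[i] <- a$metrics$amplitude_mean / res$manifest$amplitude_realized[i] - 1
  }
  expect_lt(abs(mean(rel_bpm)), 0.01)
  expect_lt(abs(mean(rel_amp)), 0.01)
})

test_that("audit log appends rows with a stable schema", {
  gen <- generate_trace(clean_spec(seed = 6, duration = 60))
  a <- audit_trace(gen$trace, gui_bpm = 15)
  rec <- audit_record(a$metrics, a$diffs, a$qa)
  log <- withr::local_tempfile(fileext = ".csv")
  append_audit_record(rec, log)
  append_audit_record(rec, log)
  back <- read_audit_log(log)
  expect_equal(nrow(back), 2)
  expect_identical(names(back), names(rec))
  expect_equal(back$actual_bpm_mean[1], a$metrics$actual_bpm_mean)
  expect_equal(back$schema_version, c(1L, 1L))
})
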