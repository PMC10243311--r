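test_that("moving average leaves constants alone and spreads an impulse", {
  fs <- 25
  n <- 100
  const <- breathing_trace(vxp_header(fs), data.frame(time = (0:(n - 1)) / fs,
                                                      amplitude = rep(0.7, n)))
  expect_equal(smooth_trace(const, 0.25), rep(0.7, n))

  imp_a <- rep(0, n); imp_a[50] <- 1
  imp <- breathing_trace(vxp_header(fs), data.frame(time = (0:(n - 1)) / fs,
                                                    amplitude = imp_a))
  sm <- smooth_trace(imp, 0.2)  # 5-sample window at 25 Hz
  expect_equal(sm[48:52], rep(1 / 5, 5))
  expect_equal(sm[c(47, 53)], c(0, 0))

  expect_error(smooth_trace(const, 0.01), class = "breathqa_config_error")
})

test_that("moving-average gain on a pure cosine matches the Dirichlet factor", {
  fs <- 25
  tr <- make_cosine_trace(duration = 60, fs = fs, bpm = 15)  # 0.25 Hz
  window <- 0.25
  k <- floor(window * fs / 2)
  gain <- sum(cos(2 * pi * 0.25 * (-k:k) / fs)) / (2 * k + 1)
  sm <- smooth_trace(tr, window)
  interior <- (k + 1):(nrow(tr$samples) - k)
  expect_lt(max(abs(sm[interior] - gain * tr$samples$amplitude[interior])),
            0.01 * 0.5)  # within 1% of the 0.5 cm amplitude
})

test_that("extrema of a noiseless cosine are found at analytic times", {
  tr <- make_cosine_trace(duration = 60, fs = 25, bpm = 15)
  ex <- detect_extrema(tr)
  expect_true(abs(sum(ex$kind == "peak") - 15) <= 1)
  expect_true(abs(sum(ex$kind == "trough") - 15) <= 1)
  # analytic extrema: peaks at multiples of 4 s, troughs offset 2 s
  analytic <- ifelse(ex$kind == "peak",
                     round(ex$time / 4) * 4,
                     round((ex$time - 2) / 4) * 4 + 2)
  expect_lte(max(abs(ex$time - analytic)), 1 / 25 + 1e-9)
  # peaks at +0.5, troughs at -0.5
  expect_equal(ex$amplitude[ex$kind == "peak"], rep(0.5, sum(ex$kind == "peak")),
               tolerance = 1e-3)
})

test_that("small high-frequency ripple does not create spurious breaths", {
  base <- detect_extrema(make_cosine_trace(duration = 60))
  rippled <- detect_extrema(make_cosine_trace(duration = 60, ripple_frac = 0.05,
                                              ripple_mult = 5))
  expect_equal(nrow(rippled), nrow(base))
  expect_identical(rippled$kind, base$kind)
})

test_that("unanalyzable signals raise the insufficient-breathing error", {
  fs <- 25
  n <- 200
  ramp <- breathing_trace(vxp_header(fs),
                          data.frame(time = (0:(n - 1)) / fs,
                                     amplitude = seq(0, 1, length.out = n)))
  expect_error(detect_extrema(ramp), class = "breathqa_insufficient_error")
  flat <- breathing_trace(vxp_header(fs),
                          data.frame(time = (0:(n - 1)) / fs,
                                     amplitude = rep(1, n)))
  expect_error(detect_extrema(flat), class = "breathqa_insufficient_error")
})

test_that("detection matches the brute-force local-extrema oracle on noiseless traces", {
  for (seed in c(2, 5, 11, 19, 23)) {
    sp <- trace_spec(duration = 60, bpm_cv = 0.12, peak_level_sd = 0.05,
                     trough_level_sd = 0.05, drift_sd_per_cycle = 0,
                     noise_sd = 0, mark_time_jitter_sd = 0,
                     mark_period_error_sd = 0, mark_miss_prob = 0, seed = seed)
    gen <- generate_trace(sp)
    got <- detect_extrema(gen$trace)
    want <- oracle_extrema(gen$trace)
    expect_identical(got$index, want$index)
    expect_identical(got$kind, want$kind)
  }
})

test_that("detected kinds always alternate and times strictly increase", {
  for (seed in c(1, 4, 7, 12, 31)) {
    gen <- generate_trace(trace_spec(duration = 60, noise_sd = 0.02, seed = seed))
    ex <- detect_extrema(gen$trace)
    expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
    expect_true(all(diff(ex$time) > 0))
  }
})

test_that("detection on a pre-smoothed trace with a minimal window is stable", {
  tr <- make_cosine_trace(duration = 60)
  base <- detect_extrema(tr)
  pre <- tr
  pre$samples$amplitude <- smooth_trace(tr, 0.25)
  again <- detect_extrema(pre, detection_config(smoothing_window = 2 / 25))
  expect_equal(nrow(again), nrow(base))
  expect_identical(again$kind, base$kind)
  expect_lte(max(abs(again$time - base$time)), 1 / 25 + 1e-9)
})

test_that("vendor marks convert to an alternating extremum series", {
  fs <- 25
  n <- 200
  t <- (0:(n - 1)) / fs
  a <- 0.5 * cos(2 * pi * t / 4)
  mark <- rep("none", n)
  mark[round(2 * fs) + 1] <- "P"   # P at 2 s
  mark[round(4 * fs) + 1] <- "Z"   # Z at 4 s
  mark[round(6 * fs) + 1] <- "P"   # P at 6 s
  tr <- breathing_trace(vxp_header(fs), data.frame(time = t, amplitude = a,
                                                   mark = mark))
  ex <- marked_extrema(tr)
  expect_equal(nrow(ex), 3)
  expect_identical(ex$kind, c("peak", "trough", "peak"))
  expect_equal(ex$time, c(2, 4, 6))

  # consecutive same-kind marks: the more extreme survives
  mark2 <- rep("none", n)
  mark2[10] <- "P"; mark2[40] <- "P"; mark2[80] <- "Z"
  a2 <- rep(0, n); a2[10] <- 1.0; a2[40] <- 1.2; a2[80] <- -1
  tr2 <- breathing_trace(vxp_header(fs), data.frame(time = t, amplitude = a2,
                                                    mark = mark2))
  ex2 <- marked_extrema(tr2)
  expect_equal(nrow(ex2), 2)
  expect_equal(ex2$amplitude[ex2$kind == "peak"], 1.2)

  one_mark <- tr
  one_mark$samples$mark <- "none"
  one_mark$samples$mark[5] <- "P"
  expect_error(marked_extrema(one_mark), class = "breathqa_insufficient_error")
})

test_that("marks placed at true extrema reproduce the detected series", {
  gen <- generate_trace(zero_var_spec(seed = 21))
  mk <- marked_extrema(gen$trace)
  dt <- detect_extrema(gen$trace)
  expect_equal(nrow(mk), nrow(dt))
  expect_identical(mk$kind, dt$kind)
  expect_lte(max(abs(mk$time - dt$time)), 1 / 25 + 1e-9)
})

test_that("invalid samples are excluded from smoothing and detection", {
  tr <- make_cosine_trace(duration = 60)
  base <- detect_extrema(tr)
  tr$samples$valid[300:320] <- TRUE  # no-op, then corrupt a stretch
  corrupted <- tr
  corrupted$samples$amplitude[300:320] <- 5  # gross spike
  corrupted$samples$valid[300:320] <- FALSE
  ex <- detect_extrema(corrupted)
  expect_equal(nrow(ex), nrow(base))
  expect_true(all(ex$amplitude <= 0.51))
})
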