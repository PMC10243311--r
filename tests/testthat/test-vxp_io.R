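test_that("raw amplitudes are converted to cm via the scale factor", {
  f <- withr::local_tempfile(fileext = ".vxp")
  writeLines(c("CRC=12",
               "Version=1.7",
               "Data_layout=amplitude,timestamp,mark",
               "Patient_ID=p1",
               "Date=20230101",
               "Total_study_time=0.08",
               "Samples_per_second=25",
               "Scale_factor=10",
               "[Data]",
               "10,0,P",
               "5,40,",
               "10,80,Z"), f)
  tr <- read_vxp(f)
  expect_equal(tr$samples$amplitude, c(1.0, 0.5, 1.0))
  expect_equal(tr$samples$time, c(0, 0.04, 0.08))
  expect_equal(tr$samples$mark, c("P", "none", "Z"))
  expect_equal(tr$header$samples_per_second, 25)
})

test_that("write_vxp / read_vxp round-trips traces including marks and extras", {
  gen <- generate_trace(trace_spec(duration = 30, seed = 42))
  tr <- gen$trace
  tr$header$extra <- c(Unknown_key = "kept-verbatim")
  f <- withr::local_tempfile(fileext = ".vxp")
  write_vxp(tr, f)
  back <- read_vxp(f)
  expect_equal(back$header$samples_per_second, tr$header$samples_per_second)
  expect_equal(back$header$scale_factor, tr$header$scale_factor)
  expect_equal(back$header$patient_id, tr$header$patient_id)
  expect_equal(back$header$extra, tr$header$extra)
  expect_equal(back$samples$time, tr$samples$time, tolerance = 1e-9)
  # amplitude within one raw unit / scale factor
  expect_lt(max(abs(back$samples$amplitude - tr$samples$amplitude)),
            1 / tr$header$scale_factor)
  expect_identical(back$samples$mark, tr$samples$mark)
})

test_that("mark multiset is invariant under parse -> serialize -> parse", {
  for (seed in c(3, 9, 27)) {
    gen <- generate_trace(trace_spec(duration = 40, seed = seed))
    f1 <- withr::local_tempfile(fileext = ".vxp")
    f2 <- withr::local_tempfile(fileext = ".vxp")
    write_vxp(gen$trace, f1)
    t1 <- read_vxp(f1)
    write_vxp(t1, f2)
    t2 <- read_vxp(f2)
    marks1 <- t1$samples[t1$samples$mark != "none", c("time", "mark")]
    marks2 <- t2$samples[t2$samples$mark != "none", c("time", "mark")]
    expect_equal(marks1, marks2)
  }
})

test_that("a generated 60 s / 25 Hz file parses to 1500 samples", {
  gen <- generate_trace(trace_spec(duration = 60, sample_rate = 25, seed = 5))
  f <- withr::local_tempfile(fileext = ".vxp")
  write_vxp(gen$trace, f)
  tr <- read_vxp(f)
  expect_equal(nrow(tr$samples), 1500)
  expect_equal(tr$header$samples_per_second, 25)
})

test_that("inverted-polarity files are auto-detected and flipped", {
  gen <- generate_trace(trace_spec(duration = 30, seed = 8))
  flipped <- gen$trace
  flipped$samples$amplitude <- -flipped$samples$amplitude
  f <- withr::local_tempfile(fileext = ".vxp")
  write_vxp(flipped, f)
  tr <- read_vxp(f)  # P marks now at low raw values -> inverted view
  expect_true(tr$header$inverted)
  p_amp <- tr$samples$amplitude[tr$samples$mark == "P"]
  z_amp <- tr$samples$amplitude[tr$samples$mark == "Z"]
  expect_gt(mean(p_amp), mean(z_amp))
  # writing restores the original file polarity
  f2 <- withr::local_tempfile(fileext = ".vxp")
  write_vxp(tr, f2)
  raw_again <- read_vxp(f2, orient = "none")
  expect_lt(max(abs(raw_again$samples$amplitude - flipped$samples$amplitude)), 1e-3)
})

test_that("malformed VXP input raises classed errors naming the problem", {
  write_fixture <- function(lines) {
    f <- tempfile(fileext = ".vxp")
    writeLines(lines, f)
    f
  }
  base_hdr <- c("Data_layout=amplitude,timestamp,mark",
                "Samples_per_second=25", "Scale_factor=10")
  expect_error(read_vxp(write_fixture(c("Data_layout=amplitude,timestamp,mark",
                                        "Scale_factor=10", "[Data]", "1,0,"))),
               "Samples_per_second", class = "breathqa_format_error")
  expect_error(read_vxp(write_fixture(c(base_hdr, "[Data]",
                                        "1,0,", "2,40,", "3,40,"))),
               "sample 3", class = "breathqa_data_error")
  expect_error(read_vxp(write_fixture(c(base_hdr, "[Data]"))),
               class = "breathqa_empty_trace")
  expect_error(read_vxp(write_fixture(c(base_hdr, "[Data]", "1,0,,extra,"))),
               "row 1", class = "breathqa_format_error")
  expect_error(read_vxp(tempfile()), class = "breathqa_io_error")
})

test_that("legacy DAT traces parse and agree with their VXP rendering", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0,1.0", "0.04,0.8", "0.08,1.0"), f)
  tr <- read_dat(f)
  expect_equal(nrow(tr$samples), 3)
  expect_true(all(tr$samples$mark == "none"))
  expect_true(all(is.na(tr$samples$phase)))
  expect_equal(tr$samples$amplitude, c(1.0, 0.8, 1.0))

  gen <- generate_trace(trace_spec(duration = 20, seed = 13))
  fv <- withr::local_tempfile(fileext = ".vxp")
  fd <- withr::local_tempfile(fileext = ".dat")
  write_vxp(gen$trace, fv)
  write_dat(gen$trace, fd)
  from_vxp <- read_vxp(fv)
  from_dat <- read_dat(fd)
  expect_equal(from_dat$samples$time, from_vxp$samples$time, tolerance = 1e-6)
  expect_equal(from_dat$samples$amplitude, from_vxp$samples$amplitude,
               tolerance = 1e-3)

  fe <- withr::local_tempfile(fileext = ".dat")
  writeLines(character(), fe)
  expect_error(read_dat(fe), class = "breathqa_empty_trace")
  fr <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0,1.0", "0.04"), fr)
  expect_error(read_dat(fr), "row 2", class = "breathqa_format_error")
})

test_that("round-trip identity holds across a generated fixture set", {
  for (seed in 1:10) {
    gen <- generate_trace(trace_spec(duration = 20, seed = seed))
    f <- withr::local_tempfile(fileext = ".vxp")
    write_vxp(gen$trace, f)
    back <- read_vxp(f)
    expect_equal(back$samples$time, gen$trace$samples$time)
    expect_lt(max(abs(back$samples$amplitude - gen$trace$samples$amplitude)),
              1 / gen$trace$header$scale_factor)
    expect_identical(back$samples$mark, gen$trace$samples$mark)
  }
})
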