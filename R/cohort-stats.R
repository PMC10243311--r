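# Aggregation of per-scan audit records into cohort distributions: Gaussian
# fits of BPM spreads, method-difference statistics, and the 95% uncertainty
# summary applicable to any new patient.

#' Fit a Gaussian to a sample
#'
#' Maximum-likelihood-style fit on the raw values: `mu` is the sample mean and
#' `sigma` the sample standard deviation, with normal-theory 95% confidence
#' intervals (t for `mu`, chi-square for `sigma`).
#'
#' @param values numeric vector (non-finite values dropped; needs n >= 2 and
#'   non-zero spread).
#' @return list of class `gaussian_fit`: `mu`, `sigma`, `mu_ci95`,
#'   `sigma_ci95`, `n`.
#' @export
fit_gaussian <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 2) abort_insufficient("need at least 2 finite values to fit a Gaussian")
  mu <- mean(x)
  s <- stats::sd(x)
  if (s == 0) abort_insufficient("values are constant; spread cannot be fitted")
  mu_ci <- mu + stats::qt(c(0.025, 0.975), df = n - 1) * s / sqrt(n)
  sigma_ci <- sqrt((n - 1) * s^2 / stats::qchisq(c(0.975, 0.025), df = n - 1))
  structure(list(mu = mu, sigma = s, mu_ci95 = mu_ci, sigma_ci95 = sigma_ci, n = n),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit (n = %d): mu = %.2f (%.2f, %.2f), sigma = %.2f (%.2f, %.2f)\n",
              x$n, x$mu, x$mu_ci95[1], x$mu_ci95[2],
              x$sigma, x$sigma_ci95[1], x$sigma_ci95[2]))
  invisible(x)
}

#' Population 95% coverage interval of a Gaussian fit
#'
#' The interval containing about 95% of the population, `mu +/- 2 sigma`.
#' The 2x convention (rather than 1.96) matches [uncertainty95()] and is how
#' the cohort uncertainties in this package are expanded throughout.
#'
#' @param fit a [fit_gaussian()] result, or a numeric `mu` with `sigma` given.
#' @param sigma population SD, used when `fit` is numeric.
#' @return numeric length-2 interval.
#' @export
#' @examples
#' coverage95(15, 4.6)  # about 6 to 24 BPM
coverage95 <- function(fit, sigma = NULL) {
  if (inherits(fit, "gaussian_fit")) {
    mu <- fit$mu; s <- fit$sigma
  } else {
    mu <- fit; s <- sigma
    if (is.null(s)) abort_config("supply 'sigma' when 'fit' is numeric")
  }
  c(mu - 2 * s, mu + 2 * s)
}

#' Expand a 1-SD statistic to a 95% uncertainty
#'
#' The package's uncertainty convention: a 95% figure is twice the
#' corresponding 1-SD cohort statistic (2 x 9.6% -> 19.2%, rounding to the
#' same integers as 1.96 x for the statistics involved here, and more
#' transparent).
#'
#' @param sd_value 1-SD statistic (any unit).
#' @return the 95% figure, `2 * sd_value`.
#' @export
uncertainty95 <- function(sd_value) 2 * sd_value

method_pairs <- function() {
  data.frame(parameter = c("BPM mean", "BPM mean", "BPM mean", "BPM SD"),
             method_a = c("GUI", "GUI", "Marked", "Marked"),
             method_b = c("Marked", "Actual", "Actual", "Actual"),
             stringsAsFactors = FALSE)
}

record_diffs <- function(records) {
  cv <- function(s, m) ifelse(is.finite(s) & is.finite(m) & m != 0, s / m, NA_real_)
  g <- records$gui_bpm
  m <- records$marked_bpm_mean
  a <- records$actual_bpm_mean
  list(
    "BPM mean:GUI:Marked" = ifelse(is.finite(g) & g > 0, (m - g) / g * 100, NA_real_),
    "BPM mean:GUI:Actual" = ifelse(is.finite(g) & g > 0, (a - g) / g * 100, NA_real_),
    "BPM mean:Marked:Actual" = ifelse(is.finite(m) & m > 0, (a - m) / m * 100, NA_real_),
    "BPM SD:Marked:Actual" =
      (cv(records$marked_bpm_sd, m) - cv(records$actual_bpm_sd, a)) * 100)
}

#' Cohort method-difference summary
#'
#' For each method pair (GUI vs marked, GUI vs actual, marked vs actual for
#' the mean BPM, and marked vs actual for the relative BPM SD), the mean and
#' sample SD of the per-scan percent differences across the cohort. Records
#' with an undefined member are excluded per pair and counted.
#'
#' @param records audit-record data frame (see [read_audit_log()]).
#' @return data frame: `parameter`, `method_a`, `method_b`, `mean_pct`,
#'   `sd_pct`, `n`, `n_excluded`.
#' @export
diff_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2) {
    abort_insufficient("need at least 2 audit records")
  }
  pairs <- method_pairs()
  d <- record_diffs(records)
  out <- pairs
  out$mean_pct <- out$sd_pct <- NA_real_
  out$n <- out$n_excluded <- 0L
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$parameter[i], pairs$method_a[i], pairs$method_b[i], sep = ":")
    x <- d[[key]]
    ok <- is.finite(x)
    out$n[i] <- sum(ok)
    out$n_excluded[i] <- sum(!ok)
    if (sum(ok) >= 2) {
      out$mean_pct[i] <- mean(x[ok])
      out$sd_pct[i] <- stats::sd(x[ok])
    }
  }
  if (all(is.na(out$mean_pct))) {
    abort_insufficient("no method pair has 2 or more defined records")
  }
  out[, c("parameter", "method_a", "method_b", "mean_pct", "sd_pct", "n", "n_excluded")]
}

#' Summarize cohort uncertainties for a new patient
#'
#' Expands the cohort 1-SD statistics to 95% figures (see [uncertainty95()]):
#' the marked-BPM mean uncertainty from the SD of per-scan marked-vs-actual
#' mean differences; the marked-BPM SD uncertainty from the SD of per-scan
#' relative-SD differences; the amplitude uncertainty from the mean per-scan
#' amplitude CV; and the inspiration/exhalation level uncertainties from the
#' mean per-scan peak/trough ranges (converted cm -> mm).
#'
#' @param records audit-record data frame with at least 2 rows.
#' @return list of class `uncertainty_summary` with fields
#'   `marked_bpm_mean_unc_pct`, `marked_bpm_sd_unc_pct`, `amplitude_unc_pct`,
#'   `inspiration_unc_mm`, `exhalation_unc_mm`, and `n`.
#' @export
summarize_uncertainty <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2) {
    abort_insufficient("need at least 2 audit records")
  }
  d <- record_diffs(records)
  sd0 <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    if (all(x == x[1])) return(0)
    stats::sd(x)
  }
  mean0 <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
  }
  amp_cv <- 100 * records$amplitude_sd / records$amplitude_mean
  structure(list(
    marked_bpm_mean_unc_pct = uncertainty95(sd0(d[["BPM mean:Marked:Actual"]])),
    marked_bpm_sd_unc_pct = uncertainty95(sd0(d[["BPM SD:Marked:Actual"]])),
    amplitude_unc_pct = uncertainty95(mean0(amp_cv)),
    inspiration_unc_mm = uncertainty95(mean0(records$peak_range * 10)),
    exhalation_unc_mm = uncertainty95(mean0(records$trough_range * 10)),
    n = nrow(records)),
    class = "uncertainty_summary")
}

#' @export
print.uncertainty_summary <- function(x, ...) {
  cat(sprintf("Breathing uncertainties for a new patient (95%%, n = %d scans)\n", x$n))
  cat(sprintf("  Marked BPM (average):  %.0f%%\n", x$marked_bpm_mean_unc_pct))
  cat(sprintf("  Marked BPM (SD):       %.0f%%\n", x$marked_bpm_sd_unc_pct))
  cat(sprintf("  Amplitude:             %.0f%%\n", x$amplitude_unc_pct))
  cat(sprintf("  Inspiration level:     %.1f mm\n", x$inspiration_unc_mm))
  cat(sprintf("  Exhalation level:      %.1f mm\n", x$exhalation_unc_mm))
  invisible(x)
}

#' Cohort summary plots
#'
#' Writes histogram and box-and-whisker PNGs for the cohort: GUI/marked/actual
#' mean-BPM histograms, per-scan method-difference box plot, per-scan BPM-SD
#' and amplitude histograms, and per-scan amplitude/peak-range/trough-range
#' histograms.
#'
#' @param records audit-record data frame.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
plot_cohort <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  png_to <- function(name, expr) {
    f <- file.path(dir, name)
    grDevices::png(f, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    files <<- c(files, f)
  }
  png_to("bpm_means.png", {
    graphics::par(mfrow = c(1, 3))
    graphics::hist(records$gui_bpm, main = "GUI BPM", xlab = "BPM", col = "grey80")
    graphics::hist(records$marked_bpm_mean, main = "Marked BPM", xlab = "BPM", col = "grey80")
    graphics::hist(records$actual_bpm_mean, main = "Actual BPM", xlab = "BPM", col = "grey80")
  })
  d <- record_diffs(records)
  png_to("method_differences.png", {
    graphics::boxplot(d, names = c("mk-GUI", "act-GUI", "act-mk", "SD diff"),
                      ylab = "per-scan difference (%)", main = "Method differences")
    graphics::abline(h = 0, lty = 2)
  })
  png_to("per_scan_variability.png", {
    graphics::par(mfrow = c(1, 3))
    graphics::hist(100 * records$marked_bpm_sd / records$marked_bpm_mean,
                   main = "Marked BPM SD", xlab = "% of mean", col = "grey80")
    graphics::hist(100 * records$actual_bpm_sd / records$actual_bpm_mean,
                   main = "Actual BPM SD", xlab = "% of mean", col = "grey80")
    graphics::hist(100 * records$amplitude_sd / records$amplitude_mean,
                   main = "Amplitude SD", xlab = "% of mean", col = "grey80")
  })
  png_to("amplitudes.png", {
    graphics::par(mfrow = c(1, 3))
    graphics::hist(records$amplitude_mean, main = "Average amplitude", xlab = "cm", col = "grey80")
    graphics::hist(records$peak_range, main = "Peak range", xlab = "cm", col = "grey80")
    graphics::hist(records$trough_range, main = "Trough range", xlab = "cm", col = "grey80")
  })
  invisible(files)
}
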