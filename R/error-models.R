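# Closed-form clinical impact models: phase-shift tumor displacement for
# prospectively gated treatment, geometric miss of a circular PTV, and
# amplitude-variability voluming error with the extra ITV margin it demands.
#
# Unit conventions, fixed package-wide: breathing amplitudes and target
# geometry in cm; peak/trough level variability v in mm; voluming error
# epsilon in percent (negative = undervoluming); margins m in mm.

#' Tumor displacement from a respiratory phase shift
#'
#' For a cosine breathing trace of amplitude `A` (half the peak-to-trough
#' distance), a phase-binning error that shifts treatment by a fraction `phi`
#' of the cycle moves the target by
#' `dy = A * (cos(2*pi*x) - cos(2*pi*(x + phi)))` at breathing phase `x`
#' (fraction of cycle, 0 = full inhale). Positive `phi` means late arrival
#' (period underestimated); the sign of the displacement is retained so the
#' direction is reported.
#'
#' @param A breathing amplitude in cm (>= 0).
#' @param x breathing phase as fraction of cycle in `[0, 1)`.
#' @param phi phase shift as fraction of cycle, `|phi| <= 1`.
#' @return signed displacement in cm (vectorized over inputs).
#' @export
#' @examples
#' phase_displacement(A = 1, x = 0.2, phi = 0.19)  # ~1.08 cm
phase_displacement <- function(A, x, phi) {
  if (any(A < 0)) abort_config("'A' must be >= 0")
  if (any(abs(phi) > 1)) abort_config("'phi' must satisfy |phi| <= 1")
  A * (cos(2 * pi * x) - cos(2 * pi * (x + phi)))
}

#' Displacement grid over amplitudes and phases
#'
#' Tabulates [phase_displacement()] for a grid of breathing amplitudes (rows)
#' and breathing phases (columns) at one phase shift, rounded half away from
#' zero to 0.1 cm as printed clinically (`rounded = FALSE` for raw values).
#'
#' @param amplitudes breathing amplitudes in cm (default 0.25--3.00 by 0.25).
#' @param phases breathing phases as cycle fractions (default 0, 0.1, ..., 0.9).
#' @param phi phase shift as cycle fraction (default 0.19, a 2-SD
#'   marked-vs-actual period uncertainty).
#' @param rounded round to 1 decimal (default `TRUE`).
#' @return numeric matrix, `dimnames` giving amplitudes (cm) and phases (%).
#' @export
displacement_table <- function(amplitudes = seq(0.25, 3, by = 0.25),
                               phases = seq(0, 0.9, by = 0.1),
                               phi = 0.19, rounded = TRUE) {
  if (!length(amplitudes) || !length(phases)) {
    abort_config("'amplitudes' and 'phases' must be non-empty")
  }
  g <- outer(amplitudes, phases, function(a, x) phase_displacement(a, x, phi))
  dimnames(g) <- list(sprintf("%.2f", amplitudes),
                      sprintf("%.0f%%", 100 * phases))
  if (rounded) round_half_up(g, 1) else g
}

#' Maximum tumor displacement over the breathing cycle
#'
#' The maximum of `|phase_displacement(A, x, phi)|` over all phases `x` has
#' the closed form `2 * A * |sin(pi * phi)|`.
#'
#' @inheritParams phase_displacement
#' @return maximum absolute displacement in cm.
#' @export
#' @examples
#' max_displacement(A = 1, phi = 0.19)  # ~1.12 cm, prints as 1.1
max_displacement <- function(A, phi) {
  if (any(A < 0)) abort_config("'A' must be >= 0")
  2 * A * abs(sin(pi * phi))
}

#' Lens (overlap) area of two equal circles
#'
#' Area shared by two circles of radius `r` whose centers are `d` apart:
#' `2 r^2 acos(d / 2r) - (d/2) sqrt(4 r^2 - d^2)` for `d < 2r`, else 0.
#'
#' @param r circle radius in cm (> 0).
#' @param d center separation in cm (>= 0).
#' @return overlap area in cm^2.
#' @export
#' @examples
#' circle_overlap_area(r = 1, d = 1.1)  # ~1.06 cm^2
circle_overlap_area <- function(r, d) {
  stopifnot_scalar_num(r, "r", positive = TRUE)
  if (any(d < 0)) abort_config("'d' must be >= 0")
  ratio <- pmin(1, d / (2 * r))  # separated circles clamp to zero overlap
  ifelse(d >= 2 * r, 0,
         2 * r^2 * acos(ratio) - (d / 2) * sqrt(pmax(0, 4 * r^2 - d^2)))
}

#' Fraction of a gated PTV missed by a displaced target
#'
#' Models the planned and the actually treated PTV as equal circles of radius
#' `ptv_radius` displaced by `displacement`; the missed fraction is
#' `(pi r^2 - overlap) / (pi r^2)`, clipped to `[0, 1]`.
#'
#' @param ptv_radius PTV radius in cm (> 0).
#' @param displacement center displacement in cm (>= 0).
#' @return missed fraction in `[0, 1]`.
#' @export
#' @examples
#' ptv_missed_fraction(1, 1.1)  # ~0.66
ptv_missed_fraction <- function(ptv_radius, displacement) {
  stopifnot_scalar_num(ptv_radius, "ptv_radius", positive = TRUE)
  if (any(displacement < 0)) abort_config("'displacement' must be >= 0")
  full <- pi * ptv_radius^2
  pmin(1, pmax(0, (full - circle_overlap_area(ptv_radius, displacement)) / full))
}

#' Voluming error from peak/trough level variability
#'
#' Amplitude variability `v = (SD(peaks) + SD(troughs)) / 2` in mm maps to a
#' relative internal-target-area error
#' `epsilon = -5.13 * v - 6.71` (percent, r^2 = 0.76 in the underlying
#' phantom/patient regression), where
#' `epsilon = (ITA_sim - ITA_real) / ITA_sim` and negative values mean the
#' simulated target is undervolumed.
#'
#' @param sd_peaks standard deviation of peak levels over the scan, mm (>= 0).
#' @param sd_troughs standard deviation of trough levels, mm (>= 0).
#' @param slope,intercept regression coefficients of the `v -> epsilon` map.
#' @return list of class `voluming_estimate` with `v` (mm) and `epsilon`
#'   (percent).
#' @export
#' @examples
#' voluming_error(2, 0)  # v = 1 mm, epsilon = -11.84%
voluming_error <- function(sd_peaks, sd_troughs, slope = -5.13, intercept = -6.71) {
  if (any(sd_peaks < 0) || any(sd_troughs < 0)) {
    abort_config("level standard deviations must be >= 0")
  }
  v <- (sd_peaks + sd_troughs) / 2
  structure(list(v = v, epsilon = slope * v + intercept),
            class = "voluming_estimate")
}

#' @export
print.voluming_estimate <- function(x, ...) {
  cat(sprintf("Voluming estimate: v = %.2f mm -> epsilon = %.2f%%\n", x$v, x$epsilon))
  invisible(x)
}

#' Extra ITV margin required by a voluming error
#'
#' `m = -epsilon * x_MIP / 2`, the additional margin (mm) needed at each end
#' of travel when the MIP length in the motion direction is `x_mip` cm;
#' floored at 0 (an overvolumed target needs no extension).
#'
#' @param epsilon voluming error in percent (negative = undervoluming).
#' @param x_mip MIP length in the direction of motion, cm (> 0).
#' @return required margin in mm.
#' @export
#' @examples
#' required_margin(-11.4, 7)  # ~4.0 mm
required_margin <- function(epsilon, x_mip) {
  if (any(x_mip <= 0)) abort_config("'x_mip' must be > 0")
  pmax(0, -epsilon / 100 * (x_mip * 10) / 2)
}

#' Margin table over MIP lengths
#'
#' @param x_mip MIP lengths in cm (default 2--7).
#' @param epsilon voluming error in percent (default -11.4, the cohort
#'   median under the default study conditions).
#' @param rounded round margins to 0.1 mm (default `TRUE`).
#' @return data frame with `x_mip_cm` and `margin_mm`.
#' @export
margin_table <- function(x_mip = 2:7, epsilon = -11.4, rounded = TRUE) {
  m <- required_margin(epsilon, x_mip)
  data.frame(x_mip_cm = x_mip,
             margin_mm = if (rounded) round_half_up(m, 1) else m)
}

#' Phase misbinning from a relative period error
#'
#' A breathing period wrong by a fraction `relative_period_error` shifts
#' phase assignment by `round(relative_period_error / bin_width)` bins (half
#' away from zero), e.g. a 19% period error with 10% bins misbins by 2 bins.
#'
#' @param relative_period_error relative period error as a fraction.
#' @param bin_width respiratory bin width as a fraction of the cycle (> 0).
#' @return integer bin-shift count (signed).
#' @export
#' @examples
#' phase_uncertainty_to_bins(0.19, 0.10)  # 2
phase_uncertainty_to_bins <- function(relative_period_error, bin_width = 0.1) {
  if (any(bin_width <= 0)) abort_config("'bin_width' must be > 0")
  as.integer(round_half_up(relative_period_error / bin_width))
}
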