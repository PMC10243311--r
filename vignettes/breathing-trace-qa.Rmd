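---
title: "Methods: breathing-trace QA for 4DCT simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breathing-trace QA for 4DCT simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathqa)
```

## The problem

4DCT reconstruction sorts projection data into respiratory bins using the
peak/trough marks a vendor gating system (RPM/RGSC) places on the surrogate
breathing trace. Those marks are produced by a real-time predictive filter
and only sometimes reviewed by the operator, so they can disagree with the
breathing the patient actually did. Because binning runs off the marks, the
disagreement propagates directly into phase assignment, target voluming and
gated delivery. `breathqa` quantifies that disagreement per scan, flags scans
beyond statistical tolerances, and converts trace variability into clinical
error estimates.

## Per-scan metrics

One breathing *phase* is the half-cycle between an adjacent peak and trough.
For a gap of $\Delta t$ seconds the rate is $30/\Delta t$ breaths per minute
(BPM). The *marked* statistics use the file's P/Z marks; the *actual*
statistics use extrema re-detected from the signal. Means are paired with
sample standard deviations ($n-1$); percentage statistics are coefficients of
variation (CV = SD/mean). Amplitude per phase is half the absolute
peak-to-trough excursion, reported as mean and SD over the scan; peak and
trough ranges (max − min of the respective levels) expose progressive
spirometry drift. The breathing-rate range uses the actual intervals (the
marked range is available programmatically): the re-detected series is the
better estimate of what the patient did, which is what the range is meant to
describe.

Method differences for one scan are
$(\mathrm{marked}-\mathrm{GUI})/\mathrm{GUI}$,
$(\mathrm{actual}-\mathrm{GUI})/\mathrm{GUI}$,
$(\mathrm{actual}-\mathrm{marked})/\mathrm{marked}$ (each $\times 100$), and
the difference of relative SDs
$(\mathrm{CV}_\mathrm{marked}-\mathrm{CV}_\mathrm{actual}) \times 100$.

## Extrema detection

`detect_extrema()` proceeds in four steps:

1. **Smoothing.** Centered moving average, default window 0.25 s. At 6--24
   BPM (0.1--0.4 Hz) a 0.25 s window attenuates the breathing component by
   under 1% (Dirichlet-kernel gain) while suppressing sensor noise. Edges use
   shrunken windows; invalid samples neither contribute nor receive values.
2. **Turning points.** Strict sign changes of the smoothed first difference;
   the first sample of any flat run wins (determinism under plateaus).
   Alternation is enforced by keeping the most extreme of any same-kind run.
3. **Fluctuation rejection.** Adjacent peak--trough pairs with excursion
   below `min_excursion_fraction` (default 0.2) of the *median* excursion, or
   separated by less than `min_half_period` (default 0.5 s, a 60 BPM
   physiological ceiling), are removed weakest-first, re-enforcing
   alternation after each removal. The median resists outlier breaths; it is
   frozen from the initial candidate set so the threshold does not drift as
   pairs are removed.
4. **Refinement.** Each surviving extremum moves to the most extreme raw
   sample within half a smoothing window, so reported times and amplitudes
   come from the recorded signal, not the filtered one.

Boundary partial cycles are kept as extrema; they simply contribute fewer
intervals. All three parameters are exposed in `detection_config()` and the
CLI configuration file. They are declared defaults chosen for 6--24 BPM
adult breathing, not reconstructions of any particular vendor algorithm.

## Clinical impact models

Units are fixed package-wide: amplitudes and geometry in cm, level
variability $v$ in mm, voluming error $\varepsilon$ in percent, margins in mm.

* **Phase-shift displacement.** For a cosine trace of amplitude $A$ (half
  the peak-to-trough distance), a phase shift $\varphi$ (fraction of cycle)
  displaces the target by
  $\Delta y = A[\cos(2\pi x) - \cos(2\pi(x+\varphi))]$ at breathing phase
  $x$; the maximum over $x$ is $2A\sin(\pi\varphi)$. Positive $\varphi$
  means late arrival; signs are kept so direction is reported.
  `displacement_table()` tabulates a 12 x 10 grid (amplitudes 0.25--3 cm,
  phases 0--90%) at $\varphi = 0.19$, the 2-SD marked-vs-actual period
  uncertainty. Printed reference versions of this grid are not reproducible
  cell-for-cell under any single rounding rule; golden tests therefore pin
  only formula-consistent cells exactly and hold the full grid to 0.15 cm.
* **Misbinning.** A relative period error $e$ with bins of width $w$ shifts
  phase assignment by $\mathrm{round}(e/w)$ bins; 19% with 10% bins is a
  2-bin shift. Both $e$ and $w$ are arguments — the 2-SD figure and the
  bin-quantized variant are both valid inputs, neither is hard-coded.
* **Gated miss.** Planned and delivered PTVs are modelled as equal circles
  of radius $r$ at separation $d$; the missed fraction is
  $(\pi r^2 - \mathrm{lens}(r,d))/\pi r^2$ with the standard circle-circle
  lens area. The model is 2D by construction.
* **Voluming.** $v = (\mathrm{SD(peaks)}+\mathrm{SD(troughs)})/2$ in mm maps
  to $\varepsilon = -5.13v - 6.71$ (%), an empirical regression
  ($r^2 = 0.76$) between surrogate level variability and internal-target-area
  error; the required margin at each end of travel is
  $m = -\varepsilon \cdot x_\mathrm{MIP}/2$ (mm), floored at zero.

## Cohort statistics and the 95% convention

`fit_gaussian()` fits raw values by sample moments with normal-theory
intervals (t for $\mu$, chi-square for $\sigma$) rather than fitting a curve
to a histogram — better-posed, and equivalent at cohort sizes of interest.
95% uncertainty figures are **2 x the 1-SD cohort statistic**
(`uncertainty95()`); 2 and 1.96 round to the same integers for every
statistic involved, and 2 is transparent. The inspiration/exhalation level
uncertainties (mm) derive from the per-scan peak/trough *range* metrics —
the per-scan variability the application actually reports — converted cm to
mm. No outliers are removed by default.

## QA tolerances

Default gates are the 1-SD cohort statistics of the default study
conditions: marked-vs-actual mean-BPM difference 9.6%, relative-SD
difference 18.4%, within-scan amplitude CV 17%, within-scan BPM CV 18%, and
a 1 s ceiling on invalid-data gaps. Any single exceedance fails the scan.
The GUI-BPM comparison is advisory only (a ±20% spread is normal), and an
undefined required metric is recorded as a failure with reason
"unanalyzable" rather than silently passing. All tolerances are overridable
in `tolerance_config()` and the CLI configuration file.

## The synthetic-trace generator

`generate_trace()` builds a piecewise half-cosine waveform between drawn
extrema, so period and level variability are independent per cycle — the
minimal model that reproduces marked-vs-actual discrepancies and amplitude
CV at the same time. Defaults are the study conditions and are not tuned per
test:

| parameter | default | rationale |
|---|---|---|
| duration, rate | 120 s @ 25 Hz | typical 4DCT simulation capture |
| per-patient BPM | Normal(15, 4.6), truncated at 4 | cohort distribution of uncoached lung patients |
| within-scan BPM CV | 0.18 | observed per-scan breathing-rate SD |
| levels | +0.3 / −0.3 cm, SD 0.072 cm | 0.3 cm mean amplitude with ~17% amplitude CV |
| drift | 0.01 cm/cycle random walk | slow spirometry drift |
| noise | 0.001 cm | marker-tracking precision scale |
| mark errors | jitter 0.41 s; per-scan period error SD 7.6%; miss 2% | calibrated, see below |

Half-cycles are truncated at 0.5 s, the same floor the detector uses, so
generator and detector share an assumption rather than fighting over one.
All randomness flows from one seed through named streams (periods, levels,
noise, marks), so adding draws to one component never perturbs another.

**Mark-error calibration.** The mark model has three parts: iid per-mark
time jitter, a per-scan systematic relative period error (one factor
stretching the whole mark sequence, emulating a predictive filter that
assigns phase with a consistent per-scan bias), and random misses, with a
0.2 s refractory separation between successive marks (marking systems do not
emit marks tens of milliseconds apart). Jitter alone cannot reproduce the
cohort-level structure: it inflates the within-scan marked CV but barely
spreads the per-scan *mean* differences, while the systematic period error
shifts a scan's marked mean without touching its CV. The two scales were
calibrated once, jointly, so that a default 281-scan cohort shows an SD of
per-scan marked-vs-actual mean-BPM differences near 9.6% and an SD of
relative-SD differences near 18.4% (checked across six seeds: 8.5--9.9% and
18.7--21.2%), then frozen. One known artifact: symmetric time jitter
inflates the mean of per-interval $30/\Delta t$ (Jensen's inequality), so
the generator's cohort *mean* marked-vs-actual difference is a few percent
more negative than real cohorts show; the calibrated quantities are the
spreads, which drive the tolerances.

**What the generator does not emulate:** cardiac contamination, coughing or
apnea events, baseline shifts from patient repositioning, and any
correlation between breathing rate and mark quality. Passing tests on
synthetic cohorts therefore demonstrate correct recovery of second-order
statistics under this model, not performance on pathological real traces.

## File formats and numerical choices

* **VXP dialect.** Key=value header (CRC, Version, Data_layout, Patient_ID,
  Date, Total_study_time, Samples_per_second, Scale_factor), a `[Data]`
  marker, then comma-separated rows ordered per `Data_layout`. Unknown
  header keys round-trip verbatim; CRC is read, not validated. Timestamps
  are integer milliseconds in the file, seconds in memory; duplicate or
  non-monotone timestamps are data errors. Raw amplitudes divide by
  `Scale_factor` to cm — whether real exports are cm or scaled integers is
  undocumented, so the scale-factor convention is explicit and tested.
* **Polarity.** Some configurations record inhalation as decreasing
  amplitude. If the mean amplitude at P marks falls below that at Z marks
  the signal is viewed inverted (flag in the header, `orient` overridable),
  keeping peak = inhale semantics stable.
* **Invalid samples** stay in the trace but are excluded from smoothing and
  detection; gaps longer than the tolerance are QA failures.
* **DAT shim.** A minimal two-column `time_s,amplitude_cm` dialect for much
  older systems; no marks, so marked metrics are undefined and the QA
  records them as unanalyzable.
* **Rounding.** Clinical tables round half away from zero (2.85 mm prints
  as 2.9), matching printed practice; `round_half_up()` is exported.
* **Edited marks** are not distinguishable from automatic ones in the file;
  both are treated identically.

## Problem sizes in the test suite

Cohort recovery tests run 281 scans of 120 s at 25 Hz; parameter-recovery
and oracle-equivalence tests use 60--210 s traces and 100-scan cohorts;
confidence-interval coverage uses 1000 replicates of n = 50; the lens-area
Monte Carlo oracle uses 10^6 points. These sizes give sampling error well
inside the asserted tolerances while keeping the suite fast.

## Known limitations

The voluming regression is an empirical fit from phantom/patient studies and
carries its $r^2 = 0.76$ scatter into every margin estimate. The gated-miss
model is a 2D circle, not a 3D target. Surrogate amplitude is taken as given
(the marker block is correlated with, but not identical to, internal target
motion). The detector's defaults are declared, conservative choices for
adult free breathing — not a reconstruction of the vendor's real-time
filter — and frequency-domain analysis is out of scope.
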