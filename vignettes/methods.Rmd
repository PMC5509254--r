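---
title: "Models and methods behind ligomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ligomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligomir)
```

# The assay model

`ligomir` analyzes (and simulates) a multiplexed ligation assay whose
readout is a denaturing PAGE gel: each miRNA in a panel of up to 26 species
is converted, via capture ligation of a universal adapter followed by
ligation of a species-specific discrimination probe and a fluorescent
common probe, into a single-stranded DNA product of a unique, known length.
Fifty thermal cycles regenerate products from each template, giving linear
(not exponential) amplification. Band position therefore identifies the
species, and integrated band fluorescence is proportional to input amount.

The simulator's expected intensity for species $i$ in lane $s$ is

$$
\mu_{is} = a_{is}\; \cdot\; e_{\mathrm{cap}} \cdot b_i \;\cdot\; C
            \;\cdot\; \eta_i(m_s) \;\cdot\; r_i \;\cdot\; d_{g(s)},
$$

where $a_{is}$ is the true amount (attomoles), $e_{\mathrm{cap}} = 0.86$
the capture-ligation efficiency, $b_i$ a fixed per-species capture-bias
factor (lognormal, CV 0.10 — a property of the probe chemistry, so it is
derived deterministically from the species name and the noise-model seed
and shared by every simulation with that model), $C = 50$ the number of
coding cycles, $\eta_i(m_s)$ the ligation efficiency at the lane's
background total-RNA mass, $r_i$ the per-species response factor (drawn
uniformly on the log10 scale within a 10-fold band), and $d_g$ a per-gel
multiplicative scanner drift. Mastermix spike-ins enter after capture, so
$e_{\mathrm{cap}}$ and $b_i$ are skipped for them — this is what lets the
calibration module separate scan drift from capture variation. Measured
intensity multiplies $\mu_{is}$ by mean-1 lognormal noise with CV
`cv_intraday_raw` and is finally soft-clipped,
$I = \mathrm{sat}\cdot\mu/(\mathrm{sat}+\mu)$, when a finite saturation
level is set.

All noise sources are multiplicative and lognormal, parameterized by their
CV. The assay's own reproducibility figures motivate this: fluorescence
deviations scale with the mean, and reported variability is given as CVs
(7.9% raw / 5.8% reference-normalized intraday; 22% interday). The default
per-gel drift SD of 0.20 is the package's decomposition of interday
variability into intraday noise plus drift:
$\sqrt{0.079^2 + 0.20^2} \approx 0.215$.

Saturation is disabled by default (`saturation_level = Inf`): the
log-linearity of expected response is then exact, which the linearity
invariant tests. A finite level reproduces the plateau seen at the top of a
dilution series; the soft-clip form keeps that plateau smooth and
differentiable. Whether the real plateau arises in the ligase chemistry or
in the scanner is not modeled separately — a single saturation stage stands
for both.

## Ligation inhibition

Above roughly 100 ng of background total RNA, coding-ligation efficiency
declines. The package models $\eta(m)$ as exactly 1 up to a threshold mass
(100 ng) and, above it, a Hill-type logistic decay in log mass rescaled for
continuity at the threshold, with a positive floor. Per-species parameters
(midpoint 300–500 ng, Hill coefficient 2.5–3.5, floor 0.05–0.15) are
derived from a hash of the species name: deterministic and repeatable, as
reference inhibition curves must be for correction to work, while still
differing between species. The functional form is a modeling choice — the
observable constraints are only that inhibition starts above ~100 ng, is
monotone, repeatable, and species-dependent — and
`correct_inhibition()` is its exact inverse by construction.

## Cross-talk

Specificity enters the simulator only as a plex × plex leakage matrix
applied to true amounts (rows: input species, columns: responding probes);
nothing is predicted from sequence. The `crosstalk_preset_let7()` matrix
plants five probe:miRNA combinations above the 5% reporting threshold —
pairs whose sequence mismatches sit far from the ligation site, where
ligation assays discriminate worst — plus several sub-threshold entries.
`crosstalk_matrix()` recovers the planted pattern from simulated
single-plex lanes.

# Gel rendering and densitometry

The forward image model draws each band as a Gaussian along the migration
axis (default SD 1.5 px) centered at
$\mathrm{row} = \alpha + \beta\,\log_{10}(\mathrm{length})$ with
$\beta < 0$ (standard denaturing-PAGE behavior in this size window: longer
products sit nearer the wells), spread uniformly across the lane's columns,
with integrated volume equal to the table intensity. A sloped additive
baseline, shot-like pixel noise
($\sigma = \sqrt{0.5\,\mathrm{signal} + \mathrm{read}^2}$), and clipping to
the bit depth complete the image. A ladder lane with known lengths is
always rendered.

Quantification composes hand-rolled 1-D operators (commercial gel software
is proprietary and undescribed; these operators are validated against the
simulator instead):

* **Lane segmentation.** Occupied lanes are runs of the column profile
  whose elevation above a rolling-minimum baseline exceeds 4 column-noise
  SDs. When the expected lane count is known and some lanes are blank, the
  missing centers are inferred on the regular lane pitch fitted to the
  detected runs, and boundaries are the midpoints between centers. All
  pixel intervals are half-open `[start, stop)`; row 1 is the well edge.
* **Background subtraction.** Rolling minimum then rolling mean (window
  25 px, wider than any band), re-centered by the median residual: a raw
  rolling minimum sits below the true baseline by about the expected
  minimum of noise over the window, and the median residual — dominated by
  band-free pixels — removes that bias. Output is clamped at zero.
* **Band detection.** Local maxima with topographic prominence at least
  `min_snr` times a robust noise estimate (MAD of first differences,
  excluding zero-clamped stretches; refined once from band-free residual
  pixels using the half-normal correction
  $\sigma = \mathrm{sd}(x_{>0})/\sqrt{1 - 2/\pi}$). The default
  `min_snr = 5` was chosen because the peak-to-saddle prominence of pure
  noise reaches about 4 SDs over a gel-length profile; a width-at-half-
  prominence of at least 2 px additionally rejects single-pixel spikes.
  Peak centers are refined by parabolic interpolation.
* **Ladder calibration.** Least squares of position on log10(length);
  the slope must be strictly negative; the fit is order-free and
  invertible inside the ladder's length range.
* **Assignment.** Nearest panel length within a tolerance (default 2 nt);
  equidistant ties go to the shorter length and are flagged
  `ambiguous_assignment`; duplicate claims keep the nearer band. Ties and
  losers are flagged, never silently dropped.
* **Integration.** Sum of the background-subtracted profile over the band
  window — area, not peak height — because area is robust to band-width
  variation between gels. Saturation is a per-pixel property, so bands are
  flagged `saturated` by inspecting raw pixels in the band window; their
  integrated value is kept but standard-curve fitting refuses saturated
  points.

# Calibration

Absolute quantification composes: (1) per-gel drift correction — the
factor is the geometric mean over that gel's spike-ins of
measured/reference intensity (geometric because the error model is
multiplicative and it is robust to one outlier spike); an optional
`by_stage` mode separates the mastermix (scan/coding) factor from the
pellet (full-chain) factor, which multiply; (2) inversion of a per-species
log-log standard curve (4 points by default); (3) inhibition correction;
(4) conversion to copies with Avogadro's number; and (5) division by cell
equivalents (counted cells, or total-RNA mass at an assumed 15 pg/cell).
With zero noise, identity drift, and efficiency 1 this chain is exactly the
inverse of the simulator, which the tests assert to machine precision; and
because the drift factor absorbs any per-gel rescaling, copy-number output
is invariant to multiplying all of a gel's intensities by a constant.

Inversion outside a curve's fitted amount range is a deliberate act:
`intensity_to_amount()` returns `NA` with an `extrapolated` flag unless
`extrapolate = TRUE`, in which case the value is returned but still
flagged. Zero intensity maps to zero amount with a `below_range` flag —
quantification below the lowest standard is the assay's own sensitivity
frontier. Copies are real numbers; rounding is presentation only.

# Statistics

**Resolvability.** The exact parameterization of the assay's fold-change
t-test is a design decision: pooled variance, both groups on a unit-mean
scale with common SD equal to the measurement CV, $df = 2n-2$, upper
one-tailed. At (fold 1.14, CV 0.058, $n = 2$) this gives $p = 0.0686$ and
93% certainty, and ≥ 99% certainty at 1.5-fold. "Certainty" is $1-p$ (the
assay's usage), not power at a fixed level; `resolvability_power()`
provides classical noncentral-t power separately, and the test suite checks
both against a brute-force integral of the t density and against
simulation.

**Error budget.** `copy_error_interval()` draws each stage factor as
normal with mean 1 and SD equal to the stage CV — matching plain CV
arithmetic — with lognormal as an option; the normal-quantile closed form
$z_{0.995}\sqrt{\sum cv_k^2}$ is the convergence oracle. Two 12% stages
give ≈ 44% at the 99th percentile.

**CV conventions.** CVs are stored as fractions and reported as percents.
`cv_summary()`'s intraday grouping takes each species' SD/mean across all
replicates; interday first averages within each gel/day. Zero-mean species
are flagged and excluded from the mean CV.

# What the generator does and does not emulate

The synthetic data reproduce the assay's *stated statistical structure*:
noise CVs, capture efficiency and bias, response-factor spread, drift,
inhibition onset, titration mixtures (S3 = 0.25·S1 + 0.75·S2,
S4 = 0.75·S1 + 0.25·S2 at 10/100/1000 amol with maximum folds 3/3/2), and
a cross-talk pattern with five >5% entries. They do not emulate sequence
thermodynamics, isomiRs or precursors, gel warping or lane smile,
length-dependent extraction bias, or real cell-line expression profiles.
Passing tests therefore demonstrate that the *pipeline* is correct and
well-calibrated under the stated noise model — not that any particular
biological result would be reproduced from wet data.

One consequence worth noting: the across-replicate copy-number CV in a
single batch simulates to roughly the intraday band CV plus
spike-correction noise (of order 10–15% at a 12% band CV). A larger
all-inclusive copy-number CV would additionally require between-day
spike-in and standard-curve variance, which a within-batch replicate CV
cannot see; the package exposes the stage CVs as parameters rather than
asserting a single headline number.

# Problem sizes and numerical choices

The test suite and acceptance script use sizes chosen to keep Monte-Carlo
error well below the asserted tolerances while remaining quick on one CPU:
12–28 replicate panels for CV recovery (the chi-square SE of a CV from $n$
replicates is about $cv/\sqrt{2(n-1)}$), 1000 draws for the mean-vs-
expectation check (3 SE bound), 100,000 draws for the 99th-percentile error
budget (±0.4 pp), 60 seeds for the standard-curve robustness rate, and
4000 simulated experiments for the power cross-check. Fits use `stats::lm`
throughout; $r^2$ is computed directly from residuals to avoid degenerate-
fit warnings on exact data; random draws are wrapped so constructors do not
perturb the caller's RNG stream, and every simulated artifact records its
seed.

# Known limitations

* Lane inference needs at least two occupied lanes to fit a pitch; a gel
  with one occupied lane and blanks elsewhere cannot be segmented against
  an expected count.
* Bands whose peak falls below ~5 column-noise SDs are reported as
  intensity 0 with `low_snr`; near that floor, integrated intensities are
  biased low before they vanish.
* Uncertainty is propagated as CVs only; there is no full posterior, no
  gel-warp correction, and no multiple-testing machinery.
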