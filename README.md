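# ligomir

Absolute miRNA quantification from length-coded ligation gel assays.

## The problem

Multiplexed ligation assays measure panels of up to 26 miRNAs at once by
ligating a miRNA-specific *discrimination probe* (carrying a length tag) to
a fluorescent common probe on each captured miRNA template. Fifty thermal
cycles of linear amplification produce, for every species, a single-stranded
DNA product of a unique length, so a denaturing PAGE gel separates the panel
into one band per miRNA and band intensity is proportional to input amount.
Combined with spike-in controls and per-miRNA standard curves, the readout
yields *absolute* expression — copies per cell — rather than expression
relative to a biological control such as RNU44.

`ligomir` implements the complete data-analysis side of such an assay for
people developing, validating, or teaching this kind of quantification:

* **Simulation** — a forward model of the signal chain: capture ligation
  (efficiency 0.86, per-species bias CV 10%), 50-cycle coding amplification,
  background-RNA ligation inhibition above 100 ng total RNA, per-species
  response factors (≤ 10× spread), per-gel scanner drift, multiplicative
  intraday noise (raw CV 7.9%, reference-normalized CV 5.8%, interday 22%),
  optional cross-talk leakage and signal saturation; plus rendering of
  synthetic 16-bit gel images.
* **Densitometry** — lane segmentation, rolling-minimum background
  subtraction, prominence-based band detection, ladder calibration
  (band position linear in log10 length), nearest-length band assignment,
  and band-area integration back to an intensity table.
* **Calibration** — spike-in drift correction (geometric mean of
  measured/reference), per-miRNA 4-point log-log standard curves, inhibition
  correction from MS2-style reference curves, and conversion to copies per
  cell (`copies = amol × 10⁻¹⁸ × N_A`, cell equivalents at 15 pg total RNA
  per cell).
* **Profiles** — raw / reference-gene / fractional / copies-per-cell
  normalization, differential ratios and fractional absolute differences,
  titration-order validation (S1 < S4 < S3 < S2), cross-talk matrices from
  single-plex lanes.
* **Statistics** — fold-change resolvability via the pooled one-tailed
  two-sample t-test, CV summaries, deviation-from-expected-ratio metrics,
  benchmarking regression, and Monte-Carlo copy-number error budgets.

## The core statistic

For a true fold-change *f* measured with coefficient of variation *cv* and
*n* replicates per group, resolvability is the upper one-tailed probability
from a pooled independent two-sample t-test with group means 1 and *f*,
common standard deviation *cv*, and 2*n* − 2 degrees of freedom:

    t = (f − 1) / (cv · √(2/n)),   p = P(T₍₂ₙ₋₂₎ > t),   certainty = 100·(1 − p)

At the assay's operating point (cv = 5.8%, duplicates) a 1.14-fold change —
the smallest ratio in the titration design S3 = 0.25·S1 + 0.75·S2,
S4 = 0.75·S1 + 0.25·S2 at the 1000-attomole level — gives p = 0.069, i.e.
93% certainty; a 1.5-fold change is resolved with better than 99% certainty.

The copy-number error budget propagates independent multiplicative stages:
with two 12%-CV stages, the 99th percentile of the absolute relative error
is ≈ 2.576·√(0.12² + 0.12²) ≈ 44%, within a 50% budget.

## Worked example

```r
library(ligomir)

panel <- make_default_panel(26, seed = 1)
panel
#> panel_design: 26-plex length-coded panel
#>   lengths: 40-140 nt; roles: reference (2), spike_in_mastermix (2),
#>   spike_in_pellet (2), target (20)

# resolvability at the assay operating point
p <- resolvability_pvalue(1.14, 0.058, 2)
sprintf("p = %.3f, certainty = %.0f%%", p, 100 * (1 - p))
#> "p = 0.069, certainty = 93%"

# titration design: S3/S4 are convex mixtures of the base samples
design  <- titration_design()
truth   <- titration_truth(panel, design)
amounts <- make_titration_samples(design, truth$s1, truth$s2)
round(amounts["miR-21-5p", ], 1)   # attomoles, low (10 amol) level
#>   S1   S2   S3   S4
#>  3.3 10.0  8.3  5.0

# simulate duplicate measurements at the raw intraday CV and check ordering
nm  <- noise_model(cv_intraday_raw = 0.079, scanner_drift_sd = 0)
dup <- amounts[, rep(colnames(amounts), each = 2)]
tab <- simulate_intensities(dup, panel, nm,
         sample_sheet(colnames(dup), replicate_id = rep(1:2, 4)), seed = 7)
res <- titration_order_check(tab, panel = panel)
sprintf("titration order: %d/%d correct (%.1f%%)",
        sum(res$per_mirna$pass), nrow(res$per_mirna),
        100 * res$fraction_correct)
#> "titration order: 21/22 correct (95.5%)"

# render a gel image and quantify it back
img <- render_gel(tab, panel, seed = 8)
q   <- quantify_gel(img, sample_sheet(colnames(dup),
                                      replicate_id = rep(1:2, 4)), panel)
m   <- merge(as.data.frame(tab), as.data.frame(q),
             by = c("sample_id", "mirna_id"))
fit <- lm(m$intensity.y ~ m$intensity.x)
sprintf("roundtrip: slope %.3f", coef(fit)[2])
#> "roundtrip: slope 0.996"   (r² = 0.992)

# copy-number error budget
copy_error_interval(c(0.12, 0.12), percentile = 99, n_sim = 1e5, seed = 1)
#> 44.1   # percent: 99% of copy numbers within ~44% of truth
```

The numbers mean: at the stated measurement noise, 21 of 22 measured species
show the strict S1 < S4 < S3 < S2 intensity ordering (the one failure is a
1.14-fold step buried in duplicate noise — exactly the regime where the
93%-certainty calculation says a few misses are expected); quantifying a
rendered gel returns the simulated band intensities essentially unchanged;
and two independent 12%-CV calibration stages keep 99% of absolute copy
numbers within ~44% of their true values.

An end-to-end synthetic study (simulate → render → quantify → calibrate →
profile → stats) is available as
`run_pipeline(run_config("outdir", seed = 1))`, or from a shell via the thin
CLI wrapper `inst/cli/ligomir.R`.

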