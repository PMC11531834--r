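---
title: "Deconvolving bimodal starch granule size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving bimodal starch granule size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulofit)
```

## The measurement and its two natural weightings

An electrical-sensing-zone counter reports each particle as an
*equivalent spherical diameter* — the diameter of the sphere displacing
the same volume — and accumulates particles into logarithmic diameter
bins. Exported traces give either per-bin counts (number weighting) or
per-bin volume percentages (volume weighting). The two weightings answer
different questions about the same sample: Triticeae endosperm starch has
B-type granules at typically more than 90 % of particles by number and
yet under 30 % of the volume, because a 22 µm A-type granule holds as
much starch as ~85 five-micron B-type granules (d³ scaling).

`granulofit` keeps the weighting and the value kind (`count`, `percent`,
`percent_density`) explicit in its central container,
`binned_distribution`, and every transform returns a new object:

* `to_density()` / `from_density()` — percent per bin divided by bin
  width. On a logarithmic axis raw percentages are not comparable across
  bins; the density is, and ∫ density dd = 100 is conserved.
* `convert_weighting()` — multiplies or divides each bin by the sphere
  volume (π/6)·d_c³ at the bin's representative diameter and
  renormalizes. One volumetric trace therefore yields both the
  volume-weighted phenotypes and the number-weighted ones (percent of
  small granules), without a second instrument run.
* `bin_population()` — bins an individually resolved population; granules
  outside the measurement window are tallied in an overflow report, never
  silently dropped.

The representative diameter of a bin is the *geometric* mean of its
edges. Bins are logarithmic, so the geometric mean is the log-midpoint;
an arithmetic midpoint would systematically inflate the d³ factor of the
weighting conversion. Bins are half-open `[low, high)` with the last bin
closed.

The instrument window defaults to 1.4–42 µm — 2 % to 60 % of a 70 µm
aperture, the usual usable range quoted for that aperture size — and is
configurable; the window and bin count are recorded in output metadata
because the source instrument's "standard settings" bin count is not a
published constant.

## The mixture model

The volumetric percent density is modelled as

$$ f(d) = 100\left[ f_B\,\mathrm{LN}(d;\mu_B,\sigma_B) +
  (1-f_B)\,\mathrm{LN}(d;\mu_A,\sigma_A)\right], $$

log-normal components in diameter, equivalently Gaussian components on
the ln-diameter axis (the two phrasings found in the field describe the
same curve). Because the fit target is a *volume* density, the mixture
weight $f_B$ is the B-type share of total granule volume, and
$100 f_B$ is the "B-type granule percentage volume" phenotype.

### Size-biasing: what the fitted diameters mean

A point worth stating loudly: if diameters in a component are
log-normal LN($\mu$, $\sigma$) *by number*, then the component seen on a
volumetric trace is the d³-size-biased version, which is again
log-normal with the same $\sigma$ but median shifted upward:
LN($\mu + 3\sigma^2$, $\sigma$). The fit therefore estimates
*volume-weighted* component diameters. At $\sigma = 0.25$ the shift is a
factor 1.21 — far from negligible. `volume_weighted_component()` maps a
simulator component's number-weighted median to the median/mean a
correct fit should recover, and the simulator's truth tables carry both.
All recovery tests in this package compare against the size-biased
truth; comparing against number-weighted medians would report a ~20 %
"error" that is purely a change of measure.

### Fitting

`fit_bimodal()` minimizes the unweighted sum of squared residuals
between the observed percent density and the model density at the bins'
geometric-mean diameters, using a bounded quasi-Newton optimizer
(`nlminb`). Choices that were genuinely open, and how they were fixed:

* **Objective.** Unweighted least squares on the density scale — the
  behaviour of a generic curve fit, which is what this analysis
  historically was. A Poisson-deviance objective on per-bin counts is
  available (`fit_options(objective = "mle")`) for sensitivity checks,
  not as default.
* **Fit target.** The even-binned density, not the raw log-binned
  percentages (raw fitting is available behind
  `fit_options(fit_raw_percent = TRUE)`).
* **Bounds.** exp(μ) ∈ [1.5, 50] µm, σ ∈ [0.05, 1], f_B ∈ [0, 1].
  Narrower than the window only where physically motivated: a component
  median below ~1.5 µm or a log-sd below a bin width is not identifiable
  from these traces. Parameters finishing on a bound are flagged
  (`boundary_flags`), and the labelling constraint exp(μ_A) > exp(μ_B)
  is imposed by relabelling *after* optimization, never as an
  optimization constraint (which manufactures boundary artifacts).
* **Initialization.** Deterministic: the axis is split at the density
  minimum between the two largest well-separated (×1.5 in diameter)
  local maxima of a lightly smoothed trace, with a 10 µm fallback split
  for unimodal-looking traces; each side provides volume-weighted
  log-moment estimates. Because a small B component often appears as a
  *shoulder* rather than a separate peak, the optimizer is started from
  both candidate splits and the better final objective wins — still
  fully deterministic.
* **Convergence.** rel.tol 1e-10, ≤500 iterations. At such tight
  tolerances `nlminb` occasionally stops with "false convergence" while
  standing on the optimum; the fit restarts once from the stopping
  point and accepts it if the restart cannot improve the objective
  beyond the tolerance. Non-convergence is reported in the result
  (`converged = FALSE`), never thrown.
* **Truncation.** The model is not renormalized to the window. The
  default window clips ~0.5 % of the A-component's upper tail, biasing
  fitted f_B upward by roughly 0.3–0.6 percentage points for typical
  mature-grain parameters — an order of magnitude below the phenotype
  differences of interest, and documented rather than corrected to keep
  the estimator faithful to the field's practice.

"Mean granule diameter" is reported as exp(μ + σ²/2), the arithmetic
mean of the fitted (volume-weighted) component; the median exp(μ) is
emitted alongside because published usage does not disambiguate the two.

### Modality classification

`classify_modality()` refits with a single log-normal and compares AIC
computed from the Gaussian-error RSS (AIC = n·log(RSS/n) + 2k). A trace
is bimodal when ΔAIC = AIC₁ − AIC₂ > 10 — a conventional "decisive"
evidence threshold — *and* the two-component f_B lies in [0.01, 0.99]
off its bounds. The f_B guard matters: a genuinely unimodal peak can be
split into two overlapping components with a nontrivial AIC gain, but it
then drives f_B to a bound. If neither fit converges the verdict is
`indeterminate`.

## Scalar phenotypes

* `granules_per_mg()`: counted granules × (total volume / counted
  aliquot volume) / grain mass. With the standard 1 mL-of-100 mL scheme
  the dilution factor is 100.
* `pct_small()`: number-weighted mass strictly below the threshold
  (default 10 µm, the conventional A/B boundary). A bin straddling the
  threshold contributes the log-scale fraction of its width below the
  threshold — granules are assumed uniform in log diameter within a bin,
  consistent with logarithmic binning. Whether the original analyses
  interpolated inside bins is unrecorded; this rule is a documented
  package decision, and its binning error is bounded in tests at
  0.5 percentage points against directly simulated populations.
* `summarize_plant()`: the experimental unit is the plant; grain-level
  records are averaged per plant (typically 3 grains), unconverged fits
  are excluded and counted, and the statistics stage refuses tables
  where one plant appears twice in a comparison cell.

## Genotype statistics

One-way fixed-effects ANOVA per phenotype, followed by Tukey's HSD in
the Tukey–Kramer form for unbalanced groups:

$$ \mathrm{CI} = \bar y_a - \bar y_b \pm
   \frac{q_{1-\alpha;k,\nu}}{\sqrt2}
   \sqrt{\mathrm{MSE}\left(\tfrac1{n_a}+\tfrac1{n_b}\right)} $$

with p-values from the studentized range distribution. For two groups
this reduces exactly to the pooled-variance t procedure (numerically to
~1e-8, the accuracy of `qtukey`). P-values are adjusted only within each
phenotype's pairwise family — phenotypes are analysed as separate linear
models, with no correction across phenotypes, matching the source
field's practice. Stratified designs (per-dpa comparisons in a
developmental series) fit one model per stratum.

## The simulator: a stated world

`sim_spec()` defines a two-component log-normal population. Defaults are
calibrated envelopes, not measured values, because within-mode
dispersions were never tabulated in the motivating work:

* A-type median 22 µm (mature grain), inside the published 18–25 µm
  peak range; B-type median 5 µm, inside 3–10 µm.
* sdlog 0.25 (A) and 0.30 (B), giving component widths comparable to
  published mature-grain traces.
* Mixing specified in exactly one convention (volume or number); the
  other follows in closed form from third moments
  m₃ = median³·exp(4.5 σ²).
* Measurement: truncation to the window *before* binning (the aperture
  cannot see out-of-window particles, and the truncated number and
  volume are reported), logarithmic binning, optional multinomial
  subsampling for counting noise.

`design_genotype_panel()` (2 genotypes × 9 plants × 3 grains, the
replicate structure of a mature-grain comparison) gives the mutant a
higher B-type volume fraction (0.32 vs 0.22), a smaller A median
(19.5 vs 22 µm) and a slightly larger B median.
`design_time_course()` encodes the developmental narrative: no B
component at 8 dpa in either genotype; in the wild type the B component
appears between 14 and 20 dpa, while the mutant already has one at
14 dpa and its A-type granules grow more slowly. Per-sample seeds are
hashed from (base seed, genotype, plant, grain, dpa), so datasets are
bit-reproducible and extending a design never changes existing samples.

What a green simulator-based test does **not** establish: agreement with
any real instrument's absolute magnitudes, non-spherical (flattened
A-type) shape effects, aperture coincidence losses, or the within-mode
dispersion of real cultivars. Tests assert recovery of the simulator's
own truth tables and the *direction* of genotype and developmental
contrasts, not published effect sizes, which are not reproducible
without the unreleased raw traces.

## Numerical and statistical honesty notes

* Density-vs-pdf oracle checks measure deviation relative to the peak
  density and in RMS: at n = 10⁶ draws the *maximum* per-bin deviation
  is a ~3σ binomial order statistic and exceeds a 1 % band with fair
  probability even for a perfect generator, so per-bin checks use a
  calibrated 4-standard-error guard instead.
* The weighting-conversion involution holds to 1e-9; converting a
  number-binned sample and binning its volumes directly agree within 2 %
  per bin at the 400-bin instrument resolution (at much coarser
  resolutions a single-granule bin can differ by up to
  e^{1.5w} − 1 from the representative-diameter approximation alone,
  with w the log bin width).
* All pipeline CSVs are written with 17 significant digits, LF endings
  and fixed column order, so a rerun with the same seed is
  byte-identical; run logs carry ISO-8601 timestamps and are the only
  non-reproducible output.

## Known limitations

* Exactly two components: no C-type granules, no compound-granule
  morphologies.
* Spherical-equivalent diameters only; the flattened geometry of A-type
  granules is invisible to the model.
* No extrapolation below the instrument window: "granules per mg" and
  "percent small" count what the window sees, and the window is reported
  with every phenotype table.
* The mixture fit is per-trace; it does not pool plants or model
  repeated measures across the time course.
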