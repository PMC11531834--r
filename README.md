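# granulofit

Deconvolution and phenotyping of bimodal starch granule size distributions
from Coulter-counter volumetric traces.

## The problem

Endosperm starch of Triticeae cereals (wheat, barley, rye) contains two
granule populations: large, lens-shaped **A-type** granules (roughly
20–30 µm across, initiated early in grain development) and small, round
**B-type** granules (roughly 2–7 µm, initiated 10–15 days later). B-type
granules typically make up more than 90 % of granules *by number* but less
than 30 % *by volume* — a duality that makes single-number size summaries
useless and motivates explicit mixture modelling. Electrical-sensing-zone
counters (Multisizer class) export these samples as volume percentages in
logarithmic diameter bins; quantitative genetics of granule initiation
needs those traces turned into per-plant phenotypes and genotype
contrasts.

`granulofit` is for plant scientists doing exactly that: it converts
log-binned volume-percentage traces to percent density, deconvolves the
density into A- and B-type log-normal components, extracts granule
phenotypes, detects the developmental onset of bimodality, and compares
genotypes with one-way ANOVA and Tukey-adjusted pairwise contrasts. A
built-in simulator generates realistic mock experiments so the entire
pipeline is testable without instrument data.

## The model

The volumetric percent density of granule diameter d is modelled as a
two-component log-normal mixture,

    f(d) = 100 · [ f_B · LN(d; μ_B, σ_B) + (1 − f_B) · LN(d; μ_A, σ_A) ]

where LN(d; μ, σ) is the log-normal pdf (Gaussian in ln d — "bimodal
Gaussian on the log axis" and "bimodal log-normal in diameter" are the
same model), and f_B is the fraction of total granule **volume** in the
B component. Parameters are estimated by bounded nonlinear least squares
on the percent-density scale; components are labelled after fitting so
that A is always the larger-diameter one. Extracted phenotypes:

* `b_volume_percent` = 100 · f_B,
* `mean_diam_X` = exp(μ_X + σ_X²/2) (arithmetic mean of the fitted
  volume-weighted component; the median exp(μ_X) is reported alongside),
* `pct_small_by_number`: percentage of granules below 10 µm by number,
  computed from the same trace via the d³ weighting conversion,
* `granules_per_mg`: absolute counts back-calculated through the
  volumetric dilution scheme (by default 1 mL counted of a 100 mL
  preparation).

Number/volume duality is closed-form through the components' third
moments m₃ = median³·exp(4.5 σ²):

    f_B(number) = (f_B(vol)/m₃_B) / (f_B(vol)/m₃_B + (1 − f_B(vol))/m₃_A)

Bimodality of a trace is decided by refitting with a single component and
comparing AIC (ΔAIC > 10 plus an interior f_B calls it bimodal).

## Worked example

Simulate a mature-grain panel (2 genotypes × 4 plants × 3 grains), fit
every trace, aggregate to plants, and compare genotypes:

```r
library(granulofit)
dir  <- file.path(tempdir(), "demo")
mock <- simulate_experiment(design_genotype_panel(n_plants = 4),
                            dir, base_seed = 2024)
res  <- cmd_fit(mock$sheet_path, file.path(dir, "out"))
head(res$phenotypes, 4)
#>          plant_id genotype b_volume_percent mean_diam_A_um mean_diam_B_um
#> mutant_1 mutant_1   mutant            32.30          24.20          7.514
#> mutant_2 mutant_2   mutant            32.19          24.18          7.533
#> mutant_3 mutant_3   mutant            32.18          24.25          7.534
#> mutant_4 mutant_4   mutant            32.13          24.33          7.523

cmp <- cmd_compare(file.path(dir, "out", "phenotypes.csv"),
                   file.path(dir, "cmp"))
cmp[, c("phenotype", "diff_means", "ci_low", "ci_high", "p_adjusted")]
#>             phenotype diff_means ci_low ci_high p_adjusted
#> 1     granules_per_mg     40.333 30.642  50.024   5.21e-05
#> 2 pct_small_by_number     -1.792 -1.869  -1.715   1.68e-10
#> 3    b_volume_percent      9.775  9.450  10.100   4.80e-13
#> 4      mean_diam_A_um     -2.970 -3.136  -2.803   7.50e-09
#> 5      mean_diam_B_um      0.689  0.675   0.704   6.42e-14
```

Reading the comparison table (each row is mutant − WT with a Tukey 95 %
CI): the simulated mutant carries ~9.8 percentage points more of its
starch volume in B-type granules and ~3.0 µm smaller A-type granules —
the two directions the simulator's default parameterization encodes.
Despite that volumetric shift, the *number* percentage of small granules
differs by under 2 points, illustrating the number/volume duality.

A single trace can be handled directly:

```r
fit <- fit_bimodal(read_trace(mock$sheet$trace_path[1]))
fit
#> <fit_result> converged in 26 iter, rss=14.04 | B-vol%=22.28, A=27.20 um, B=6.81 um
```

The command line mirrors the same three stages:

```sh
Rscript -e 'granulofit::granulofit_cli()' simulate --out sim --seed 7
Rscript -e 'granulofit::granulofit_cli()' fit \
    --sample-sheet sim/sample_sheet.csv --out fits
Rscript -e 'granulofit::granulofit_cli()' compare \
    --table fits/phenotypes.csv --out cmp --plots
```

## Trace file format

One delimited text file per measurement (`,` for `.csv`, tab for
`.tsv`): header `bin_low_um, bin_high_um, value` plus optional
`weighting`, `value_kind`, `sample_id`, `genotype`, `plant`, `dpa`
columns. Bins must be contiguous and strictly increasing; decimal commas
are rejected unless `decimal = "comma"` is passed. This CSV is the bridge
from instrument exports — reshape the instrument's bin table to these
columns and the rest of the pipeline applies unchanged.

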