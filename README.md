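# cqman

Single-reaction quantification of real-time PCR (qPCR) amplification curves,
and a six-indicator evaluation suite for benchmarking curve-analysis methods
on dilution-series data.

## What it does

Given one well's raw per-cycle fluorescence, `cqman` estimates how much
target was present at cycle zero, with no standard curve and no
baseline-phase heuristics:

1. **Sigmoid fit.** The four-parameter modified Gompertz model
   `y(x) = y0 + (ymax − y0)·exp(−exp(−(x − x0)/b))` is fitted to the raw
   fluorescence by Levenberg–Marquardt least squares.
2. **Second-derivative maximum (SDM).** The end of the exponential phase is
   located analytically at `x_SDM = x0 − b·ln u*` with `u* = (3+√5)/2`; the
   fluorescence there always sits at the fixed fraction
   `exp(−u*) ≈ 0.0729` of the amplitude.
3. **Quantification cycle.** The threshold is the midpoint
   `Fq = (y0 + F_SDM)/2` and the quantification cycle `Cq` inverts the
   sigmoid in closed form; `Cq` always falls `≈ 0.235·b` cycles before the
   SDM, inside the exponential phase by construction.
4. **Per-reaction efficiency.** A three-parameter exponential
   `F_n = c + α·E^n` is fitted over the integer cycles of the exponential
   phase (window extended backwards to at least 4 points); per-gene mean
   efficiency averages all usable reactions.
5. **Initial target quantity.** `F0 = E_mean^(−Cq)`.

The indicator suite (`indicator_report()`) scores any method's `F0` values on
a dilution series by bias (extreme-ratio and log–log slope), mean absolute
relative error, coefficient of variation, within-replicate variance, and
resolution (detectable fold difference from a 95% prediction interval);
`rank_synthesis()` aggregates method ranks across indicators with a Friedman
test. A mechanistic per-cycle kinetics simulator
(`simulate_dilution_plate()`, `simulate_ntc()`) generates dilution-series
plates with known ground truth — deliberately *not* sampled from the
Gompertz model, so the analyzer is always tested under model mismatch.

## Worked example

```r
library(cqman)
library(dplyr)

plate <- simulate_dilution_plate(
  levels = c(150000, 15000, 1500, 150, 15),  # 10-fold series, copies
  replicates = 3, genes = 2,
  base_config = sim_config(seed = 42))

results <- analyze_plate(plate$curves)
results |> count(status)
#> # A tibble: 1 × 2
#>   status     n
#>   <chr>  <int>
#> 1 ok        30

results |> select(well, cq, e_individual, e_mean, f0) |> head(3)
#> # A tibble: 3 × 5
#>   well            cq e_individual e_mean        f0
#>   <chr>        <dbl>        <dbl>  <dbl>     <dbl>
#> 1 gene01_L1_R1  16.2         1.84   1.82 0.0000585
#> 2 gene01_L1_R2  16.2         1.84   1.82 0.0000585
#> 3 gene01_L1_R3  16.2         1.84   1.82 0.0000585

report <- indicator_report(
  results |> filter(status == "ok") |> select(gene, concentration, f0),
  expected_ratio = 1e4)
glance(report)
#> # A tibble: 1 × 6
#>   bias_ratio_dev bias_slope_dev mean_relative_error mean_cv mean_precision resolution_fold
#>            <dbl>          <dbl>               <dbl>   <dbl>          <dbl>           <dbl>
#> 1          1564.         0.0163               0.123       0              0            1.13
```

All 30 noiseless wells quantify. Per-gene mean efficiencies come out at 1.82
against simulated truths of 1.84–1.86 — the small deficit is the expected
behaviour of an exponential-window estimator on a saturating signal — and
`f0` falls close to 10-fold per dilution step. On the indicator scale a
perfectly calibrated method scores bias 0, relative error 0, CV 0%,
precision 0 and resolution 1; replicate scatter (CV, precision) is exactly 0
here because the example is noiseless, while the nonzero bias and relative
error trace back to the efficiency deficit compounding over ~16–31 cycles.
(All numbers are the code's actual output for this seed.)

A command-line front end over the same functions lives in
`inst/scripts/cqman.R` (`analyze`, `indicators`, `simulate`, `rank`
subcommands).

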