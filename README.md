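# paleocycles

Reconstructing multicentennial cycles of human population growth from
radiocarbon archives, and measuring their synchrony with climate stability
and solar forcing.

## The problem

Compilations of hundreds of thousands of archaeological ¹⁴C dates
(p3k14c, EUROEVOL, RADON, neolithicRC and kin) are the main quantitative
window on Holocene paleodemography. The standard summary is the *summed
probability distribution* (SPD): the sum over dates of each date's
calibrated probability density over calendar time, read as a proxy for
human activity. `paleocycles` implements a complete, tested pipeline from
raw date tables to growth-cycle statistics:

1. **Calibration & SPD** — deduplication, a density-dependent precision
   filter `SD ≤ max(220 − √(8·10⁵ km² · n), 40)` (with `n` the local dates/km²
   on 4°×4° cells), non-normalized calibration against an IntCal-style
   curve, per-site binning of calibrated medians (100 a bandwidth), and
   bin-averaged summation.
2. **Growth rates** — the relative growth rate
   `RGR(t) = {SPD(t+Δt) − SPD(t)} / {SPD(t) Δt}` on 100 a slices, then the
   standard treatment applied to every series: a 130 a distance-decaying
   (triangular) smoothing kernel, subtraction of a 1500 a moving average,
   and division by the standard deviation (σ-normalization).
3. **Synchrony statistics** — raw Fourier periodograms; the trimmed
   correlation `r_T` (a zero-lag cross-extremogram: Pearson correlation on
   the upper and lower quartiles of the reference series); and the *phase
   overlap*: the fraction of |b|-mass sharing the sign of the reference
   series' boom/bust phases inside tapered peak windows (100 a linear
   taper), re-adjusted so that identical signals score exactly 100% —
   uncorrelated series score ~50%. Overlap > 67% is classified as strong
   synchrony; overlap < 49% with `r_T < 0` as antiphase.
4. **Regionalization** — spatial permutation tests of sites on 4° cells
   (p values with step-up false-discovery q values, both thresholded at
   .05), signed combined scores clustered by k-means with the small-region
   penalty `withinss × (1 + exp{−10(N_min/N* − 1)})`, `N* = 120`, and
   area-weighted continental averaging of regional growth rates.
5. **Proxy alignment** — reference-free multi-record dynamic time warping
   of paleoclimate chronologies: penalized pair distances
   `D_ij = cost / overlap × (1 + (d/100)²)`, convergence weights
   `w_ij = exp{−(D_ij/D̄)²}·w_j`, displacement by the weighted mean of
   pairwise warps, hard-capped at ±150 a, iterated 4–8 times.
6. **Climate stability** — weighted PCA of the aligned ensemble; the
   stability index is `−normalize(Σ_{c≤5} |d PC_c/dt|)`, blended across the
   5.8–6.2 ka BP segment junction; comparison forcings are the
   sign-reversed total solar irradiance and tree-ring homogeneity
   (sign-flipped across-tree spread).
7. **Boom/bust logit** — logistic regression of boom/bust labels
   (sign of RGR) on a time-lagged RGR (350 a before 7 ka BP, 210 a after),
   the stability index, and −TSI, in variants 1V/2V/3V, with the
   boom-minus-bust hindcast `2·p̂ − 1`.
8. **Synthetic data** — generators for every input (population
   trajectories carrying 360/500/680 a cycles, clustered site geography,
   wiggly monotone calibration curves, proxy ensembles with bounded
   chronological distortions, coupled solar forcing) so the whole chain
   runs and is validated with no downloads.

Everything is tidyverse-shaped: functions take a data frame first and
return tibbles, results chain with the pipe, fitted objects have
`tidy()`/`glance()` methods, and result types have `autoplot()` methods.

## Worked example

From a synthetic population carrying 360/500/680 a growth cycles to their
spectral recovery:

```r
library(paleocycles)

sc    <- scenario(seed = 42, n_dates = 5000, n_sites = 600, curve_wiggle = 0)
curve <- make_calibration_curve(sc)
pop   <- make_population(sc)

dates  <- sample_dates(pop$population, curve, sc) |> filter_by_precision()
growth <- spd(dates, curve, window = c(9000, 3000)) |> rgr() |> preprocess()

dominant_periods(power_spectrum(growth), 3)
#> # A tibble: 3 × 3
#>   frequency period power
#>       <dbl>  <dbl> <dbl>
#> 1   0.00153   656.  8.77
#> 2   0.00203   492.  4.02
#> 3   0.00254   393.  1.22

synchrony_stats(growth, preprocess(rgr(pop$population)))
#> # A tibble: 1 × 3
#>   overlap   r_t label
#>     <dbl> <dbl> <chr>
#> 1    93.7 0.886 strong synchrony
```

The three dominant periods land on the generating 680/500/360 a cycles to
within one to two spectral bins at this sample size (they sit within one
Rayleigh bin at 20,000 dates), and the reconstructed growth rate is
strongly synchronous with the generating one: 94% phase overlap,
`r_T = 0.89`. `run_pipeline(default_config(seed = 1))` chains every stage
— SPD, pooled and regional growth, proxy alignment, stability index,
logit hindcasts, synchrony tables — and writes delimited outputs plus a
JSON manifest when an output directory is configured.

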