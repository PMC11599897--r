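---
title: "Methods: from radiocarbon tables to growth cycles and climate synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from radiocarbon tables to growth cycles and climate synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(paleocycles)
```

This vignette explains the models and procedures `paleocycles` implements,
the parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data validation does and does not show.

## Time conventions

All regular series live on a strictly descending calendar grid in years
before present (cal BP, 0 BP = 1950 CE), so "forward in time" means
decreasing cal BP and rows read chronologically from top to bottom. SPDs
are built on a 5 a internal grid and aggregated (by averaging) to 100 a
analysis slices; the slice width follows the standard binning convention,
and the fine internal grid simply keeps calibration structure from being
lost before aggregation.

## Calibration and SPD construction

A radiocarbon measurement `(y, s)` is calibrated against a curve
`μ(t) ± σ(t)` by evaluating, at each calendar age `t`, the Gaussian
likelihood of `y` with combined variance `s² + σ(t)²`. The density is
deliberately **not** normalized per date: normalization divides by the
integral of the likelihood, which varies with the local slope of the curve
and thereby manufactures spikes in the summed distribution. A consequence
worth knowing: the SPD of dates spread *uniformly over the ¹⁴C axis* is
flat through any monotone curve when densities are non-normalized (a sum
of evenly spaced Gaussians is constant), so the calibration-artifact
control `artifact_rgr()` returns a near-zero growth null by default and
only exhibits plateau artifacts when its `normalize` flag is switched on.
That asymmetry is the empirical argument for the non-normalized choice.

Dates are deduplicated on the key (¹⁴C age, ¹⁴C error, longitude,
latitude); site labels are excluded from the key because the same sample
recurs across compilations under different site spellings. The precision
filter removes a date when its lab error exceeds
`max(220 − sqrt(8e5 · n), 40)` years, with `n` the dates-per-km² density
of its 4°×4° cell; `n` is interpreted literally as a density in dates/km²
(cell areas from a spherical-Earth formula) and dates outside any
populated cell are treated as `n = 0`. Within each site, dates whose
calibrated median ages fall within 100 a of each other (complete-linkage
clustering cut at the bandwidth; sensitivity range 50–150 a exposed via
the `bin_width`/`h` arguments) share a bin; bin members are averaged
before summation so that intensively resampled site phases do not swamp
the signal.

## Growth rates and the standard filter

The relative growth rate is the forward difference
`RGR(t) = {SPD(t+Δt) − SPD(t)} / {SPD(t) Δt}` with `Δt` one 100 a slice;
slices with zero SPD yield NA (flagged, never silently zero). Note that a
forward difference is effectively centred half a slice later than its
stamp; comparisons against generating truth therefore use `rgr()` of the
true population trajectory, not the instantaneous generator rate.

Every compared series passes the same treatment (`preprocess()`):

* smoothing with a **triangular kernel of 130 a half-width** — the kernel
  shape is open in principle (`kernel` argument); triangular realizes a
  distance-decaying weight with the stated length;
* detrending by subtracting a **1500 a moving average**, windows truncated
  at the series ends (no padding);
* mean removal and division by the standard deviation (σ-normalization).

The closed-form response of this chain (triangular gain
`sinc²(πh/P)` times detrending gain `1 − sinc(πW/P)`) passes the
multicentennial band and suppresses both sub-centennial noise and the
millennial trend; the test suite checks the measured response against that
closed form. Attenuation of a 3000 a oscillation relative to a 500 a one
is about a factor 2 — informative but not total, which is why the
detrending window, not the smoothing length, is the parameter to tighten
if slower trends must be excluded.

## Synchrony statistics

**Phase overlap.** Peak phases of the reference series are the maximal
runs where `|a| > ε` with a common sign; `ε` defaults to `0.05 σ` of the
normalized series ("exceeding a small value"). Runs are extended 100 a to
each side with linearly decaying weight; on the 100 a analysis grid the
taper's first step already reaches zero, so it only becomes active on
finer grids. The statistic is the weighted |b|-mass agreeing in sign with
the reference peak divided by the total weighted |b|-mass, rescaled by the
reciprocal of the reference's raw self-overlap (a factor close to one)
so that `phase_overlap(x, x)` is exactly 100, and clipped to [0, 100].
The denominator uses `|b|` over all peak windows rather than same-sign
windows only; this is what centres independent noise at ~50%, the
documented baseline. The mask is defined on the reference series; a
symmetric (union-mask) variant of the trimmed correlation is available via
a flag since the literature is ambiguous on this point.

**Trimmed correlation.** Pearson correlation restricted to time steps
where the reference series lies in its outer quartiles
(`tail_fraction = 0.25`); with 0.5 it degenerates to the plain Pearson
correlation. Fewer than 8 retained points flag the result undefined.

**Classification.** Strong synchrony above 67% overlap; antiphase below
49% with negative `r_T`; intermediate otherwise. The thresholds are
strict inequalities.

## Regionalization

Per 400 a time slice (tiling 3.0–9.8 ka BP), each 4° cell's growth
statistic is the relative change of its SPD between the slice's first and
last 100 a bins. The null distribution comes from permuting the
site-to-cell assignment — sites, not dates, are the exchangeable units,
since a site's dates are not independent of each other. One-sided ranks
give `p = min(p_hi, p_lo)` with the deviation sign; q values are
Benjamini–Hochberg within the slice (the step-up procedure, chosen where
only "false discovery rates" is specified). Cells passing both thresholds
(.05) score `(1 − p) + (1 − q)`, signed — the combination rule is a
package choice, monotone in both significances and bounded by 2. Cells
with fewer than 10 dates are excluded.

For clustering, the feature vector (signed score, lon, lat) is
standardized to unit variance so that statistical deviation and geography
are commensurate — the relative scaling is the main open knob and is
flagged for sensitivity analysis. k-means runs with 25 restarts over
k = 2..12, minimizing `withinss × (1 + exp{−10(N_min/N* − 1)})` with
`N* = 120`; the penalty only binds when candidate regions approach `N*`
dates, which is exactly its design intent (regions big enough for robust
SPDs). Continental averages weight regions by *area* (spherical cell
areas), so a sparsely dated region counts as much as an equally large
dense one; bins where a region's rate is undefined drop out of that bin's
average.

## Reference-free chronology alignment

Proxy records are split at the mid-Holocene variability shift into an
early (> 5.8 ka BP) and late (< 6.2 ka BP) segment, both keeping the
5.8–6.2 ka overlap zone. Within a segment, records are standardized and
interpolated to a 20 a grid over each pair's common support (the
discretization step is a package choice; the spec'd cap makes finer grids
pointless), and dynamic time warping with squared-difference local cost
and symmetric unit steps yields the non-normalized path cost. The pair
distance is `cost / overlap × (1 + (d/100)²)`: `overlap` is the fraction
of the *shorter* record covered by the common support (chosen over the
union convention so a short record fully inside a long one is not
penalized twice), and `d` is the maximal time distortion along the path.

Pair weights `w_ij = exp{−(D_ij/D̄)²} · w_j` (record weights start at
`1/n` and update to `w_j = Σ_i w_ij / Σ_ij w_ij`) convert distances into a
soft consensus: each record's timings move by `Σ_j w_ij (T′_ij − T_i)`.
The ±150 a cap is applied to the *cumulative* displacement from the
original chronology — the stricter of the two readings (a per-iteration
flag exists) — because the cap expresses a prior on total age-model error,
not on step size. Monotonicity of timings is preserved; violations are
repaired by isotonic projection and counted. Iteration runs 4–8 rounds
until the mean absolute update drops below 1 a; non-convergence returns
the last state with a warning (the weighted displacement is a damped
averaging map, so residual oscillation at the 1 a level is benign).

## Stability index and forcings

Aligned records are standardized, multiplied by their final weights `w_j`
(records that never synchronized contribute little), interpolated to a
common 20 a grid restricted to jointly covered time steps (records with
internal sampling gaps over 500 a are dropped), and decomposed by PCA.
The stability index smooths the leading five components *before*
differencing (smoothing after differencing would re-amplify the sampling
noise the smoothing is meant to kill), sums the absolute central-difference
derivatives, normalizes, and flips the sign — high values mean the
multivariate climate state changes slowly. The early and late segments are
blended with linear cross-fade weights across 5.8–6.2 ka BP and
re-normalized.

Total solar irradiance enters sign-reversed (low irradiance empirically
accompanies high stability) after resampling and the standard filter.
Tree-ring homogeneity is the sign-flipped, filtered across-tree standard
deviation of ring widths; years with a single tree are excluded.

## Boom/bust logistic regression

Labels are the sign of the preprocessed growth rate (exact zeros are
flagged out). The endogenous input is the growth rate read 350 a earlier
before 7 ka BP and 210 a earlier after it, linearly interpolated.
Variants: 1V = lagged rate; 2V = stability + (−TSI); 3V = all three.
Fitting is maximum likelihood (IRLS via `glm`) on every grid step with
listwise deletion — per-step fitting was chosen over per-episode fitting
because the hindcast `2p̂ − 1` is itself a per-step series and the two
conventions coincide as the grid refines. Perfect separation triggers a
ridge-stabilized IRLS refit (penalty 10⁻⁶) with a warning. The hindcast's
skill is reported, like every other comparison, as phase overlap and
trimmed correlation against the growth-rate series.

Two statistical notes on validation. Joint ±2-SE coverage of three ML
coefficients is ~0.87–0.94 *by construction* under a correctly specified
model, so coefficient recovery is asserted per coefficient (expected
~95%). And coefficient *signs* are recovered statistically, not in every
replicate: the weakest, collinear coefficient occasionally flips in a
noisy draw.

## What the synthetic generators emulate — and what they do not

`scenario()` fixes the study conditions: a 9–3 ka BP window; growth-rate
cycles of periods 360/500/680 a with amplitude 0.003 a⁻¹ each on a
0.0003 a⁻¹ trend (population swings of order ±25%, the boom/bust regime);
lab errors uniform in 30–70 a; clustered site geography (Gaussian
mixture, emulating the strong spatial clumping of real site maps);
monotone calibration curves with smooth ~20 a wiggles; proxy ensembles
sharing one latent signal through smooth chronological distortions capped
at 150 a plus independent noise (σ = 0.5 of the standardized latent,
matching decadal-to-centennial proxy quality); and forcing series with the
same periods plus red noise. Site counts scale with date counts in larger
experiments (~8 dates/site, the ratio of the real compilations); holding a
small site count fixed while inflating dates would exaggerate the
per-site binning in a way no real archive does.

What passing tests on these data show: the pipeline's operators are
correct (exact anchors, closed-form responses), the chain is unbiased
enough to recover known cycles at realistic sample sizes, alignment
genuinely increases ensemble coherence under bounded distortions, and the
logit machinery recovers a known law. What they do not show: robustness to
taphonomic loss, reservoir effects, research-intensity biases in date
submission, non-Gaussian proxy noise, or age-model errors larger or
rougher than the smooth bounded distortions generated here. Headline
numbers from real archives (specific overlap percentages between
continental growth and solar forcing, explained-variance gains of the real
98-record ensemble) depend on those data and are outside what synthetic
validation can certify.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: zero-variance series cannot be normalized
(the check is relative, `sd < 10⁻¹⁰·max|x|`, so floating-point residue of
a constant does not masquerade as signal); empty date sets, non-overlapping
record pairs (distance `Inf`, pair excluded) and peakless references
(overlap NA) are flagged rather than coerced. k-means ties break by the
first minimal objective over the k range; taper ties between two adjacent
peaks resolve to the larger weight, i.e. the nearer peak.

The validation suite runs at sizes a laptop handles in minutes: 20,000
dates (2,500 sites) for end-to-end cycle recovery, 12 proxies × 20 seeds
for the alignment gain, 50 replicates for logit recovery, 200 pairs for
the noise baseline of the phase overlap. These sizes were chosen so that
the statistical assertions have comfortable margins at the conditions
above.
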