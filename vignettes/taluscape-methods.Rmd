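---
title: "Methods: radiocarbon calibration, climate trends, and refugial occupancy in taluscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiocarbon calibration, climate trends, and refugial occupancy in taluscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taluscape)
```

taluscape reconstructs the timing and climatic driver of a local
extinction (extirpation) of a talus-dwelling, temperature-sensitive
mammal, and projects where climatically suitable habitat remains under
warming. This vignette documents the models, their assumptions, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## 1. Radiocarbon calibration of fecal pellets

**Model.** A pellet's Fraction Modern (Fm) is a noisy observation of the
atmospheric radiocarbon signature μ(t) in the (average) year t the
vegetation it derives from was fixed. With analytical error σₘ and curve
uncertainty σ_c(t), the calendar-age posterior under a uniform prior on
the curve's tabulated support is

p(t) ∝ exp(−(Fm − μ(t))² / 2(σₘ² + σ_c(t)²)).

Assumptions: errors Gaussian; no reservoir or fractionation corrections
(applied upstream by the lab); composited pellets carry one averaged Fm
whose posterior is an *average-age* distribution, not the age of any
single pellet.

**Curve handling.** `append_curves()` joins a conventional pre-bomb table
to a post-bomb (bomb-spike) segment; in any overlap the post-bomb segment
wins, because post-bomb compilations are built from direct atmospheric
measurements. `read_curve()` accepts conventional ¹⁴C ages and converts
them with Fm = exp(−age/8033) (Libby mean-life), propagating sigma to
first order. Curve mean and sigma are interpolated linearly between
tabulated years — differences are below reporting resolution.

**Grid step.** The posterior is evaluated on a uniform year grid. The
default step is 0.5 yr when a post-bomb segment is present (the spike's
gradient demands it) and 1 yr otherwise; a uniform grid keeps the density
a simple probability mass vector. The step is a user argument: on the
spike's steep branches a per-mil Fm error maps to calendar features only
~0.05 yr wide, so oracle-equivalence tests run `calibrate(step = 0.02)`.
At coarser steps the *location* of mass is still correct to within a step,
but mass can concentrate on the nearest grid points; tests that compare
mode masses to 1e-6 must resolve the density.

**95% ranges.** `hpd_intervals()` returns highest-posterior-density
regions (the OxCal convention, matching multi-interval bomb-spike
solutions), not central quantiles: grid points are ranked by density, the
smallest set reaching the target mass is taken, ties at the threshold
density are included (this makes the region well defined on flat plateau
segments), and contiguous points are merged into intervals. Inflating σₘ
can only widen the total range (tested as a property).

## 2. Station record QC, trends, and the delta method

Daily means are (tmax + tmin)/2, the standard convention for cooperative
station records. Missing daily values strictly between recorded days are
linearly imputed in time; leading/trailing gaps stay missing; imputation
is idempotent and never touches recorded values. Missing days are counted
*before* imputation — otherwise the inclusion thresholds (< 15 missing
days/yr for annual temperature, < 10 for June–August) would be vacuous.
Named year-exclusion lists are accepted on top of the automatic rule,
since real studies publish explicit exclusions.

Trends are ordinary least squares of the annual value on calendar year,
with `total_change = slope × (last − first year)` and a t-based 95% CI.
Epoch contrasts split the record at "including and preceding" the split
year (default 1955, the bomb-spike epoch): Welch's t, Mann–Whitney
(exact for small samples), Spearman's rank trend against year, and a
pooled two-proportion z-test for binary predicates such as negligible
(< 2 cm) April snowpack. Slope differences between two records use a
Welch-style t on the slope estimates with Welch–Satterthwaite degrees of
freedom. The "April snow" statistic defaults to the mean of daily April
readings and is configurable to the April-1 reading, the two common
readings of an "accumulated April snow depth"; the choice does not affect
any closed-form test.

`delta_offset()` implements delta-method downscaling: the historical grid
is the current grid plus the station-observed difference
mean(historical years) − mean(base years) of the chosen annual variable.
This assumes the spatial *pattern* of temperature is stationary and only
its level shifts — the standard delta-method assumption.

**QC fallback in the pipeline.** The default synthetic world has 15%
missing days, so *every* year fails the < 15-day rule even though the
imputed annual means are excellent. `run_pipeline()` therefore uses
QC-included years when at least three exist, and otherwise falls back to
all years with finite means, recording `qc_fallback = TRUE` in the
report. Library users calling `fit_trend()` directly choose their own
inclusion.

## 3. Refugial occupancy modelling

Predictors: `refugial_mst(grid, site, r)` is the minimum MST over cells
whose *center* lies within r km (Euclidean, projected metres) of the site
centroid — cell-center inclusion is the simplest defensible convention
and is applied consistently on both the predictor and projection sides.
It is nonincreasing in r by construction. Talus area within 1 km clips
the hand-mapped talus polygons against the disk (Sutherland–Hodgman
against a 256-gon, < 0.1% area error) and is log-transformed with a
log(area + 1 m²) floor so zero-talus sites stay finite.

Spatial thinning draws a site uniformly at random, keeps it, discards all
sites within 250 m, and repeats — a seeded random maximal independent set
of the proximity graph.

Models: occupancy ~ Bernoulli(logit⁻¹(β₀ + βᵀx)) fitted by maximum
likelihood (`stats::glm.fit` under the hood; an independent
`optim()`-based likelihood maximisation cross-checks the log-likelihood
to 1e-6 in the tests). Ten candidates — refugial MST at each radius 1–5
km, alone and with log talus area — are ranked by
AICc = −2logL + 2k + 2k(k+1)/(n−k−1), ties broken by fewer parameters
then name. Complete separation (classes dividing perfectly along a
predictor, which is exactly what a sharp thermal threshold produces) is
detected and flagged; an optional ridge-penalised Newton fit keeps
coefficients finite, but the default leaves the flag visible rather than
silently regularising, because a separated fit still ranks correctly by
likelihood and its 0.5-probability threshold −β₀/β₁ remains meaningful.

The comparison against a previously published model takes that model's
coefficients as configuration (they are external input, not re-estimated)
and uses an exact binomial test of the observed extirpation count. The
null's success probability is not uniquely determined by the phrase
"exact binomial test", so three nulls are implemented: the pooled mean of
per-site predicted extirpation probabilities (default), a fixed 0.5, and
the exact heterogeneous Poisson-binomial. Two-sided p sums all outcomes
no more likely than the observed one (minimum-likelihood convention);
for 14/14 extirpations at pooled 0.5 this is 2·0.5¹⁴ ≈ 1.22e-4.

## 4. Habitat projection

Scenario deltas are uniform scalar offsets added cellwise (ensemble-mean
offsets; per-cell delta rasters would be a straightforward extension).
Refugial cells are strictly below the threshold (a cell exactly at
threshold is not refugial, mirroring the "<" convention); suitable cells
are within the dispersal radius of a refugial cell, computed as an exact
Euclidean center-to-center dilation (equivalent to a distance transform,
verified against an all-pairs oracle). Areas are cell counts × cell
size², with percent declines against the current (zero-delta) baseline
and rounding only at reporting. Warming can only shrink both areas under
a uniform offset; refugia are always a subset of suitable habitat.

## 5. What the synthetic world is — and is not

Defaults state a Tahoe-like world: a 1910–2015 daily record warming at
1.9 °C/century with σ = 0.5 °C daily noise and 15% missing days; a
calibration curve with a 0.98 Fm plateau and a +0.8 spike at 1955 (9-yr
sine-ramp rise, 16-yr exponential decay — an asymmetric pulse whose two
branches force genuinely bimodal calibrations); a 110×110-cell, 270-m MST
grid built from sparse Gaussian peaks (lapse rate 6.5e-3 °C/m, relief up
to 900 m); and 200 sites whose occupancy is drawn from
logit⁻¹(20 − 1.4·MSTmin(4 km)), i.e. a true threshold of 20/1.4 ≈ 14.3 °C
at a true dispersal radius of 4 km.

Choices made once, on realism grounds: the seasonal cosine sums to
exactly zero within each calendar year (so the noiseless generator
recovers the trend slope exactly, a clean oracle); terrain uses *sparse*
cold pools so the refugial minimum genuinely changes between radii —
without that, the five radius predictors are nearly collinear and no
method could identify the generating radius ("clear signal"); talus
polygons are squares placed fully inside the 1-km disk so their
within-disk area is known exactly.

Not emulated: interannual climate variability beyond iid daily noise,
autocorrelation, instrument changes or inhomogeneities; curve wiggles on
the pre-bomb plateau (it is flat, so pre-bomb measurements return the
whole plateau as their range); spatial autocorrelation of occupancy
beyond what the shared temperature surface induces; imperfect detection.
A green test therefore establishes correctness of the *computations*
under the stated generating model, not robustness to real-data
pathologies such as inhomogeneous records or detection error.

One deliberate consequence of the stated world: the generating total
temperature change over 1910–2015 is 1.9 °C/century × 1.05 centuries =
1.995 °C. Recovery tests and the acceptance report check CI coverage of
this generating value (the nominal-95% event), not of the rounded
1.9 °C figure.

## 6. Known limitations

* No geospatial CRS machinery: coordinates are assumed already projected
  in metres; rasters travel as ESRI ASCII grids and polygons as GeoJSON.
* Overlapping talus polygons would double-count area; inputs are assumed
  hand-delineated and disjoint.
* The calibration grid is uniform per curve; a locally adaptive grid
  would be more economical on appended curves with very different
  segment resolutions.
* The binomial comparison treats sites as independent; a
  spatially correlated alternative is out of scope.
* AICc model selection among highly correlated radius predictors is
  honest about, but cannot remove, their intrinsic similarity: with weak
  signal the selected radius is variable, and only the replicate-level
  recovery rate (reported by `scripts/acceptance.R`) is meaningful.
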