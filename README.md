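# taluscape

Tools for reconstructing and projecting the climatic collapse of
talus-dwelling small-mammal metapopulations — the motivating case being the
American pika (*Ochotona princeps*), a temperature-sensitive lagomorph whose
persistence depends on cool "refugial" microclimates reachable within its
dispersal range.

The package implements the full analysis chain such a study needs, each
stage usable on its own:

1. **Radiocarbon calibration of fecal pellets** (`calibrate()`,
   `hpd_intervals()`). Pellet radiocarbon content, expressed as Fraction
   Modern (Fm), is converted to a calendar-age posterior against a
   calibration curve that appends a post-bomb atmospheric segment to a
   conventional pre-bomb table (`append_curves()`). For a measurement with
   analytical error σₘ the likelihood of calendar year *t* is

   p(t) ∝ N(Fm | μ(t), √(σₘ² + σ_c(t)²)),

   with μ, σ_c the interpolated curve mean and uncertainty. Reported 95%
   ranges are highest-posterior-density regions, which on the two-branched
   bomb spike are routinely multi-interval.

2. **Weather-record QC and trends** (`impute_daily()`, `summarize_years()`,
   `fit_trend()`, `compare_epochs()`, `compare_slopes()`, `delta_offset()`).
   Daily station records are linearly imputed inside gaps, years are
   screened by pre-imputation missing-day counts (< 15 days/yr for annual
   temperature, < 10 for June–August), and annual means are tested for
   linear trends and pre/post-1955 contrasts (Welch, Mann–Whitney,
   Spearman, two-proportion z). `delta_offset()` yields the delta-method
   station offset used to reconstruct historical temperature surfaces.

3. **Refugial occupancy modelling** (`refugial_mst()`,
   `talus_area_within()`, `spatial_thin()`, `fit_logistic()`,
   `rank_models()`, `occupancy_threshold()`,
   `binomial_extirpation_test()`, `classification_rates()`). Site
   predictors are the minimum mean summer temperature (MST) within 1–5 km
   of the site centroid and log talus area within 1 km. Ten candidate
   logistic models (each radius, with and without talus area) are ranked by
   AICc = −2logL + 2k + 2k(k+1)/(n−k−1); the best single-covariate model
   gives the p = 0.5 occupancy threshold −β₀/β₁.

4. **Habitat projection** (`apply_scenario()`, `refugial_mask()`,
   `suitable_mask()`, `area_summary()`). Uniform warming offsets are
   applied to an MST raster; cells strictly below the refugial threshold
   are refugia, cells within the dispersal radius of a refugium are
   climatically suitable, and areas are tallied in km² with percent
   declines against the current-period baseline.

5. **Synthetic data** (`synthetic_scenario()`, `make_calibration_curve()`,
   `make_daily_weather()`, `make_temperature_grid()`,
   `make_sites_with_occupancy()`, `write_scenario_inputs()`) generates
   every input above with known ground truth, so the whole chain is
   testable offline.

## Worked example

```r
library(taluscape)

# a synthetic world: bomb-spike curve, warming station record, MST grid,
# sites with model-generated occupancy
sc <- synthetic_scenario(seed = 3)
curve <- make_calibration_curve(sc$curve_spec)
d <- calibrate(radiocarbon_measurement("PT-13", fm = 1.25,
                                       fm_sigma = 0.004), curve)
print(d)
#> Calendar-age density: Fm = 1.25 +/- 0.004
#>   support: 1650 - 2015 AD, step 0.5 yr
#>   95% HPD ranges:
#>     1958.5 - 1958.5  (mass 0.224)
#>     1981.0 - 1982.0  (mass 0.761)
```

An Fm of 1.25 exceeds the pre-bomb plateau, so the pellet must post-date
the 1955 bomb spike; the curve crosses 1.25 twice (rising limb, decaying
limb), giving a bimodal posterior: the pellets date to 1958 or to
1981–1982 (combined mass ≥ 0.95).

```r
an <- summarize_years(impute_daily(make_daily_weather(sc)))
fit_trend(an$mat, an$year)
#> Linear trend: slope 0.01919 /yr (SE 8.95e-05), p = 1.91e-139, N = 106
#>   total change over 1910-2015: +2.01 (95% CI 2 to 2.03)
```

The fitted warming (+2.01 °C over 1910–2015) recovers the generating
1.9 °C/century rate over the 105-yr record (truth 1.995 °C).

```r
tg <- make_temperature_grid(sc$grid_spec, seed = 3)
st <- make_sites_with_occupancy(sc$occupancy_spec, tg$mst, seed = 3)
head(rank_models(st)[, c("model", "k", "aicc", "delta_aicc")], 2)
area_summary(tg$mst, c(current = 0, `2050` = 2.74),
             threshold = 14.2, dispersal_km = 4)
```

The end-to-end orchestration is `run_pipeline()` /
`taluscape_main()` (CLI subcommands
`simulate | calibrate | trends | occupancy | project | run`); a wrapper
script is installed at `system.file("cli", "taluscape",
package = "taluscape")`.

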