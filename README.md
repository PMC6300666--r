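# co2scd

Summer CO2 drawdown analysis for high-latitude atmospheric CO2 records.

At stations like Point Barrow (71°N, Alaska), atmospheric CO2 falls
steeply between early July and late August as northern ecosystems take
up carbon. The depth of that decline on the detrended seasonal curve —
the **summer CO2 drawdown (SCD)** — is a station-based proxy for the net
summer carbon uptake of the upwind land region. This package is for
carbon-cycle and biogeochemistry researchers who want to ask, from such
a record plus gridded climate fields: *does summer temperature control
summer carbon uptake, and has that control changed between decades?*

The chain it implements:

1. **Decomposition** — fit a quadratic growth trend plus four seasonal
   harmonics (periods 365/k days on a leap-day-free axis) to the record,
   discard observations beyond 5 residual standard deviations, and
   band-split the residuals with gap-aware Gaussian FWHM filters
   (45.66 d and 390 d) into short-term variation S(t) and slow residual
   variation L(t). The detrended seasonal curve is
   `D(t) = harmonics(t) + S(t) − L(t)`.
2. **Drawdown** — per year, `SCD = mean D(July 1–7) − mean D(Aug 25–31)`
   (positive = CO2 declined), with two robustness variants that use the
   spring zero-crossing and trough dates of D(t), climatological or
   per-year.
3. **Regional series** — July–August composites of gridded temperature,
   precipitation and cloud cover, aggregated over vegetated land
   (mean annual NDVI > 0.1) north of 50°N by cosine-latitude weighting,
   or weighted by a station footprint sensitivity map.
4. **Statistics** — with all series detrended per period, the partial
   correlation `R_SCD-T` of drawdown on temperature controlling for
   precipitation and cloudiness; its error bar from exhaustive
   14-of-17-year subsampling; the regression sensitivity `γ_SCD-T`
   (ppm °C⁻¹); Welch/z tests between periods; lagged correlations; a
   15-year moving-window analysis whose trend-in-r is tested by a
   permutation test (naive OLS p-values are badly anti-conservative on
   overlapping windows); and pixelwise correlation maps.

A synthetic-data generator (`simulate_world()`) produces a Barrow-like
record whose July–August drawdown is coupled to a gridded summer
temperature mode with a known, period-dependent coefficient — zero
before 1996, −2 ppm °C⁻¹ after — plus AR(1) synoptic noise, gaps,
outlier spikes, and NDVI/respiration/footprint fields, so the whole
pipeline is testable against ground truth offline.

## Worked example

```r
library(co2scd)
rep <- run_pipeline(run_config(seed = 42))
print(rep)
#> <scd_report>
#>   early:  R_SCD-T = -0.250 (p = 0.369), gamma = -0.18 +- 0.19
#>   late:   R_SCD-T = -0.911 (p = 2.31e-06), gamma = -1.37 +- 0.17
#>   compare: p(r) = 0, p(gamma) = 4.91e-06
#>   moving window: trend -0.0401 / yr (p = 0.01)
```

Reading it: in the early period (1979–1995) the drawdown shows no
significant temperature control (`R_SCD-T = −0.25`, p = 0.37), while in
the late period (1996–2012) warm summers strongly reduce the drawdown
(`R_SCD-T = −0.91`, p < 10⁻⁵): exactly the coupling contrast the
generator imposed (0 → −2 ppm °C⁻¹). The sensitivity `gamma` is the
drawdown change per °C after removing precipitation and cloud effects;
it is attenuated relative to the imposed −2 because the 1.5-month
filter smooths part of the summer limb perturbation — which is why the
correlation and its significance, not the raw slope, carry the
inference. The between-period tests reject equality for both r and
gamma, and the 15-year moving-window correlation declines at
−0.04 r yr⁻¹ (permutation p = 0.01).

```r
s <- rep$summary
sprintf("clim zero-crossing DOY %.1f, trough DOY %.0f",
        s$phenology$zero_crossing_doy, s$phenology$trough_doy)
#> "clim zero-crossing DOY 176.1, trough DOY 226"
sprintf("subsample r (14-of-17): early %.2f +- %.2f, late %.2f +- %.2f",
        s$early$subsample_mean, s$early$subsample_sd,
        s$late$subsample_mean, s$late$subsample_sd)
#> "subsample r (14-of-17): early -0.24 +- 0.17, late -0.91 +- 0.03"
```

`run_config()` takes period definitions, the drawdown method
(`fixed-window`, `climatological-dates`, `annual-dates`), the weighting
(`coslat`, `footprint`), the controls, and an output directory; with
`outdir` set it writes `scd.csv`, `regional_series.csv`,
`correlations.csv`, `pheno.csv` and a machine-readable `summary.json`,
byte-identical on reruns with the same seed. Configurations can also be
read from YAML (`read_run_config()`), and
`inst/scripts/run_pipeline.R` wraps the whole thing for shell use. Real
inputs enter through `read_co2()` (NOAA daily, weekly, CSV dialects)
and `read_grid_nc()` (CF-NetCDF, dimensions time/lat/lon with units).

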