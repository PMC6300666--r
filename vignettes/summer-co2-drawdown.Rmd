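---
title: "Summer CO2 drawdown and its temperature control: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summer CO2 drawdown and its temperature control: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

High-latitude atmospheric CO2 stations record a pronounced seasonal
cycle: concentrations fall steeply through July and August as boreal and
Arctic ecosystems photosynthesise, and recover through autumn and
winter. The depth of that summer decline at a station such as Point
Barrow — the *summer CO2 drawdown* (SCD), measured on the detrended
seasonal curve between early July and late August — integrates the net
carbon uptake of the vast upwind land region and can be tracked over
decades from a single record. The scientific question this package
serves is whether, and how, the interannual control of summer
temperature over that uptake has changed between decades: a positive
temperature control (warm years, more uptake) is the classic
expectation for temperature-limited northern ecosystems, while an
emerging negative control (warm years, less uptake) signals that
warming has begun to suppress, rather than stimulate, summer carbon
uptake.

`co2scd` implements the full analysis chain — curve decomposition,
drawdown definitions, regional aggregation of gridded climate and
vegetation fields, and the detrended partial-correlation statistics —
together with a synthetic-data generator that imposes a known
drawdown–temperature coupling, so that every stage can be tested
against ground truth without any external downloads.

## Curve decomposition

A station record (daily in-situ or weekly flask-style) is modelled as

$$c(t) = \underbrace{a_0 + a_1 t + a_2 t^2}_{\text{growth trend}}
       + \underbrace{\sum_{k=1}^{4} \left[ b_k \sin \tfrac{2\pi k t}{365}
         + c_k \cos \tfrac{2\pi k t}{365} \right]}_{\text{mean seasonal cycle}}
       + r(t),$$

fitted by least squares over the retained observations. The residuals
$r(t)$ are then digitally filtered with two gap-aware Gaussian kernels
specified by their full width at half maximum: a 45.66-day (1.5-month)
filter yielding $S(t)$, the residual variation on seasonal-to-synoptic
time scales, and a 390-day filter yielding $L(t)$, the slow residual
variation not captured by the quadratic. The components recombine as

$$\text{trend}(t) = \text{poly}(t) + L(t), \qquad
  D(t) = \text{harmonics}(t) + S(t) - L(t),$$

where $D(t)$ is the detrended seasonal curve from which all drawdown
and phenology quantities are read. At every retained record the exact
identity $\text{trend} + D + (r - S) = c$ holds; the test suite asserts
it to $10^{-9}$ ppm.

Numerical choices worth stating:

* **Time axis and harmonic period.** All series live on a 365-day
  (noleap) axis: February 29 is dropped on input, so each calendar year
  occupies exactly 365 samples and day-of-year windows are identical
  across years. On this axis the calendar-locked seasonal cycle is
  exactly 365-periodic, so the harmonic basis uses periods $365/k$
  days. (A 365.25-day basis — the natural choice on a real-calendar
  axis — would drift a quarter day per year against the noleap axis,
  about 8.5 days over a 34-year record, leaving a spurious
  slowly-growing seasonal residual.)
* **Filter kernel.** The kernels are Gaussians truncated at $\pm 3
  \sigma$ with $\sigma = \mathrm{FWHM} / (2\sqrt{2 \ln 2})$, with
  weights renormalised over the available (non-missing) samples. Gaps
  are never interpolated; a day with no data anywhere within $3\sigma$
  is marked missing in the output. Edges are handled by the same
  renormalisation; days within half a year of either end carry an
  `edge` flag since the long filter is only partially supported there.
* **Conditioning.** The quadratic is fitted on a centred, scaled time
  basis and the coefficients transformed back exactly, so 34-year
  records do not lose precision to an ill-conditioned design.
* **Outlier rule.** Records beyond 5 residual standard deviations of
  the current fit are discarded and the function refitted, iterating to
  a fixed point (at most 5 passes; one pass almost always suffices).
  Weekly records skip the rule — flask products arrive pre-screened.
  An exactly-fitting series (residual SD below $10^{-9}$ ppm) skips it
  too, since the threshold would otherwise be numerical noise.

## Drawdown definitions and phenology

Three per-year drawdown definitions are provided, all on $D(t)$:

* `fixed-window` (the primary definition): mean over July 1–7 minus
  mean over August 25–31, so a positive SCD means CO2 declined and a
  warm, low-uptake year shows a *lower* SCD.
* `climatological-dates`: $D$ at the climatological spring
  zero-crossing date minus $D$ at the climatological trough date, the
  dates being read from the multi-year mean curve.
* `annual-dates`: the same, with each year's own dates.

The spring zero-crossing is the fractional day (linear interpolation
between bracketing days) where $D$ crosses zero downward within days
100–300; when transient excursions create several downward crossings
the one nearest day 178 is taken. The trough is the day of minimum $D$
within days 150–300, earliest on ties; the search window excludes
winter minima. Date trends over years are ordinary least-squares
slopes with t-test p-values.

## Regional aggregation

Gridded monthly fields (temperature, precipitation, cloud cover) are
composited to July–August values — means for state variables, totals
for precipitation, the climatological convention — and aggregated to
one scalar per year in either of two ways: a cosine-latitude weighted
mean over vegetated land north of 50°N (vegetated = long-term mean
annual NDVI strictly above 0.1), or a footprint-weighted mean in which
each pixel is weighted by the station's surface sensitivity times
cosine latitude, with **no** sensitivity cut-off, so weakly sensitive
pixels contribute in proportion. All inputs must share one grid;
mismatches are an error, never silently regridded.

Extreme warm days are counted per pixel against the empirical 90th
percentile (linear interpolation between order statistics, the default
quantile definition) of all July–August daily temperatures pooled over
a base period, with *strictly above* as the exceedance rule. The
percentile is computed per pixel, not pooled across space. The
within-summer temperature variability diagnostic is the sample SD of
July–August daily temperature per pixel-year (at least 50 of the 62
days required), aggregated regionally and tested for a trend.

## Statistics

All per-period series are first linearly detrended within the period.
The temperature control of the drawdown is the partial correlation
$R_{\mathrm{SCD}\text{-}T}$: the Pearson correlation of the residuals
of SCD and temperature after regressing each on the controls
(precipitation and cloudiness; optionally also sea-ice extent or mean
summer temperature — extra controls enter the same code path). The
p-value uses $t = r\sqrt{(n-2-k)/(1-r^2)}$ on $n-2-k$ degrees of
freedom with $k$ controls; with 11 samples and 2 controls this
reproduces the conventional significance thresholds for short
satellite-era periods. The regression sensitivity
$\gamma_{\mathrm{SCD}\text{-}T}$ is the temperature coefficient of a
multiple regression of SCD on temperature, precipitation and cloud,
with its standard error.

The error bar on a period's correlation is the standard deviation of
the correlations over subsamples of $m$ of the $n$ years (14 of 17 by
default, 11 of 14 for shorter satellite records). When
$\binom{n}{m}$ is small — $\binom{17}{14} = 680$ — all subsets are
enumerated, making the distribution exact and deterministic; otherwise
1000 seeded random draws are used. The full-sample p-value is the
reported significance. Periods are compared by Welch's t-test on the
two draw sets (correlations) or a z-test on the coefficient difference
(sensitivities).

Two diagnostics probe the temporal structure. Lagged correlations
relate this year's drawdown to temperature one or two years earlier
(controls stay contemporaneous). The moving-window analysis computes
the partial correlation in 15-year windows advanced one year at a time,
each window detrended independently. Because consecutive windows share
14 of their 15 years, the window correlations are strongly
autocorrelated and a naive regression p-value for "is r trending?" is
severely anti-conservative (we measured a ~60% null rejection rate at
a nominal 5%). The trend is therefore tested by permutation: the
(year, SCD, temperature, controls) tuples are shuffled jointly —
preserving the coupling, destroying the time order — and the observed
OLS slope of r on window-centre year is ranked against 199 permuted
slopes. This test is exact under the stationary-coupling null; a
directional alternative (`"less"` for a declining r) is available when
the hypothesis is a loss of positive coupling.

Pixelwise correlation maps apply the same detrended partial
correlation per masked pixel, with significance reported at the 0.05
and 0.1 levels; no multiple-testing correction is applied, and the map
difference between periods is reported as later minus earlier. These
choices mirror standard practice for such maps and are stated here so
the maps are read as descriptive, not inferential.

## The synthetic world

`truth_params()` fixes the study conditions; `simulate_world()`
generates every pipeline input with recorded ground truth.

* **CO2 record.** 1979–2012 daily, quadratic growth (355 ppm base,
  1.7 ppm/yr, 0.011 ppm/yr²) plus a four-harmonic seasonal cycle whose
  amplitude/phase pairs project a Barrow-like shape (spring maximum,
  steep July decline, late-August trough ~9.5 ppm below the mean,
  winter plateau). Each year's July–August descending limb is deepened
  by the imposed drawdown anomaly $d_y = \beta(\text{period}) \cdot
  T_y + \varepsilon_y$, applied through a smooth limb-shaped weight
  (zero before July 1, −1 by August 25, relaxed to zero by year end) so
  the perturbation is confined to the summer decline rather than a
  phase shift. Defaults: $\beta = 0$ before 1996 and $-2$ ppm/°C from
  1996, $\varepsilon_y \sim N(0, 0.5\,\text{ppm})$, matching the
  contrast the analysis is designed to detect. On top: AR(1) synoptic
  noise (lag-1 correlation 0.7, marginal SD 1 ppm — a modelling choice;
  the synoptic spectrum of a real station is not characterised here),
  5% random gaps, and rare spikes of 5–20 noise-SDs so the outlier
  rule has work to do.
* **Climate fields.** A 20 × 40 pixel grid over 50–80°N (desk-scale
  stand-in for a 0.5° product). July and August temperature anomalies
  share one regional interannual mode with SD 0.8 °C — the *same*
  series that drives the CO2 coupling — plus spatially correlated pixel
  noise re-centred so the cosine-latitude regional summer mean equals
  the mode exactly (a construction identity the tests assert to
  $10^{-10}$). Precipitation and cloudiness carry their own modes,
  partially correlated with temperature (+0.3 and −0.4), so the
  controls in the partial correlation are non-trivial. Daily
  July–August temperature adds day-to-day noise of SD 3 °C; it is
  generated only for July–August, the window every consumer (extreme
  days, variability) uses.
* **Vegetation and respiration.** Summer NDVI is a poleward-declining
  climatology (falling below the 0.1 vegetated threshold at the
  highest latitudes, so the mask is non-trivial) plus a
  period-dependent temperature response (+0.02 NDVI/°C before the
  break, 0 after), minus an optional heat-stress penalty per extreme
  warm day, clipped to [−0.1, 1]. Heterotrophic respiration follows
  the Q10 law, $HR = HR_0 \, q_{10}^{(T-T_0)/10}$, positive in both
  periods. The footprint is a smooth two-lobe bump (Alaska/Chukchi
  plus Siberia) max-normalised to 1 — a stand-in consumed like a
  transport-model sensitivity map, never a simulation of one.

What the generator does *not* emulate — real synoptic spectra,
transport variability, fires, permafrost dynamics, observation-system
changes — bounds what passing tests show: they demonstrate that the
pipeline recovers a coupling of the imposed structure at realistic
noise levels, not that any particular real-world record contains one.

## Problem sizes and determinism

Default desk-scale runs use the 34-year daily record (12 410 samples),
the 20 × 40 grid, exhaustive 680-subset resampling and 199
permutations; a full pipeline run takes a few seconds, and the
repository's acceptance script (a pipeline run plus a 30-seed recovery
study) a couple of minutes. Every random component — generator,
subsampling, permutations — draws from seeds derived deterministically
from one root seed, so a configuration reruns byte-identically; the
test suite asserts this on the written outputs.

## Limitations

* The fixed July/August windows are day-of-year based; on real (leap)
  calendars this differs from fixed dates by at most one day.
* Correlations on 17-year periods with 2 controls have 13 degrees of
  freedom; the subsample SD quantifies sampling spread, not
  autocorrelation effects, and no effective-sample-size correction is
  applied.
* The weekly path fits at weekly stamps and evaluates on the daily
  axis; with sparse flask-like records the short filter is supported
  by ~6 points per window, so weekly drawdowns are noisier than daily
  ones (the tests bound the difference at 0.5 ppm RMS under moderate
  noise).
* Regridding, VPD computation from raw meteorology, field-significance
  testing and transport modelling are out of scope; footprints, VPD,
  sea-ice extent and flux fields are consumed as prepared inputs.
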