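---
title: "Methods: wet-bulb heat exposure and neonatal mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wet-bulb heat exposure and neonatal mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`heatnatal` implements a complete pipeline for estimating the effect of in
utero extreme-heat exposure on neonatal mortality: a psychrometric
conversion, location-specific percentile thresholds, gestational exposure
accounting, a high-dimensional fixed-effects linear probability model with
cluster-robust inference, and a synthetic study world with planted effects
on which every stage is validated end to end. This vignette records the
model, the tunable parameters, the numerical choices, and the design
decisions that were genuinely open.

## Wet-bulb temperature

Heat stress depends jointly on temperature and humidity, because humidity
impedes evaporative cooling. The pipeline therefore works on wet-bulb
temperature, computed from daily dry-bulb temperature $t$ (°C) and relative
humidity $rh$ (percent, 0–100) with Stull's closed-form approximation:

$$
wt = t\,\arctan\!\big(0.151977\sqrt{rh + 8.313658}\big) + \arctan(t + rh)
  - \arctan(rh - 1.676331)
  + 0.00391838\, rh^{3/2} \arctan(0.023101\, rh) - 4.686035,
$$

with all arctangents in radians. Two conventions are worth recording. The
humidity exponents are $1/2$ and $3/2$ — the standard Stull fit; typeset
versions of the formula sometimes render them ambiguously, and only the
half-integer reading yields physically sane values (at saturation
$wt \approx t$; checked to within 0.5 °C over 0–45 °C). Second, inputs
outside the fit's stated validity envelope (roughly $rh \in [5, 99]$,
$t \in [-20, 50]$) are computed, not rejected: daily satellite fields are
converted wholesale, and `climate_wetbulb()` attaches an out-of-envelope
count so a run can log how often the envelope was left. Values are not
clipped.

## Percentile thresholds

"Extreme" is defined locally and seasonally: for each location, season
$s \in \{1,2,3,4\}$ (calendar quarters: Jan–Mar, Apr–Jun, Jul–Sep, Oct–Dec)
and target year $\tau$, the cutoff at percentile $p$ is the $p$-th
percentile of all daily wet-bulb values at that location in season $s$ of
the $k$ preceding years $\tau-k, \dots, \tau-1$ (default $k = 3$; about
270 pooled days). Heat uses $p \in \{75, 85, 90, 95\}$, cold
$p \in \{25, 15, 10, 5\}$.

Numerical choices:

- **Percentile estimator.** Sorted-order linear interpolation
  (`stats::quantile` type 7), the common default; the estimator is recorded
  in the exposure metadata sidecar because different conventions move
  cutoffs by fractions of the day-to-day spread.
- **Rolling versus fixed references.** The default window rolls
  ($\tau-k \dots \tau-1$). Long-climatology variants ($k$ beyond what the
  record supports rolling, e.g. an 18-year reference on an 18-year record)
  use a fixed pooled window applied to every target year
  (`reference = "fixed"`). Rolling variants with larger $k$ restrict the
  analyzable birth range accordingly (with $k=5$, births from October of
  year $\mathrm{start}+5$).
- **Location key.** Thresholds are computed per climate pixel and clusters
  inherit their pixel's thresholds; the location key is a parameter, so
  cluster-level or aggregated thresholds are a relabeling away.

A calibration property pins the construction: on iid stationary synthetic
climate, about 10% of days in a held-out year exceed the P90 cutoff. Under
strong day-to-day persistence the pooled window's *effective* sample is much
smaller than 270 and the sample quantile acquires a small tail bias (held-out
exceedance nearer 12% at persistence 0.9); this is a property of percentile
estimation on autocorrelated data, not of the implementation, so the
calibration check is defined on iid noise.

## Exposure metrics

For a child born in calendar month $m$, the gestational window is the nine
full months $m-9, \dots, m-1$ (birth timing is known to the month, so there
is no day-of-birth proration; windows are 273–276 days). Each day is
compared with the cutoff of its own (location, season, calendar year) — a
window spanning a year boundary deliberately mixes threshold vintages.
Two margins are accumulated per percentile:

- cumulative exceedance (intensive margin):
  $\sum_d \max(0,\, wt_d - c_d)$ in °C·day for heat, and the shortfall
  $\sum_d \max(0,\, c_d - wt_d)$ for cold;
- exceedance days (extensive margin): the count of days with strict
  exceedance (heat) or strict shortfall (cold).

A day exactly at the cutoff is not extreme (strict inequalities on both
sides). Postnatal counterparts are computed over the birth month itself and
serve as controls in one robustness variant. The precipitation control is
the arithmetic mean of the nine monthly values at the cluster's 0.5°
precipitation cell.

Implementation note: because both margins are additive over days and every
day's cutoff depends only on its own (location, season, year), per-day
exceedances are aggregated to calendar months once and window sums are sums
of nine monthly aggregates. This is exact, and the test suite verifies it
against an independent per-day loop for every metric. Births whose window
(or birth month, or precipitation series) is not fully covered go to a
rejects table with a reason; there is no imputation.

## The regression model

The estimating equation is a linear probability model on the per-1,000
scale:

$$
1000 \cdot \mathrm{death}_{icrmt} = \alpha_1 \mathrm{Exposure}_{icrmt}
 + \beta' X_{icrmt} + \mu_c + \gamma_t + \delta_{rm} + \varepsilon_{icrmt},
$$

with DHS-cluster fixed effects $\mu_c$, birth-year effects $\gamma_t$, and
2°-grid-cell-by-birth-month effects $\delta_{rm}$; $X$ holds infant gender
and birth order, mother's age, age squared and education tier, and
window-mean precipitation. A linear (not logistic) specification keeps
$\alpha_1$ directly interpretable as additional deaths per 1,000 births per
unit of exposure and makes parameter recovery exact in expectation.

The fixed effects are absorbed by iterated group demeaning (alternating
projections) with tolerance $10^{-10}$ on the largest absolute group mean
and a 10,000-sweep ceiling; one factor converges in a single pass, crossed
factors typically in a few dozen. Slopes come from OLS on the residualized
columns (Frisch–Waugh). A regressor annihilated by the demeaning (no
within-group variation) raises a rank error naming the column rather than
returning a spurious zero.

Inference is CR1 cluster-robust at the DHS-cluster level:
$(X'X)^{-1}\big(\sum_g s_g s_g'\big)(X'X)^{-1}$ scaled by
$\frac{G}{G-1}\cdot\frac{n-1}{n-k}$, with t-tests and 95% CIs on $G-1$
degrees of freedom. The absorbed degrees of freedom in $k$ are counted as
$1 + \sum_f (L_f - 1)$ — exact for one factor and for connected crossed
factors sharing only the intercept, an approximation otherwise; the
convention is recorded in every fit object because software differs at the
third decimal of SEs. Singleton fixed-effect groups are retained (a flag
drops them) but always counted in $k$; with every cluster a singleton the
estimator collapses to HC1, which the tests verify.

## The synthetic world

The real microdata are access-restricted, so validation runs on a
synthetic world that reproduces the study's *structure*: clusters nested in
2° cells nested in countries; births October 2006 – June 2020; daily
climate 2003–2020. Defaults (5 countries × 100 clusters × 100 births ≈
50,000 births on a 10° × 10° tropical box at 0.5° pixels) are a
reduced-scale version of the survey geometry.

Climate is latitude-dependent mean + seasonal sinusoid (hemisphere-correct
phase) + linear warming trend (0.3 °C/decade) + AR(1) daily anomalies, and
a seasonal humidity cycle clipped to [5, 99]%. The anomaly process
(persistence 0.9, innovation s.d. 2.5 °C, marginal s.d. ≈ 5.7 °C) was
chosen once so that seasonal-mean anomalies have s.d. ≈ 1.5–2 °C —
consistent with interannual variability of land-surface temperature at
seasonal scale, and the feature that gives exposure enough within-cluster
variation for planted effects of the magnitude reported in this literature
to be estimable at ~50,000 births. One consequence worth knowing: under a
*linear* trend the rolling threshold adapts with a constant ~2-year lag, so
rolling-threshold exceedance is stationary by construction; rising exposure
over time is visible only against a fixed baseline climatology, and the
test suite measures it that way.

Outcomes follow a linear probability process: baseline 0.029 (29 deaths
per 1,000), plus $\beta_{heat} \times$ (group multiplier) per °C·day of
90th-percentile cumulative heat on the per-1,000 scale (default
$\beta_{heat} = 0.03$), plus cluster, birth-year, and cell-by-month random
effects and small covariate terms, clipped to $[0,1]$ with the clip
fraction reported (warning above 5%, error above 50%). Every planted term
is linear in the fitted model's columns and constant within some absorbed
factor, so regressing the pre-Bernoulli linear predictor on exposure
returns $\beta_{heat}$ to machine precision — the tests use this as the
generative calibration check. Prenatal visits are Poisson with log-rate
$\log \mu_0 + \gamma\,\mathrm{cumheat}_{90}$, $\gamma \le 0$ (default
−0.0015, $\mu_0 = 4$). Group multipliers (urban, water, sanitation, wealth,
electricity, education) scale $\beta_{heat}$ for the named subgroup and
default to 1; setting `mult_urban = 0` gives a rural-only world,
`mult_unimproved_water = 2` a water-vulnerability world, `beta_heat = 0`
a null world. An optional confounded variant ties the cell-by-month
effects to the seasonal cycle to demonstrate the omitted-variable bias that
the cell-by-birth-month fixed effects exist to remove.

What the generator does *not* emulate: real African geography, DHS sampling
weights, sibling correlation, gestational-age variation, spatially
correlated humidity, or displaced GPS coordinates. Passing tests therefore
show that the pipeline recovers known truths under the stated generative
process — they do not certify the substantive estimates on restricted real
data.

## Validation design

Monte Carlo replicates are distinct climate worlds crossed with fresh
outcome draws (the planted truth enters only the outcome stage), e.g. 20
worlds × 5 draws for 100 recovery replicates. This matches the targeted
experiment — the estimator's sampling distribution over outcome noise, with
the exposure design varying across worlds — at a fraction of the compute.
Reduced problem sizes are stated in the tests themselves: full-scale worlds
(~50,000 births) for recovery and heterogeneity, reduced worlds (~6,000
births, 150 clusters) for size and placebo calibration, 200 pixels × 4
years for threshold calibration.

Known limitations: the cold-placebo battery on a heat-only world inherits a
small negative association through the climate-driven correlation between
heat and cold metrics, so its rejection rates sit slightly above pure size;
the absorbed-degrees-of-freedom count is approximate for non-nested crossed
factors; and the migration filter's arithmetic (duration in integer years,
converted at 12 months/year, required to cover conception through
interview) is this package's documented operationalization, not an inferred
one.
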