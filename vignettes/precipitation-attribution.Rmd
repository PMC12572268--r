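---
title: "Attributing health-service disruption to precipitation with ancrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing health-service disruption to precipitation with ancrain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancrain)
```

## The problem

Routine health services in settings with fragile transport infrastructure are
vulnerable to rainfall: heavy or prolonged precipitation can make unpaved
roads impassable, cut patients off from clinics, and occasionally damage or
close the clinics themselves. Antenatal care (ANC) is a particularly
informative outcome — appointments are time-constrained within pregnancy, so
a disrupted month is more likely to reflect a missed service than a deferred
one, and demand is driven mainly by demography, making it projectable.

`ancrain` quantifies this relationship from two routinely available inputs:

* a facility-month panel of ANC service counts, as exported from a health
  management information system (DHIS2-style, with its characteristic
  missingness), and
* gridded daily precipitation (reanalysis-style lat/lon/time cubes).

## The attribution model

Two ordinary-least-squares models are fitted to the logged counts
$\log(y_{i,t} + \epsilon)$, with $\epsilon = 1$ so that zero-count months are
representable:

* **M0** (precipitation-free): year, month, urban/rural setting, zone,
  ownership, altitude, and the distance to the closest other facility;
* **M1** (precipitation-aware): M0's covariates plus precipitation indices,
  selected from a candidate set by backward stepwise AIC.

The candidate indices are ETCCDI-informed monthly summaries per grid cell:
the monthly cumulative total, the maximum 5-day consecutive total (Rx5day),
their 1-, 2-, 3-, 4- and 9-month lags, squares, cubes and the
cumulative-by-Rx5day product. Facilities are matched to grid cells by
nearest-centre search (a k-d tree over cell centres in degree space, exact
ties to the lowest cell index).

The disruption attributed to precipitation in facility $i$, month $t$ is the
difference of back-transformed predictions

$$\Delta_{i,t} = \hat y_{0,i,t} - \hat y_{1,i,t},
\qquad \hat y = \max(e^{X\hat\beta} - \epsilon,\, 0),$$

restricted to *deficit* months ($\Delta_{i,t} > 0$): only months where the
precipitation-aware model predicts fewer services count as disruptions.
Summed deficits are expressed as a percentage of total services, split by
whether the month's cumulative precipitation reached the extreme threshold
(by default the 90th percentile of all historical cell-month totals), and
optionally converted to affected pregnancies.

Counterfactual and scenario analyses substitute a different precipitation
series into the fitted design — an early-period "pre-change" climate or a
projection ensemble member — leaving every non-climate covariate and both
fitted models untouched. The difference between the factual and substituted
disruption totals is the package's measure of how much of the disruption is
attributable to the precipitation regime itself.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `epsilon` | 1 | offset inside the log; makes zero counts finite and maps count 0 to response 0 |
| `lags` | 1, 2, 3, 4, 9 months | lag set for both monthly indices; the 9-month lag spans a full pregnancy |
| `percentile_q` | 90 | extreme-month threshold percentile of historical monthly totals (mm/month) |
| `sparse_missing_threshold` | 0.9 | facilities with a *strictly greater* missing fraction are excluded |
| `visits_per_pregnancy` | 4.4 | delivered ANC appointments per live birth, for pregnancy conversion |
| `threshold_pool` | all cells | whether the extreme percentile pools every grid cell or only facility-matched cells |

Both pregnancy conversions are provided (`per_pregnancy` divides by 4.4;
`per_visit` counts each disrupted visit as one affected pregnancy) because
reported figures in this literature use both conventions inconsistently;
neither is privileged.

## Data cleaning rules

* **Closure repair.** Missing reports inside a closure confirmed by secondary
  sources are replaced by zero counts — the facility was closed, so no
  services were delivered. Observed counts are never overwritten, and missing
  reports outside any confirmed closure are treated as random non-reporting
  and excluded from fitting (not imputed).
* **Sparse facilities.** A facility missing more than 90% of its months is
  dropped entirely; the inequality is strict, so a facility at exactly the
  threshold is retained.
* **Altitude.** Missing altitudes are mean-imputed from the observed ones.
* **Collinearity.** Covariate pairs are screened (Cramér's V for categorical
  pairs); when a pair is strongly associated the designated second member is
  dropped — facility type tracks ownership, and district is nested in zone,
  so type and district are removed by default.
* **Lag warm-up.** Months whose lagged indices are undefined carry explicit
  `NA` markers and are excluded from fitting, never zero-filled; the
  synthetic generator extends its grid 9 months before the analysis period so
  that every analysis month has defined lags.

## The synthetic-data generator

The generator exists so the full pipeline is testable end to end without any
restricted data. It emulates:

* **Facilities** placed uniformly over the grid extent, with the categorical
  structure of a national facility census: five zones (districts nested
  within zone), urban/rural setting, four ownership classes, facility types
  drawn conditionally on ownership (so the collinearity screen has real
  structure to find), and altitudes on a plausible plateau range.
* **Rainfall** as a Bernoulli–gamma stochastic weather generator: each day is
  wet with a season-dependent probability and wet-day amounts are gamma
  distributed, scaled so the unconditional daily mean matches the configured
  wet/dry-season means (defaults 6 and 0.3 mm/day, wet season
  November–April). With a small per-cell-month probability (default 0.03) an
  extreme burst (default 250 mm) is added over 1–5 consecutive days, which
  drives Rx5day by construction. No rainfall distribution is canonical for
  this purpose; any generator with the right seasonal moments and an
  extreme-event mixture serves, and the Bernoulli–gamma form is the standard
  weather-generator choice.
* **Service counts** drawn exactly from the log-linear model:
  `count = max(0, round(exp(X beta_true + noise) - 1))`, with default
  coefficients matching the signs and magnitudes of the historical fit (e.g.
  cumulative precipitation −0.0004 per mm). The published per-metre distance
  coefficient is not usable as a literal per-metre value at this scale, so
  the generator uses a per-metre magnitude (3e-5) that yields realistic
  between-facility contrasts.
* **Missingness** as independent non-reporting at a configured rate plus
  closure-linked gaps, reproducing the two mechanisms the cleaning rules
  address.

One master seed drives documented per-component substreams (facilities,
grid, counts, missingness, closures), so each stage is individually
reproducible.

What the generator does *not* emulate: spatial correlation of rainfall
between cells, within-facility serial correlation of counts beyond what the
covariates induce, seasonal demand for ANC itself, and reporting artefacts
such as end-of-quarter heaping. Passing tests therefore demonstrate that the
statistical machinery is correct under the stated model, not that the model
captures every feature of real reporting systems.

## Numerical and design choices

* **Rx5day windows** are confined within the calendar month (no cross-month
  windows), matching the monthly resolution of the analysis; the index is
  computed by cumulative sums and verified in tests against an exhaustive
  window scan.
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7), the most common convention.
* **Degrees to metres** uses an equirectangular local projection (longitude
  scaled by the cosine of the mean latitude, 111,320 m per degree). Any
  consistent metric preserves the regression's information; the constant is
  configurable.
* **AIC convention**: the parameter count includes the intercept and the
  Gaussian error variance; differences between nested fits are unaffected.
* **Stepwise ties** (equal AIC improvement) are broken by removing the term
  with the larger current p-value, making selection deterministic.
* **Back-transformation** is the naive `exp(Xb) - epsilon` floored at zero,
  with no smearing correction by default: the attribution statistic is a
  *difference* of two back-transformed predictions from models with nearly
  identical error variance, so the retransformation bias largely cancels; a
  multiplicative smearing factor can be passed to `predict_counts()`.
* **Extreme attribution** is month-level: a deficit counts as
  extreme-attributed iff its month's cumulative precipitation meets the
  threshold. The threshold is always computed from the historical window,
  never recomputed per scenario.
* **Ensemble member selection** picks the members with the lowest and
  highest grand mean monthly precipitation, and for the middle role the
  member closest to the median of the grand means — "median" being the
  natural reading of a three-way lowest/mean/highest split of a small
  ensemble. Ties break by member name, so the choice is order-invariant.
* **Calendar remapping** for counterfactuals aligns month *m* of the k-th
  analysis year with month *m* of the k-th alternative year (cycling if the
  alternative window is shorter), preserving seasonality. When the
  alternative series already covers the analysis calendar (the substitution
  identity case) no remapping occurs, and re-substituting the factual series
  reproduces the factual run bit for bit.
* **Zone terms** stay in the fixed covariate set by default rather than the
  stepwise candidate set; only precipitation indices are subject to
  selection. The candidate set can be overridden via
  `pipeline_config(candidate_terms = ...)`.
* **NGO ownership** is absorbed into the reference level with CHAM by
  default (there are typically few NGO facilities and fits of this model
  family report no separate NGO coefficient); `ngo_separate = TRUE` gives it
  its own column.

## Problem sizes

The test suite exercises the pipeline on worlds of 80 facilities over 4
years on a 5×5 half-degree grid, and the parameter-recovery study
uses 150 facilities × 48 months with 200 noise replicates (β for cumulative
precipitation −0.0004, log-scale noise SD 0.3) — sizes at which the
cumulative-precipitation coefficient is estimated with a |t| ratio around
8–10, comfortably inside the asymptotic regime, while a full run stays
under a minute. The bundled acceptance script runs 150 facilities over 12
years (~19,000 facility-months after cleaning).

## Known limitations

* Plain OLS on logged counts: no count likelihood (Poisson/negative
  binomial), no facility random effects, no clustered standard errors.
* Year and month enter as single numeric covariates, so seasonality is
  captured only through the precipitation terms; a monotone month trend is a
  crude stand-in for calendar effects.
* The attribution is associational: the counterfactual-difference statistic
  inherits any confounding in M1's precipitation coefficients.
* Monthly resolution cannot see within-month postponements; lagged terms
  only partially capture appointments shifted to the following month.
* Scenario percentages depend on an externally supplied service/birth
  projection, which the package treats as a constant input across scenarios.
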