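---
title: "Methods: process-based phenology forecasting with phenocast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: process-based phenology forecasting with phenocast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenocast)
```

phenocast implements an automated, species-level plant phenology
forecasting system as a reusable toolkit: thermal-forcing phenology models
fit to status-based monitoring observations, a cross-validated stacked
ensemble, statistical downscaling of coarse sub-daily climate forecasts,
gridded multi-member prediction of event dates with uncertainty and
anomaly maps, and forecast verification. This vignette describes the
models, the choices behind their implementation, and what the synthetic
experiments shipped with the package do and do not demonstrate.

## The day axis

Forcing accumulation for a spring event can begin in the preceding
autumn, so all arithmetic runs on an *extended day index*: day 1 is
1 January of the event year, day 0 is 31 December of the prior year, and
1 November of the prior year is day −60. Predicted "day of year" values
are simply this index; an event predicted before 1 January carries its
negative index. This removes every special case at the year boundary.

The observed temperature series that feeds a forecast starts on
1 November of the prior year by default. A 30 November start is available
as a configuration option (`observed_start: "30 Nov"`); for spring
phenophases driven by forcing alone the choice is immaterial because
forcing start days rarely precede late autumn, but both conventions
appear in operational systems so both are supported.

## The phenology model family

All members consume one driver: daily mean 2-m air temperature, in
degrees C. The three process-based members accumulate daily forcing
units from a start day `t1` and predict the event on the first day the
accumulated forcing meets a requirement:

* **thermal time** (growing degree days): daily unit
  $\max(0, T_i - T_b)$; event when the sum reaches $F^*$. Parameters
  $t_1$, $T_b$ (degrees C), $F^*$ (degree-days).
* **alternating**: forcing is degree-days above 0 C, but the requirement
  relaxes with accumulated chill: on day $d$ it is
  $a + b\,e^{c\,\mathrm{NCD}_d}$, where $\mathrm{NCD}_d$ counts days
  since $t_1$ colder than a 5 C chill threshold and $c < 0$. The 5 C
  threshold is the standard value in the alternating-model literature
  and is kept fixed unless overridden.
* **uniforc**: a sigmoidal forcing response
  $1/(1 + e^{b_\sigma (T_i - c_\sigma)})$ with $b_\sigma < 0$ enforced so
  that forcing increases with temperature; event when the sum reaches
  $F^*$.

The fourth member is a **linear** regression of onset day on the mean
temperature over a fixed window (default days 1–60, i.e. January and
February): a deliberately simple statistical member that anchors the
ensemble where the process members are weakly identified.

These four are the canonical suite of the thermal-forcing family. They
stand in for the exact sub-model set of any particular operational
system; the fitting, stacking, prediction and storage machinery is
agnostic to the member list, which can be swapped per species through
the `members` argument of `fit_stacked_ensemble()`.

Two degenerate-input rules apply everywhere: interior gaps of at most 3
consecutive missing temperature days are linearly interpolated, while a
longer gap inside the accumulation window makes that cell's prediction
missing (silent zero-filling would bias forcing sums); and a requirement
that is never met within the series returns a no-event sentinel (`NA`)
rather than an extrapolated date.

## Observation filtering

Status-based monitoring yields repeated yes/no/unsure answers per plant
and phenophase. Onsets are derived with the standard quality rules: an
onset is the first "yes" of a yes-series and is kept only when the same
plant has a "no" within the preceding 30 days (so the onset is actually
bracketed); plants with conflicting same-day records or more than one
yes-series inside a 12-month window are dropped entirely for that
phenophase; "unsure" records are ignored. Models are only fit for
species–phenophase groups with at least 30 onsets (boundary inclusive).
The filter is order-insensitive and idempotent.

## Fitting and stacking

The forcing-model objective — RMSE between predicted and observed onset
days — is a step function of the parameters (predictions move in
whole-day jumps), so derivative-based optimizers stall on its plateaus.
Each member is therefore fit by a seeded, bounded differential-evolution
search (population 40, at most 120 generations, relative tolerance
1e-4), with documented default bounds per family wide enough for
temperate spring phenophases: `t1` in [−60, 100], `T_base` in [−5, 15] C,
`F_star` in [10, 2000] degree-days, and analogous ranges for the other
families (`default_bounds()`). Candidate parameter sets that predict no
event for an observation are charged a large finite penalty (365 days)
so the search is repelled from, but not trapped in, degenerate regions.
The linear member's objective is quadratic, so it is fit exactly by
ordinary least squares instead. Any parameter can be frozen through the
`fixed` argument (e.g. a known start day), which both sharpens
identifiability and speeds up cross-validation.

Ensemble weights are learned by stacking: observations are partitioned
into 100 random folds (reduced to leave-one-out below 100 observations;
folds are assigned per observation, not per site — with volunteer
networks most sites contribute a single plant, so the distinction is
minor at these scales), each member is fit on every training fold and
predicted on its held-out fold, and the weights minimize the RMSE of the
weighted out-of-fold prediction subject to $w \ge 0$, $\sum w = 1$.
Because the weights sum to one this is a small simplex-constrained
quadratic program in the member *error* vectors, which the package
solves exactly by active-set enumeration. Degenerate optima get a
deterministic resolution: among weight vectors attaining the minimum,
prefer the smallest weighted member mean-squared error (hopeless members
are excluded rather than cancelled against each other), then the fewest
members; exact ties between interchangeable members resolve to the
uniform weight (four identical members each get 0.25). After the weights
are fixed, every member is refit once on the full data set; the weights
are not re-estimated afterwards.

At prediction time the ensemble is the weighted mean of member predicted
days, rounded to a whole day. Members predicting no event at a cell are
dropped and the weights renormalized over the responders; if the
responding weight falls below 0.5 the ensemble declines to forecast
there. This keeps one pathological member from deleting a forecast while
refusing to publish minority-supported dates.

A latitude-only least-squares baseline (onset day on site latitude) is
fit per group; it supplies the long-term, spatially corrected expected
date from which forecast anomalies are measured.

## Downscaling

Coarse (0.25-degree-style) sub-daily forecast cubes are first averaged to
daily means (four 6-h steps per day; a trailing partial day is dropped,
an interior partial day is an error), regridded to the fine grid by
inverse-distance weighting (4 nearest coarse centers, power 2; a fine
point coinciding with a center returns that center's value; points
outside the coarse bounding box fall back to the nearest center), and
then corrected per fine cell and calendar month by an affine map
$a_{cm} x + b_{cm}$.

The affine maps come from *asynchronous regression* against a historical
archive: for each cell and month, the coarse and fine samples are sorted
and paired by empirical quantile (the longer sample's quantile function
linearly interpolated to the shorter one's length, so archives with
different missing days still pair), and ordinary least squares on the
rank-paired values gives the slope and intercept. Pairing by rank rather
than timestamp matches the distributions instead of the (asynchronous)
weather, and makes the fit invariant to any permutation of timestamps
within a month. A single linear segment per month is used — two
parameters per cell-month — rather than piecewise tails; years are
pooled within each calendar month. Cell-months with fewer than 30 values
or zero variance are flagged missing, never fabricated. Distances are
Euclidean in degrees: at the modest extents of a forecast grid the
great-circle correction changes IDW weights negligibly, and the same
metric is used in fitting and application so any distortion cancels.

## Gridded forecasts and uncertainty

A forecast for one issue date splices observed temperatures (up to the
day before issue) with each downscaled forecast member (from the issue
day onward; on overlap the forecast side wins, since the observed
archive may lag). Each of the nominally five members is run through the
phenology ensemble, giving five predicted-day grids. The published
product per species and phenophase is:

* **point estimate** — the member mean, rounded to a day;
* **uncertainty** — the member sample standard deviation (n − 1
  denominator), i.e. the spread induced by the climate forecast, the
  dominant uncertainty source at seasonal leads (the process models
  themselves are deterministic);
* **95% prediction interval** — the normal approximation
  point ± 1.96 sd, clipped to the forecast day span. A five-member
  min/max range was rejected: the range of five draws is not a 95%
  interval;
* **anomaly** — point estimate minus the latitude-baseline expectation;
  negative is earlier than average.

Cells where fewer than 3 of 5 members respond are missing; cells with a
responding majority are summarized over the responders and flagged
partial. Every layer is cropped to the species range mask. Members whose
series do not reach the configured horizon (default nine months past
issue) are discarded and replaced from a configured fallback list of
preceding forecasts.

## Verification

Events are matched to forecasts by species, phenophase and nearest grid
cell (ties to the lower index); events on masked-out cells are dropped
and counted. For each issue date the table reports the number of matched
events, RMSE, mean signed error (positive = predicted later than
observed), mean absolute error, and mean forecast uncertainty. By
default an issue date is scored against the events that had not yet
occurred at issue — the events that forecast could still inform — with
plain per-date scoring available via `scope = "all"`; the choice only
affects which events enter each row, not the metrics.

## Storage and the pipeline

Fitted models are stored as text-based JSON documents (schema-versioned,
full-precision, stable key order, so stored models diff cleanly under
version control) with a metadata index per store; grids travel as
compressed netCDF-4 with CF-style attributes. The pipeline commands —
`cmd_fit()`, `cmd_build_downscaling()`, `cmd_forecast()`,
`cmd_verify()`, `cmd_synth()` — are single-shot, idempotent under a
fixed seed, and driven by one YAML configuration; a thin command-line
wrapper ships in `inst/cli/phenocast.R`. Scheduling (e.g. a cron cadence
of a few days) is an operations concern left outside the package.
`cmd_forecast()` writes every product to a staging directory and moves
the files into the publish directory only after all products succeed, so
an interrupted or failing run leaves the previously published forecasts
byte-identical.

## The synthetic study system

Because the real inputs (volunteer phenology networks, gridded
temperature analyses, seasonal forecast systems) require live downloads,
every test and the acceptance script run on seeded synthetic data with
known ground truth:

* **climate** — per cell,
  $T(d) = \bar T - \lambda(\phi - \phi_0) + A \sin(2\pi (d - d_0)/365) + \varepsilon$:
  an annual mean of 12 C, seasonal amplitude 10 C (warm peak in mid
  July), a latitudinal lapse of 0.8 C per degree, and Gaussian daily
  noise (default 1 C where noise is wanted). These values put synthetic
  spring onsets in March–May at mid latitudes, matching the phenology
  the system targets.
* **observations** — sites drawn at random grid cells; onsets are the
  true model's predictions plus rounded Gaussian noise (2 days where
  noise is wanted — of the order of the reporting granularity of
  volunteer status monitoring); status records are constructed to pass
  the filter (a "no" 7 days before each onset), with optional injected
  violations for filter tests.
* **downscaling truth** — the fine archive is an exact known affine map
  (slopes 0.8–1.2, intercepts ±2 C) of the IDW-interpolated coarse
  archive, so recovery can be checked to machine precision; the coarse
  cube carries a mean-zero diurnal harmonic so daily aggregation is
  exact.
* **forecast members** — the first member is the truth; the rest add
  smooth perturbations whose standard deviation grows with lead time
  (0.02–0.03 C per day of lead), emulating ensemble dispersion.

The end-to-end experiment (20 × 20 grid, 2 species, 5 members, 3 issue
dates; 30 observations per species, the fitting threshold) checks two
properties: with every noise source at zero the full
fit → downscale → forecast → verify chain reproduces every event exactly
(verification RMSE 0 at all issue dates), and with lead-time-growing
member spread the mean forecast uncertainty declines as the issue date
approaches the events. In that experiment the forcing members are fit
with the start day frozen at 1 January — the generating truth — keeping
the zero-noise chain exactly identifiable; with `t1` free, near-optimal
plateaus (`t1`, `T_base`, `F_star` trade off along whole-day steps) can
leave one-day residuals that are indistinguishable on real data but
would obscure the exact-zero check. Problem sizes throughout (tens of
sites, hundreds of cells, two archive years) are chosen so the full
suite runs in minutes on one core while every property stays sharply
testable.

What passing these tests shows: the algorithms are implemented
correctly, the pipeline is internally consistent, and uncertainty
propagates with the right qualitative behavior. What it does not show:
skill on real phenology. Real observations carry reporting biases and
spatial clustering; real temperature fields have fronts, inversions and
elevation structure that a smooth sinusoid lacks; real forecast members
are not unbiased perturbations of the truth. Verification numbers from
synthetic seasons therefore say nothing about operational error
magnitudes — they certify machinery, not ecology.

## Known limitations

* Temperature is the only driver; photoperiod, precipitation and soil
  moisture are out of scope, as are two-phase chilling-sequential
  models.
* The downscaling is a monthly affine map — no piecewise tails, no
  precipitation, no bias correction beyond the affine term.
* The ensemble carries climate-member spread only; parameter and model
  uncertainty within the phenology ensemble are not propagated (the
  process models are deterministic).
* Within-season assimilation of incoming phenology observations is not
  attempted: forecasts condition on climate alone.
* Fold assignment in stacking is by observation; blocking by plant or
  site would be preferable when many observations share a plant.
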