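# phenocast

Automated, species-level forecasting of plant phenology — the dates of
budburst, flowering, fruiting and fall colors — from daily temperature
data. phenocast is aimed at ecological forecasters who want to run a
full phenology forecasting pipeline offline: fit process-based models to
status-based monitoring observations, combine them into a stacked
ensemble, downscale coarse seasonal climate forecasts to a fine grid,
produce gridded event-date forecasts with uncertainty and anomaly maps,
and verify those forecasts once the events are observed.

## The model at the core

The workhorse is the thermal-forcing family of phenology models. Daily
forcing units derived from daily mean temperature $T_i$ accumulate from
a start day $t_1$, and the event is predicted on the first day $d$ with

$$\sum_{i = t_1}^{d} f(T_i) \ge F^*$$

where, for the basic thermal-time (growing-degree-day) member,
$f(T_i) = \max(0,\, T_i - T_b)$ and $F^*$ is the forcing requirement.
Four members — thermal time, alternating (chill-relaxed requirement),
uniforc (sigmoidal forcing), and a linear regression on mean spring
temperature — are fit per species and phenophase by a seeded bounded
global search, then combined into a weighted ensemble. The weights are
learned by stacking: minimize held-out RMSE over 100-fold
cross-validation subject to $w_m \ge 0$, $\sum_m w_m = 1$, then refit
every member on the full data.

Forecast uncertainty comes from the climate, not the (deterministic)
phenology models: the ensemble is run over five downscaled climate
forecast members, and the member spread gives the forecast standard
deviation, a 95% prediction interval (point ± 1.96 sd), and an anomaly
against a latitude-corrected long-term baseline. Coarse (0.25-degree,
6-hourly) forecasts are downscaled with per-cell, per-calendar-month
asynchronous regression: sorted fine values regressed on sorted coarse
values, pairing by quantile rather than timestamp.

Everything is testable offline: seeded synthetic generators produce
temperature grids, observations, archives and forecast members with
known ground truth.

## A worked example

Fit a stacked ensemble to synthetic observations whose truth is a
thermal-time model (budburst at 300 degree-days above 5 °C), then
forecast a grid:

```r
library(phenocast)

cube  <- synth_temperature_cube(seed = 42, nlat = 8, nlon = 8, noise_sd = 1)
truth <- phenology_model("thermal_time", list(t1 = 1, T_base = 5, F_star = 300))
so    <- synth_observations(seed = 42, truth, cube, n = 40, noise_sd = 2)

ens <- fit_stacked_ensemble(
  so$observations, so$temps,
  members = c("thermal_time", "uniforc", "linear"),
  k = 100, fixed = list(thermal_time = list(t1 = 1), uniforc = list(t1 = 1)),
  seed = 1
)
tidy(ens)
#> # A tibble: 3 × 4
#>   member       family       weight oof_rmse
#>   <chr>        <chr>         <dbl>    <dbl>
#> 1 thermal_time thermal_time  0.360     2.24
#> 2 uniforc      uniforc       0.64      2.20
#> 3 linear       linear        0         2.99
glance(ens)
#> # A tibble: 1 × 4
#>   n_members k_folds stacked_oof_rmse best_member_oof_rmse
#>       <int>   <int>            <dbl>                <dbl>
#> 1         3      40             2.18                 2.20
```

With 40 observations the 100 folds degrade to leave-one-out (k = 40).
The two forcing members explain the data about equally well (out-of-fold
RMSE ≈ 2.2 d against 2 d of observation noise) and share the weight;
the linear member is priced out. The stacked out-of-fold RMSE (2.18 d)
never loses to the best single member. A latitude baseline provides the
anomaly reference:

```r
baseline <- fit_latitude_baseline(so$observations)
baseline
#> <latitude_baseline> day = -102.70 +5.589 * latitude (n = 40)
```

(≈ 5.6 days later per degree northward — the imprint of the synthetic
0.8 °C/degree latitudinal lapse). Run the ensemble over climate members
and bundle the forecast product:

```r
grids <- run_member_forecasts(list(cube, cube, cube), ens)
summ  <- summarize_members(grids)
summ$anomaly <- compute_anomaly(summ$point_estimate, baseline, cube$lats)
product <- apply_range_mask(summ, synth_range_mask(8, 8, "all"),
                            "species_a", "budburst", issue_day = 40,
                            lats = cube$lats, lons = cube$lons, ref_year = 2019)
product
#> <forecast_product> species_a / budburst, issued day 40 (2019): 8 x 8 cells, 64 in range
summary(as_tibble(product)$prediction)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>    88.0   106.5   122.0   120.4   135.2   148.0
```

Predicted budburst spans day 88 (late March, warm southern cells) to
day 148 (late May, cold northern cells). With identical members the
spread — and hence the prediction interval width — is zero;
`autoplot(product)` maps the prediction, anomaly or uncertainty layer.

The same flow is available as single-shot pipeline commands
(`cmd_synth()`, `cmd_fit()`, `cmd_build_downscaling()`,
`cmd_forecast()`, `cmd_verify()`) driven by a YAML config, with a thin
CLI in `inst/cli/phenocast.R`; `cmd_forecast()` publishes atomically, so
a failed run never corrupts previously published forecasts. See the
vignette (`vignettes/phenology-forecasting.Rmd`) for the methods.

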