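# stratodyn

Joint quantification of early-animal biodiversity dynamics and the
sedimentary rock record across the Ediacaran–Cambrian transition
(~580–510 Ma), for paleobiologists who want to ask whether apparent
diversity signals track the rock record that hosts them.

The late Ediacaran fossil record poses a specific statistical problem: most
genus ranges are calibrated only loosely within a global age framework, the
preserved rock volume varies enormously through time and between regions,
and sampling effort is concentrated on a few exceptionally preserved
surfaces. `stratodyn` implements the quantitative machinery needed to
analyse all of this jointly:

- **Monte Carlo age-uncertainty resampling.** Every fossil occurrence
  carries an uncertainty category 1–4 (1 = bracketing radiometric
  constraints, 4 = poorly constrained correlation). Category-1 records
  prescribe their full calibrated range; category 2–4 records contribute a
  single age drawn uniformly from their permitted interval, and a genus's
  realized range is the envelope of its records' contributions. Replicate
  datasets (10,000 at study scale) propagate the age uncertainty into every
  downstream statistic.
- **Moving-window diversity dynamics.** Range-through genus richness and
  Foote's per-capita origination and extinction rates from
  boundary-crosser counts,

  p = ln((N_bt + N_Ft)/N_bt)/Δt,  q = ln((N_bt + N_bL)/N_bt)/Δt,

  on 1-Ma moving windows stepped every 100 ka (the window labelled 570.5
  spans 570.9–570.0 Ma), with mean/min/max aggregation across replicates.
- **Rock-record budgeting.** Volume flux (terrane area × mean unit
  thickness, spread uniformly over each unit's duration) and marine
  depositional area / nondeposition fraction on a 50-ka grid, partitioned
  by lithofacies (siliciclastic / limestone / dolostone × shelf-to-basin
  depth classes), with leave-one-region-out sensitivity filtering.
- **Sampling intensity.** Moving counts of fossiliferous beds and
  bedding-plane surfaces, counting poorly constrained surfaces across their
  full permitted duration (maximum possible sampling intensity).
- **Correlation suite.** Spearman's ρ (average ranks, t-approximation
  p-values) between richness, rock quantities, sampling intensity, and
  carbonate δ¹³C / δ²³⁸U series, on raw and first-differenced series, with
  10-point moving-mean/moving-minimum smoothing for sparse isotope records.
- **Synthetic study system.** A generator that emulates the statistical
  structure of such compilations — four successive assemblages, mixed
  uncertainty categories, regional unit stacks with hiatuses,
  anticorrelated isotope curves — and records the generating truth, so the
  whole pipeline is testable by parameter recovery.

## Worked example

```r
library(stratodyn)

grid <- time_grid(580, 522)               # 1-Ma windows / 100-ka steps / 50-ka flux bins
cfg  <- synth_config(master_seed = 1)     # 200 genera in 4 assemblages, 8 regions
data <- synthetic_dataset(cfg, grid)

# diversity under age-uncertainty resampling, 100 replicates
div <- replicate_diversity(data$occurrences, grid,
                           n_replicates = 100, master_seed = 42)
dplyr::filter(div, label %in% c(570.5, 551.5, 524.5))
#> # A tibble: 3 x 10
#>   label richness_mean richness_min richness_max p_mean  p_min p_max q_mean q_min q_max
#>   <dbl>         <dbl>        <dbl>        <dbl>  <dbl>  <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1  570.          9.09            7           11  0.332 0      0.770  0.342 0     0.941
#> 2  552.         20.5            14           24  0.201 0      0.491  0.454 0.171 0.770
#> 3  524.         19.3            15           25  0.364 0.0823 0.770 NA    NA    NA
```

`richness_mean` is the across-replicate mean genus richness in the window
(so 20.5 genera in the 551.9–551.0 Ma window, with the replicate envelope
14–24); `p`/`q` are per-capita origination/extinction rates in 1/Ma.
Extinction is reported missing in windows younger than the 530-Ma
truncation, where last appearances cannot be constrained.

```r
# rock record and correlations
flux  <- compute_volume_flux(data$units, grid)
preds <- window_rock_predictors(flux, units = data$units,
                                region_areas = cfg$regions, grid = grid)
intens <- intensity_series(data$surfaces, grid)
correlation_report(div, preds["vol_all"], intensity = intens, cutoff = 535)
#> # A tibble: 9 x 6
#>   predictor          subset         mode                  rho  p_value     n
#>   <chr>              <chr>          <chr>               <dbl>    <dbl> <int>
#> 1 sampling_intensity all            raw               0.698   1.06e-84   572
#> 2 sampling_intensity pre (>535 Ma)  raw               0.740   8.52e-79   447
#> 3 sampling_intensity post (<535 Ma) raw               0.153   8.91e- 2   125
#> 4 vol_all            all            raw               0.00820 8.45e- 1   572
#> ...
```

Here reconstructed richness tracks sampling intensity strongly before the
535-Ma cutoff (ρ = 0.74) but not after (ρ = 0.15, p = 0.09) — the
diagnostic contrast the pipeline is built to expose. The isotope side:

```r
pr <- pair_geochem(data$geochem, "moving_mean_vs_mean", k = 10)
tidy(spearman_cor(pr$x, pr$y))
#> # A tibble: 1 x 6
#>   estimate  p.value     n method   mode  subset
#>      <dbl>    <dbl> <int> <chr>    <chr> <chr>
#> 1   -0.763 2.92e-56   289 spearman raw   all
```

recovering the generator's target anticorrelation (−0.7) between the
smoothed carbon and uranium isotope series.

Each result type has a plot: `plot_diversity()` (mean ± replicate
envelope), `plot_flux()`, `plot_area()`, `plot_intensity()`, or just
`autoplot()` on the object.

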