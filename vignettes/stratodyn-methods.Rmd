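---
title: "Methods: diversity dynamics and the rock record under age uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity dynamics and the rock record under age uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratodyn)
```

`stratodyn` quantifies Ediacaran–Cambrian biodiversity dynamics jointly
with the sedimentary rock record that hosts the fossils. This vignette is
the package's own account of the models it implements, the assumptions
behind them, the tunable parameters that matter, and the numerical
conventions — in the order the pipeline runs them.

## The time grid

All series share one grid (`time_grid()`), with two binning conventions:

- **Moving windows** for diversity, sampling and correlation series: one
  window per 0.1-Ma label step. Under the default `printed_example`
  convention the window labelled $L$ spans $(L + 0.4,\; L - 0.5)$ Ma, so
  label 570.5 covers 570.9–570.0 Ma and label 570.4 covers 570.8–569.9 Ma.
  This span is 0.9 Ma even though such windows are conventionally called
  "1-Ma moving windows"; because the labelled example is the only
  bit-exact anchor for the convention, the package follows it and exposes
  `window_convention = "symmetric_1ma"` ($L \pm 0.5$) as the alternative.
  Per-capita rates always divide by the span actually used.
- **Flux bins** of 50 ka for rock volume and area series, half-open
  $[\text{older}, \text{younger})$ so a unit boundary on a grid line
  contributes only to the older bin (no double counting).

Window edges and labels are computed in integer deci-/centi-Ma and divided
once, so printed labels are exact and no tolerance juggling is needed
downstream. Fine bins aggregate onto windows by the mean over bins whose
midpoints fall inside the window; midpoints (at ·025/·075 Ma) can never
coincide with window edges (at ·0 Ma), so no tie-break is required.

Ages are Ma before present, larger = older, and every interval is stored
as (older bound, younger bound).

## Age-uncertainty resampling

Each occurrence record carries an uncertainty category 1–4: 1 means the
hosting surface is calibrated by bracketing radiometric constraints (with
an age-depth model), 2 a carbon-isotope chemostratigraphic best fit, 3 a
biostratigraphic best fit only, 4 poorly constrained correlation. The
resampling model (`realize_ranges()`):

- a category-1 record prescribes its full calibrated range — both bounds
  enter the taxon's envelope;
- a category-2–4 record contributes a single age drawn **uniformly** from
  its permitted `(min_age, max_age)` interval. Uniformity is a choice: the
  age framework constrains only the interval, and the flat density is the
  maximum-entropy distribution on it. The draw is per occurrence, not per
  taxon, because the uncertainty belongs to the hosting surface; taxa
  sharing a surface would ideally share a draw, which the package does not
  model (records are independent).
- a taxon's realized first/last appearance is the envelope (oldest,
  youngest) of its records' contributions.

`generate_replicates()` repeats this under seeds derived from a master
seed by an explicit stream split (`sample.int` under the master seed), so
replicates are mutually independent and the whole sequence is reproducible
from one integer. The study-scale analysis uses 10,000 replicates;
package tests use 100 and the acceptance script 500, which is enough for
the mean/min/max summaries to stabilise at the grid resolution used here
(the envelope widens only logarithmically in replicate count).

Before resampling, the diversity filter (`filter_occurrences()`) removes
trace fossils, records identified only as holdfasts (they may duplicate
genera already present), taxa flagged as taxonomically doubtful, and
lagerstätte records (their exceptional preservation inflates richness
relative to the background record). Each exclusion is a separate toggle
because the sampling-intensity series deliberately uses a different set
(see below).

## Diversity metrics

Richness is range-through: a genus counts in every window its closed
realized range $[\mathrm{lad}, \mathrm{fad}]$ intersects. Closed-interval
intersection is a convention choice (the alternative half-open rule
differs only when an endpoint equals a window edge, a measure-zero event
for resampled ages); it is used consistently by richness and by the
boundary-crosser bookkeeping, with these edge rules for a window with
older edge $o$ and younger edge $y$:

- crosses the older edge iff $\mathrm{fad} \ge o$ and $\mathrm{lad} < o$;
- crosses the younger edge iff $\mathrm{lad} \le y$ and $\mathrm{fad} > y$.

The four classes ($N_{bt}$ both, $N_{bL}$ bottom only, $N_{Ft}$ top only,
$N_{FL}$ confined) partition window richness exactly — a property the
test suite checks against brute-force per-taxon enumeration. Foote's
per-capita rates follow in closed form:

$$p = \ln\!\frac{N_{bt}+N_{Ft}}{N_{bt}}\,/\,\Delta t, \qquad
  q = \ln\!\frac{N_{bt}+N_{bL}}{N_{bt}}\,/\,\Delta t,$$

per Ma. When $N_{bt}=0$ both rates are reported missing — not zero and
not an error: with no range-through taxa the per-capita denominator is
undefined, and coding it as 0 would fabricate stasis in sparse windows.

Two young-edge truncations guard against edge artefacts of a compilation
that cannot observe ranges beyond its young limit: extinction rates are
not reported in windows labelled younger than 530 Ma and richness not
younger than 522 Ma (both configurable). Origination is reported over the
full grid. Replicates aggregate element-wise to mean/min/max with
pairwise missing-value removal.

`genus_density()` divides per-window richness by a window-aggregated rock
quantity (volume or area of the hosting lithology); windows with zero or
missing rock are missing rather than infinite, and are excluded from the
unit-max normalization used for plotting overlays.

## Rock-record budgeting

A rock unit's volume is terrane area (km²) × mean thickness (m → km).
Mean rather than maximum thickness damps the bias of using maximum area
estimates. The volume spreads uniformly over the unit's age span — the
compilation assumes a continuous depositional rate, which smooths real
short-term variability — and each 50-ka bin receives the share
proportional to overlap. Three invariants pin the arithmetic down:
per-unit conservation (allocations sum to area × thickness, relative
tolerance 1e−9), bin-wise additivity of the lithofacies/region partition,
and linearity over disjoint unit sets.

Depositional area per bin is the sum of terrane areas of regions with at
least one marine nonevaporitic unit overlapping the bin; the
nondeposition fraction is its complement over total terrane area. Areas
are constant per region (a per-unit area column can override this where a
region's outcrop is well enough known to vary through time). Lithofacies
percentages normalize within the marine nonevaporitic universe;
phosphorite and diamictite are counted inside that universe by default —
they are marine precipitates/deposits, and excluding them is a one-line
`universe=` argument for users who prefer the stricter reading. Bins with
a zero denominator are missing, not 0: "no rock" carries no percentage
information.

`leave_region_out()` removes one region from every table for sensitivity
re-runs (the dominance of a single large terrane, e.g. a Siberia-like
platform, can drive global series).

## Sampling intensity

The intensity series counts fossiliferous beds/bedding-plane surfaces (or
sites/sections where surfaces are unavailable — whatever one row of the
surfaces table represents) in every window their permitted age interval
touches. For poorly constrained surfaces this is deliberately the
**maximum possible** sampling intensity across the host unit's duration.
The filter differs from the diversity filter: trace-only records are
excluded, but holdfast-only and taxonomically excluded body-fossil
records count — a surface is evidence of sampling effort regardless of
whether its fossils survive taxonomic scrutiny. First differences are not
offered for intensity: stretching surfaces across their maximum range
flattens differences onto zero and makes the transform uninformative.

## Correlation suite

Spearman's ρ is computed as the Pearson correlation of average ranks
(ties share their mean rank) after pairwise deletion of incomplete pairs,
with the two-sided p-value from the t approximation on $n-2$ degrees of
freedom — standard at the series lengths involved (10²–10³ windows) and
checked in the tests against exhaustive small-$n$ enumeration and against
`stats::cor.test`. At least 3 complete pairs are required; results carry
`n`, a mode label (raw / first-difference) and a subset label.

Because moving-window series are strongly autocorrelated, every
correlation is also run on first differences $d_i = x_{i+1} - x_i$ (old
to young, missing values propagating). Differencing removes shared trend;
no further prewhitening is applied.

Sparse isotope records are smoothed by a 10-point moving mean — and,
for the uranium series, alternatively a 10-point moving minimum, which
tracks the reducing end-member through intervals where diagenesis shifts
individual samples heavy. Smoothed series are paired by nearest smoothed
age within a 0.5-Ma gap (configurable); the gap guards against pairing
across the large sampling gaps the smoothing is meant to bridge.
Pre/post partitions at an age cutoff (default 535 Ma, the onset of the
basal-Cambrian carbon-isotope excursion) assign the element whose label
equals the cutoff to the older side, matching the ">535 Ma" reading; rock
units split Ediacaran/Cambrian at 538.8 Ma where needed. Both cutoffs are
arguments, not constants.

## The synthetic study system

`synth_config()` + `synthetic_dataset()` generate data with the
statistical structure the pipeline assumes, plus the generating truth:

- **Taxa.** Four successive assemblages (Avalon 575–559, White Sea
  560–550, Nama 550.5–538, Cambrian 535–522 Ma) with 40/60/40/60 genera.
  True ranges have uniform origins within the assemblage window and
  exponential durations (mean 3 Ma, truncated to the window) — the
  simplest range model with a realistic right skew. Lithological
  affinities follow the assemblages' character (deep-water siliciclastic
  Avalon, shallow siliciclastic White Sea, carbonate-rich Nama and
  Cambrian).
- **Records.** Each genus is represented by the two records that define
  its range endpoints, mirroring compilations that store taxonomic ranges
  rather than full occurrence lists; `records_per_taxon_extra` adds
  interior records for sensitivity runs. Categories are drawn from a
  mixture (default 0.25/0.35/0.25/0.15) with half-widths 0/0.5/1.5/3 Ma;
  a category 2–4 record reports its anchor age ± the half-width, and a
  category-1 record reports the exact range. Interior records matter for
  recovery behaviour: an interior record can only extend the realized
  envelope outward, so compilations rich in interior records bias
  resampled richness high near range ends, whereas endpoint records give
  symmetric overshoot/undershoot. Separate non-body taxa (trace,
  holdfast-only, flagged, lagerstätte) exercise the filters and sit
  outside the truth set, so "true richness" is defined over exactly the
  taxa the diversity filter retains.
- **Rock record.** Eight regions with fixed terrane areas (a scaled-down
  stand-in for the ~24 composite successions such compilations contain);
  each region's stack alternates units (exponential durations, mean 2 Ma;
  lognormal thicknesses, median 150 m; lithofacies from a weight table)
  and hiatuses (probability 0.25 per step, exponential durations).
- **Geochemistry.** A smooth latent carbon curve (sum of incommensurate
  sinusoids), an antithetic uranium curve mixed with an independent
  smooth component to hit a target rank anticorrelation (default −0.7),
  additive noise (0.4‰ / 0.04‰), irregular sample ages, and a configured
  fraction of samples carrying both isotopes.
- **Surfaces.** Cluster with the assemblages; 60% carry narrow
  (≤ 0.3 Ma) brackets, the rest 1–4-Ma brackets emulating surfaces dated
  only by their host unit.

All distributional choices are stand-ins — none is estimated from real
data — and all are configurable. What passing recovery tests show is that
the *pipeline* is faithful: true richness sits inside the 100-replicate
envelope in ≥95% of windows, and category-1-only data reproduce the truth
exactly. What they do not show is realism of the generator relative to
the actual Ediacaran–Cambrian record, whose preservational and collection
biases (lagerstätte clustering, monographic effort, correlated regional
age models) the generator deliberately does not attempt to mimic.

## Problem sizes and numerical choices

Tests run the resampling at 100 replicates on 200 genera over a 580–522-Ma
grid (572 windows, 1,160 flux bins); the acceptance script uses 500
replicates. These sizes were chosen because every summary statistic used
downstream is stable at them; the study-scale 10,000 replicates change
only the extremes of the envelope. Determinism everywhere comes from a
single master seed and explicit stream splitting — no generator shares or
reuses R's global RNG state (`withr::with_seed` restores it).

Degenerate inputs are contracts, not surprises: zero-duration units are
an error naming the unit; an all-zero series refuses unit-max
normalization; a window with no range-through taxa yields missing rates;
an empty input table yields empty, validly typed output.

## Known limitations

- Interval-valued occurrence bounds are taken as given; the package does
  not model the age framework itself (no age-depth or correlation
  modelling), and draws are independent across records even where surfaces
  share a section.
- No in-bin sampling model: gap-filler or three-timer rates and
  shareholder-quorum subsampling are out of scope because range-style
  compilations cannot support them.
- Volume flux inherits the continuous-deposition assumption and constant
  per-region areas; both smooth real variability and cap the resolution
  at which flux minima are meaningful.
- The Spearman p-values treat windows as independent observations; with
  moving windows they are not, which is precisely why the
  first-difference mode exists and why p-values on raw moving series
  should be read as descriptive.
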