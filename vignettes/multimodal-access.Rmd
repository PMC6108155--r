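---
title: "Multi-modal floating-catchment accessibility and the spatial access ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal floating-catchment accessibility and the spatial access ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmspar)
```

## The model

Floating catchment area methods measure *potential* spatial access to a
service: how much supply a resident could plausibly reach, accounting for
everyone else competing for the same supply. The enhanced two-step variant
(E2SFCA) implemented here extends the classic model in two ways: travel
impedance decays with time inside each catchment, and the population is
split by transportation mode, with each mode travelling under its own
catchment threshold and decay schedule.

**Step 1 (supply-to-demand ratio).** Each supply site $i$ with capacity
$C_i$ serves the decay-weighted population that can reach it under *any*
mode $M$:

$$R_i = \frac{C_i}{\sum_{M}\ \sum_{k:\ d_{ki,M} \le d_M} P_{k,M}\, W(d_{ki,M})}$$

where $P_{k,M}$ is the population of demand unit $k$ travelling by mode
$M$, $d_{ki,M}$ the travel time in minutes, and $d_M$ the mode's
catchment threshold (defaults: 30 min car, 60 min bus).

**Step 2 (spatial access index, SPAI).** Each demand unit $j$ sums the
ratios of the sites it can reach per mode, and across modes:

$$A_{j,M} = \sum_{i:\ d_{ji,M} \le d_M} R_i\, W(d_{ji,M}), \qquad
  A_j = \sum_M A_{j,M}.$$

**Step 3 (spatial access ratio, SPAR).** Each score family is normalized
by its unweighted study-area mean: $S_j = A_j / \bar A$. By construction
the mean SPAR is exactly 1, and $\mathrm{SD}(S) = \mathrm{CV}(A) =
\mathrm{CV}(S)$. This normalization is the package's central statistic:
it absorbs the arbitrary scale the impedance coefficient imposes on SPAI,
which is why SPAR is stable across coefficient choices while SPAI is not.

**Impedance.** The decay kernel is Gaussian, $W = e^{-d^2/\beta}$, with
$\beta$ in minutes². Weights are *stepped*: the catchment is divided into
travel-time sub-zones (car 0–10/10–20/20–30 min; bus additionally 30–60
min) and the kernel is evaluated once per sub-zone at its representative
time — by default the band midpoint (5, 15, 25, 45 min) — so all trips
in a band share one weight. `gaussian_weight()` applied to the exact time
is available via `weighting = "continuous"`, but all reference results
use the stepped form.

When no realized travel behaviour exists to calibrate $\beta$, it is
anchored by a *critical weight*: `derive_beta(d_ref, w_crit)` solves
$e^{-d_\mathrm{ref}^2/\beta} = w_\mathrm{crit}$. Anchoring the outermost
sub-zone at $w = 0.01$ gives $\beta \approx 135.7$ (car, 25 min) and
$\approx 439.7$ (bus, 45 min), rounded up to the grid minima 140 and 440.
The default sensitivity grids are 13 equally spaced values, 140–320 (car,
step 15) and 440–1040 (bus, step 50), whose Cartesian product gives the
169 coefficient combinations of the default sensitivity run.

## Numerical and design choices

* **Sub-zone intervals** are left-closed, right-open, with the *last
  interval closed*: a trip at exactly the threshold (30 or 60 min) is
  inside the catchment. Published band labels ("0–10, 10–20, 20–30") do
  not fix the convention; this one maps every in-catchment time to
  exactly one band.
* **Zero-denominator sites** (no in-catchment population in any mode) get
  $R_i = 0$: the site serves nobody and contributes nothing. This keeps
  the conservation identity well defined — the population-weighted total
  access $\sum_j \sum_M P_{j,M} A_{j,M}$ equals the summed capacity of
  sites with positive denominators, exactly; the test suite asserts it to
  relative $10^{-9}$ on random scenes.
* **Units with zero population in a mode** still receive that mode's
  SPAI (the potential access of a hypothetical traveller); they simply
  add nothing to any denominator.
* **The SPAR mean** is the unweighted arithmetic mean over all demand
  units, zeros included. An alternative would average only units with
  nonzero population in the focal mode; we do not, and the mean-SPAR = 1
  identity in the result tables reflects the unweighted convention.
* **Dispersion** uses the sample standard deviation (denominator
  $n-1$). With hundreds of units the difference from the population SD
  is negligible, but the convention is fixed for reproducibility.
* **Rounding** is internal-full-precision everywhere; the 3-decimal
  presentation columns in output files use round-half-away-from-zero
  (`round_half_away()`), matching how the reference weight table is
  printed. The published weight-range statements mix
  rounded-then-subtracted and subtracted-then-rounded arithmetic; we
  always subtract at full precision first.
* **OD symmetry**: the same entry serves step 1 ($d_{ki}$) and step 2
  ($d_{ji}$). The long CSV format (origin, destination, minutes; absent
  row = unreachable) makes sparse bus matrices natural.

## The ANOVA battery

`run_grid()` runs the pipeline over the coefficient grid;
`hypothesis_battery()` then tests, for every score family (car, bus,
integrated × SPAI, SPAR) and every focal mode, (a) whether per-unit
scores differ across the focal mode's coefficients, pooling over the
other grid, and (b) within each fixed focal coefficient, whether they
differ across the other mode's grid. The twelve tests conventional in
this literature are tagged with hypothesis ids 7–18; the battery also
emits the symmetric combinations (id `NA`) because the pooling choice is
genuinely ambiguous in the source literature — per-unit observations
pooled over the non-focal grid is our recorded convention, and both $F$
and $p$ are returned so alternatives can be compared.

Two analytic facts anchor the battery. First, because every cell's SPAR
mean is exactly 1, the between-group variance of SPAR group means is
zero to machine precision: every SPAR hypothesis returns $F \le 10^{-10}$
and $p = 1$ *on any scene whatsoever*. Second, SPAI has no such
protection, and on scenes with realistic structure its ANOVA across
coefficients is strongly significant. The degenerate case of identical
groups is defined as $F = 0$, $p = 1$, never NaN.

## What the synthetic generator emulates — and what it does not

`generate_scene()` produces the inputs the model consumes: supply sites
with Poisson capacities (mean 4, floored at 1), demand units with
Poisson populations (mean 1600) split into car/bus subpopulations by the
local vehicle-ownership probability, and per-mode OD minutes. Its
defaults state a specific world, chosen once:

* 293 sites / 543 units on a 60 km square — the scale of a mid-size
  metropolitan case study;
* supply 95 % clustered in an 8 km core: provider addresses concentrate
  in central corridors;
* bus service only within 10 km of the center, bus time =
  10 min overhead + distance at 18 km/h, car at 60 km/h with small
  lognormal noise (SD 0.08 on the log scale) — so car strictly beats
  bus on every pair where both exist;
* vehicle ownership 0.75 in the core vs 0.97 in the periphery: the
  carless (bus-riding) population concentrates where transit exists;
* 45 % of demand units in the core, the rest uniform — with the bus
  radius this leaves ~52 % of units with *no* bus-reachable site within
  60 min, echoing the reference study's context (55 % of units beyond
  30 bus-minutes of the nearest provider).

The supply concentration and the ownership gradient are not cosmetic.
With spatially uniform ownership and uniform unit density, step 1 forces
the unweighted mean car SPAI to be non-*decreasing* in $\beta_{car}$
(the bus term in each denominator is fixed while the car numerator
grows). The empirically observed *decrease* of mean car SPAI with
$\beta_{car}$ requires centrally concentrated supply whose outer
sub-zones are populated by car-rich periphery — exactly the structure
above. The directional checks are asserted at the anchored grid minima
(car direction at fixed $\beta_{bus} = 440$, bus direction at fixed
$\beta_{car} = 140$); pooled over the other grid the car direction is
not monotone, and nothing in the model says it should be.

What the generator does **not** emulate: road networks and congestion
(times are planar), transit schedules and their temporal variation,
population-weighted centroid placement, and spatially autocorrelated
population sizes. A green test on synthetic scenes therefore establishes
the *algebraic and structural* behaviour of the method — conservation,
normalization, sensitivity contrasts, directionality — not the printed
access values of any real study area, which depend on proprietary travel
-time matrices.

## Worked example

```{r}
sc <- generate_scene(scene_spec(n_supply = 40, n_demand = 80, seed = 1))
res <- run_access(sc, default_modes())
res
head(res$scores[, c("id", "spai_car", "spai_bus", "spar_integrated")], 3)
mean(res$scores$spar_integrated)  # 1 by construction
```

```{r}
sens <- run_grid(sc, default_modes(),
                 grids = list(car = build_grid(140, 320, 5),
                              bus = build_grid(440, 1040, 5)))
bat <- hypothesis_battery(sens)
subset(bat, !is.na(hypothesis) & is.na(fixed_beta),
       select = c(hypothesis, family, F, p))
```

## Known limitations

* Travel-time estimation is out of scope: the package consumes OD
  minutes and is agnostic about how they were produced.
* Coordinates, when present, are planar kilometers in an unspecified
  local frame; there is no CRS handling, and the GeoJSON export labels
  itself non-geographic.
* The battery applies no multiple-testing correction, by design.
* Catchment thresholds and sub-zone boundaries are user choices; results
  at a threshold boundary depend on the closed-last-interval convention
  noted above.
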