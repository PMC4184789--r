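---
title: "Methods: otolith d18O isoscapes, stock simulation and vital-effect testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: otolith d18O isoscapes, stock simulation and vital-effect testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Otolith aragonite records ambient conditions through two linear relations
and one thermodynamic one.

**Water composition.** Seawater δ¹⁸O mixes conservatively with salinity:
δ¹⁸O~w~ (VSMOW) = γ·S + δ₀. Two relations ship in the registry:
`northsea-mixing` (γ = 0.29 ‰ per salinity unit, δ₀ = −9.85 ‰, a
basin-scale regression type for the North Sea) and `natl-mixing`
(γ = 0.55, δ₀ = −18.98, the published open-ocean North Atlantic regional
fit). The slope is the quantity that matters for temperature-proxy error
propagation; the intercept sets absolute water values (≈ +0.30 ‰ VSMOW at
S = 35, typical of North Sea bottom water).

**Scale conversion.** Water values are converted from the VSMOW to the
VPDB scale with the standard affine map δ~VPDB~ = 0.97002·δ~VSMOW~ − 29.98
before entering the fractionation relation. This replicates the published
processing order of the analysis this package re-implements, even though
the fractionation relation was originally calibrated with water on VSMOW.
We keep that order deliberately: it is internally consistent (predictions
and inversions use the same convention throughout), and the package's
sensitivity operations reproduce the published error-propagation figures
under it. The `delta_value` class makes the scale explicit everywhere so
the two conventions cannot be silently mixed.

**Fractionation.** Temperature dependence follows
1000·ln α = a·10³/T + b with α = (1000 + δ~o~)/(1000 + δ~w~), T in Kelvin.
The registry ships `kim-aragonite` (a = 17.88, b = −31.14; laboratory
inorganic aragonite) and `geffen-plaice` (a = 16.75, b = −27.09). The
plaice entry is a documented *stand-in*: the exact coefficients of the
juvenile-plaice rearing study could not be verified offline, so a
published biogenic-aragonite relation of the same form and qualitative
behaviour (shallower temperature dependence, slightly heavier predictions
at warm temperatures) is used under the registry name. No quantitative
result in the test suite or the acceptance report depends on it.

Temperatures are carried internally in Kelvin; user-facing interfaces use
°C (+273.15). Inversion for temperature uses the closed-form rearrangement
T = a·10³ / (1000·ln α − b), with a bisection fallback for degenerate
coefficient sets; the round trip is tested to 10⁻⁶ K.

## From fields to stock signatures

**Isoscapes.** `compute_d18O_field()` composes the chain element-wise over
a half-open, south-west-anchored 0.5° grid (cells identified by row/col
from the origin). Multiple years are pooled by averaging predicted deltas
per cell × month; averaging is done in δ-space, not ratio space, because
at per-mil magnitudes the difference is far below measurement error.
Missing cells inside a requested set are an error, never imputed.

**Occupancy.** "Cells containing 80 % of geolocations" is operationalised
as a greedy count-ranked prefix: per stock and month, rank cells by
geolocation count (ties by ascending cell id) and keep the shortest prefix
whose cumulative share reaches the fraction. The construction is
deterministic, order-independent, and nested in the fraction (f₁ < f₂
implies occupancy(f₁) ⊆ occupancy(f₂)). Years are pooled by default,
matching the pooling decision the original analysis made after finding
inter-annual stability; a per-year mode exists.

**Random walk.** Annual paths are January–December cell sequences. The
January cell is uniform on the January occupancy set; each later month is
uniform on (adjacency neighbourhood of the current cell) ∩ (next month's
occupancy set). Two deliberately-exposed ambiguities:

* *Adjacency* defaults to the 8-neighbourhood **including staying put**
  ("moving to any adjacent cell" at monthly resolution does not exclude
  zero net displacement); 4-neighbour and no-stay are options.
* *Stranding*: when the intersection is empty the walker relocates to the
  nearest next-month cell by Chebyshev grid distance (ties by cell id),
  deterministically, with a per-path relocation counter in the output.
  This guarantees complete 12-month paths, which the ensemble sizes of the
  original design imply; a resample policy is available. When monthly
  centroids move faster than one cell per month, relocations are routine
  and the counter is the honest record of that.

One master seed drives a per-stock derived stream (a stable hash of the
stock label), so any stock's ensemble can be regenerated independently and
identically.

**Growth weighting.** Annual signatures are normalised weighted means of
the 12 monthly values. OG1 = all months 1.0; OG2 = Apr–Sep 1.0, Oct–Mar
0.67; OG3 = Apr–Sep 1.0, Oct–Dec 0.83, Jan–Mar 0.50. Both OG2 and OG3
give the April–September opaque zone ≈ 60 % of annual weight, and OG3's
breeding-month weight is the hyaline rate reduced by 40 %
(0.83 × 0.60 ≈ 0.50) — arithmetic the tests assert. The aggregation
window is the calendar year matching the scenario labels; weights are
relative deposition rates, absolute growth is never modelled.

## Assignment

The discriminant is univariate (annual δ¹⁸O is the only feature, as in the
source analysis): Gaussian classes with a pooled within-class variance and
equal priors by default, under which decision boundaries are exactly the
midpoints of adjacent class means. Leave-one-out accuracy is computed
exactly in O(n) by downdating the held-out class mean and the pooled sum
of squares, not by n refits. Posterior scores sum to one; exact ties break
to the lower class index. The test suite checks the classifier against an
independent numeric-integration Bayes-rate oracle on three Gaussian
classes parameterised by the published stock means and SDs
(2.58/0.23, 1.10/0.17, 1.66/0.16 ‰): LOO accuracy must sit within ±0.5
points of that oracle at n = 10,000 per class. Note the source analysis
reports 96.70 % for 27 measured values with a single misclassification;
26/27 = 96.30 %, and this package reports exact fractions — the
discrepancy is flagged here rather than reproduced.

## Individual profile comparison

Daily otolith δ¹⁸O is predicted from daily mean tag temperature (10-minute
records are collapsed to daily means first) and the salinity at the daily
interpolated position, then averaged by calendar month (months with fewer
than 15 contributing days are flagged partial). Track interpolation is
planar piece-wise linear in latitude/longitude — at North Sea scales the
great-circle correction is negligible against 0.5° cells.

**Alignment.** "Inflection points" are implemented as interior local
extrema — the winter maxima and summer minima that seasonal δ¹⁸O profiles
visibly share — rather than second-derivative zeroes, matching how
interactive tuning software is actually used on such records. Extrema are
paired in order when counts and types agree; otherwise an order-preserving
dynamic-programming match on extremum values (skips permitted, penalised
by the series variance) picks the anchors and the fallback is logged. The
warp is piece-wise linear and strictly monotone, with the first and last
spots anchored to the predicted window endpoints; anchors violating
monotonicity are dropped. Spot dating between anchors is linear in
distance (the open question of how the original tuning interpolated is
resolved the simplest defensible way).

**Offsets.** Per fish, the measured profile's extreme values (single
extreme spot by default; a k-extreme-spot mean is an option) are compared
with the predicted monthly extremes over the same window. Group summaries
are mean ± SE with a one-sided paired Wilcoxon signed-rank test whose
direction is fixed by the group-mean sign (exact distribution for ≤ 25
pairs). Two statistical honesty notes:

* With only 4 pairs the exact one-sided test cannot reach p < 0.05
  (minimum p = 1/16), so significance at the source design's group size is
  unattainable by construction; the tests therefore assert direction and
  magnitude, not stars, at n = 4.
* Selecting the extreme of a noisy profile biases the minimum offset down
  and the maximum offset up by the same amount. The two cancel in the
  combined (min + max) mean, which is what the recovery and unbiasedness
  properties check; the per-extreme rows remain available and their
  selection bias is inherent to extreme-value comparison, not a bug.

## The synthetic world

The generator states one world and the tests live in it:

* Grid 49.5–58° N × 0–8° E at 0.5° (the study core plus the English
  Channel strip the named regions need).
* Bottom temperature: winter minimum 6.5 °C everywhere; summer maximum
  16.5 °C south of 54.5° N ramping to 9.5 °C north of 56° N (a
  stratification front — mixed shallow south, cold stratified north),
  seasonal sinusoid peaking mid-August/September, field noise SD 0.15 °C,
  no systematic year effect. This keeps the northern sector below 12 °C in
  every month while southern stocks cycle over ≈ 6.5–16.5 °C.
* Salinity: 35.0 west of 4° E, freshening 0.45 per degree eastward (the
  fresher, more variable eastern sector; noise SD 0.05 west / 0.25 east).
* Three stocks with disjoint summer centroids (north, east, west)
  converging on overlapping southern winter grounds; geolocation scatter
  0.8°; fortnightly track anchors; record lengths 97–512 days.
* Noise at instrument precision: tag 0.2 °C (white — sensor noise, not
  environmental autocorrelation), annual δ¹⁸O 0.07 ‰, spot δ¹⁸O 0.20 ‰.
* Vital effects: constant per-stock offsets or piecewise-by-temperature
  offsets (thresholds 9 and 14 °C, emulating a thermal-window
  interpretation); defaults give the northern stock a constant positive
  offset and the southern stocks negative offsets at thermal extremes.
* Measured otolith values are manufactured by the package's own prediction
  chain plus offsets plus noise, so with offsets and noise at zero,
  measurement equals prediction exactly — the closure the tests assert.

What the world does **not** emulate: real circulation, stratification
dynamics or river plumes; density-dependent or directional movement;
temperature-dependent growth feedback; sub-monthly growth structure.
A green test therefore establishes that the pipeline's logic and
statistics behave as specified under the stated structure — not that the
generator is an ocean model.

## Numerical choices

* Scale conversion is affine and exactly invertible; round trips are
  tested to 10⁻⁹ ‰.
* Temperature inversion: closed form, bisection fallback bracketed at
  150–500 K, tolerance 10⁻⁹; round trip asserted to 10⁻⁶ K.
* Occupancy ties, stranding relocation ties and posterior ties all break
  by ascending index — every tie in the package is deterministic.
* Ages use a 365-day year (reporting precision is 0.1 year; leap days are
  below it), anchored to a notional 1 February birthday.
* Pressure–depth: 1 m = 1.46 psi, linear, origin-preserving.
* The weight-share and bias figures quoted anywhere in the documentation
  are computed by the test suite or acceptance script at run time, never
  asserted as constants of the implementation.

## Interfaces and scope

All tabular I/O is comma-separated UTF-8 with header rows and ISO-8601
dates; configuration, manifests and summaries are JSON. The command-line
front end exposes `generate`, `all` and `report`; finer-grained
stage subcommands were deliberately folded into `all` because every stage
runs in seconds on synthetic data and the stage outputs written by `all`
(ensembles, assignment, offsets, summary) are themselves re-loadable.

Known limitations: the discriminant is univariate by design; carbon
isotopes and pH effects on water δ¹⁸O are out of scope; the geolocation
algorithm itself (tidal matching) is not implemented — tracks enter as
data; and the `geffen-plaice` coefficients are a stand-in as described
above.
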