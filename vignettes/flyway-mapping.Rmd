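---
title: "Mapping migratory flyways with dynamic Brownian bridge movement models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping migratory flyways with dynamic Brownian bridge movement models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywayr)
```

## The model and its assumptions

A utilization distribution (UD) is a probability density over space giving
an animal's relative frequency of occurrence. Kernel estimators ignore the
order and timing of telemetry fixes and perform poorly for actively
migrating birds; the Brownian bridge movement model instead conditions on
consecutive fixes and asks where the animal plausibly was *in between*.
Between fixes $z_a$ (time $t_a$, location-error SD $\delta_a$) and $z_b$
($t_b$, $\delta_b$), position at relative time $\alpha$ is bivariate
normal with mean $z_a + \alpha (z_b - z_a)$ and per-axis variance

$$ s(\alpha) \;=\; T\,\alpha(1-\alpha)\,\sigma^2_m
   \;+\; (1-\alpha)^2 \delta_a^2 \;+\; \alpha^2 \delta_b^2 ,
   \qquad T = t_b - t_a . $$

The assumptions are: isotropic Gaussian location error with known
per-class SD; conditionally Brownian (undirected, memoryless) motion
between fixes; and a mobility parameter $\sigma^2_m$ (m²/s) that is
piecewise constant along the track. The *dynamic* model lets
$\sigma^2_m$ switch at behavioral breakpoints, which is what
distinguishes fast, directional flight from slow, tortuous stopover
behavior — the property the flyway maps rely on to separate corridors
from stopover sites.

### Variance estimation

`estimate_variances()` slides a window of `window_size` fixes one fix at a
time. Within a window, every even-indexed fix is treated as an independent
observation of the bridge pinned at its odd-indexed neighbors, and the
likelihood is maximized over $\sigma^2_m$ by a Brent-type bounded search
on $\log \sigma^2$ (relative tolerance $10^{-6}$, bounds
$[10^{-4}, 10^{4}]$ m²/s). A two-variance alternative is fitted at every
breakpoint outside the two margins, and
$\mathrm{BIC} = -2\log L + k \log n_{\text{int}}$ decides between them,
with $k = 1$ or $k = 2$. Two choices here were genuinely open and are
worth recording:

* **The breakpoint is not counted as a free parameter** ($k = 2$, not 3).
  The comparison is deliberately the one-versus-two-variance contrast; the
  breakpoint index is a discrete nuisance selected by profile likelihood.
  Counting it would penalize switching more heavily and is available by
  editing the BIC line, but the two-parameter form matches the intended
  contrast and recovers simulated switches reliably (≥ 90 % of windows
  straddling a true mid-track variance switch select the split model, with
  the breakpoint localized within one margin).
* **Per-segment combination across windows is an unweighted mean** over
  all windows that cover the segment outside their margins. Weighting
  schemes (e.g., by window centrality) were considered and rejected for
  transparency; the averaging already smooths single-window noise.

Defaults `window_size = 31`, `margin = 11` correspond to roughly six days
of GPS data or four weeks of Argos data at typical waterfowl duty cycles.
Larger windows stabilize $\sigma^2_m$ but blur short behavioral episodes;
larger margins sharpen breakpoint detection but cannot place breakpoints
near window edges. Events shorter than one window get a single event-wide
MLE rather than being discarded — short Argos events are data, not noise.
Margins require at least three locations because the bridge likelihood
needs a pinned-pinned-observed triple.

### Rasterization

`compute_ud()` integrates each segment's bridge density over $\alpha$ and
accumulates *exact per-cell Gaussian mass* — products of one-dimensional
interval probabilities — rather than density-at-center × area. This
matters whenever the local SD (error-dominated near fix times) is smaller
than a cell. The $\alpha$ quadrature is a midpoint rule on an adaptive
grid: the step is capped so the bridge mean never advances more than half
the local kernel SD (nor an eighth of a cell side) per step, with
`alpha_steps` (default 25) as the coarse baseline; without this, closely
spaced evaluation points leave visible "beading" along fast segments on
fine grids. Each Gaussian slice is truncated at `truncation_radius` (4)
local SDs; the lost tail mass is restored by the final renormalization to
total mass 1. Segments are weighted by their elapsed time, so the UD is
time-averaged occupancy. If more than $10^{-4}$ of pre-normalization mass
touches the grid boundary the function stops and asks for more padding
instead of silently clipping.

A Monte-Carlo oracle (10⁶ draws of $(\alpha, z)$, binned on the grid)
agrees with the rasterizer cell-by-cell at the 3-standard-error level,
allowing only the binomial chance rate of excursions — a strict all-cells
3 SE bound is statistically unattainable over thousands of cells, so the
test admits at most the ~0.27 % expected excursion rate (and 6 SE
absolutely).

## Grid, projection and formats

The paper-level convention "10 km² grid resolution" is read as cell
*area*, giving a square side of $\sqrt{10}$ km ≈ 3162.3 m; the
alternative 10-km-side reading is available via `cell_side_km`. All UDs
of one analysis share a single `grid_spec` — aggregation and %VI are
cell-wise operations and silently misalign otherwise, so grid equality is
enforced bitwise. Coordinates are projected with a spherical Lambert
azimuthal equal-area projection centered on the data centroid: equal-area
is required so that cell mass keeps its areal meaning, and the centered
azimuthal form keeps distortion below 1.5 % over 3000-km tracks (checked
against geodesic distances). Cells follow a half-open convention — a
point on a shared edge belongs to the larger-index cell — so binning is
deterministic. Rasters export as ESRI ASCII grids and contours as WGS84
GeoJSON; both are plain text.

## Preprocessing rules

* **Hourly best-fix retention** keeps the best location class per clock
  hour (quality order `G > 3 > 2 > 1 > 0 > A > B > Z`, ties to the earlier
  fix) and floors the timestamp to the hour. This is designed for
  Argos-style duty cycles (~22 h gaps), where the sub-hour timestamp
  carries little information relative to kilometre-scale errors. For
  sub-hourly GPS sampling the truncation moves timestamps by a large
  fraction of the gap and inflates apparent speeds — validation runs on
  dense simulated GPS therefore skip thinning, and users with rapid GPS
  schedules should too.
* **Error assignment** fills one isotropic SD per fix: 23.5 m for GPS,
  450 m for Argos class 3 up to 7920 m for class B. The intermediate
  class values (630 / 1190 / 2580 / 5070 m for classes 2 / 1 / 0 / A) are
  package defaults interpolating the published endpoints, not published
  estimates; they are user-overridable and clearly labeled as such.
* **Speed plausibility filtering** removes class-Z (rejected) fixes
  unconditionally, then greedily removes whichever fix most reduces the
  maximum implied geodesic speed until all speeds are ≤ `vmax_kmh`
  (default 120 km/h, a sustained-flight ceiling for waterfowl). This is a
  deliberately simple stand-in for more elaborate published Argos
  filters, which are external software; no fidelity to them is claimed.
* **Event segmentation** is a heuristic operationalization of criteria
  (geography, movement scale, arrival/departure dates) that do not come
  with an algorithm. Stationary seasonal ranges are maximal fix runs
  staying within `stationary_radius_km` (50) of their running centroid
  for ≥ `dwell_days` (21; stopovers of a few days must *not* register as
  seasonal ranges, hence a multi-week threshold). Events are the fixes
  between departure and arrival; an event is *complete* only when the
  flanking ranges are distinct areas (centroid separation
  > 2 × radius) — loops back to the origin do not count. A middle range
  dwelling under `molt_max_days` (45) *and* lying close to the preceding
  seasonal range (under a third of the span between its neighbors) is
  tagged a molt/staging cluster: travel to and from it stays in the
  event, its interior fixes are excluded. Season labels use poleward
  displacement (arrival poleward of departure ⇒ spring). When more than
  two seasonal ranges exist the labeling is exposed (`range_id`, `stage`)
  for per-animal override rather than guessed. Durations are fractional
  days floored at 0.01 d so sub-day migration events keep positive
  weight; durations from under a day to several months are exercised in
  the tests.

## Aggregation and contours

`aggregate_uds()` multiplies each child UD by its weight in days, sums,
and re-scales to 1; the result is invariant to common weight rescaling.
The hierarchy weights are: event duration (event → individual), the
bird's total migration days (individual → population), and the child's
*mean* migration-event duration (population → species and species →
multi-species). Seasons are pooled — spring and fall events of one bird
feed the same route. Population membership is an explicit input table
(marking-site proximity in the motivating analyses), never inferred.

Contours are standard UD volume contours: cells sorted by mass
descending (ties broken by row-major index), shortest prefix reaching the
nominal cumulative mass, so the 50/75/99 % regions are nested by
construction. Polygonization is exact boundary-edge tracing of the cell
union on the analysis lattice (interior on the left; holes preserved with
opposite orientation) — no smoothing or resampling, so polygon area equals
cell count × cell area identically. The three-way zone reading follows
waterfowl practice: ≤ 50 % stopover sites, 50–75 % core movement areas,
75–99 % flight corridors.

## Sensitivity analysis

%VI is the volume of intersection, $100 \sum_{\text{cells}} \min(p, q)$
— the standard UD overlap index; Bhattacharyya's affinity was the
considered alternative and was not used because "percent volume of
intersection" names this statistic in the home-range literature. Raw
(not contour-truncated) UDs enter the overlap. For each
$k = 1, 4, 7, \dots$ (step 3, with $k = n$ appended when the grid does
not land on it, because the full sample is the single reference
combination), up to 100 distinct combinations are drawn uniformly without
replacement — exhaustively when $\binom{n}{k} \le 100$ — aggregated with
duration weights, and compared with the full flyway UD. LOESS
(span 0.75, degree 2 — conventional defaults, configurable) smooths the
means; `asymptote_check()` calls the curve `ASYMPTOTIC` when the last
three smoothed increments are each under 2 percentage points, else
`INCREASING`, and reports the final slope for comparing cohorts. Fixing
`rng_seed` reproduces a curve bit-identically.

## The synthetic cohort generator

`simulate_cohort()` emulates the features of multi-species Asian
waterfowl telemetry that the pipeline must survive: alternating
stationary dwells (winter, stopovers, breeding, optional molt cluster)
and directed flight along per-population corridors with per-individual
lateral waypoint jitter; Argos class-dependent error (hundreds of meters
to ~8 km, plus rejected class-Z fixes) versus 23.5-m GPS error; irregular
gamma-distributed sampling targeting mean gaps of 4.5 h (GPS) and 22.4 h
(Argos); and shared corridors with individual variation. Movement is
built as piecewise processes — mean-reverting jitter of intensity
`stopover_sigma2` (2 m²/s) in dwells, constant-speed corridor following
(60 km/h) plus a Brownian-bridge perturbation of intensity
`flight_sigma2` (200 m²/s) in flight — rather than one switching SDE,
because exact regime labels and true variances are the point: every fix
carries ground truth. Fix instants are inserted into the simulation grid
so truth is evaluated exactly at observation times. All randomness flows
from one master seed through fixed per-individual substreams, so cohorts
are reproducible and individuals independent.

What the simulator does *not* emulate — habitat selection, wind, diel
structure, Argos error anisotropy, tag failure — bounds what passing
tests show: they validate the estimator and aggregation machinery under
the stated model, not performance on any particular real dataset. One
honest artifact deserves note: simulated flight alternates constant-speed
legs with abrupt stops, so bridges spanning a junction have large
interpolation residuals and the estimated $\sigma^2_m$ near transitions
exceeds the configured flight value (occasionally saturating the upper
search bound). Real birds decelerate smoothly; the effect widens
corridors slightly near stopovers but never reverses the flight-versus-
stopover ordering, which is the property the maps depend on (recovered
for 100 % of simulated individuals at the default 100× contrast).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately compact
conditions chosen as representative: cohorts of 2–20 birds (31 for the
single-population structural check, mirroring the largest motivating
population sample), 201-fix tracks with 50 replicates for variance
recovery, 10⁶-draw Monte-Carlo oracles, and coarse (10–20 km) cells for
multi-bird pipelines. Degenerate inputs are handled explicitly: tracks
with all-identical coordinates pin $\sigma^2_m$ to the lower bound with a
warning; events with fewer fixes than a window fall back to one global
variance with a message; empty-after-filtering tracks warn; zero-mass or
boundary-touching rasters abort with instructions rather than renormalize
silently.

## Known limitations

* The speed filter is not the published Argos "hybrid" filter; heavily
  corrupted Argos tracks may retain different fix subsets than the
  original workflows would.
* Winter-versus-breeding labeling assumes poleward breeding; Southern
  Hemisphere or longitudinal migrations need the exposed per-animal
  override.
* $\sigma^2_m$ carries no uncertainty interval; window-to-window spread
  in `$windows` is diagnostic only.
* Contours are lattice polygons; cartographic smoothing is out of scope.
* Hourly truncation is inappropriate for sub-hourly GPS schedules (see
  above).
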