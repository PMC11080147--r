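---
title: "Methods: demersal HMM geolocation and movement analytics in shelftrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demersal HMM geolocation and movement analytics in shelftrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`shelftrack` reconstructs and analyses the movements of demersal coastal
fish tracked simultaneously with pop-up satellite archival tags (PSATs)
and passive acoustic telemetry. This vignette is the package's account of
the models it implements, the constants it assumes, and the design
decisions taken where the methodology left genuine choices open.

## 1. The geolocation model

### State space and movement kernels

The fish's daily position is a latent cell on a regular lon/lat grid
(cell-centre registered, default 0.03°, WGS84 degrees; all depths are
metres positive down and all timestamps UTC). The hidden state is the
pair (cell, behaviour) with two behaviours, *resident* and *migratory*.
Behaviour switches with a fixed symmetric matrix (stay probability 0.9 by
default). This matrix is not estimated: with one observation surface per
day and strong spatial autocorrelation there is little information to
estimate it from, and the smoothed posterior is insensitive to moderate
changes; it is exposed as `state_stay` in `forwardBackward()`.

The spatial transition is convolution with a behaviour-specific kernel: a
discretised 2-D Gaussian truncated at a hard radius equal to the
migratory swimming speed times one day (2 m s⁻¹ × 86 400 s = 172.8 km),
with sd half the radius, normalised to sum 1. The "speed" is read as a
hard daily bound with most mass well inside it; the resident kernel is
the same shape scaled by `resident_fraction` (default 0.1, i.e. a
17.3 km daily bound). Cell dimensions in km are evaluated at the grid's
central latitude; over a 2° domain the induced anisotropy error is well
under a cell.

One convention had to be fixed: which kernel governs a day on which the
behaviour switches. `shelftrack` uses the resident kernel only for
resident→resident moves and the migratory kernel for every move involving
the migratory behaviour (a switching day is a moving day). Besides being
behaviourally sensible, this makes the joint transition operator exactly
symmetric, which gives the smoother an exact time-reversal property (the
test suite checks that reversing the stack reverses the posterior
sequence to 1e-9).

Convolution is computed by FFT with zero padding; negative round-off
values are clamped to zero. Mass convolved beyond the grid edge or onto
land is simply lost and the joint posterior renormalised each day — the
standard treatment in gridded geolocation. A consequence worth knowing:
with completely uninformative likelihoods the smoothed marginals are not
exactly uniform near the boundary (the renormalised chain behaves like a
bridge conditioned to stay in the domain). The flat-likelihood sanity
test therefore uses a kernel whose support covers the whole grid, for
which uniformity is exact.

### Observation likelihood layers

Each deployment day carries a named set of non-negative weight surfaces,
all land-masked and rescaled to max 1 (the posterior is invariant to
per-day scale; a scale-invariance test asserts this):

* **L, light longitude** — Gaussian density in longitude at the tag's
  estimate with its reported sd, constant across latitude. Estimates
  more than 3 sd outside the grid are dropped with a warning.
* **S, SST** — integrated Gaussian: Φ((max+τ−f)/τ) − Φ((min−τ−f)/τ) of
  the day's tag SST range [min, max] against field value f, with
  tolerance τ = 0.5 °C by default.
* **H, depth–temperature profile** — product over profile levels of the
  same integrated-Gaussian form (per-level sd 1 °C default), computed in
  log space and renormalised; profiles deeper than the field's deepest
  level are truncated with a warning. The source methodology gives no
  error sds for these layers; 0.5 °C (SST) and 1 °C (profile) are
  package defaults chosen to bracket typical satellite-product and
  ocean-model errors, and are configurable.
* **O, ocean heat content** — OHC(x) = ρ c_p Σ (T − T_iso) Δz over
  levels warmer than the reference isotherm (ρ = 1025 kg m⁻³,
  c_p = 3993 J kg⁻¹ K⁻¹), with layer thicknesses from consecutive level
  midpoints; the weight is a Gaussian likelihood of tag OHC against field
  OHC with sd a fraction (default 0.1) of the field OHC range.
* **B, two-sided bathymetry** — the demersal assumption: the fish
  touches the seafloor at least once a day, so with a daily
  maximum-depth record only cells whose seafloor is within ±10 m of it
  are admissible (binary layer). Without depth data the layer admits
  water shallower than a conservative 300 m cap. If the two-sided band
  is empty (depth deeper than any seafloor on the grid) the layer falls
  back to the one-sided rule (seafloor ≥ depth − band) with a warning
  rather than silently discarding the day.
* **K, known locations** — Gaussian bumps at tagging/pop-up positions
  (sd one grid cell) and at acoustic centre-of-activity positions
  (sd max(one cell, 800 m detection range)). A known-location day
  *masks* the other layers to the smallest top-weight region holding
  99% of the K mass, then multiplies: archival data may refine the
  position within the acoustically-constrained region but cannot
  override it. Masking rather than plain multiplication is a deliberate
  choice — a conflicting archival layer otherwise drags the posterior
  away from a day on which the fish was demonstrably at a receiver.
  Positions on land snap to the nearest water cell with a warning.
  Tags that surface but transmit late get a pop-up drift buffer: a
  binary disk of radius gap × 20 km day⁻¹ around the first transmitted
  position.

Days with no usable stream carry the uniform water surface. If a day's
combined product is identically zero (mutually exclusive layers), it is
replaced by uniform water and flagged on the returned track.

### Smoothing, model selection, point estimates

The forward–backward recursions are standard; the model log-likelihood is
the sum of log forward normalisers. Candidate layer combinations — all
subsets of the observed sources that include B, with K always retained —
are ranked by AIC = 2k − 2 log L with k = number of sources + 1
(the state-switch parameter). The "+1" convention is a documented choice:
the layers themselves carry no fitted parameters, so k counts the model's
structural dimensions. Ties go to the smaller model.

Daily positions are the posterior-mean lon/lat (states marginalised).
Posterior means of multimodal surfaces can fall between modes — on land
or on the wrong isobath — which motivates the snapping stage:

* **Depth snapping** moves any position whose seafloor is outside the
  ±10 m band of the day's maximum depth to the nearest (great-circle)
  admissible water cell; days without depth data snap only off land or
  off seafloor beyond the 300 m cap. Exact distance ties break to the
  lowest cell index (column-major), making the correction deterministic
  and idempotent.
* **Least-cost distances** are measured on a 16-neighbour (rook,
  diagonal, knight) graph over water cells with great-circle edge
  weights. Unobstructed pairs short-circuit to the exact great-circle
  distance; obstructed pairs use Dijkstra (via igraph). On this
  anisotropic lattice the grid metric overestimates the geodesic by up
  to ~4%; note also that knight-move edges can step across a
  single-cell-wide land spit (two-cell barriers are impassable).
  Interpolated intermediate positions are inserted along the in-water
  polyline, linearly in time by cumulative path length, and the minimum
  travelled distance is the sum of segment path lengths.

## 2. Acoustic analytics

Detections occurring isolated in periods under 24 h are discarded; the
filter retains a detection iff a companion detection of the *same*
individual exists within ±24 h at *any* receiver (the companion-receiver
question is ambiguous in the field; any-receiver is the weaker and safer
reading, and the boundary case of exactly 24 h counts as within). The
residency index is I_R = D_D / T_P with D_D the count of distinct UTC
calendar days with a detection and T_P the *inclusive* day span from
release to last detection. Two day-count conventions deliberately
coexist — the inclusive acoustic span (`spanDaysInclusive()`) and the
exclusive PSAT deployment duration (`durationDaysExclusive()`) — because
published cohort tables use both; each is exposed and named.

Bins are aligned to UTC clock hours. Diel phases use the NOAA
solar-position formulas with the refraction-corrected zenith of 90.833°,
valid for |lat| < 66°; the suite cross-checks sunrise/sunset against an
independent ephemeris implementation to ±2 min. Days are UTC calendar
days throughout; in a study region within UTC±1 the day-boundary drift
this induces is accepted. The spawning season is the contiguous month
set March–August (configurable).

A co-occurrence event is one (receiver, bin) pair with ≥2 distinct tags,
labelled by the diel phase of the bin midpoint; group size is the
distinct-tag count. The event unit is the receiver-bin, not the tag
pair, and consecutive bins of one encounter count as separate events —
both documented conventions.

## 3. Behavioural segmentation

Daily steps (great-circle km) and turning angles (signed bearing change,
wrapped to (−π, π], spherical bearings on the same 6371-km sphere as all
distances) are discretised: step bins by within-individual quantiles
(default 5), angle bins uniform (default 8, half-open so exactly π falls
in the last bin). Each day contributes one step token and one angle
token to a pooled categorical vocabulary.

Tracks are segmented by **exact dynamic-programming changepoint
detection** maximising the summed multinomial log-likelihood of segments
minus a per-changepoint penalty (default (V−1) log n / 2 with V the
vocabulary size, minimum segment length 3 days). Greedy binary splitting
was evaluated first and rejected: isolating an interior behavioural bout
requires two simultaneous cuts whose individual gains can each fall
below the penalty while their joint gain clears it, and the exact
optimum fixes precisely this failure. Segmentation is invariant to
relabelling of bin identities (multinomial symmetry; tested).

Segments pooled across individuals are clustered by latent Dirichlet
allocation fitted with a collapsed Gibbs sampler written in C++
(symmetric priors α = β = 0.1, 2000 sweeps, fixed seed), at
`max_states` = 6 topics. Pooling matters: behavioural states are
population-level constructs, and with only a handful of segments per
fish the mixed-membership model cannot share topics reliably. Collapsed
Gibbs is also prone to local modes that split one behaviour across two
near-identical topics, so the sampler runs a small number of restarts
(default 5, seeds derived deterministically from the input seed) and
keeps the chain with the highest collapsed joint likelihood. The number
of behavioural states is the smallest K whose K largest topics cover
>90% of observations; each segment takes its dominant topic, and states
are named deterministically by mean step length — largest =
"transiting", smallest = "area-restricted", any middle ranks
"intermediate-k" — which resolves label switching across seeds.

## 4. Activity and depth

MA = √(X² + Y² + Z²). The high-activity threshold is the individual's
95th percentile of MA over its full series — linear-interpolation
percentile (R type 7), strictly-above events — so the overall event rate
is ≤5% by construction and thresholds are never pooled across
individuals (pooling is tested *against*: it misclassifies quiet
individuals). Daily activity is the percentage of that day's samples
above threshold; months summarise daily values within individual first.
Month pairs are compared by Wilcoxon signed-rank on per-individual
monthly means, exact distribution for n ≤ 25 without ties, normal
approximation with continuity correction otherwise; identical paired
values yield p = 1 by convention (no evidence of difference), Bonferroni
multiplies by the number of tested pairs (capped at 1), and a compact
letter display (insert–absorb) summarises the adjusted matrix at
α = 0.05. Depth densities use 1-m bins per calendar month, normalised
within month, with mean temperature per occupied bin.

## 5. Seasonal habitat use

PSAT positions and acoustic COAs merge into one position per tag-day,
preferring the COA when both exist (COAs are treated as known locations
upstream, so demoting them here would be inconsistent). Spawning
season-years ("spawning-2019") support the philopatry filter: eligible
individuals have ≥2 distinct spawning seasons with ≥5 daily positions
each.

KUDs are bivariate Gaussian product-kernel densities computed on a
planar azimuthal-equidistant projection about the positions' centroid —
degree-space KDE distorts east–west distances by ~25% at 37° latitude,
which is why the projection exists. The default bandwidth is the
reference (href) convention of the home-range literature,
h = σ̂ n^(−1/6) with σ̂ = √((var x + var y)/2); the evaluation grid spans
the positions plus a 4h margin at 150 × 150 cells unless a shared grid
is supplied for comparisons. Contours are drawn at the density levels
enclosing 50% and 95% of total mass (cell-sum quantiles, so the density
integrates to 1 on the grid to ~1e-6 and the analytic 50%-area of an
isotropic Gaussian, 2π ln 2 h², is reproduced to 1%). Overlap between
seasons reports the 50% and 95% contour intersection-over-union, the UD
product integral ∬ UD_a UD_b dA, and a UDOI variant that scales the
product integral by the area of the union of the two 95% regions. No
single overlap statistic is canonical for philopatry; these are explicit
additions and labelled as such.

## 6. The synthetic world

`worldSpec()` fixes every constant of the synthetic shelf. The defaults
are the observation conditions the pipeline is designed for, not tuning
knobs; they are chosen once and stated here.

* **Geometry**: 3° × 2° domain (10–7°W, 36–38°N) at 0.03°; a sinuous
  northern coastline (amplitude 0.25°, wavelength 1.2°) with the
  seafloor deepening linearly offshore at 1.5 m km⁻¹, reaching ~300 m
  at the southern edge. The sinuosity matters: depth contours then bend
  in longitude as well as latitude, so the bathymetric band genuinely
  informs both coordinates, as real shelf topography does.
* **Ocean fields**: SST = 18 + 5 cos(2π(doy − 227)/365.25) °C with
  −1 °C per degree northward and +0.3 °C per degree eastward, spanning
  roughly 13–24 °C over the year as a temperate eastern-boundary shelf
  does; temperature at depth = SST − 0.05 °C m⁻¹ × z on 13 standard
  levels (0–300 m), with optional field noise (default off — tag-side
  sensor noise is modelled separately).
* **Movement**: two-state correlated random walk; transiting draws
  gamma steps with mean 25 km day⁻¹ and wrapped-Cauchy turning
  concentration ρ = 0.8, area-restricted 4 km day⁻¹ and ρ = 0.1 (well
  separated at the grid scale and within the 172.8 km day⁻¹ bound);
  proposals onto land redraw with gradual step shrinkage. The daily
  maximum depth is the local seafloor minus |N(0, 2 m)| — the demersal
  assumption made literal.
* **Observation**: depth quantised to 0.5 m (sensor noise sd 0.5 m),
  temperatures to 0.05 °C; light-based longitude on 85% of days with
  sd 0.3° (the availability matches the ~83% typical of recovered
  tags; the sd sits in the published range for light-based longitude on
  shelves); SST samples on 5% of days (surface visits are rare for a
  demersal fish, matching the sparse SST availability of real
  deployments); profiles on 85%, maximum depth on 100%. Acoustic
  transmissions at uniform 60–120 s delays, detected with logistic
  probability p(d) = 1/(1 + exp((d − 800 m)/150 m)) — midpoint at the
  ~800 m tested detection range, scale 150 m a free parameter.
  Acceleration is generated directly as a magnitude series (baseline
  |N(1 g, 0.08 g)|) with Poisson burst events whose daily rate follows
  a summer-peaked monthly curve, since the analysis uses only MA.

What the generator does **not** emulate: tides and currents (no
advection of the fish or the drift buffer), mesoscale oceanographic
structure (fronts, upwelling filaments) beyond the smooth gradients,
light-level curves themselves (longitude estimates are drawn directly),
receiver detection-range variability with sea state, tag loss and
biofouling, and vertical behaviour within the day beyond a simple
sinusoid. Passing the recovery benchmarks therefore demonstrates the
pipeline's internal correctness and its accuracy *under the stated
observation model* — not performance on any real ocean, where
field-model mismatch (e.g. a biased SST product) adds errors that have
no synthetic counterpart here.

## 7. Problem sizes and numerical conventions

The test suite and the acceptance script run, by design, at desk scale:
the smoother-vs-oracle property uses 100 random 5×5-cell, 4-day
instances against a dense transition-matrix path sum (agreement to
1e-10); geolocation recovery uses 20 fish × 60 days on the full
100 × 66 shelf grid (the pooled median great-circle error is compared to
the 3-cell ≈ 10 km yardstick, and the same stacks re-smoothed without
the bathymetric layer must do worse); behavioural recovery uses 10 fish
× 180 days with 50/40/60/30-day behaviour blocks — bouts of a few weeks
to two months, the scale of seasonal residency phases, and long enough
that each block is identifiable to the changepoint penalty; activity
detection uses 4 days of 5-s archival data per check. Summary-table
rounding is half-up at each column's printed precision (base `round()`
is banker's rounding and does not reproduce printed tables); means ± SE
use the sample sd over non-missing entries divided by √n. One recomputed
table quantity deserves a note: the mean PSAT deployment duration over
the 11 reporting tags is 166.45 d from the per-row dates, while the
published mean row prints 167; the package reports the recomputed value.

All distances are haversine on a 6371-km sphere; bearings use the same
sphere (geosphere's ellipsoidal default is overridden for consistency).
ESRI ASCII grid is the raster interchange format for bathymetry and
fields — a plain-text, single-band format sufficient for gridded
geographic rasters; in-memory constructors cover everything else.

## 8. Known limitations

* The smoother's boundary treatment (mass loss + renormalisation)
  slightly repels the posterior from the domain edge on data-poor days;
  enlarge the domain margin if tracks approach it.
* Posterior-mean positions are not constrained to water before
  snapping; always run `snapTrack()` before measuring distances.
* The 16-neighbour path graph can cross single-cell land spits; rasters
  should be at a resolution where barriers are ≥2 cells wide.
* The LDA state count inherits the 90% rule's discreteness: with very
  unbalanced behaviours a rare state below 10% of observations is, by
  construction, not counted.
* COA positions are detection-weighted receiver means and carry the
  array's geometry; with a single receiver hearing the fish, the COA is
  that receiver's position regardless of where the fish was within
  range.
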