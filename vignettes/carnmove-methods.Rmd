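---
title: "Behavior-aware movement analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-aware movement analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

carnmove implements a behavior-stratified analysis pipeline for GPS
telemetry of terrestrial carnivores: track cleaning and rarefaction,
state-space imputation of missing fixes, hidden Markov classification of
movement behavior, home-range estimation, multi-scale landscape
covariates, and behavior- season- and light-stratified integrated step
selection analysis (iSSA). This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, and what
the synthetic-data generator does and does not emulate.

## Preprocessing

Relocations arrive as `(id, timestamp, x, y)` tables in a projected
CRS; all geometry is metric. Three rules clean and regularize them:

* **Speed screening.** Consecutive implied speeds above 50 km/h are
  biologically impossible for a coyote-sized carnivore; while any such
  speed exists, the fix with the largest implied speed to its neighbors
  is removed and speeds are recomputed. Speeds in (10, 50] km/h are
  improbable but possible: those fixes are kept and flagged
  (`speed_flag`) for audit. The iterated rule is a reproducible,
  deterministic stand-in for case-by-case manual inspection; the flag
  log preserves everything a reviewer would have looked at.
* **Rarefaction.** Mixed collar schedules (2/6/7-h, occasionally
  sub-hourly) are thinned to a target interval by greedy forward
  selection: starting at the first fix, the next fix whose gap rounds
  to the target at a 15-min grain is retained. Greedy selection is
  seedless and deterministic; a global optimizer could retain slightly
  more fixes after irregular holes but would make retention depend
  non-locally on future data. When a gap overshoots the window (a data
  hole), the first fix past the hole restarts the chain, so the hole
  survives as a long gap rather than discarding the rest of the track.
* **Bursts.** Behavioral analysis uses maximal runs of nominally 2-h
  fixes spanning at least 8 days with never more than 4 consecutive
  missing slots. Fixes are snapped to a slot grid by rounding gap
  multiples; empty slots inside a kept burst are materialized as
  missing rows, which is what the imputation stage consumes.

Step geometry uses the mathematical bearing convention
(counterclockwise from east); turning angles are successive bearing
differences wrapped to $(-\pi, \pi]$, undefined after a zero-length
step because the incoming bearing does not exist there.

## Missing-fix imputation (CTCRW)

Missing slots are filled by single imputation under a continuous-time
correlated random walk: an integrated Ornstein--Uhlenbeck velocity
process per coordinate axis,

$$dv = -\beta\, v\, dt + \sqrt{2\beta}\,\sigma\, dW,\qquad
  x(t) = x(0) + \int_0^t v(s)\, ds,$$

with measurement error $\tau$. Here $\beta$ (1/h) is the velocity
autocorrelation rate, $\sigma$ (m/h) the stationary velocity SD, and
$\tau$ (m) the GPS noise SD. The exact Gaussian likelihood over the
observed slots is computed by Kalman filtering (compiled inner loop)
and maximized by bounded quasi-Newton from two starts of the rate
parameter. Choices that matter:

* $x$ and $y$ are independent with shared parameters — the standard
  CTCRW practice; nothing in the data motivates anisotropy, and the
  parameter count halves.
* $\tau$ is estimated but floored at 1 m. Stationary collars show
  meter-scale jitter, and a vanishing $\tau$ degenerates the
  likelihood when positions are nearly collinear.
* The model is fitted per burst. Pooling across bursts of an animal is
  possible in principle, but bursts are separated by weeks of collar
  rescheduling and the movement regime can differ; per-burst fitting
  is the conservative choice.
* Each missing slot is filled with one draw from its marginal
  Rauch--Tung--Striebel smoothing distribution (single imputation).
  Imputed fixes are flagged `source = "imputed"`; they keep the step
  series contiguous for HMM fitting, and every stratum or decoded step
  touching one is excluded from the selection analysis downstream.
* A rate estimate at its upper bound (50/h) means no detectable
  velocity persistence — white-noise-like positions — and is flagged
  rather than silently reported.

## Hidden Markov movement model

Steps are classified into latent behavioral states with an HMM whose
emissions are a gamma step-length distribution (mean $\mu_i$, SD
$s_i$, internally shape/scale) and a wrapped Cauchy turning-angle
distribution (location $m_i$, concentration $\rho_i \in [0,1)$) per
state, an $N \times N$ transition matrix $\Gamma$ and initial law
$\delta$. Three states carry the standard carnivore reading: encamped
(short steps), foraging (intermediate steps, weak directionality), and
traveling (long, directionally persistent steps); 2- and 4-state
alternatives are fitted as competitors.

Fitting maximizes the scaled forward-algorithm likelihood (compiled)
by L-BFGS-B on working parameters: log means and SDs, free turn
locations, logit concentrations, multinomial-logit transition rows and
initial law. The score is analytic via the Fisher identity — the
gradient of the marginal likelihood is the posterior-weighted
complete-data score, with posteriors from a compiled forward-backward
pass — which makes fits at several thousand steps take seconds.
Details:

* **Zero step lengths.** Stationary collars report 0–2 m "steps" that
  a gamma with shape > 1 cannot absorb at 0; lengths are floored at
  1 m (configurable), below GPS noise, before the density.
* **Missing data.** A missing step length contributes transitions
  only; a missing turning angle contributes the length term only.
* **Multistart.** Starting step-length means are all ascending
  combinations of {5, 50, 200, 500, 1500} m crossed with turn
  concentrations {0.2, 0.7}; the winner by likelihood is kept and the
  grid is logged with the model. The grid spans the encamped-to-
  traveling scales so at least one start is near any plausible optimum.
* **Canonical labels.** States are stored sorted by ascending mean, so
  relabeling cannot change reported results; the likelihood itself is
  label-invariant.
* Turn-angle locations are estimated freely but initialized at 0;
  "high turning angle" behavior is expressed through low initial
  concentration rather than a location constraint, since nothing pins
  the location a priori.

Decoding provides the Viterbi path and forward-backward posteriors.
Candidate models (N = 2, 3, 4) are compared by three sequential
criteria: biological plausibility (state means ordered and separated
by at least a 3x ratio — a configurable operationalization of
"distinct behaviors"), predictive power (mean per-step maximum
posterior > 0.85), and minimum AIC among survivors, with
$k = 4N + N(N-1) + (N-1)$ parameters. No survivor is an error with
the full criteria report attached, never a silent fallback.

## Seasons and light

A fix is in the snow season iff its date falls in the calendar window
for its elevation regime — December 10 to April 15 below 300 m,
November 20 to May 1 at or above 300 m (inclusive, year-wrapping);
elevation is sampled from the DEM at the fix, not per animal, because
the rule is about where the animal is. Sunrise and sunset come from
the NOAA solar-position equations (Meeus-based, −0.833° altitude) at
the study reference coordinates; across a study-area-sized window the
event-time error is under a minute, far below the 2-h rule width.
Diurnal is 2 h after sunrise to 2 h before sunset, nocturnal 2 h after
sunset to 2 h before sunrise, and the two 4-h windows centered on the
events are crepuscular; boundary instants are crepuscular (closed
windows), consistent with windows centered on the events. At extreme
day lengths (> 20 h) the nocturnal window would go negative; the
implementation clamps it to zero length and warns, since the study
latitude never reaches that regime. Polar latitudes are refused.

## Home ranges

Home ranges use 7-h rarefied locations, per animal, for the full
period and per season (partitions under 30 locations are skipped with
a logged reason; the floor is our documented default, chosen so a
partition always has enough points for stable hulls).

* **a-LoCoH.** The sphere of influence $a$ is the maximum pairwise
  distance in the data. Each location's local hull uses neighbors
  added in ascending distance while the cumulative distance sum stays
  within $a$ (the published adaptive rule). Hulls are sorted by
  ascending area — ties broken by fewer vertices, then construction
  order, for determinism — and unioned until the isopleth share of
  locations is covered, boundary inclusive. Duplicate locations are
  deduplicated before hull construction (zero-area duplicate hulls
  would otherwise game the ordering) but all locations count toward
  the isopleth.
* **Union area.** The union of overlapping convex hulls is measured
  exactly by vertical slab decomposition: slab boundaries at every
  vertex and every pairwise edge crossing, one linear y-interval per
  hull per slab, midpoint interval-union integration. No grid
  approximation is involved; the polygon is stored as its component
  hulls (a multipart polygon whose parts may overlap; the area is
  overlap-corrected).
* **MCP.** The (100 − isopleth)% of locations farthest from the
  arithmetic-mean centroid are removed and the convex hull of the rest
  is reported.

A note on geometry: with the cumulative-distance rule, local
neighborhoods do not in general span the whole data set even when $a$
equals the data diameter, so the 100% a-LoCoH union is usually a
strict subset of the convex hull — that is the point of the method.
The convex-hull identity holds when some locations can reach the rest
within the cumulative budget (flat or centrally-anchored
configurations), and exactly when $a$ is unbounded; the tests exercise
both regimes.

## Landscape covariates

Nine covariates form the global selection model, evaluated at step
endpoints (endpoint sampling is the standard iSSA design; the source
protocol does not state along-path sampling):
local binary forest and open indicators at the cell scale (10 m in the
reference data), focal forest and open proportions within 500 m,
forest-open edge density within 50 m (length of shared forest-open
cell boundaries divided by circle area, m/m²; other class adjacencies
are not edges), Simpson heterogeneity $1 - \sum p_i^2$ of forest,
open and wetland within 500 m (anthropogenic excluded, proportions
renormalized over the three classes), corridor density within 100 m
and 500 m, elevation in hectometers (the "per 100 m" table scaling),
and slope in radians from Horn's 3x3 gradient with edge replication.
Wetland/freshwater is the land-cover outgroup; anthropogenic cover is
too rare to act as one. Focal scales of 100 m and 250 m are omitted
deliberately: they are nearly collinear with the 10 m and 500 m
scales.

"km/100 m" is read as kilometers of corridor within a 100 m-radius
circle — length per neighborhood, not per unit area — which keeps the
local and landscape corridor metrics on comparable scales. Focal
membership is by cell center inside the circle; circles clipped at the
raster edge use the available cells and record the coverage fraction,
rather than inventing padding. Covariates are used on their natural
scales throughout (no z-standardization is applied); coefficients are
therefore per natural unit.

## Integrated step selection

Each usable decoded step becomes one stratum: the used step plus 10
random steps drawn by resampling the pooled empirical step-length and
turn-angle distributions of all individuals (empirical resampling, not
a parametric refit, matching the availability definition; pooled
rather than per-dataset, with a flag point in the code where
stratified resampling could be swapped in). Random endpoints falling
off the landscape are redrawn, up to 100 attempts. Strata whose used
step lacks a defined turning angle (first step of a burst, step after
a zero-length step) are dropped and logged, because cos(turn) is a
model covariate; strata touching imputed fixes are excluded.

Each candidate carries ln(step length), cos(turning angle) and the
nine landscape covariates. Strata are partitioned into the
2 seasons x 3 light classes x 3 behaviors = 18 datasets, each fitted
independently — no pooling, no random effects, one column per dataset
as in the source tables, and no multiple-testing correction (none is
applied there). The conditional-logistic partial likelihood

$$\ell(\beta) = \sum_s \left[ \beta^\top z_{s,\mathrm{used}} -
  \log \sum_{j=0}^{10} \exp(\beta^\top z_{s,j}) \right]$$

is maximized by Newton--Raphson on the analytic gradient and Hessian,
with step-halving (the partial likelihood never decreases) and a 1e-8
ridge on the Hessian diagonal against flat directions. Standard errors
are from the inverse observed information. A covariate with no
within-stratum contrast anywhere is refused by name; a coefficient
walking past ±15 is reported as separated with an infinite-SE marker.
Significance uses the strict 2·SE < |β| rule; collinearity is
diagnosed with VIFs (OLS of each covariate on the rest over all
candidate rows).

## Time budgets

Per (season, light) cell, the per-behavior location counts are
normalized to proportions (full precision retained; display rounding
is half-up at 2 decimals, matching how such tables are printed).
"Hours per day" multiplies the proportion by the season-specific mean
daily duration of the light period, computed from the solar module
over the dates actually monitored in that season — the averaging
window is our documented choice; the source table does not state one.
The three period durations sum to 24 h by construction.

## The synthetic-data generator

No collar data are deposited with the source study, so the generator
is the package's ground truth. It emulates: a landscape of the study's
four reclassified cover types with contiguous patches (rank-thresholded
smoothed Gaussian random fields, exact class proportions), sharp
relief from lowlands to a plateau crossing the 300 m season threshold
(sigmoid plus low-frequency field, rescaled to the relief amplitude),
sparse straight linear corridors with analytically checkable density;
and tracks from the exact generative mirror of the fitted HMM (Markov
chain over states, gamma lengths, wrapped Cauchy turns) with state
means 7/198/1426 m, 2-h fixes, missingness defaulting to the reported
8.5% average (capped at 25%, above the reported 20.5% maximum), and
optional habitat selection by an importance-sampling scheme: 50
candidate endpoints per step from the movement kernel, one chosen by
softmax of the linear predictor — the standard construction that a
conditional logistic regression with movement covariates can recover.
Tracks reflect at the landscape boundary rather than erroring.

Default state parameters are the reported means with SDs of
6/160/1100 m and turn concentrations 0.1/0.3/0.8 (near-uniform turning
when encamped, directional persistence when traveling); the reported
ranges (0–29, 0–1297, 59–8619 m) sit well inside these distributions.
The transition matrix defaults to 0.8 self-transition, consistent with
roughly third/third/third time budgets and multi-hour behavioral
persistence at a 2-h fix interval.

What the generator does **not** emulate — and hence what green tests
do not establish about field data: snow depth (season is purely the
calendar/elevation rule; no snow covariate exists), fix-quality/DOP
structure in GPS error, multi-animal interaction or territoriality,
temporally varying landscapes, and habitat-dependent behavior
switching (transitions are state-homogeneous). Parameter-recovery
results therefore validate the estimators, not the ecological model.

## Validation problem sizes and numerics

The test suite validates each stage against independent oracles:
exhaustive path enumeration for HMM recursions (N ≤ 3, T ≤ 8, 1e-8),
the direct joint-Gaussian density for the Kalman filter (n ≤ 6, 1e-8),
brute-force pairwise distances and convex hulls for home-range
geometry, cell enumeration and closed forms for covariates, and
brute-force partial-likelihood maximization for the conditional
logistic fit (1e-6). Simulation studies use n = 5000 steps over 20
seeds for state recovery and model selection, 20 tracks of 30 days for
selection-coefficient coverage, and 20 integrated-OU series of n =
2000 for rate recovery — sizes at which the relevant asymptotics have
clearly set in while a full run of the suite stays in the minutes
range on one core.

Numerical conventions: log-space emission clamping at ±1e30; scaled
forward/backward recursions; step-length floor 1 m; CTCRW noise floor
1 m; ridge 1e-8 on the clogit Hessian; half-up display rounding;
ties in hull ordering broken deterministically. Degenerate inputs
(collinear point sets, empty partitions, single-fix animals,
no-contrast covariates, polar latitudes) raise typed errors or logged
skips rather than propagating silently.

## Known limitations

* The speed screen is a proxy for expert inspection; it can keep a
  plausible-speed erroneous fix that a human with home-range context
  would remove. The flag log is the audit trail.
* Transition probabilities are covariate-free; behavior-dependent
  responses to the landscape enter only through the stratified iSSA.
* The 18 datasets are fitted independently; population-level pooling
  (random effects) is out of scope, so per-dataset coefficients are
  noisy when a dataset is small — the per-dataset stratum floor (20)
  refuses the worst cases.
* a-LoCoH areas depend on the deterministic tie-breaking of equal-area
  hulls; alternative tie orders can change the area within the
  resolution of a single hull.
* GeoJSON/ASCII-grid I/O covers interchange with GIS tools; no
  coordinate reference system transformations are performed — inputs
  must already be projected in meters.
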