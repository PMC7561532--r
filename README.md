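# carnmove

Behavior-aware movement analysis for GPS-collared carnivores.

Terrestrial carnivores partition their days among behaviors — resting
(encamped), foraging, traveling — and their habitat choices differ by
behavior, by season (snow vs snow-free), and by light (day, twilight,
night). Analyses that pool all relocations blur those differences:
selection that happens only while traveling at night disappears under
the hours spent encamped. carnmove implements the full pipeline that
makes behavior-, season- and light-stratified inference possible from
raw GPS collar data, for movement ecologists working with relocation
tables, land-cover and elevation rasters, and linear-feature layers.

## What it computes

* **Preprocessing** — speed-based error screening (fixes implying
  > 50 km/h removed iteratively; 10–50 km/h flagged for review),
  rarefaction of mixed fix schedules to a nominal interval (2 h for
  behavior, 7 h for home ranges; 15-min rounding grain), and
  extraction of analysis bursts (≥ 8 days of 2-h fixes, never more
  than 4 consecutive missed fixes), plus net squared displacement for
  residency screening.
* **Missing-fix imputation** — a continuous-time correlated random
  walk (integrated Ornstein–Uhlenbeck velocity: $dv = -\beta v\,dt +
  \sqrt{2\beta}\,\sigma\,dW$, position the integral of $v$,
  measurement noise $\tau$), fitted per burst by exact Kalman-filter
  maximum likelihood; missing slots are filled by single imputation
  from the smoothing distribution and flagged.
* **Hidden Markov movement models** — 2-, 3- and 4-state HMMs with
  gamma step lengths and wrapped Cauchy turning angles, fitted by
  direct likelihood maximization with an analytic (Fisher-identity)
  score and a multistart grid; Viterbi decoding, forward–backward
  state posteriors, and sequential model selection: biological
  plausibility, predictive power (mean maximum posterior > 0.85),
  then AIC.
* **Home ranges** — 95% adaptive local convex hulls (a-LoCoH, with
  the sphere of influence $a$ = maximum pairwise distance and exact
  union areas) and 95% minimum convex polygons, full-period and per
  season.
* **Landscape covariates** — local (cell) and 500-m forest/open
  cover, 50-m forest–open edge density, 500-m Simpson heterogeneity,
  corridor density within 100 m and 500 m (km per circle), elevation
  (per 100 m) and slope (radians, Horn's method).
* **Integrated step selection (iSSA)** — each used step matched with
  10 random steps resampled from the pooled empirical step-length and
  turn-angle distributions; conditional logistic regression (in-package
  Newton–Raphson on the analytic partial-likelihood gradient/Hessian)
  per season × light × behavior dataset, with ln(step length) and
  cos(turning angle) as movement covariates, VIF diagnostics and the
  2·SE significance rule.
* **Time budgets** — proportions of locations and hours per day spent
  in each behavior per season and light period.
* **Synthetic data** — a landscape and track generator with known
  ground truth (HMM-driven movement with optional habitat selection
  via an importance-sampling scheme), so every stage is testable
  without field data.

## Worked example

Simulate a collared animal on a synthetic landscape, run the core
stages, and inspect the results:

```r
library(carnmove)

stack <- make_landscape(landscape_spec(seed = 7))
#> <landscape_stack> 256 x 256 cells of 20 m (26.2 km2), 6 corridors

spec  <- track_spec(duration_days = 40, missingness = 0.085, seed = 42)
sim   <- simulate_track(spec, stack)
fixes <- drop_fixes(sim$fixes, 0.085, seed = 43)

scr    <- filter_speed(fixes)
bursts <- extract_bursts(rarefy(scr$fixes, 2))
b      <- bursts[[1]]

pars <- fit_ctcrw(b)
#> <ctcrw_params> beta 2.41 /h, sigma 559 m/h, tau 1.02 m, loglik -6951.24
b <- impute_missing(b, pars, seed = 44)

steps <- steps_from_burst(b)
fit <- multistart_fit(steps, 3)   # full default start grid, ~20 s
#> <movement_model> 3 states, loglik -4000.316, k = 20, AIC 8040.63
#>  state step_mean step_sd turn_loc turn_rho
#>      1       6.8     5.0     0.56    0.131
#>      2     261.7   237.4    -0.38    0.179
#>      3    1230.8   872.3     0.13    0.325

dec <- state_posteriors(fit, steps)
predictive_power(dec)
#> [1] 0.94

pts <- cbind(b$x, b$y)
alocoh(pts, adaptive_a(pts), 95)
#> <homerange> aLoCoH 95% (NA, all): 13.43 km2 from 481 locations
```

The three fitted states read directly as encamped / foraging /
traveling: mean step lengths of ~7 m, ~260 m and ~1230 m per 2-h step
(the generator's truth is 7 / 198 / 1426 m), with directional
persistence increasing across states. The predictive-power index 0.94
exceeds the 0.85 threshold, so the model is considered strongly
predictive; the 95% a-LoCoH home range of this 40-day track is
13.4 km². `run_pipeline(run_config(...))` chains all stages — through
season/light assignment, time budgets, seasonal home ranges and the
stratified selection fits — and writes CSV/GeoJSON/ASCII-grid
artifacts plus a JSON run report.

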