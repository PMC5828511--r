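---
title: "Crossing-triggered analysis of plume-tracking flight: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossing-triggered analysis of plume-tracking flight: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumecross)
```

# The scientific problem

Flying insects locate odor sources by tracking wind-borne plumes. In a
laminar wind tunnel with a stationary plume, a tracked insect's
time-varying position determines the odor concentration it experiences, so
each *plume crossing* — a maximal interval during which the experienced
concentration exceeds a detection threshold — is a well-defined sensory
event. The canonical reactive account of tracking is *surge and cast*:
surge upwind on plume contact, cast crosswind after losing it. The question
this package is built around is whether responses to individual crossings
are purely reactive, or modulated by measurable features of the encounter:
its peak concentration, and the insect's *history* — how many crossings it
has already made in the flight.

`plumecross` implements the full analysis chain: crossing extraction and
peak alignment, confound-controlled crossing statistics, three
trajectory-generating tracking models (surge-cast, centerline-inferring,
and infotaxis) whose history signatures can be compared against data, a
hybrid crossing model mixing surge-cast and infotaxis responses, and a
synthetic trajectory generator with *injectable, known* effects so every
stage is testable by parameter and sign recovery.

# Coordinate frame and core definitions

The flyable volume is `[0, 1.3] x [-0.15, 0.15] x [-0.15, 0.15]` m with +x
pointing downwind; the upwind unit vector is `(-1, 0, 0)`. *Heading* is the
unsigned angle (degrees) between the velocity vector and upwind: 0 is
directly upwind, 90 crosswind, 180 downwind. The plume is a stationary
axial tube with Gaussian cross-section
`c(x, y, z) = c_max exp(-r^2 / 2 sigma(x)^2)`, `sigma(x) = sigma0 +
widen_rate * x`. Concentrations are in arbitrary, dataset-relative units
(the empirical quantity is only known up to a multiplicative factor), so
the crossing threshold is expressed in the same units.

Each crossing is aligned to its concentration peak (`t = 0`); its analysis
window runs until the plume is re-entered or the flight ends, and the
heading time course is resampled onto a fixed 0–1 s post-peak grid with a
validity mask where the window ends early. Crossing numbers count all
crossings in temporal order *before* any exclusion: the early/late variable
reflects the insect's full experience, while exclusions are geometric
(`apply_exclusions(..., renumber = TRUE)` gives the other convention).
Exclusion rules: drop crossings in the upwind- or downwind-most 30 cm
(less room to turn into), and crossings whose initial heading is outside
60–120 degrees (upwind turns are only visible from a crosswind start).

# The statistical layer

**Partial correlation.** Confound control is by residualization: the target
(e.g. heading at 300 ms post-peak) is regressed on the conditioners (OLS
with intercept) and the residual is Pearson-correlated with the predictor
(e.g. `c_peak`). Confidence intervals bootstrap whole trajectories, since
crossings within a flight are dependent.

**Binary vs. threshold-linear models.** Two nested models of the
post-crossing heading are compared:
`h = a_h h0 + a_x x0 + h_< + h_> Theta(c_peak - c_th)` and the same plus
`a_c c_peak Theta(c_peak - c_th)`. Both are fitted by least squares with
`c_th` grid-searched over the 1st–99th percentiles of `c_peak` (100 steps;
the objective is piecewise-smooth in `c_th`, so grid + per-grid OLS is
exact up to grid resolution). The F-test of the nested pair replaces the
number of crossings with the number of unique trajectories — conservative,
because crossings from one flight are not independent. The
anticonservative crossing-count p-value is also reported, and is provably
never larger.

**History dependence.** For each crossing, `Delta h(t) = h(t) - h(0)`
(the package's definition of the heading change; a pre-crossing-average
baseline is not implemented because `h(0)` is the only baseline the data
model guarantees at every crossing). At each timepoint the best linear
prediction of `Delta h(t)` from `x0` and flight time `T` is fitted over
*all* crossings pooled and subtracted, giving `h*(t)`, which therefore
averages to zero by construction. Early (crossing number 1–2) and late
(3+) groups are compared with a Welch t-test whose group sizes are
unique-trajectory counts (same conservative substitution). A positive
late-minus-early difference means later crossings turn less upwind.

**Crossing-number correlation.** The complementary continuous analysis:
partial correlation between crossing number (capped at 5; higher numbers
are rare) and `Delta h` time-averaged over 350–450 ms, conditioned on
`(x0, T)`, with trajectory-count degrees of freedom.

**Threshold selection.** The detection threshold is chosen by a scan: a low
capture threshold defines a pool of potential crossings; each candidate
threshold splits the pool by `c_peak`, and the separation score is the
below-minus-above difference of group-mean headings averaged over the
first second post-peak. The score rises until the candidate passes the
true behavioral threshold and then plateaus; the elbow is operationalized
as the point of maximum discrete curvature (a choice otherwise made
by eye).

# The tracking models

**Base walker.** All reactive models share a correlated random walk on the
velocity, `tau dv/dt = -v + eta xi + b w_c`, with `tau = 0.42` s,
`eta = 1.9` m/s, `b = 0.25` m/s (values fitted to match empirical speed,
angular-velocity and crosswind-position distributions;
`fit_base_walker()` reproduces that distribution-matching fit). `w_c`
points crosswind toward the tunnel centreline — a standing "casting" bias.
Integration is Euler–Maruyama at `dt = 0.01` s with the noise drawn fresh
per step inside the drift, making `eta`'s effective role dt-dependent;
`dt` is therefore part of the configuration and recorded in outputs.
Boundaries reflect (position mirrored, wall-normal velocity negated).

**Surge-cast.** Adds a transient upwind force `a(t) w_u`, where `a(t)` is
an alpha-function kernel `A (t/tau_s) exp(1 - t/tau_s)` (unit peak, so the
force peaks at exactly `A = 0.8` m/s at lag `tau_s = 0.07` s) convolved
with a delta train at crossing concentration peaks, detected online as the
first local maximum while above threshold.

**Centerline-inferring.** Replaces the reflexive surge with information
use: a 2D Gaussian belief over the plume centreline (likelihood variance
`(2 m)^2` per axis, prior `(5 m)^2`) is conjugately updated at each
crossing, the crosswind bias points at the MAP estimate, and a continuous
upwind drive `k = k* / |K|` grows as the posterior covariance determinant
shrinks. The belief mean decays to `(0, 0)` and the covariance back to the
prior with memory timescale `tau_m = 10` s, applied continuously (per
step); applying it only between crossings is the untested alternative.
`k*` is not a magic constant: `calibrate_upwind_gain()` picks it so the
drive after two belief updates equals the surge-cast amplitude, giving the
two augmented models comparable crossing-triggered dynamics.

**Infotaxis.** A lattice agent (2 cm spacing over the flyable volume;
tests use a 4 cm coarsening) holds a probability field over source
locations, updated by Bayes' rule from deterministic hits (inside the
discretized plume) and misses, under a turbulent-plume likelihood
`rate = (R a / |dr|) exp(V dx_down / 2D - |dr| / lambda)` with `D = 0.09`
m²/s, `R = 1000` Hz, and `lambda = 2D/V` (infinite particle lifetime). It
moves to minimize expected posterior entropy (found branch contributing
zero), with ties broken first toward the candidate holding more posterior
mass and then in the fixed order stay, -x, +x, -y, +y, -z, +z.

Two design points deserve emphasis because they were forced by the
mathematics rather than chosen freely:

* *Detector size.* With `R = 1000` Hz and a centimetre-scale detector the
  per-step hit probability saturates near 1 over most of the tunnel; a
  single miss then annihilates nearly the whole belief, the agent
  degenerates into axial end-to-end sweeps, and essentially no crossing
  survives the mid-tunnel/crosswind exclusions. At `a_det = 2` mm — the
  physical scale of an insect antenna, decoupled from the numerical
  lattice — the likelihood leaves saturation and the documented
  phenomenology appears: mid-tunnel crosswind crossings, multi-encounter
  sequences, and the characteristic weakening of late upwind turns. 2 mm
  is the package default.
* *Degenerate-belief fallback.* A purely greedy rule deadlocks once the
  belief collapses to (near) a point away from the agent: no observation
  changes a point mass, every candidate's expected entropy ties, and
  "stay" wins forever. `run_infotaxis()` therefore switches to
  exploitation when no move offers information gain: it walks toward the
  belief mode along a noisy straight line (step axis sampled proportional
  to the remaining displacement). This is self-correcting — a miss at the
  believed source eliminates that cell and restarts the search — and is
  the only stochastic element of a run.

Batch simulations default to starts uniform over the lattice and durations
log-uniform in 10–60 s: the history signature of infotaxis lives in
extended multi-encounter runs, matching the long empirical recordings such
simulations are compared against. `simulate_batch_infotaxis(match_to =)`
instead draws each run's start and length (path length / lattice spacing)
from an existing trajectory set.

**Hybrid crossings.** Each infotaxis crossing is paired with a random
surge-cast crossing of the same crossing number and
`Delta h_hybrid(t) = P/100 Delta h_sc(t) + (1 - P/100) Delta h_it(t)`.
Because the mixture and the group means are linear, the late-minus-early
difference of the hybrid pool (time-averaged 0.3–0.8 s) is exactly linear
in `P`, so the `P*` matching any target difference has a closed form,
clipped to `[0, 100]`; its spread over random pairings quantifies pairing
noise. The target is an input: the natural choice is an empirically measured
fly value, which depends on the dataset at hand.

# The synthetic world

`generate_dataset()` produces base-walker flights plus crossing-triggered
surges of amplitude `A = (A0 + g_c c_peak) * hist(n)`, with
`hist(n) = rho` for crossings 3+ (step variant mirroring the early/late
split) or `rho^(n-1)` (smooth variant for the crossing-number analysis).
Defaults and what they emulate:

* `A0 = 0.4` m/s, `g_c = 0.5` (m/s per concentration unit): surge
  amplitudes span the surge-cast model's 0.8 m/s scale over the observable
  `c_peak` range, so concentration dependence is present but not dominant.
* `rho = 0.7`: a moderate attenuation between the checked extremes.
* plume `sigma0 = 0.02` m, threshold 0.1 `c_max`: a narrow laminar plume
  (detection radius about 4 cm) that still spans neighbouring cells of the
  coarsened 4 cm test lattice.
* durations log-uniform 2–20 s, starts uniform in the downwind half: makes
  multiple crossings per flight common.
* per-trajectory lognormal heterogeneity (sd 0.5) of the casting bias `b`:
  individuals differ in how tightly they cast, so flights differ in
  encounter rate. This is not cosmetic: with a single shared rate the
  crossing number is nearly collinear with flight time and the flight-time
  conditioner would absorb any genuine history effect — the analysis would
  be unidentifiable on its own test data.
* `heading_noise = 0` degrees by default: the empirical velocities such
  datasets store are already Kalman-smoothed; the option exists to stress
  the pipeline.

What the generator does *not* emulate: plume turbulence or intermittency
beyond what the flight path itself produces, landing/takeoff behaviour
(landing is simply the end of the series), wind-speed-dependent turning,
and any visual responses. A green recovery test therefore establishes that
the pipeline detects the stated effect structure at realistic noise — not
that real insects carry that structure.

# Numerical choices and degenerate inputs

* Heading is undefined at zero speed; such samples error by default and are
  masked (`na_zero = TRUE`) inside the extractor. Infotaxis "stay" steps
  carry the previous nonzero displacement's velocity.
* Crossing windows shorter than the 1 s grid are retained with a validity
  mask, not dropped; all window averages are mask-aware.
* `t = 0` conditioning on `h0` makes the residual constant; the
  concentration curve reports that timepoint as undefined rather than
  failing.
* The conjugate centerline update is numerically exact (diagonal 2x2);
  non-positive variances raise immediately.
* Belief updates renormalize each step and abort on an all-zero posterior
  (an impossible observation under the belief).
* The compiled infotaxis loop and the pure-R reference implementation
  consume the RNG identically and produce identical paths over short
  horizons; over hundreds of steps they may eventually diverge at an exact
  floating-point tie, which is why the equivalence test uses 40-step runs.
* The speed-decay check uses the Euler-consistent timescale estimator
  `dt / (1 - per-step ratio)` (exact for the scheme); the continuous-time
  `e^-1` ratio carries an irreducible ~1.2% discretization bias at
  `dt = 0.01`, `tau = 0.42`. Autocorrelation checks run in a wall-free
  arena (reflections decorrelate velocities) and avoid sample-mean
  subtraction, whose bias is O(tau / T) at these correlation lengths.

# Known limitations

* The acceptance layer is property- and sign-based by design: headline
  empirical numbers (fitted detection thresholds, crossing counts, matched
  mixing fractions, per-experiment p-values) are functions of wind-tunnel
  recordings that are not publicly available and cannot be reproduced at
  desk scale.
* The early/late sign of the infotaxis model weakens around
  `D = 0.18` m²/s in our stated world (it recovers at both smaller and
  larger `D`); resolving its sign there requires pooled batches of around
  a thousand runs.
* Greedy infotaxis in a deterministic laminar world is structurally
  degenerate without the exploitation fallback; conclusions about
  "infotaxis" from this package are conclusions about this
  greedy-plus-exploitation operationalization.
* No multiple-testing correction across timepoints: per-timepoint p-values
  are reported raw, matching the analysis convention this package
  reimplements.
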