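# plumecross

Crossing-triggered analysis of insect plume-tracking flight.

Flying insects track wind-borne odor plumes to find food and mates. In a
laminar wind tunnel with a stationary plume, every *plume crossing* — a
maximal interval during which the experienced concentration exceeds a
detection threshold — is a well-defined sensory event, and the insect's
heading time course around each crossing (heading = angle between velocity
and upwind, 0° = straight upwind) is the behavioral response. `plumecross`
is for researchers asking whether those responses are purely reactive or
modulated by features of the encounter: its **peak concentration** and the
insect's **history** (how many crossings it has already made).

The package provides:

* **Crossing extraction** — segmentation of 3D trajectories into
  peak-aligned crossings with covariates (`c_peak`, position `x0`, initial
  heading `h0`, flight time `T`, crossing number), the standard geometric
  exclusion rules (30 cm tunnel-end margins, 60–120° initial heading), and
  the detection-threshold selection scan.
* **Crossing statistics** — residualized partial correlations with
  trajectory-level bootstrap CIs; the nested *binary* vs. *threshold-linear*
  concentration-response models
  `h = a_h h0 + a_x x0 + h_< + (h_> + a_c c_peak) Θ(c_peak − c_th)`
  compared by an F-test with conservative unique-trajectory degrees of
  freedom; and the early (crossings 1–2) vs. late (3+) history analysis on
  the confound-corrected heading change `h*(t)` (pooled mean zero by
  construction).
* **Three trajectory-generating tracking models** — a fitted correlated
  random walk (`τ v̇ = −v + η ξ + b w_c`, τ = 0.42 s, η = 1.9 m/s,
  b = 0.25 m/s) augmented by (i) a reactive surge-cast alpha-function
  surge (0.8 m/s peak, 0.07 s timescale), (ii) a Bayesian
  centerline-inferring upwind drive `k = k*/|K|`, or replaced by (iii) a
  lattice infotaxis agent minimizing expected Shannon entropy of a source
  belief under a turbulent-plume likelihood.
* **Hybrid crossing analysis** — convex mixtures
  `Δh = P/100 Δh_sc + (1−P/100) Δh_it` with a closed-form, clipped solution
  for the mixing percentage matching any target history difference.
* **A synthetic trajectory generator** with injectable, known concentration
  and history effects, so the whole pipeline is testable by parameter and
  sign recovery without any external data.

See `vignettes/plume-tracking-methods.Rmd` for the models, assumptions,
parameter meanings and design decisions.

## Worked example

Generate a synthetic dataset with known effects (stronger surges at higher
concentrations, surges attenuated to 60% from the third crossing on),
extract and filter crossings, and run the two headline analyses:

```r
library(plumecross)

tunnel <- wind_tunnel()          # 1.3 x 0.3 x 0.3 m flyable, V = 0.4 m/s
plume  <- gaussian_plume()       # sigma = 2 cm, threshold 0.1 c_max

flights <- generate_dataset(
  synthetic_effects(conc_gain = 1.0, history_factor = 0.6,
                    n_traj = 500, seed = 42),
  tunnel, plume, walker_params())

crossings <- apply_exclusions(
  extract_crossings(flights, plume$threshold), exclusion_policy(), tunnel)
crossings
#> crossing_set: 782 crossings from 353 trajectories, grid 0-1 s (101 points), threshold 0.1

heading_concentration_curve(crossings, timepoints = c(0.2, 0.3, 0.4),
                            n_boot = 500, seed = 1)
#>     time   estimate      ci_lo       ci_hi            p     n defined
#> 1:   0.2 -0.1894706 -0.2603348 -0.11124471 2.506376e-07   732    TRUE
#> 2:   0.3 -0.1418770 -0.2200842 -0.06769012 1.888119e-04   690    TRUE
#> 3:   0.4 -0.1494936 -0.2212206 -0.06639283 1.678944e-04   631    TRUE

history_dependence(crossings)
#> history_analysis: 101 timepoints; mean late-early difference 3.87 deg; p < 0.05 at 25/101 timepoints
```

The negative partial correlations (peak concentration vs. heading 200–400 ms
after the peak, conditioned on `x0` and `h0`) recover the injected
concentration dependence: higher concentrations → smaller headings → stronger
upwind turns. The positive late-minus-early `h*` difference recovers the
injected history attenuation: later crossings turn less upwind, by about 4°
on average, even after the best linear predictions from tunnel position and
flight time are removed.

Model signatures (scaled-down analogues of the model comparison):

```r
ks  <- calibrate_upwind_gain()                       # centerline upwind gain
sc  <- simulate_batch(150, "surge-cast", seed = 1)   # reactive
cl  <- simulate_batch(150, "centerline", seed = 1, k_star = ks)
it  <- simulate_batch_infotaxis(150, seed = 1)       # 2 cm lattice by default
```

Surge-cast batches show no early/late distinction, centerline-inferring
batches show *stronger* late upwind turns (negative difference — opposite to
data), and infotaxis batches show *weaker* late upwind turns (positive
difference — the data's sign). `pool_history_difference()` summarizes each.

## Command line

```sh
Rscript inst/cli/plumecross.R synth    --n-traj 200 --seed 1 --out out/synth
Rscript inst/cli/plumecross.R simulate --model infotaxis --n-traj 100 --out out/it
Rscript inst/cli/plumecross.R analyze  --analysis history \
        --traj out/synth/trajectories.csv --out out/hist
Rscript inst/cli/plumecross.R heatmap  --traj out/it/trajectories.csv --out out/heat
```

Every stage writes its resolved configuration (`config.yaml`) next to its
outputs, so each artifact is reproducible from its manifest alone.

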