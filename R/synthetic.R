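#' Injectable effect structure for synthetic datasets
#'
#' The synthetic generator produces base-walker flight plus a
#' crossing-triggered upwind surge whose amplitude carries two injectable,
#' known effects mirroring the phenomena the analysis pipeline is built to
#' detect:
#'
#' * concentration dependence: surge amplitude
#'   `A = A0 + conc_gain * c_peak`, so stronger encounters trigger stronger
#'   upwind turns (`conc_gain > 0` makes the downstream partial correlation
#'   between `c_peak` and post-crossing heading negative);
#' * history dependence: the amplitude is attenuated by `history_factor`
#'   (`rho`) for crossings with number >= 3 (step variant, mirroring the
#'   early 1-2 / late 3+ split), or by `rho^(n-1)` with
#'   `history_decay = "smooth"` (for the crossing-number correlation
#'   analysis). `rho = 1` disables history dependence; `rho = 0` silences
#'   surges from the third crossing on.
#'
#' Defaults are chosen so surge amplitudes span the surge-cast model's
#' 0.8 m/s scale over the observable `c_peak` range.
#'
#' @param base_surge_amp A0, m/s.
#' @param conc_gain g_c, (m/s) per concentration unit.
#' @param history_factor rho in `[0, 1]`.
#' @param history_decay `"step"` (attenuate crossings 3+) or `"smooth"`
#'   (`rho^(n-1)`).
#' @param surge_threshold Minimum excursion peak concentration that triggers
#'   a surge; defaults to the plume detection threshold.
#' @param heading_noise Additive observation noise on stored headings,
#'   degrees (velocity directions are perturbed post hoc).
#' @param n_traj Number of trajectories.
#' @param duration_range Log-uniform flight duration range, seconds.
#' @param rate_heterogeneity Standard deviation of the per-trajectory
#'   lognormal multiplier on the casting bias `b` (default 0.5). Individual
#'   insects differ in how tightly they cast about the plume axis, so real
#'   flights differ in encounter rate; without this heterogeneity the
#'   crossing number is nearly collinear with flight time and the
#'   flight-time conditioner would absorb any genuine history effect.
#' @param seed RNG seed; generation is a pure function of
#'   (parameters, seed).
#' @return Object of class `synthetic_effects`.
#' @export
synthetic_effects <- function(base_surge_amp = 0.4, conc_gain = 0.5,
                              history_factor = 0.7,
                              history_decay = c("step", "smooth"),
                              surge_threshold = NULL, heading_noise = 0,
                              n_traj = 300, duration_range = c(2, 20),
                              rate_heterogeneity = 0.5, seed = 1L) {
  history_decay <- match.arg(history_decay)
  vals <- c(base_surge_amp, conc_gain, history_factor, heading_noise,
            n_traj, duration_range, rate_heterogeneity)
  if (!all(is.finite(vals))) stop("non-finite synthetic-effects parameter")
  stopifnot(base_surge_amp >= 0, history_factor >= 0, history_factor <= 1,
            heading_noise >= 0, n_traj >= 1, rate_heterogeneity >= 0,
            duration_range[1] > 0, duration_range[2] >= duration_range[1])
  structure(list(base_surge_amp = base_surge_amp, conc_gain = conc_gain,
                 history_factor = history_factor,
                 history_decay = history_decay,
                 surge_threshold = surge_threshold,
                 heading_noise = heading_noise, n_traj = as.integer(n_traj),
                 duration_range = as.numeric(duration_range),
                 rate_heterogeneity = rate_heterogeneity,
                 seed = as.integer(seed)),
            class = "synthetic_effects")
}

# perturb velocity directions by ~N(0, sd_deg) about a random axis
# perpendicular to v; preserves speed so only headings are noised
add_heading_noise <- function(tr, sd_deg) {
  v <- tr$velocities
  n <- nrow(v)
  speed <- sqrt(rowSums(v^2))
  ok <- speed > 0
  theta <- stats::rnorm(n, 0, sd_deg * pi / 180)
  raw <- matrix(stats::rnorm(3 * n), n, 3)
  # component of raw orthogonal to v, normalized
  proj <- rowSums(raw * v) / pmax(speed^2, 1e-12)
  perp <- raw - proj * v
  pn <- sqrt(rowSums(perp^2))
  u <- perp / pmax(pn, 1e-12)
  vn <- cos(theta) * v + sin(theta) * speed * u
  vn[!ok, ] <- v[!ok, ]
  tr$velocities <- vn
  tr
}

#' Generate a synthetic trajectory dataset with known injected effects
#'
#' Simulates `effects$n_traj` base-walker trajectories with
#' crossing-triggered surges of amplitude
#' `A = (A0 + conc_gain * c_peak) * hist(n)` (see [synthetic_effects()]),
#' start positions uniform in the downwind half of the tunnel and durations
#' log-uniform in `duration_range`. Reproducible: the same
#' `(effects, tunnel, plume, walker)` yields bit-identical output.
#'
#' @param effects A [synthetic_effects()].
#' @param tunnel A [wind_tunnel()].
#' @param plume A [gaussian_plume()].
#' @param walker A [walker_params()].
#' @return Named list of trajectories, with the injected ground truth
#'   attached as attribute `"ground_truth"`.
#' @export
generate_dataset <- function(effects = synthetic_effects(),
                             tunnel = wind_tunnel(),
                             plume = gaussian_plume(),
                             walker = walker_params()) {
  stopifnot(inherits(effects, "synthetic_effects"))
  set.seed(effects$seed)
  out <- lapply(seq_len(effects$n_traj), function(i) {
    dur <- draw_duration(effects$duration_range)
    start <- draw_start_position(tunnel)
    wi <- walker
    if (effects$rate_heterogeneity > 0) {
      mult <- exp(stats::rnorm(1, 0, effects$rate_heterogeneity))
      wi$b <- walker$b * mult
    }
    v0 <- draw_initial_velocity(wi)
    tr <- sim_walker(round(dur / wi$dt), start, v0, wi, tunnel,
                     plume, mode = 1L, A0 = effects$base_surge_amp,
                     conc_gain = effects$conc_gain,
                     rho = effects$history_factor,
                     smooth_decay = effects$history_decay == "smooth",
                     surge_threshold = effects$surge_threshold,
                     id = sprintf("synth_%04d", i))
    if (effects$heading_noise > 0)
      tr <- add_heading_noise(tr, effects$heading_noise)
    tr
  })
  names(out) <- vapply(out, `[[`, "", "id")
  attr(out, "ground_truth") <- unclass(effects)
  out
}

#' Deterministic toy concentration series
#'
#' Builds a 1D concentration series from non-overlapping triangular pulses
#' with known peak positions and amplitudes, for exercising the crossing
#' extractor against hand-computable fixtures.
#'
#' @param n Series length (samples).
#' @param pulses Data frame with columns `pos` (peak sample index), `width`
#'   (half-width in samples) and `amp` (peak amplitude above baseline).
#' @param baseline Baseline level (default 0).
#' @return Numeric vector of length `n` whose maximum over pulse `i`'s
#'   support is exactly `baseline + amp[i]` at index `pos[i]`.
#' @export
make_toy_concentration_series <- function(n, pulses = NULL, baseline = 0) {
  stopifnot(n >= 1)
  out <- rep(baseline, n)
  if (is.null(pulses) || nrow(pulses) == 0) return(out)
  stopifnot(all(c("pos", "width", "amp") %in% names(pulses)))
  o <- order(pulses$pos)
  pulses <- pulses[o, ]
  lo <- pulses$pos - pulses$width
  hi <- pulses$pos + pulses$width
  if (nrow(pulses) > 1 && any(lo[-1] <= hi[-nrow(pulses)]))
    stop("overlapping pulses")
  for (k in seq_len(nrow(pulses))) {
    i <- max(1, ceiling(lo[k])):min(n, floor(hi[k]))
    out[i] <- out[i] +
      pulses$amp[k] * pmax(0, 1 - abs(i - pulses$pos[k]) / pulses$width[k])
  }
  out
}
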