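#' Base correlated-random-walk parameters
#'
#' The baseline flight model for all reactive simulators is a 3D correlated
#' random walk on the velocity,
#' `tau * dv/dt = -v + eta * xi + b * w_c`,
#' where `xi` is a standard-normal 3-vector sampled independently at each
#' timestep, `w_c` is the unit vector in the crosswind (y, z) plane pointing
#' from the agent toward the tunnel centreline, and `b` a moderate "casting"
#' bias. Defaults are the values fitted to the empirical flight speed,
#' angular-velocity and crosswind-position distributions: `tau = 0.42` s,
#' `eta = 1.9` m/s, `b = 0.25` m/s.
#'
#' @param tau Turning timescale, seconds.
#' @param eta Noise scale, m/s.
#' @param b Crosswind centreline bias, m/s.
#' @param dt Integration / sampling timestep, seconds (must be `< tau`).
#' @return Object of class `walker_params`.
#' @export
walker_params <- function(tau = 0.42, eta = 1.9, b = 0.25, dt = 0.01) {
  stopifnot(is.finite(tau), tau > 0, is.finite(eta), eta >= 0,
            is.finite(b), b >= 0, is.finite(dt), dt > 0)
  if (dt >= tau) stop("dt must be smaller than tau")
  structure(list(tau = tau, eta = eta, b = b, dt = dt),
            class = "walker_params")
}

#' Surge parameters
#'
#' The surge-cast model adds to the base walker a transient upwind force
#' `a(t) * w_u` where `a(t)` is the convolution of an alpha-function kernel
#' with a train of delta functions at the crossing concentration-peak times.
#' The kernel is `u(s) = s * exp(1 - s)` (unit peak at `s = 1`), so a single
#' trigger produces a force peaking at exactly `amplitude` m/s, `timescale`
#' seconds after the trigger. Defaults: amplitude 0.8 m/s, timescale 0.07 s.
#'
#' @param amplitude Peak surge amplitude A, m/s.
#' @param timescale Alpha-function timescale, seconds.
#' @export
surge_params <- function(amplitude = 0.8, timescale = 0.07) {
  stopifnot(is.finite(amplitude), amplitude >= 0,
            is.finite(timescale), timescale > 0)
  structure(list(amplitude = amplitude, timescale = timescale),
            class = "surge_params")
}

#' Alpha-function surge kernel
#'
#' `alpha_kernel(t, timescale, amplitude)` evaluates
#' `amplitude * (t/timescale) * exp(1 - t/timescale)` for `t >= 0` (0 for
#' `t < 0`): a transient with unit-normalized peak `amplitude` at
#' `t = timescale`.
#'
#' @param t Time lag(s) since the trigger, seconds.
#' @param timescale Kernel timescale, seconds.
#' @param amplitude Peak value.
#' @export
alpha_kernel <- function(t, timescale = 0.07, amplitude = 0.8) {
  s <- t / timescale
  ifelse(s >= 0, amplitude * s * exp(1 - s), 0)
}

# draw an initial velocity from the walker's near-stationary distribution
draw_initial_velocity <- function(params) {
  stats::rnorm(3, 0, params$eta * sqrt(params$dt / (2 * params$tau)))
}

# uniform start in the downwind half of the tunnel, away from the walls
draw_start_position <- function(tunnel) {
  ext <- tunnel$extent
  c(stats::runif(1, ext[1] / 2, ext[1] * 0.98),
    stats::runif(1, -0.45 * ext[2], 0.45 * ext[2]),
    stats::runif(1, -0.45 * ext[3], 0.45 * ext[3]))
}

draw_duration <- function(range = c(2, 20)) {
  exp(stats::runif(1, log(range[1]), log(range[2])))
}

#' One Euler step of the base walker (R reference implementation)
#'
#' Reference stepper used to validate the compiled simulator: draws
#' `rnorm(3)` and advances the state by one Euler-Maruyama step with
#' reflecting boundaries. The compiled path (`simulate_base_walker` etc.)
#' consumes the RNG identically, so both produce bit-identical trajectories
#' from the same seed.
#'
#' @param state List with elements `pos` and `vel` (numeric length-3 each).
#' @param params A [walker_params()].
#' @param tunnel A [wind_tunnel()].
#' @return Updated state list.
#' @export
step_base_walker <- function(state, params, tunnel) {
  xi <- stats::rnorm(3)
  f <- params$dt / params$tau
  d <- c(0, 0, 0) - c(0, state$pos[2], state$pos[3])
  dn <- sqrt(sum(d^2))
  wc <- if (dn > 1e-12) d / dn else c(0, 0, 0)
  v <- state$vel + f * (-state$vel + params$eta * xi + params$b * wc)
  p <- state$pos + v * params$dt
  b <- tunnel_bounds(tunnel)
  for (ax in 1:3) {
    for (i in 1:8) {
      if (p[ax] < b[ax, "lo"]) { p[ax] <- 2 * b[ax, "lo"] - p[ax]; v[ax] <- -v[ax] }
      else if (p[ax] > b[ax, "hi"]) { p[ax] <- 2 * b[ax, "hi"] - p[ax]; v[ax] <- -v[ax] }
      else break
    }
  }
  list(pos = p, vel = v)
}

# shared wrapper around the compiled core
sim_walker <- function(n_steps, start, v0, params, tunnel, plume,
                       mode = 0L, A0 = 0, conc_gain = 0, rho = 1,
                       smooth_decay = FALSE, surge_threshold = NULL,
                       tau_s = 0.07, k_star = 0, Ks_var = 4, K0_var = 25,
                       tau_m = 10, id = "sim", takeoff_time = 0) {
  if (is.null(surge_threshold)) surge_threshold <- plume$threshold
  res <- sim_walker_cpp(as.integer(n_steps), params$dt, params$tau,
                        params$eta, params$b, as.numeric(start),
                        as.numeric(v0), tunnel$extent,
                        c(plume$centerline, plume$sigma0, plume$widen_rate,
                          plume$c_max),
                        plume$threshold, as.integer(mode),
                        A0, conc_gain, rho, as.integer(smooth_decay),
                        surge_threshold, tau_s, k_star, Ks_var, K0_var, tau_m)
  tr <- trajectory(id = id, dt = params$dt, positions = res$positions,
                   velocities = res$velocities,
                   concentrations = res$concentrations,
                   takeoff_time = takeoff_time)
  attr(tr, "triggers") <- data.frame(index = res$trigger_index + 1L,
                                     amplitude = res$trigger_amplitude)
  tr
}

#' Simulate the base correlated random walker
#'
#' @param duration Flight duration in seconds.
#' @param params A [walker_params()].
#' @param tunnel A [wind_tunnel()].
#' @param plume A [gaussian_plume()] used only to record the experienced
#'   concentration.
#' @param start Start position (length 3); drawn uniformly in the downwind
#'   half if `NULL`.
#' @param v0 Initial velocity; drawn from the near-stationary velocity
#'   distribution if `NULL`.
#' @param id Trajectory id.
#' @return A [trajectory()].
#' @export
simulate_base_walker <- function(duration, params = walker_params(),
                                 tunnel = wind_tunnel(),
                                 plume = gaussian_plume(), start = NULL,
                                 v0 = NULL, id = "base") {
  if (is.null(start)) start <- draw_start_position(tunnel)
  if (is.null(v0)) v0 <- draw_initial_velocity(params)
  sim_walker(round(duration / params$dt), start, v0, params, tunnel, plume,
             mode = 0L, id = id)
}

#' Simulate the surge-cast model
#'
#' Base walker plus an additive upwind alpha-function surge triggered at the
#' concentration peak of each plume crossing (detected online as the first
#' local maximum of the experienced concentration while above the detection
#' threshold).
#'
#' @inheritParams simulate_base_walker
#' @param surge A [surge_params()].
#' @return A [trajectory()]; the online trigger times and amplitudes are
#'   attached as attribute `"triggers"`.
#' @export
simulate_surge_cast <- function(duration, params = walker_params(),
                                surge = surge_params(),
                                tunnel = wind_tunnel(),
                                plume = gaussian_plume(), start = NULL,
                                v0 = NULL, id = "surge-cast") {
  if (is.null(start)) start <- draw_start_position(tunnel)
  if (is.null(v0)) v0 <- draw_initial_velocity(params)
  sim_walker(round(duration / params$dt), start, v0, params, tunnel, plume,
             mode = 1L, A0 = surge$amplitude, conc_gain = 0, rho = 1,
             tau_s = surge$timescale, id = id)
}

#' Simulate the centerline-inferring model
#'
#' Base walker where (i) the crosswind bias `w_c` points toward the MAP
#' estimate of the plume centreline under a 2D Gaussian belief updated at
#' each crossing peak, and (ii) a continuous upwind drive `k = k_star / |K|`
#' grows as the belief covariance determinant `|K|` shrinks. The belief mean
#' decays exponentially to (0, 0), and its covariance back to the prior, with
#' memory timescale `tau_m` (applied continuously, every step).
#'
#' @inheritParams simulate_base_walker
#' @param k_star Upwind gain scaling; `k = k_star / |K|` has units m/s.
#'   See [calibrate_upwind_gain()].
#' @param belief A [centerline_belief()] providing the prior and likelihood
#'   variances and memory timescale.
#' @export
simulate_centerline_inferring <- function(duration, k_star,
                                          params = walker_params(),
                                          belief = centerline_belief(),
                                          tunnel = wind_tunnel(),
                                          plume = gaussian_plume(),
                                          start = NULL, v0 = NULL,
                                          id = "centerline") {
  if (is.null(start)) start <- draw_start_position(tunnel)
  if (is.null(v0)) v0 <- draw_initial_velocity(params)
  stopifnot(is.finite(k_star), k_star > 0)
  sim_walker(round(duration / params$dt), start, v0, params, tunnel, plume,
             mode = 2L, k_star = k_star, Ks_var = belief$obs_var[1],
             K0_var = belief$prior_var[1], tau_m = belief$tau_m, id = id)
}

#' Simulate a batch of reactive-model trajectories
#'
#' Convenience wrapper drawing start positions uniformly in the downwind half
#' of the tunnel and durations log-uniformly in `duration_range`, mirroring
#' the synthetic-data defaults so crossing statistics see comparable
#' within-trajectory crossing sequences across models.
#'
#' @param n_traj Number of trajectories.
#' @param model `"base"`, `"surge-cast"` or `"centerline"`.
#' @param seed RNG seed (optional).
#' @param duration_range Log-uniform duration range, seconds.
#' @param ... Passed to the per-model simulator.
#' @inheritParams simulate_base_walker
#' @return Named list of trajectories.
#' @export
simulate_batch <- function(n_traj, model = c("surge-cast", "centerline",
                                             "base"),
                           params = walker_params(), tunnel = wind_tunnel(),
                           plume = gaussian_plume(), seed = NULL,
                           duration_range = c(2, 20), ...) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  fun <- switch(model,
                "base" = simulate_base_walker,
                "surge-cast" = simulate_surge_cast,
                "centerline" = simulate_centerline_inferring)
  out <- lapply(seq_len(n_traj), function(i) {
    fun(duration = draw_duration(duration_range), params = params,
        tunnel = tunnel, plume = plume,
        id = sprintf("%s_%04d", model, i), ...)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

# kinematic feature histograms used by the distribution-matching fit
walker_feature_hists <- function(trajs, breaks) {
  sp <- list(); av <- list(); yy <- list()
  for (tr in trajs) {
    v <- tr$velocities
    s <- sqrt(rowSums(v^2))
    n <- length(s)
    dot <- rowSums(v[-n, , drop = FALSE] * v[-1, , drop = FALSE])
    cosang <- dot / pmax(s[-n] * s[-1], 1e-12)
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi / tr$dt  # deg/s
    sp[[length(sp) + 1]] <- s
    av[[length(av) + 1]] <- ang
    yy[[length(yy) + 1]] <- tr$positions[, 2]
  }
  f <- function(x, br) {
    x <- pmin(pmax(unlist(x), br[1]), br[length(br)])
    cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE),
                    nbins = length(br) - 1)
    cnt / sum(cnt)
  }
  list(speed = f(sp, breaks$speed), angvel = f(av, breaks$angvel),
       y = f(yy, breaks$y))
}

#' Fit base-walker parameters by distribution matching
#'
#' Fits `(tau, eta, b)` so that the simulated speed, angular-velocity and
#' crosswind-position distributions match those of a reference trajectory
#' set: the objective is the sum of L2 distances between normalized
#' histograms, minimized by Nelder-Mead (log-scale parameters, clamped to the
#' search bounds) started from the best point of a coarse grid. Simulations
#' inside the objective use common random numbers (a fixed internal seed), so
#' the objective is deterministic.
#'
#' @param ref List of reference trajectories (at least 10).
#' @param tunnel,plume Environment for the fitting simulations.
#' @param dt Timestep of the fitting simulations.
#' @param n_sim Trajectories simulated per objective evaluation.
#' @param sim_duration Duration of each, seconds.
#' @param lower,upper Named search bounds for `tau`, `eta`, `b`.
#' @param seed Internal common-random-number seed.
#' @param maxit Nelder-Mead iteration cap; non-convergence raises an error
#'   carrying the best point found (condition field `best`).
#' @return A [walker_params()] with attributes `objective` and `convergence`.
#' @export
fit_base_walker <- function(ref, tunnel = wind_tunnel(),
                            plume = gaussian_plume(), dt = 0.01,
                            n_sim = 40, sim_duration = 6,
                            lower = c(tau = 0.05, eta = 0.05, b = 0.005),
                            upper = c(tau = 2.5, eta = 6, b = 2),
                            seed = 1L, maxit = 400) {
  ref <- as_traj_list(ref)
  if (length(ref) < 10) stop("need at least 10 reference trajectories")
  sp_max <- max(vapply(ref, function(tr) max(sqrt(rowSums(tr$velocities^2))),
                       0))
  breaks <- list(speed = seq(0, sp_max * 1.3, length.out = 31),
                 angvel = seq(0, 4000, length.out = 31),
                 y = seq(-tunnel$extent[2] / 2, tunnel$extent[2] / 2,
                         length.out = 31))
  ref_h <- walker_feature_hists(ref, breaks)
  clamp <- function(p) pmin(pmax(p, lower), upper)
  objective <- function(logp) {
    p <- clamp(exp(logp))
    pars <- walker_params(tau = p[1], eta = p[2], b = p[3], dt = dt)
    sim <- local({
      set.seed(seed)
      lapply(seq_len(n_sim), function(i)
        simulate_base_walker(sim_duration, pars, tunnel, plume,
                             id = sprintf("fit_%03d", i)))
    })
    sim_h <- walker_feature_hists(sim, breaks)
    sqrt(sum((sim_h$speed - ref_h$speed)^2)) +
      sqrt(sum((sim_h$angvel - ref_h$angvel)^2)) +
      sqrt(sum((sim_h$y - ref_h$y)^2))
  }
  grid <- expand.grid(tau = c(0.2, 0.42, 0.8), eta = c(1, 1.9, 3),
                      b = c(0.1, 0.25, 0.5))
  g_obj <- apply(grid, 1, function(p) objective(log(as.numeric(p))))
  p0 <- log(as.numeric(grid[which.min(g_obj), ]))
  fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  best <- clamp(exp(fit$par))
  if (fit$convergence != 0) {
    cond <- simpleError("fit_base_walker: optimizer did not converge")
    cond$best <- best
    stop(cond)
  }
  out <- walker_params(tau = best[1], eta = best[2], b = best[3], dt = dt)
  attr(out, "objective") <- fit$value
  attr(out, "convergence") <- fit$convergence
  out
}

#' Calibrate the centerline-inferring upwind gain
#'
#' The upwind drive of the centerline-inferring model is `k = k_star / |K|`.
#' This helper chooses `k_star` so that after `n_crossings` conjugate belief
#' updates (no memory decay) the drive equals a target amplitude --
#' by default the surge-cast model's peak surge of 0.8 m/s -- giving the two
#' augmented models comparable crossing-triggered dynamics.
#'
#' @param target Drive amplitude to match after `n_crossings` updates, m/s.
#' @param n_crossings Number of belief updates at which to match.
#' @param belief A [centerline_belief()] for the prior / likelihood variances.
#' @return The scalar `k_star` (units m^5/s given variances in m^2).
#' @export
calibrate_upwind_gain <- function(target = 0.8, n_crossings = 2,
                                  belief = centerline_belief()) {
  v <- belief$prior_var
  for (i in seq_len(n_crossings)) v <- 1 / (1 / v + 1 / belief$obs_var)
  target * prod(v)
}
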