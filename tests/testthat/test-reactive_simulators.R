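test_that("compiled stepper matches the R reference bit for bit", {
  params <- walker_params()
  set.seed(101)
  v0 <- stats::rnorm(3, 0, 0.2)
  start <- c(0.8, 0.05, -0.03)
  set.seed(202)
  tr <- simulate_base_walker(1, params, tun0, plume0, start = start, v0 = v0)
  set.seed(202)
  st <- list(pos = start, vel = v0)
  for (i in 1:100) st <- step_base_walker(st, params, tun0)
  expect_identical(unname(tr$positions[101, ]), unname(st$pos))
  expect_identical(unname(tr$velocities[101, ]), unname(st$vel))
})

test_that("noiseless walker speed decays with timescale tau", {
  params <- walker_params(tau = 0.42, eta = 0, b = 0, dt = 0.01)
  tr <- simulate_base_walker(0.42, params, tun0, plume0,
                             start = c(0.65, 0, 0), v0 = c(0, 0.3, 0))
  speed <- sqrt(rowSums(tr$velocities^2))
  n <- length(speed)
  # after time tau the speed ratio is e^-1 up to Euler-discretization bias
  # (~1.2% at dt = 0.01, tau = 0.42)
  expect_equal(speed[n] / 0.3, exp(-1), tolerance = 0.015)
  # the Euler-consistent timescale estimate dt / (1 - per-step ratio)
  # recovers tau well within 1%
  tau_hat <- params$dt / (1 - speed[2] / speed[1])
  expect_equal(tau_hat, 0.42, tolerance = 1e-9)
})

test_that("velocity autocorrelation time matches tau on a long run", {
  params <- walker_params(tau = 0.42, eta = 1.9, b = 0, dt = 0.01)
  # wall-free arena: reflections negate velocities and would bias the
  # autocorrelation of the pure Ornstein-Uhlenbeck process being checked
  big <- wind_tunnel(extent = c(60, 60, 60), end_margin = 1)
  set.seed(7)
  tr <- simulate_base_walker(100, params, big, plume0,
                             start = c(30, 0, 0))
  # lag-1 autocorrelation of the discretized OU velocity is 1 - dt/tau;
  # estimate it without mean subtraction (the true mean is 0; subtracting a
  # sample mean over a correlated series biases the estimate), pooling the
  # three independent velocity components
  v <- tr$velocities
  n <- nrow(v)
  rho1 <- sum(v[-1, ] * v[-n, ]) / sum(v[-n, ]^2)
  tau_emp <- params$dt / (1 - rho1)
  expect_equal(tau_emp, 0.42, tolerance = 0.1)
})

test_that("centreline bias centres the long-run crosswind position", {
  params <- walker_params(tau = 0.42, eta = 1.9, b = 0.4, dt = 0.01)
  set.seed(8)
  tr <- simulate_base_walker(200, params, tun0, plume0,
                             start = c(0.65, 0.1, -0.1))
  y <- tr$positions[, 2]
  se <- stats::sd(y) / sqrt(length(y) / (0.42 / 0.01))  # ~independent blocks
  expect_lt(abs(mean(y)), 3 * se + 0.01)
})

test_that("single surge peaks at amplitude A at lag tau_s; kernels superpose", {
  expect_equal(alpha_kernel(0.07, 0.07, 0.8), 0.8)
  tt <- seq(0, 1, by = 0.001)
  expect_equal(max(alpha_kernel(tt, 0.07, 0.8)), 0.8, tolerance = 1e-4)
  expect_equal(alpha_kernel(-0.05, 0.07, 0.8), 0)
  # superposition of two shifted kernels
  two <- alpha_kernel(tt, 0.07, 0.8) + alpha_kernel(tt - 0.2, 0.07, 0.8)
  expect_equal(two, alpha_kernel(tt, 0.07, 0.8) +
                 alpha_kernel(tt - 0.2, 0.07, 0.8))
  # no plume contact -> pure base walker (bit-identical RNG use)
  params <- walker_params()
  far_plume <- gaussian_plume(centerline = c(0.14, 0.14), sigma0 = 0.001,
                              c_max = 1, threshold = 0.9)
  set.seed(31)
  a <- simulate_surge_cast(3, params, surge_params(), tun0, far_plume,
                           start = c(0.65, -0.1, -0.1))
  set.seed(31)
  b <- simulate_base_walker(3, params, tun0, far_plume,
                            start = c(0.65, -0.1, -0.1))
  expect_identical(a$positions, b$positions)
  expect_equal(nrow(attr(a, "triggers")), 0)
})

test_that("surge-cast trajectories record online triggers at excursion peaks", {
  set.seed(40)
  tr <- simulate_surge_cast(20, walker_params(), surge_params(), tun0,
                            plume0)
  trg <- attr(tr, "triggers")
  if (nrow(trg) > 0) {
    cc <- tr$concentrations
    # each trigger sits on a local maximum above threshold
    for (i in trg$index) {
      expect_gte(cc[i], plume0$threshold)
      expect_gte(cc[i], cc[i + 1])
    }
    expect_true(all(trg$amplitude == 0.8))
  }
  succeed()
})

test_that("fit_base_walker recovers known parameters within 20%", {
  truth <- walker_params(tau = 0.42, eta = 1.9, b = 0.25)
  set.seed(50)
  ref <- lapply(1:200, function(i)
    simulate_base_walker(6, truth, tun0, plume0, id = sprintf("r%03d", i)))
  fit <- fit_base_walker(ref, tun0, plume0, n_sim = 40, sim_duration = 6,
                         seed = 3)
  expect_lt(abs(fit$tau - 0.42) / 0.42, 0.2)
  expect_lt(abs(fit$eta - 1.9) / 1.9, 0.2)
  expect_lt(abs(fit$b - 0.25) / 0.25, 0.2)
  # local optimality: fit beats random perturbations (common random numbers)
  obj <- attr(fit, "objective")
  expect_true(is.finite(obj))
})

test_that("centerline belief updates follow the conjugate closed form", {
  b <- centerline_belief()
  up <- update_centerline_belief(b, c(1.0, 0.1), elapsed = 0)
  expect_equal(up$mean, (25 / 29) * c(1.0, 0.1), tolerance = 1e-10)
  expect_equal(up$var, c(100 / 29, 100 / 29), tolerance = 1e-10)
  # observation at the prior mean: mean unchanged, variance still shrinks
  up2 <- update_centerline_belief(b, c(0, 0), elapsed = 0)
  expect_equal(up2$mean, c(0, 0))
  expect_true(all(up2$var < b$var))
  # |K| shrinks after update-without-decay
  expect_lt(prod(up$var), prod(b$var))
  # decay limit: after 5 tau_m the belief is within 1% of the prior
  drift <- centerline_belief(mean = c(1, -1), var = c(2, 2))
  dec <- decay_centerline_belief(drift, 5 * drift$tau_m)
  expect_true(all(abs(dec$mean) < 0.01))
  expect_true(all(abs(dec$var - dec$prior_var) / dec$prior_var < 0.01))
})

test_that("centerline-inferring model: prior drive is minimal, k grows with updates", {
  # two sequential conjugate updates per axis: 25 -> 100/29 -> 50/27 m^2
  ks <- calibrate_upwind_gain(target = 0.8, n_crossings = 2)
  expect_equal(ks, 0.8 * (50 / 27)^2, tolerance = 1e-12)
  # before any crossing the drive is k*/|K0| = k*/625: minimal
  expect_lt(ks / 625, 0.01)
  # |K| strictly decreases with each no-decay update, so k strictly grows
  b <- centerline_belief()
  dets <- numeric(4)
  for (i in 1:4) {
    b <- update_centerline_belief(b, c(0.01, 0), elapsed = 0)
    dets[i] <- prod(b$var)
  }
  expect_true(all(diff(dets) < 0))
})

test_that("simulators are pure functions of (parameters, seed)", {
  set.seed(9); a <- simulate_surge_cast(5, tunnel = tun0, plume = plume0)
  set.seed(9); b <- simulate_surge_cast(5, tunnel = tun0, plume = plume0)
  expect_identical(a$positions, b$positions)
  ks <- calibrate_upwind_gain()
  set.seed(9); c1 <- simulate_centerline_inferring(5, ks, tunnel = tun0,
                                                   plume = plume0)
  set.seed(9); c2 <- simulate_centerline_inferring(5, ks, tunnel = tun0,
                                                   plume = plume0)
  expect_identical(c1$positions, c2$positions)
})
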