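# shared fixtures: the default stated world used across tests
tun0 <- wind_tunnel()
plume0 <- gaussian_plume()
walker0 <- walker_params()

# small synthetic dataset cached across test files (fast: ~0.1 s)
synth_small <- function(seed = 1, n_traj = 120, ...) {
  generate_dataset(synthetic_effects(n_traj = n_traj, seed = seed, ...),
                   tun0, plume0, walker0)
}

# crossings of a dataset after the standard exclusions
crossings_of <- function(trajs, threshold = plume0$threshold) {
  apply_exclusions(extract_crossings(trajs, threshold), exclusion_policy(),
                   tun0)
}

# hand-built two-sample trajectory for I/O round trips
toy_trajectory <- function(id = "toy", n = 50, dt = 0.01, seed = 7) {
  set.seed(seed)
  pos <- cbind(seq(0.4, 0.6, length.out = n),
               0.05 * sin(seq(0, 4 * pi, length.out = n)),
               rep(0.01, n))
  vel <- cbind(rep(0.2, n), 0.1 * cos(seq(0, 4 * pi, length.out = n)),
               rep(0, n))
  trajectory(id, dt, pos, vel, conc_raw(pos, plume0))
}

# trajectory with a prescribed concentration series (positions/velocities
# chosen mid-tunnel, crosswind heading, so nothing is excluded by accident)
traj_with_conc <- function(conc, dt = 0.01, id = "conc", vx = 0) {
  n <- length(conc)
  pos <- cbind(rep(0.65, n), seq(-0.05, 0.05, length.out = n), rep(0, n))
  vel <- cbind(rep(vx, n), rep(0.3, n), rep(0, n))
  trajectory(id, dt, pos, vel, conc)
}
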