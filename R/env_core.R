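#' Wind-tunnel geometry
#'
#' Describes the flyable section of the wind tunnel and the coordinate frame
#' used throughout the package: `x` is the long (wind) axis with +x pointing
#' downwind, `x = 0` at the upwind wall of the flyable section; `y` and `z`
#' are crosswind axes centred at 0, so the flyable volume is
#' `[0, Lx] x [-Ly/2, Ly/2] x [-Lz/2, Lz/2]`. The upwind unit vector is
#' `(-1, 0, 0)`.
#'
#' @param extent Numeric length-3, flyable extents in metres
#'   (default `c(1.3, 0.3, 0.3)`).
#' @param wind_speed Wind speed V in m/s (along +x, downwind).
#' @param end_margin Margin in metres at each end of the tunnel used by the
#'   crossing exclusion rules (default 0.30).
#' @return An object of class `wind_tunnel`.
#' @examples
#' tun <- wind_tunnel()
#' tun$extent
#' @export
wind_tunnel <- function(extent = c(1.3, 0.3, 0.3), wind_speed = 0.4,
                        end_margin = 0.30) {
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 3, all(is.finite(extent)), all(extent > 0))
  if (!is.finite(wind_speed) || wind_speed < 0)
    stop("wind_speed must be a finite non-negative number")
  if (!is.finite(end_margin) || end_margin <= 0 || end_margin >= extent[1] / 2)
    stop("end_margin must satisfy 0 < end_margin < extent[1]/2")
  structure(list(extent = extent, wind_speed = wind_speed,
                 end_margin = end_margin),
            class = "wind_tunnel")
}

#' @export
print.wind_tunnel <- function(x, ...) {
  cat(sprintf("wind_tunnel: %.2f x %.2f x %.2f m, V = %.2f m/s, end margin %.2f m\n",
              x$extent[1], x$extent[2], x$extent[3], x$wind_speed, x$end_margin))
  invisible(x)
}

# axis-wise position bounds of the flyable volume
tunnel_bounds <- function(tunnel) {
  cbind(lo = c(0, -tunnel$extent[2] / 2, -tunnel$extent[3] / 2),
        hi = c(tunnel$extent[1], tunnel$extent[2] / 2, tunnel$extent[3] / 2))
}

position_inside <- function(pos, tunnel, tol = 1e-9) {
  b <- tunnel_bounds(tunnel)
  all(pos >= matrix(b[, "lo"], nrow(pos), 3, byrow = TRUE) - tol) &&
    all(pos <= matrix(b[, "hi"], nrow(pos), 3, byrow = TRUE) + tol)
}

#' Stationary Gaussian plume
#'
#' Axial plume along the wind (x) axis with a radially symmetric Gaussian
#' cross-section: concentration is maximal on the centreline `(y_c, z_c)` and
#' falls off with radial distance as
#' `c(x, y, z) = c_max * exp(-((y - y_c)^2 + (z - z_c)^2) / (2 sigma(x)^2))`
#' with `sigma(x) = sigma0 + widen_rate * x`. `widen_rate = 0` describes the
#' laminar (non-widening) case; a positive value lets the plume widen slightly
#' downwind. Concentrations are carried in arbitrary, dataset-relative units,
#' so the crossing-detection threshold is expressed in the same units.
#'
#' @param centerline Length-2 `(y_c, z_c)` centreline position in metres.
#' @param sigma0 Cross-sectional standard deviation at `x = 0`, metres.
#' @param widen_rate d(sigma)/dx, dimensionless (default 0).
#' @param c_max Peak concentration, arbitrary units.
#' @param threshold Crossing-detection threshold, same units as `c_max`.
#' @return An object of class `gaussian_plume`.
#' @examples
#' pl <- gaussian_plume()
#' concentration_at(c(0.5, 0, 0), pl, wind_tunnel())
#' @export
gaussian_plume <- function(centerline = c(0, 0), sigma0 = 0.02,
                           widen_rate = 0, c_max = 1, threshold = 0.1) {
  centerline <- as.numeric(centerline)
  stopifnot(length(centerline) == 2, all(is.finite(centerline)))
  if (!is.finite(sigma0) || sigma0 <= 0) stop("sigma0 must be > 0")
  if (!is.finite(widen_rate) || widen_rate < 0) stop("widen_rate must be >= 0")
  if (!is.finite(c_max) || c_max <= 0) stop("c_max must be > 0")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= c_max)
    stop("threshold must satisfy 0 < threshold < c_max")
  structure(list(centerline = centerline, sigma0 = sigma0,
                 widen_rate = widen_rate, c_max = c_max,
                 threshold = threshold),
            class = "gaussian_plume")
}

#' @export
print.gaussian_plume <- function(x, ...) {
  cat(sprintf(
    "gaussian_plume: centerline (%.3f, %.3f) m, sigma0 %.3f m, widen %.3g, c_max %.3g, threshold %.3g\n",
    x$centerline[1], x$centerline[2], x$sigma0, x$widen_rate, x$c_max,
    x$threshold))
  invisible(x)
}

#' Plume concentration at a position
#'
#' Evaluates the Gaussian plume model at one or more positions. Deterministic;
#' positions must lie inside the flyable volume.
#'
#' @param position Numeric length-3 vector, or an n x 3 matrix of positions
#'   (metres).
#' @param plume A [gaussian_plume()].
#' @param tunnel A [wind_tunnel()]; positions are checked against its bounds.
#' @return Concentration(s) in the plume's arbitrary units.
#' @export
concentration_at <- function(position, plume, tunnel) {
  if (is.null(dim(position))) position <- matrix(position, nrow = 1)
  stopifnot(ncol(position) == 3)
  if (!position_inside(position, tunnel))
    stop("position outside the flyable volume")
  conc_raw(position, plume)
}

# no domain check; used by simulators where positions are inside by
# construction
conc_raw <- function(position, plume) {
  sig <- plume$sigma0 + plume$widen_rate * position[, 1]
  r2 <- (position[, 2] - plume$centerline[1])^2 +
        (position[, 3] - plume$centerline[2])^2
  plume$c_max * exp(-r2 / (2 * sig^2))
}

#' Heading of a velocity vector
#'
#' Heading is the unsigned angle, in degrees, between a velocity vector and
#' the upwind direction `(-1, 0, 0)`: 0 deg means flying directly upwind,
#' 90 deg crosswind, 180 deg directly downwind. Computed as the arccosine of
#' the normalized dot product, so it is invariant to positive rescaling of
#' the velocity.
#'
#' @param velocity Numeric length-3 vector or an n x 3 matrix of velocities
#'   (m/s).
#' @param na_zero If `TRUE`, zero-speed rows yield `NA` (to be masked by the
#'   caller) instead of an error.
#' @return Heading(s) in degrees, in `[0, 180]`.
#' @examples
#' heading_of(c(-1, 0, 0)) # 0: directly upwind
#' heading_of(c(0, 1, 0))  # 90: crosswind
#' @export
heading_of <- function(velocity, na_zero = FALSE) {
  if (is.null(dim(velocity))) velocity <- matrix(velocity, nrow = 1)
  stopifnot(ncol(velocity) == 3)
  speed <- sqrt(rowSums(velocity^2))
  zero <- speed == 0 | !is.finite(speed)
  if (any(zero) && !na_zero)
    stop("heading undefined for zero-speed velocity; mask such samples")
  # upwind unit vector is (-1, 0, 0), so cos(heading) = -vx / |v|
  ang <- rep(NA_real_, length(speed))
  ok <- !zero
  ang[ok] <- acos(pmin(1, pmax(-1, -velocity[ok, 1] / speed[ok]))) * 180 / pi
  if (length(ang) == 1) ang[[1]] else ang
}

#' Flight trajectory
#'
#' A uniformly sampled time series of one flight: 3D position (m), 3D
#' velocity (m/s) and the experienced odor concentration (arbitrary units),
#' sampled every `dt` seconds starting at `takeoff_time`.
#'
#' @param id Trajectory identifier (string).
#' @param dt Sampling interval in seconds.
#' @param positions n x 3 matrix of positions (m).
#' @param velocities n x 3 matrix of velocities (m/s).
#' @param concentrations Numeric vector of length n (a.u.).
#' @param takeoff_time Time of the first sample, seconds (default 0).
#' @param tunnel Optional [wind_tunnel()]; if supplied, positions are checked
#'   to lie inside the flyable volume (tolerance 1e-9 m).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(id, dt, positions, velocities, concentrations,
                       takeoff_time = 0, tunnel = NULL) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  concentrations <- as.numeric(concentrations)
  n <- nrow(positions)
  if (n < 2) stop("trajectory must have at least 2 samples")
  if (nrow(velocities) != n || length(concentrations) != n)
    stop("positions, velocities and concentrations must have equal length")
  if (ncol(positions) != 3 || ncol(velocities) != 3)
    stop("positions and velocities must have 3 columns")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.null(tunnel) && !position_inside(positions, tunnel))
    stop(sprintf("trajectory '%s': positions outside the flyable volume", id))
  structure(list(id = as.character(id), dt = dt, positions = positions,
                 velocities = velocities, concentrations = concentrations,
                 takeoff_time = takeoff_time),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s': %d samples at dt = %g s (%.2f s)\n",
              x$id, nrow(x$positions), x$dt, (nrow(x$positions) - 1) * x$dt))
  invisible(x)
}

traj_times <- function(traj) {
  traj$takeoff_time + (seq_len(nrow(traj$positions)) - 1) * traj$dt
}

as_traj_list <- function(x) {
  if (inherits(x, "trajectory")) list(x)
  else if (is.list(x) && all(vapply(x, inherits, TRUE, "trajectory"))) x
  else stop("expected a trajectory or a list of trajectories")
}

#' Read / write trajectory tables
#'
#' The on-disk format is a flat CSV table with one row per timestep and
#' columns `traj_id, t, x, y, z, vx, vy, vz, odor`; rows of one trajectory
#' are contiguous and time-sorted. The round trip is lossless to floating
#' point representation.
#'
#' @param trajs A trajectory or list of trajectories.
#' @param path File path.
#' @return `read_trajectories` returns a (possibly empty) named list of
#'   `trajectory` objects; `write_trajectories` returns `path` invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  trajs <- as_traj_list(trajs)
  tabs <- lapply(trajs, function(tr) {
    data.table::data.table(
      traj_id = tr$id, t = traj_times(tr),
      x = tr$positions[, 1], y = tr$positions[, 2], z = tr$positions[, 3],
      vx = tr$velocities[, 1], vy = tr$velocities[, 2],
      vz = tr$velocities[, 3], odor = tr$concentrations)
  })
  tab <- if (length(tabs)) data.table::rbindlist(tabs) else
    data.table::data.table(traj_id = character(), t = numeric(),
                           x = numeric(), y = numeric(), z = numeric(),
                           vx = numeric(), vy = numeric(), vz = numeric(),
                           odor = numeric())
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tab <- data.table::fread(path)
  if (nrow(tab) == 0) return(list())
  need <- c("traj_id", "t", "x", "y", "z", "vx", "vy", "vz", "odor")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trajectory table is missing columns: ", paste(miss, collapse = ", "))
  ids <- unique(tab$traj_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$traj_id == id, ]
    dts <- diff(sub$t)
    if (any(dts <= 0))
      stop(sprintf("trajectory '%s': non-monotone time column", id))
    if (diff(range(dts)) > 1e-6 * mean(dts))
      stop(sprintf("trajectory '%s': mixed sampling interval", id))
    trajectory(id = id, dt = mean(dts),
               positions = cbind(sub$x, sub$y, sub$z),
               velocities = cbind(sub$vx, sub$vy, sub$vz),
               concentrations = sub$odor, takeoff_time = sub$t[1])
  })
  names(out) <- ids
  out
}

#' Read / write an experiment configuration (YAML)
#'
#' Configurations are plain named lists (tunnel extents, wind speed, plume
#' parameters, crossing threshold, exclusion margins, RNG seed, ...)
#' serialized as YAML so every run can store its resolved configuration next
#' to its outputs.
#'
#' @param config Named list.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)
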