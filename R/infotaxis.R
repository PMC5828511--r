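#' Lattice over the flyable volume
#'
#' Regular 3D lattice the infotaxis agent moves on: x points every `spacing`
#' metres from the upwind wall, y and z symmetric about 0 so the lattice
#' always contains the tunnel (and plume) centreline. Default spacing 2 cm.
#'
#' @param tunnel A [wind_tunnel()].
#' @param spacing Lattice spacing, metres.
#' @return Object of class `infotaxis_lattice` with coordinate vectors,
#'   dimensions and per-cell index/coordinate tables.
#' @export
infotaxis_lattice <- function(tunnel = wind_tunnel(), spacing = 0.02) {
  stopifnot(spacing > 0)
  ext <- tunnel$extent
  x <- seq(0, by = spacing, length.out = floor(ext[1] / spacing) + 1)
  my <- floor(ext[2] / 2 / spacing)
  mz <- floor(ext[3] / 2 / spacing)
  y <- spacing * (-my:my)
  z <- spacing * (-mz:mz)
  nx <- length(x); ny <- length(y); nz <- length(z)
  idx <- as.matrix(expand.grid(ix = seq_len(nx), iy = seq_len(ny),
                               iz = seq_len(nz)))
  coords <- cbind(x[idx[, 1]], y[idx[, 2]], z[idx[, 3]])
  structure(list(x = x, y = y, z = z, nx = nx, ny = ny, nz = nz,
                 spacing = spacing, idx = idx, coords = coords,
                 ncell = nx * ny * nz),
            class = "infotaxis_lattice")
}

#' @export
print.infotaxis_lattice <- function(x, ...) {
  cat(sprintf("infotaxis_lattice: %d x %d x %d cells at %g m spacing\n",
              x$nx, x$ny, x$nz, x$spacing))
  invisible(x)
}

cell_linear <- function(lat, i, j, k) {
  i + lat$nx * ((j - 1) + lat$ny * (k - 1))
}

#' Internal turbulent-plume model of the infotaxis agent
#'
#' Parameters of the time-averaged hit-rate likelihood the agent assumes:
#' effective turbulent diffusivity `D` (default 0.09 m^2/s), source emission
#' rate `R_emit` (default 1000 Hz), wind speed `V` (+x downwind), odor
#' particle lifetime `tau_p` (default infinite, giving correlation length
#' `lambda = 2 D / V`), detector size `a_det` (default 2 mm, the scale of an
#' insect antenna) and the decision clock `dt` (default one lattice cell per step at
#' a typical 0.4 m/s flight speed).
#'
#' @param D Turbulent diffusivity, m^2/s.
#' @param R_emit Source emission rate, Hz.
#' @param V Wind speed, m/s.
#' @param tau_p Odor particle lifetime, seconds (`Inf` allowed).
#' @param a_det Detector size, metres.
#' @param dt Time per lattice step, seconds.
#' @return Object of class `infotaxis_model` with the derived correlation
#'   length `lambda`.
#' @export
infotaxis_model <- function(D = 0.09, R_emit = 1000, V = 0.4, tau_p = Inf,
                            a_det = 0.002, dt = 0.05) {
  stopifnot(D > 0, R_emit > 0, V > 0, a_det > 0, dt > 0, tau_p > 0)
  lambda <- if (is.infinite(tau_p)) 2 * D / V else
    sqrt(D * tau_p / (1 + V^2 * tau_p / (4 * D)))
  structure(list(D = D, R_emit = R_emit, V = V, tau_p = tau_p,
                 a_det = a_det, dt = dt, lambda = lambda),
            class = "infotaxis_model")
}

#' @export
print.infotaxis_model <- function(x, ...) {
  cat(sprintf(
    "infotaxis_model: D = %g m^2/s, R = %g Hz, V = %g m/s, lambda = %g m, dt = %g s\n",
    x$D, x$R_emit, x$V, x$lambda, x$dt))
  invisible(x)
}

#' Time-averaged hit rate at a displacement from a candidate source
#'
#' The turbulent-plume likelihood kernel:
#' `rate = (R_emit * a_det / |dr|) * exp(V * dx_down / (2 D) - |dr| / lambda)`
#' where `dr = agent - source` and `dx_down` is its component along +x
#' (downwind). The rate is highest directly downwind of the source. The
#' per-step hit probability is `1 - exp(-rate * dt)`.
#'
#' @param agent Length-3 agent position (m), or n x 3 matrix.
#' @param source Length-3 candidate source position, or n x 3 matrix.
#' @param model An [infotaxis_model()].
#' @return Hit rate(s), Hz.
#' @export
hit_rate <- function(agent, source, model) {
  if (is.null(dim(agent))) agent <- matrix(agent, nrow = 1)
  if (is.null(dim(source))) source <- matrix(source, nrow = 1)
  if (nrow(agent) == 1 && nrow(source) > 1)
    agent <- agent[rep(1, nrow(source)), , drop = FALSE]
  dr <- agent - source
  d <- sqrt(rowSums(dr^2))
  if (any(d == 0)) stop("agent and source cells coincide; handled by the found branch")
  model$R_emit * model$a_det / d *
    exp(model$V * dr[, 1] / (2 * model$D) - d / model$lambda)
}

#' Per-step hit-probability field over lattice displacements
#'
#' Precomputes `1 - exp(-rate * dt)` for every possible (agent - source)
#' displacement on the lattice; [belief_update()] and [choose_move()] take
#' this field. The zero displacement is assigned probability 1 (an agent at
#' the source cannot miss), which implements the "found" likelihood branch.
#'
#' @param lattice An [infotaxis_lattice()].
#' @param model An [infotaxis_model()].
#' @return 3D array over displacements.
#' @export
hit_prob_field <- function(lattice, model) {
  dx <- lattice$spacing * (-(lattice$nx - 1)):(lattice$nx - 1)
  dy <- lattice$spacing * (-(lattice$ny - 1)):(lattice$ny - 1)
  dz <- lattice$spacing * (-(lattice$nz - 1)):(lattice$nz - 1)
  g <- expand.grid(dx = dx, dy = dy, dz = dz)
  d <- sqrt(g$dx^2 + g$dy^2 + g$dz^2)
  rate <- ifelse(d > 0,
                 model$R_emit * model$a_det / pmax(d, 1e-12) *
                   exp(pmin(model$V * g$dx / (2 * model$D) -
                            d / model$lambda, 700)),
                 Inf)
  p <- 1 - exp(-rate * model$dt)
  p[d == 0] <- 1
  array(p, dim = c(length(dx), length(dy), length(dz)))
}

# per-source-cell hit probability seen from agent cell (ai, aj, ak)
agent_hit_probs <- function(pf, lattice, ai, aj, ak) {
  di <- ai - lattice$idx[, 1] + lattice$nx
  dj <- aj - lattice$idx[, 2] + lattice$ny
  dk <- ak - lattice$idx[, 3] + lattice$nz
  d1 <- 2 * lattice$nx - 1; d2 <- 2 * lattice$ny - 1
  pf[di + d1 * ((dj - 1) + d2 * (dk - 1))]
}

#' Shannon entropy of a probability vector, in nats
#'
#' `S = -sum(p log p)` with the `0 log 0 = 0` convention; `S = 0` iff the
#' distribution is a point mass.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Bayesian belief update from a hit or miss
#'
#' Multiplies each candidate-source cell's probability by the per-step hit
#' probability (hit) or its complement (miss) of the agent's current cell,
#' then renormalizes. The agent's own cell carries the "found" likelihood
#' (hit probability 1), so a miss there eliminates it.
#'
#' @param belief Probability vector over lattice cells (sums to 1).
#' @param agent_cell Integer length-3 lattice indices `(ix, iy, iz)` of the
#'   agent.
#' @param observation `"hit"` or `"miss"`.
#' @param pf Precomputed [hit_prob_field()].
#' @param lattice An [infotaxis_lattice()].
#' @return Updated, normalized belief vector.
#' @export
belief_update <- function(belief, agent_cell, observation, pf, lattice) {
  p <- agent_hit_probs(pf, lattice, agent_cell[1], agent_cell[2],
                       agent_cell[3])
  w <- if (identical(observation, "hit")) belief * p else belief * (1 - p)
  s <- sum(w)
  if (s <= 0) stop("numerically degenerate belief: observation has zero likelihood")
  w / s
}

# expected posterior entropy of observing at candidate cell (ci, cj, ck)
expected_entropy_at <- function(belief, pf, lattice, ci, cj, ck) {
  p <- agent_hit_probs(pf, lattice, ci, cj, ck)
  p_found <- belief[cell_linear(lattice, ci, cj, ck)]
  wh <- belief * p
  ph <- sum(wh)
  s_hit <- if (ph > 0) shannon_entropy(wh / ph) else 0
  wm <- belief * (1 - p)
  pm <- sum(wm)
  s_miss <- if (pm > 0) shannon_entropy(wm / pm) else 0
  (1 - p_found) * (ph * s_hit + pm * s_miss)
}

# candidate moves in the documented tie-break order
move_offsets <- rbind(stay = c(0, 0, 0),
                      xm = c(-1, 0, 0), xp = c(1, 0, 0),
                      ym = c(0, -1, 0), yp = c(0, 1, 0),
                      zm = c(0, 0, -1), zp = c(0, 0, 1))

#' Greedy infotaxis move choice
#'
#' Evaluates the expected posterior entropy
#' `E[S'|j] = (1 - p_found(j)) * (p_hit(j) S_hit(j) + (1 - p_hit(j)) S_miss(j))`
#' for staying and for each of the six lattice neighbours (the found branch
#' contributes zero entropy), with the hit probability marginalized over the
#' current belief, and returns the minimizer. Ties (within 1e-12) are broken
#' first toward the candidate with the larger posterior source mass (so a
#' point-mass belief at a neighbour attracts the agent instead of tying with
#' "stay", whose expected entropy is also zero there), then by the fixed
#' preference order stay, -x, +x, -y, +y, -z, +z.
#'
#' @inheritParams belief_update
#' @return List with `cell` (chosen indices), `move` (offset name) and
#'   `expected_entropy` (named vector over candidates, NA if off-lattice).
#' @export
choose_move <- function(belief, agent_cell, pf, lattice) {
  ee <- rep(NA_real_, nrow(move_offsets))
  pfound <- rep(-1, nrow(move_offsets))
  names(ee) <- rownames(move_offsets)
  for (m in seq_len(nrow(move_offsets))) {
    cand <- agent_cell + move_offsets[m, ]
    if (cand[1] < 1 || cand[1] > lattice$nx || cand[2] < 1 ||
        cand[2] > lattice$ny || cand[3] < 1 || cand[3] > lattice$nz) next
    ee[m] <- expected_entropy_at(belief, pf, lattice, cand[1], cand[2],
                                 cand[3])
    pfound[m] <- belief[cell_linear(lattice, cand[1], cand[2], cand[3])]
  }
  best <- min(ee, na.rm = TRUE)
  tied <- which(!is.na(ee) & ee <= best + 1e-12)
  pick <- tied[which.max(pfound[tied])]  # which.max: first on exact ties
  list(cell = agent_cell + move_offsets[pick, ],
       move = rownames(move_offsets)[pick], expected_entropy = ee)
}

#' Run one infotaxis trajectory
#'
#' Alternates deterministic observation (hit iff the agent's cell centre is
#' inside the discretized laminar plume, i.e. concentration at or above the
#' plume threshold), Bayesian belief update, and greedy expected-entropy
#' move choice, starting from a uniform belief over the lattice. The run
#' stops after `n_steps` steps or as soon as the posterior mass at the
#' agent's cell exceeds `found_threshold`. The lattice path is emitted as a
#' standard continuous-time trajectory (cell centres at `model$dt` spacing,
#' finite-difference velocities with the last nonzero displacement carried
#' through "stay" steps, true-plume concentrations), so the crossing
#' extractor applies unchanged.
#'
#' @param start Length-3 start position (m; snapped to the nearest cell) or
#'   integer cell indices.
#' @param n_steps Number of decision steps (`>= 1`).
#' @param model An [infotaxis_model()].
#' @param plume The true [gaussian_plume()].
#' @param tunnel A [wind_tunnel()].
#' @param lattice An [infotaxis_lattice()]; defaults to `tunnel` at 2 cm.
#' @param found_threshold Posterior-mass stopping criterion.
#' @param id Trajectory id.
#' @param engine `"cpp"` (compiled fast path, default) or `"r"` (reference
#'   implementation); both consume the RNG identically and produce the same
#'   paths.
#' @return A [trajectory()] with attribute `"infotaxis"`: list with `hits`
#'   (logical), `entropy` (nats, per step), `found` (flag) and `path`
#'   (cell indices).
#' @export
run_infotaxis <- function(start, n_steps, model = infotaxis_model(),
                          plume = gaussian_plume(), tunnel = wind_tunnel(),
                          lattice = NULL, found_threshold = 0.95,
                          id = "infotaxis", engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(lattice)) lattice <- infotaxis_lattice(tunnel)
  stopifnot(n_steps >= 1)
  if (is.integer(start) && length(start) == 3) {
    cell <- start
  } else {
    cell <- c(which.min(abs(lattice$x - start[1])),
              which.min(abs(lattice$y - start[2])),
              which.min(abs(lattice$z - start[3])))
  }
  pf <- attr(lattice, "pf_cache")
  if (is.null(pf) || !identical(attr(pf, "model"), unclass(model))) {
    pf <- hit_prob_field(lattice, model)
    attr(pf, "model") <- unclass(model)
  }
  in_plume <- conc_raw(lattice$coords, plume) >= plume$threshold
  if (engine == "cpp") {
    lp <- log(pf)
    l1p <- ifelse(pf < 1, log1p(-pf), 0)
    res <- run_infotaxis_cpp(as.integer(cell), as.integer(n_steps),
                             as.numeric(pf), as.numeric(lp),
                             as.numeric(l1p),
                             c(lattice$nx, lattice$ny, lattice$nz),
                             in_plume, found_threshold)
    path <- res$path; hits <- res$hits; entropy <- res$entropy
    used <- res$used; found <- res$found
  } else {
    belief <- rep(1 / lattice$ncell, lattice$ncell)
    path <- matrix(0L, n_steps + 1, 3)
    hits <- logical(n_steps)
    entropy <- numeric(n_steps)
    path[1, ] <- cell
    found <- FALSE
    used <- n_steps
    for (s in seq_len(n_steps)) {
      hit <- in_plume[cell_linear(lattice, cell[1], cell[2], cell[3])]
      hits[s] <- hit
      belief <- belief_update(belief, cell, if (hit) "hit" else "miss", pf,
                              lattice)
      entropy[s] <- shannon_entropy(belief)
      if (belief[cell_linear(lattice, cell[1], cell[2], cell[3])] >
          found_threshold) {
        found <- TRUE; used <- s; break
      }
      mv <- choose_move(belief, cell, pf, lattice)
      gain <- entropy[s] - min(mv$expected_entropy, na.rm = TRUE)
      if (mv$move == "stay" && gain < 1e-10) {
        # degenerate belief: no move offers information gain, so the greedy
        # rule would camp forever. Exploit instead: walk toward the belief
        # mode along a noisy straight line (axis sampled proportional to
        # the remaining displacement); a miss at the believed source then
        # eliminates it, restarting the search.
        mode_cell <- lattice$idx[which.max(belief), ]
        d <- mode_cell - cell
        tot <- sum(abs(d))
        if (tot > 0) {
          u <- stats::runif(1) * tot
          ax <- which(u < cumsum(abs(d)))[1]
          step <- c(0L, 0L, 0L); step[ax] <- sign(d[ax])
          cell <- cell + step
        }
      } else {
        cell <- mv$cell
      }
      path[s + 1, ] <- cell
    }
    storage.mode(path) <- "integer"
  }
  path <- path[seq_len(used + ifelse(found, 0, 1)), , drop = FALSE]
  if (nrow(path) < 2) path <- rbind(path, path)  # degenerate 1-step run
  pos <- cbind(lattice$x[path[, 1]], lattice$y[path[, 2]],
               lattice$z[path[, 3]])
  n <- nrow(pos)
  vel <- rbind(diff(pos) / model$dt, matrix(NA_real_, 1, 3))
  vel[n, ] <- vel[n - 1, ]
  # carry the last nonzero displacement through "stay" steps
  nzero <- rowSums(vel^2) == 0
  if (any(nzero)) {
    lastv <- NULL
    for (i in seq_len(n)) {
      if (!nzero[i]) lastv <- vel[i, ]
      else if (!is.null(lastv)) vel[i, ] <- lastv
    }
    # leading stays: backfill from the first nonzero displacement
    first_nz <- which(!nzero)[1]
    if (!is.na(first_nz) && first_nz > 1)
      vel[seq_len(first_nz - 1), ] <- matrix(vel[first_nz, ], first_nz - 1,
                                             3, byrow = TRUE)
  }
  tr <- trajectory(id = id, dt = model$dt, positions = pos,
                   velocities = vel, concentrations = conc_raw(pos, plume))
  attr(tr, "infotaxis") <- list(hits = hits[seq_len(used)],
                                entropy = entropy[seq_len(used)],
                                found = found, path = path)
  tr
}

#' Simulate a batch of infotaxis trajectories
#'
#' By default, starts are drawn uniformly over the lattice and run lengths
#' log-uniformly in `duration_range` (default 10-60 s): infotaxis needs
#' extended multi-encounter runs for its history dependence to express
#' itself, mirroring the long empirical flights such simulations are
#' matched against. Alternatively, pass `match_to` (a list of trajectories,
#' e.g. a synthetic dataset): each run then starts at the matched
#' trajectory's discretized start position and lasts for the number of
#' lattice points that trajectory traversed (its path length divided by the
#' lattice spacing).
#'
#' @inheritParams run_infotaxis
#' @param n_runs Number of trajectories (ignored if `match_to` is given).
#' @param seed RNG seed (optional).
#' @param duration_range Log-uniform duration range, seconds.
#' @param match_to Optional trajectory list to draw starts and run lengths
#'   from.
#' @return Named list of trajectories (each with the `"infotaxis"` sidecar
#'   attribute).
#' @export
simulate_batch_infotaxis <- function(n_runs, model = infotaxis_model(),
                                     plume = gaussian_plume(),
                                     tunnel = wind_tunnel(), lattice = NULL,
                                     seed = NULL,
                                     duration_range = c(10, 60),
                                     match_to = NULL,
                                     found_threshold = 0.95) {
  if (is.null(lattice)) lattice <- infotaxis_lattice(tunnel)
  if (!is.null(seed)) set.seed(seed)
  pf <- hit_prob_field(lattice, model)
  attr(pf, "model") <- unclass(model)
  attr(lattice, "pf_cache") <- pf
  if (!is.null(match_to)) {
    match_to <- as_traj_list(match_to)
    n_runs <- length(match_to)
  }
  out <- lapply(seq_len(n_runs), function(i) {
    if (is.null(match_to)) {
      cell <- c(sample.int(lattice$nx, 1), sample.int(lattice$ny, 1),
                sample.int(lattice$nz, 1))
      n_steps <- max(2L, round(draw_duration(duration_range) / model$dt))
      start <- as.integer(cell)
    } else {
      tr <- match_to[[i]]
      start <- tr$positions[1, ]
      pathlen <- sum(sqrt(rowSums(diff(tr$positions)^2)))
      n_steps <- max(2L, round(pathlen / lattice$spacing))
    }
    run_infotaxis(start, n_steps, model, plume, tunnel, lattice,
                  found_threshold, id = sprintf("infotaxis_%04d", i))
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}
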