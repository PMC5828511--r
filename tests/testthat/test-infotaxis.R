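# small lattice + model used throughout: cheap but structurally complete
it_lattice <- infotaxis_lattice(tun0, spacing = 0.04)
it_plume <- gaussian_plume(sigma0 = 0.02)
it_model <- infotaxis_model(V = 0.4, a_det = 0.002,
                            dt = it_lattice$spacing / 0.4)
it_pf <- hit_prob_field(it_lattice, it_model)

test_that("hit rate has the stated closed form and asymmetries", {
  mod <- infotaxis_model(D = 0.09, R_emit = 1000, V = 0.4, a_det = 0.01)
  expect_equal(mod$lambda, 2 * 0.09 / 0.4)
  # on-axis directly downwind with tau_p -> Inf: exponent cancels exactly
  r <- hit_rate(c(0.9, 0, 0), c(0.4, 0, 0), mod)
  expect_equal(r, 1000 * 0.01 / 0.5, tolerance = 1e-12)
  # downwind / upwind ratio at equal distance = exp(V |dx| / D)
  rd <- hit_rate(c(0.9, 0, 0), c(0.4, 0, 0), mod)
  ru <- hit_rate(c(0.4, 0, 0), c(0.9, 0, 0), mod)
  expect_equal(rd / ru, exp(0.4 * 0.5 / 0.09), tolerance = 1e-9)
  # strictly decreasing with crosswind distance at fixed x
  ys <- seq(0.02, 0.14, by = 0.02)
  rr <- hit_rate(cbind(0.9, ys, 0), matrix(c(0.4, 0, 0), length(ys), 3,
                                           byrow = TRUE), mod)
  expect_true(all(diff(rr) < 0))
  # finite particle lifetime shortens lambda
  expect_lt(infotaxis_model(tau_p = 1)$lambda, mod$lambda)
  expect_error(hit_rate(c(0.4, 0, 0), c(0.4, 0, 0), mod), "found")
})

test_that("belief updates conserve mass and behave like Bayes rule", {
  ncell <- it_lattice$ncell
  unif <- rep(1 / ncell, ncell)
  agent <- c(10L, 4L, 4L)
  up_miss <- belief_update(unif, agent, "miss", it_pf, it_lattice)
  up_hit <- belief_update(unif, agent, "hit", it_pf, it_lattice)
  expect_equal(sum(up_miss), 1, tolerance = 1e-12)
  expect_equal(sum(up_hit), 1, tolerance = 1e-12)
  # miss eliminates the agent's own cell (found likelihood = 1)
  own <- agent[1] + it_lattice$nx *
    ((agent[2] - 1) + it_lattice$ny * (agent[3] - 1))
  expect_equal(up_miss[own], 0)
  # under a miss, relative mass loss is monotone in the per-step hit
  # probability of each source cell
  pvec <- plumecross:::agent_hit_probs(it_pf, it_lattice, agent[1],
                                       agent[2], agent[3])
  ratio <- up_miss / unif
  ord <- order(pvec)
  expect_true(all(diff(ratio[ord]) < 1e-12))
  # a miss lowers entropy relative to uniform (strict: likelihood varies)
  expect_lt(shannon_entropy(up_miss), log(ncell))
  # point-mass belief is unchanged by any observation
  point <- rep(0, ncell); point[500] <- 1
  expect_equal(belief_update(point, c(3L, 3L, 3L), "miss", it_pf,
                             it_lattice)[500], 1)
  expect_equal(belief_update(point, c(3L, 3L, 3L), "hit", it_pf,
                             it_lattice)[500], 1)
  # impossible observation -> degeneracy error
  expect_error(belief_update(point, it_lattice$idx[500, ], "miss", it_pf,
                             it_lattice), "degenerate")
})

test_that("greedy move choice minimizes expected entropy with documented ties", {
  ncell <- it_lattice$ncell
  # point mass at a neighbouring cell -> that move chosen, E = 0
  agent <- c(10L, 4L, 4L)
  nb <- agent + c(1L, 0L, 0L)
  point <- rep(0, ncell)
  point[nb[1] + it_lattice$nx * ((nb[2] - 1) + it_lattice$ny * (nb[3] - 1))] <- 1
  mv <- choose_move(point, agent, it_pf, it_lattice)
  expect_equal(unname(mv$cell), as.integer(nb))
  expect_equal(unname(mv$expected_entropy["xp"]), 0, tolerance = 1e-12)
  # expected entropy of the chosen move never exceeds the current entropy
  set.seed(33)
  b <- runif(ncell); b <- b / sum(b)
  for (i in 1:3) {
    cell <- c(sample.int(it_lattice$nx, 1), sample.int(it_lattice$ny, 1),
              sample.int(it_lattice$nz, 1))
    mv <- choose_move(b, cell, it_pf, it_lattice)
    expect_lte(min(mv$expected_entropy, na.rm = TRUE),
               shannon_entropy(b) + 1e-9)
  }
  # y-symmetric belief about the agent: tie broken toward -y by the
  # documented order (never +y)
  bsym <- rep(0, ncell)
  agent <- c(16L, 4L, 4L)
  for (dy in c(-2L, 2L)) {
    cc <- agent + c(0L, dy, 0L)
    bsym[cc[1] + it_lattice$nx * ((cc[2] - 1) + it_lattice$ny * (cc[3] - 1))] <- 0.5
  }
  mvs <- choose_move(bsym, agent, it_pf, it_lattice)
  expect_false(identical(mvs$move, "yp"))
})

test_that("compiled and R engines produce identical short runs", {
  for (s in c(1, 7)) {
    set.seed(s)
    r1 <- run_infotaxis(c(0.9, 0.05, 0), 40, it_model, it_plume, tun0,
                        it_lattice, engine = "cpp")
    set.seed(s)
    r2 <- run_infotaxis(c(0.9, 0.05, 0), 40, it_model, it_plume, tun0,
                        it_lattice, engine = "r")
    i1 <- attr(r1, "infotaxis"); i2 <- attr(r2, "infotaxis")
    expect_identical(i1$path, i2$path)
    expect_identical(i1$hits, i2$hits)
    expect_equal(i1$entropy, i2$entropy, tolerance = 1e-10)
  }
})

test_that("runs conserve belief machinery and start with a hit inside the plume", {
  # start on the plume axis -> deterministic first hit
  set.seed(2)
  tr <- run_infotaxis(c(0.9, 0, 0), 30, it_model, it_plume, tun0,
                      it_lattice)
  expect_true(attr(tr, "infotaxis")$hits[1])
  # entropy decreases on the first (uniform-belief) update
  ent <- attr(tr, "infotaxis")$entropy
  expect_lt(ent[1], log(it_lattice$ncell))
  # trajectory is a valid standard trajectory on the lattice clock
  expect_s3_class(tr, "trajectory")
  expect_equal(tr$dt, it_model$dt)
  expect_true(all(tr$concentrations >= 0))
})

test_that("mean one-step entropy change is negative over a batch", {
  runs <- simulate_batch_infotaxis(15, it_model, it_plume, tun0, it_lattice,
                                   seed = 6, duration_range = c(5, 20))
  deltas <- unlist(lapply(runs, function(tr) {
    diff(attr(tr, "infotaxis")$entropy)
  }))
  expect_lt(mean(deltas), 0)
})
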