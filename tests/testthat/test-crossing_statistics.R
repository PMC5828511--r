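test_that("partial_correlation matches its residualization oracle", {
  set.seed(11)
  # self-correlation without conditioners
  x <- rnorm(50)
  expect_equal(partial_correlation(x, x, n_boot = 0)$estimate, 1)
  # residualization oracle: target and predictor share only the common
  # driver z; conditioning on z leaves two independent noises
  n <- 10000
  z <- rnorm(n)
  tgt <- z + rnorm(n)
  prd <- z + rnorm(n)
  raw <- cor(tgt, prd)
  pc <- partial_correlation(tgt, prd, conditioners = z, n_boot = 0)
  expect_gt(raw, 0.4)
  expect_lt(abs(pc$estimate), 3 / sqrt(n))
  # conditioners orthogonal to both variables: equals plain Pearson
  set.seed(12)
  m <- 2000
  a <- rnorm(m); b <- 0.5 * a + rnorm(m)
  q <- qr.resid(qr(cbind(1, a, b)), cbind(rnorm(m), rnorm(m)))
  pc2 <- partial_correlation(a, b, conditioners = q, n_boot = 0)
  expect_equal(pc2$estimate, cor(a, b), tolerance = 1e-10)
  # constant residual -> undefined
  expect_error(partial_correlation(a, b, conditioners = a, n_boot = 0),
               "undefined")
})

test_that("partial_correlation is invariant to affine maps of conditioners", {
  set.seed(5)
  n <- 500
  z1 <- rnorm(n); z2 <- rnorm(n)
  tgt <- z1 - z2 + rnorm(n)
  prd <- z1 + rnorm(n)
  p1 <- partial_correlation(tgt, prd, cbind(z1, z2), n_boot = 0)$estimate
  p2 <- partial_correlation(tgt, prd, cbind(3 * z1 - 7, -0.5 * z2 + 2),
                            n_boot = 0)$estimate
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("concentration curve recovers the injected effect and its null", {
  ds <- generate_dataset(synthetic_effects(conc_gain = 0.8, n_traj = 400,
                                           seed = 21),
                         tun0, plume0, walker0)
  cs <- crossings_of(ds)
  cur <- heading_concentration_curve(cs, timepoints = c(0.2, 0.3),
                                     n_boot = 200, seed = 2)
  expect_true(all(cur$defined))
  expect_true(all(cur$estimate < 0))
  expect_true(all(cur$p < 0.05))
  # t = 0 conditioned on h0: constant residual, reported as undefined
  cur0 <- heading_concentration_curve(cs, timepoints = 0, n_boot = 0)
  expect_false(cur0$defined)
})

test_that("threshold-linear SSE never exceeds binary SSE and F-test dfs are conservative", {
  ds <- synth_small(seed = 8, n_traj = 200)
  cs <- crossings_of(ds)
  fit <- fit_threshold_models(cs, timepoint = 0.3)
  expect_lte(fit$threshold_linear$sse, fit$binary$sse)
  expect_gte(fit$p, fit$p_crossing_df)
  expect_named(fit$threshold_linear$coef,
               c("a_h", "a_x", "h_below", "h_above", "a_c"))
  rng <- range(cs$meta$c_peak)
  expect_true(fit$binary$c_th >= rng[1] && fit$binary$c_th <= rng[2])
  # too few trajectories -> error
  few <- subset_ids <- unique(cs$meta$traj_id)[1:4]
  cs_few <- cs
  keep <- cs$meta$traj_id %in% few
  cs_few$meta <- cs$meta[keep, ]
  cs_few$h <- cs$h[keep, , drop = FALSE]
  cs_few$valid <- cs$valid[keep, , drop = FALSE]
  expect_error(fit_threshold_models(cs_few), "trajectories")
})

test_that("history analysis zeroes perfectly explained heading changes", {
  # build a crossing set whose Delta h is an exact linear function of
  # (x0, T): the confound fit must absorb it, h*(t) identically 0
  ds <- synth_small(seed = 14, n_traj = 60)
  cs <- crossings_of(ds)
  lin <- 25 + 40 * cs$meta$x0 - 3 * cs$meta$T
  cs$h <- matrix(cs$meta$h0, nrow(cs$h), ncol(cs$h)) + lin
  cs$valid[] <- TRUE
  hd <- history_dependence(cs)
  expect_true(all(abs(hd$by_time$mean_early) < 1e-9))
  expect_true(all(abs(hd$by_time$mean_late) < 1e-9))
})

test_that("pooled h*(t) averages to zero by construction", {
  cs <- crossings_of(synth_small(seed = 15, n_traj = 150))
  hd <- history_dependence(cs)
  expect_true(all(abs(hd$by_time$pooled_mean) <
                    1e-9 * max(1, max(abs(cs$h), na.rm = TRUE))))
})

test_that("history analysis recovers an injected step attenuation", {
  ds <- generate_dataset(
    synthetic_effects(history_factor = 0.4, n_traj = 500, seed = 16),
    tun0, plume0, walker0)
  hd <- history_dependence(crossings_of(ds))
  bt <- hd$by_time[hd$by_time$time >= 0.3 & hd$by_time$time <= 0.6, ]
  expect_gt(mean(bt$diff_late_early), 2)
  # the trajectory-level test is deliberately conservative, so demand
  # consistency of the sign rather than pointwise significance
  expect_true(mean(bt$diff_late_early > 0) > 0.9)
})

test_that("crossing-number partial correlation sees smooth decay, not confounds", {
  # smooth per-crossing decay: positive partial correlation
  ds <- generate_dataset(
    synthetic_effects(conc_gain = 0, history_factor = 0.5,
                      history_decay = "smooth", base_surge_amp = 0.8,
                      rate_heterogeneity = 0.8, n_traj = 500, seed = 2),
    tun0, plume0, walker0)
  r <- crossing_number_partial_corr(crossings_of(ds), n_boot = 200,
                                    seed = 1)
  expect_gt(r$estimate, 0)
  expect_lt(r$p, 0.05)
  # rho = 1: null
  ds1 <- generate_dataset(
    synthetic_effects(conc_gain = 0, history_factor = 1, n_traj = 300,
                      seed = 18), tun0, plume0, walker0)
  r1 <- crossing_number_partial_corr(crossings_of(ds1), n_boot = 200,
                                     seed = 1)
  expect_true(r1$ci[1] <= 0 && r1$ci[2] >= 0)
})

test_that("conditioning absorbs a crossing number determined by flight time", {
  # construct data where crossing number is a deterministic function of T
  # and Delta h depends only on T: conditioning on (x0, T) removes it
  set.seed(19)
  n <- 400
  traj <- rep(sprintf("t%02d", 1:40), each = 10)
  Tt <- as.vector(replicate(40, sort(runif(10, 0, 20))))
  num <- as.vector(replicate(40, 1:10))
  dh <- 2 * Tt + rnorm(n, 0, 0.1)
  pc <- partial_correlation(dh, num, cbind(runif(n), Tt), traj = traj,
                            n_boot = 0)
  expect_lt(abs(pc$estimate), 0.12)
})
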