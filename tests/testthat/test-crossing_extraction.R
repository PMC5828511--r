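test_that("single- and no-excursion series extract as expected", {
  tr <- traj_with_conc(c(0, 0.5, 2, 5, 2, 0.5, 0))
  cs <- extract_crossings(tr, threshold = 1)
  expect_equal(n_crossings(cs), 1)
  expect_equal(cs$meta$peak_index, 4)  # value 5
  expect_equal(cs$meta$c_peak, 5)
  expect_equal(cs$meta$crossing_number, 1)
  # all below threshold -> empty set, not an error
  cs0 <- extract_crossings(traj_with_conc(rep(0.1, 10)), threshold = 1)
  expect_equal(n_crossings(cs0), 0)
})

test_that("the crossing window ends when the series re-exceeds threshold", {
  # [0, 2, 0, 3, 0], threshold 1: two crossings; by the end rule applied by
  # hand, crossing 1's window is samples 2..3 (ends when the series
  # re-exceeds threshold at sample 4) and crossing 2 runs to the end
  tr <- traj_with_conc(c(0, 2, 0, 3, 0), dt = 0.1)
  cs <- extract_crossings(tr, threshold = 1, grid = seq(0, 0.4, by = 0.1))
  expect_equal(cs$meta$crossing_number, c(1, 2))
  expect_equal(cs$meta$peak_index, c(2, 4))
  expect_equal(cs$meta$c_peak, c(2, 3))
  # window 1: peak at sample 2, next excursion starts at sample 4, so the
  # window covers relative times 0 and 0.1 s only
  expect_identical(cs$valid[1, ], c(TRUE, TRUE, FALSE, FALSE, FALSE))
  # window 2: peak at sample 4, trajectory ends at sample 5
  expect_identical(cs$valid[2, ], c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(cs$meta$end_time, c(0.2, 0.4))
  # h(0) equals h0
  expect_equal(cs$h[, 1], cs$meta$h0)
})

test_that("extraction is idempotent and order-invariant", {
  ds <- synth_small(seed = 6, n_traj = 20)
  cs1 <- extract_crossings(ds, plume0$threshold)
  cs2 <- extract_crossings(rev(ds), plume0$threshold)
  o1 <- order(cs1$meta$traj_id, cs1$meta$t_peak)
  o2 <- order(cs2$meta$traj_id, cs2$meta$t_peak)
  expect_equal(cs1$meta[o1, ], cs2$meta[o2, ])
  expect_equal(extract_crossings(ds, plume0$threshold)$meta, cs1$meta)
})

test_that("higher-threshold excursions nest inside lower-threshold ones", {
  # at a higher threshold every excursion is a sub-interval of a
  # lower-threshold excursion (an excursion can split into several, so peak
  # TIMES need not be a subset; interval containment is the true nesting)
  ds <- synth_small(seed = 6, n_traj = 40)
  th <- plume0$threshold
  cs_lo <- extract_crossings(ds, th)
  for (mult in c(2, 4, 8)) {
    cs_hi <- extract_crossings(ds, th * mult)
    m <- cs_hi$meta
    # every high-threshold peak sample is above the low threshold, hence
    # inside some low-threshold excursion
    for (i in seq_len(nrow(m)))
      expect_gte(ds[[m$traj_id[i]]]$concentrations[m$peak_index[i]], th)
    # and every low-threshold peak that clears the higher threshold is the
    # maximum of its containing high-threshold excursion, so it must
    # reappear as a high-threshold peak
    lo_keep <- cs_lo$meta[cs_lo$meta$c_peak >= th * mult, ]
    k_lo <- paste(lo_keep$traj_id, lo_keep$peak_index)
    k_hi <- paste(m$traj_id, m$peak_index)
    expect_true(all(k_lo %in% k_hi))
  }
})

test_that("exclusion rules keep exactly the compliant crossings", {
  ds <- synth_small(seed = 2, n_traj = 60)
  cs <- extract_crossings(ds, plume0$threshold)
  kept <- apply_exclusions(cs, exclusion_policy(), tun0)
  expect_true(all(kept$meta$x0 >= 0.3 & kept$meta$x0 <= 1.0))
  expect_true(all(kept$meta$h0 >= 60 & kept$meta$h0 <= 120))
  # numbering is preserved from before exclusion
  expect_true(any(kept$meta$crossing_number >
                    ave(kept$meta$crossing_number, kept$meta$traj_id,
                        FUN = seq_along)))
  # manual spot checks of the rules
  drop_pos <- cs$meta$x0 < 0.3 | cs$meta$x0 > 1.0
  drop_head <- is.na(cs$meta$h0) | cs$meta$h0 < 60 | cs$meta$h0 > 120
  expect_equal(n_crossings(kept), sum(!drop_pos & !drop_head))
  # per-rule flags
  only_pos <- apply_exclusions(cs, exclusion_policy(apply_heading = FALSE),
                               tun0)
  expect_equal(n_crossings(only_pos), sum(!drop_pos))
  # renumbering alternative
  renum <- apply_exclusions(cs, exclusion_policy(), tun0, renumber = TRUE)
  expect_true(all(ave(renum$meta$crossing_number, renum$meta$traj_id,
                      FUN = seq_along) == renum$meta$crossing_number))
})

test_that("crossing tables round trip through CSV", {
  cs <- crossings_of(synth_small(seed = 3, n_traj = 25))
  path <- file.path(tempdir(), "crossings.csv")
  write_crossings(cs, path)
  back <- read_crossings(path)
  expect_equal(back$meta$c_peak, cs$meta$c_peak)
  expect_equal(back$grid, cs$grid)
  expect_equal(back$threshold, cs$threshold)
  expect_equal(unname(back$h), unname(cs$h), tolerance = 1e-9)
  expect_equal(unname(back$valid), unname(cs$valid), ignore_attr = TRUE)
})

test_that("threshold scan localizes a known surge-triggering threshold", {
  # surges only above c = 0.4; capture pool at 0.05. The separation score
  # should rise to a plateau near 0.4 with the elbow within one candidate
  # step of the truth.
  ds <- generate_dataset(
    synthetic_effects(base_surge_amp = 0.8, conc_gain = 0,
                      history_factor = 1, surge_threshold = 0.4,
                      n_traj = 500, seed = 12),
    tun0, plume0, walker0)
  cands <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  scan <- threshold_scan(ds, cands, capture_threshold = 0.05)
  expect_equal(nrow(scan$scores), length(cands))
  expect_true(all(is.finite(scan$scores$score)))
  expect_true(abs(scan$elbow - 0.4) <= 0.1 + 1e-9)
  # scores beyond the true threshold stop growing (plateau / decline)
  s <- scan$scores$score
  expect_gt(s[4] - s[1], 0)
  # single candidate is returned trivially
  one <- threshold_scan(ds[1:50], 0.2, capture_threshold = 0.05)
  expect_equal(one$elbow, 0.2)
})

test_that("no-separation data yield scores indistinguishable from 0", {
  # surge for every excursion regardless of concentration: no threshold
  # separates behavior, scores within ~2 SE of zero
  ds <- generate_dataset(
    synthetic_effects(base_surge_amp = 0.8, conc_gain = 0,
                      history_factor = 1, surge_threshold = 0.0001,
                      n_traj = 300, seed = 13),
    tun0, plume0, walker0)
  scan <- threshold_scan(ds, c(0.2, 0.4, 0.6), capture_threshold = 0.15)
  ok <- is.finite(scan$scores$score)
  expect_true(all(abs(scan$scores$score[ok]) <=
                    2.5 * scan$scores$se[ok] + 1e-9))
})
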