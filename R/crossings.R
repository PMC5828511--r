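#' Plume-crossing set
#'
#' A `crossing_set` holds one row per plume crossing (a maximal
#' above-threshold excursion of the experienced concentration) together with
#' its peak-aligned heading time course:
#'
#' * `meta`: data.table with `traj_id`, `crossing_number` (temporal order
#'   within the trajectory, starting at 1, assigned before any exclusion),
#'   `peak_index`, `t_peak` (absolute time of the concentration peak, the
#'   crossing's `t = 0`), `c_peak`, `x0` (wind-axis position at the peak),
#'   `h0` (heading at the peak, degrees), `T` (flight time since takeoff at
#'   the peak) and `end_time` (when the insect re-entered the plume or the
#'   trajectory ended);
#' * `h`: crossings x timepoints matrix of headings resampled onto the fixed
#'   post-peak grid;
#' * `valid`: same-shape logical mask, `FALSE` where the crossing window
#'   ended before the grid point (or heading was undefined).
#'
#' @name crossing_set
NULL

new_crossing_set <- function(meta, h, valid, grid, threshold) {
  structure(list(meta = meta, h = h, valid = valid, grid = grid,
                 threshold = threshold),
            class = "crossing_set")
}

#' @export
print.crossing_set <- function(x, ...) {
  cat(sprintf(
    "crossing_set: %d crossings from %d trajectories, grid 0-%g s (%d points), threshold %g\n",
    nrow(x$meta), length(unique(x$meta$traj_id)), max(x$grid),
    length(x$grid), x$threshold))
  invisible(x)
}

#' Number of crossings in a crossing set
#' @param cs A `crossing_set`.
#' @export
n_crossings <- function(cs) nrow(cs$meta)

# heading-change matrix Delta h(t) = h(t) - h0 (rows with undefined h0 -> NA)
delta_h <- function(cs) {
  sweep(cs$h, 1, cs$meta$h0, `-`)
}

subset_crossings <- function(cs, keep) {
  new_crossing_set(cs$meta[keep, ], cs$h[keep, , drop = FALSE],
                   cs$valid[keep, , drop = FALSE], cs$grid, cs$threshold)
}

#' Extract plume crossings from trajectories
#'
#' A plume crossing is a maximal interval during which the experienced odor
#' concentration is at or above `threshold`. Each crossing is aligned to its
#' concentration maximum (`t = 0`); its analysis window runs until the next
#' excursion begins or the trajectory ends (landing), and the heading time
#' course is linearly resampled onto the fixed post-peak `grid` with a
#' validity mask where the window ends early. Crossing numbers are assigned
#' in temporal order within each trajectory, starting at 1, before any
#' exclusion is applied.
#'
#' @param x A trajectory or list of trajectories.
#' @param threshold Detection threshold, same arbitrary units as the
#'   concentrations (`> 0`).
#' @param grid Post-peak time grid, seconds (default 0 to 1 s in 10 ms
#'   steps).
#' @return A [crossing_set].
#' @examples
#' tun <- wind_tunnel(); pl <- gaussian_plume()
#' tr <- simulate_surge_cast(5, tunnel = tun, plume = pl)
#' extract_crossings(tr, threshold = pl$threshold)
#' @export
extract_crossings <- function(x, threshold, grid = seq(0, 1, by = 0.01)) {
  stopifnot(is.finite(threshold), threshold > 0)
  trajs <- as_traj_list(x)
  metas <- list(); hs <- list(); vs <- list()
  for (tr in trajs) {
    cc <- tr$concentrations
    n <- length(cc)
    above <- cc >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    h_all <- heading_of(tr$velocities, na_zero = TRUE)
    times <- traj_times(tr)
    for (j in seq_along(runs)) {
      s <- starts[runs[j]]; e <- ends[runs[j]]
      peak <- s - 1L + which.max(cc[s:e])
      wend <- if (j < length(runs)) starts[runs[j + 1]] - 1L else n
      rel_t <- (peak:wend - peak) * tr$dt
      hseg <- h_all[peak:wend]
      ok <- !is.na(hseg)
      if (sum(ok) >= 2) {
        ih <- stats::approx(rel_t[ok], hseg[ok], xout = grid,
                            rule = 1)$y
      } else if (sum(ok) == 1) {
        ih <- ifelse(abs(grid - rel_t[ok]) < 1e-12, hseg[ok], NA_real_)
      } else {
        ih <- rep(NA_real_, length(grid))
      }
      vmask <- grid <= rel_t[length(rel_t)] + 1e-12 & !is.na(ih)
      metas[[length(metas) + 1]] <- data.table::data.table(
        traj_id = tr$id, crossing_number = j,
        peak_index = peak, t_peak = times[peak], c_peak = cc[peak],
        x0 = tr$positions[peak, 1], h0 = h_all[peak],
        T = (peak - 1) * tr$dt, end_time = times[wend])
      hs[[length(hs) + 1]] <- ih
      vs[[length(vs) + 1]] <- vmask
    }
  }
  if (!length(metas)) {
    meta <- data.table::data.table(
      traj_id = character(), crossing_number = integer(),
      peak_index = integer(), t_peak = numeric(), c_peak = numeric(),
      x0 = numeric(), h0 = numeric(), T = numeric(), end_time = numeric())
    return(new_crossing_set(meta, matrix(NA_real_, 0, length(grid)),
                            matrix(FALSE, 0, length(grid)), grid, threshold))
  }
  new_crossing_set(data.table::rbindlist(metas), do.call(rbind, hs),
                   do.call(rbind, vs), grid, threshold)
}

#' Crossing exclusion policy
#'
#' The geometric exclusion rules applied before any crossing statistic:
#' crossings in the upwind- or downwind-most `end_margin` (default 30 cm) of
#' the tunnel are dropped, as are crossings whose initial heading `h0` falls
#' outside the crosswind window (default 60-120 degrees). Crossing numbers
#' are assigned before exclusion, so an excluded crossing still advances the
#' early/late count (set `renumber = TRUE` in [apply_exclusions()] for the
#' alternative convention).
#'
#' @param end_margin Margin at each tunnel end, metres.
#' @param h0_window Length-2 initial-heading window, degrees.
#' @param apply_position,apply_heading Per-rule on/off flags.
#' @export
exclusion_policy <- function(end_margin = 0.30, h0_window = c(60, 120),
                             apply_position = TRUE, apply_heading = TRUE) {
  stopifnot(end_margin > 0, length(h0_window) == 2,
            h0_window[1] >= 0, h0_window[1] < h0_window[2],
            h0_window[2] <= 180)
  structure(list(end_margin = end_margin, h0_window = h0_window,
                 apply_position = apply_position,
                 apply_heading = apply_heading),
            class = "exclusion_policy")
}

#' Apply geometric exclusion rules to a crossing set
#'
#' @param cs A [crossing_set].
#' @param policy An [exclusion_policy()].
#' @param tunnel A [wind_tunnel()] (for the wind-axis extent).
#' @param renumber If `TRUE`, crossing numbers are re-assigned among the
#'   surviving crossings; by default the pre-exclusion numbering is kept.
#' @return Filtered [crossing_set].
#' @export
apply_exclusions <- function(cs, policy = exclusion_policy(),
                             tunnel = wind_tunnel(), renumber = FALSE) {
  stopifnot(inherits(cs, "crossing_set"))
  keep <- rep(TRUE, nrow(cs$meta))
  if (policy$apply_position) {
    lo <- policy$end_margin
    hi <- tunnel$extent[1] - policy$end_margin
    keep <- keep & cs$meta$x0 >= lo & cs$meta$x0 <= hi
  }
  if (policy$apply_heading) {
    keep <- keep & !is.na(cs$meta$h0) &
      cs$meta$h0 >= policy$h0_window[1] & cs$meta$h0 <= policy$h0_window[2]
  }
  out <- subset_crossings(cs, which(keep))
  if (renumber && nrow(out$meta) > 0) {
    out$meta[, crossing_number := seq_len(.N), by = "traj_id"]
  }
  out
}

#' Threshold-selection scan
#'
#' Implements the detection-threshold selection procedure: a low "capture"
#' threshold defines a pool of potential crossings; each candidate threshold
#' then splits the pool by `c_peak` into below- and above-candidate groups,
#' and the separation score is the difference (below minus above) of the
#' group-mean headings time-averaged over the first second post-peak, with
#' uncertainty propagated from the two groups' standard errors. Since true
#' plume encounters trigger upwind turns (lower headings), the score rises
#' with the candidate until it passes the true detection threshold and then
#' plateaus; the "elbow" is reported as the point of maximum discrete
#' curvature (most negative second difference) of the score curve.
#'
#' @param trajs Trajectory list.
#' @param candidates Ascending candidate thresholds (same units as the
#'   concentrations).
#' @param capture_threshold Low threshold defining the pool of potential
#'   crossings.
#' @param window Averaging window, seconds (default first 1 s post-peak).
#' @param policy,tunnel Exclusions applied to the pool before scoring.
#' @return List with `scores` (data.table: candidate, score, se, n_below,
#'   n_above) and `elbow` (the selected candidate).
#' @export
threshold_scan <- function(trajs, candidates, capture_threshold,
                           window = c(0, 1),
                           policy = exclusion_policy(),
                           tunnel = wind_tunnel()) {
  stopifnot(length(candidates) >= 1, !is.unsorted(candidates))
  cs <- extract_crossings(trajs, capture_threshold)
  cs <- apply_exclusions(cs, policy, tunnel)
  sel <- cs$grid >= window[1] & cs$grid <= window[2]
  hw <- cs$h[, sel, drop = FALSE]
  vw <- cs$valid[, sel, drop = FALSE]
  hw[!vw] <- NA_real_
  tavg <- rowMeans(hw, na.rm = TRUE)
  okrow <- is.finite(tavg)
  tavg <- tavg[okrow]
  cpk <- cs$meta$c_peak[okrow]
  rows <- lapply(candidates, function(th) {
    below <- tavg[cpk < th]; abov <- tavg[cpk >= th]
    if (length(below) < 2 || length(abov) < 2) {
      data.table::data.table(candidate = th, score = NA_real_,
                             se = NA_real_, n_below = length(below),
                             n_above = length(abov))
    } else {
      sc <- mean(below) - mean(abov)
      se <- sqrt(stats::var(below) / length(below) +
                 stats::var(abov) / length(abov))
      data.table::data.table(candidate = th, score = sc, se = se,
                             n_below = length(below),
                             n_above = length(abov))
    }
  })
  scores <- data.table::rbindlist(rows)
  defined <- which(is.finite(scores$score))
  elbow <- if (length(defined) < 3) {
    if (length(defined)) scores$candidate[defined[which.max(scores$score[defined])]]
    else NA_real_
  } else {
    s <- scores$score[defined]
    curv <- -(s[-c(1, 2)] - 2 * s[-c(1, length(s))] + s[-c(length(s) - 1, length(s))])
    scores$candidate[defined[which.max(curv) + 1L]]
  }
  if (length(candidates) == 1) elbow <- candidates
  list(scores = scores, elbow = elbow)
}

#' Read / write crossing tables
#'
#' Flat CSV with one row per crossing: the `meta` columns plus wide
#' millisecond-labelled heading columns `h_<ms>` and validity columns
#' `v_<ms>` for the post-peak grid.
#'
#' @param cs A [crossing_set].
#' @param path File path.
#' @export
write_crossings <- function(cs, path) {
  ms <- formatC(round(cs$grid * 1000), width = 4, flag = "0")
  h <- data.table::as.data.table(cs$h)
  data.table::setnames(h, paste0("h_", ms))
  v <- data.table::as.data.table(cs$valid)
  data.table::setnames(v, paste0("v_", ms))
  tab <- cbind(cs$meta, h, v)
  tab$.threshold <- cs$threshold
  data.table::fwrite(tab, path)
  invisible(path)
}

#' @rdname write_crossings
#' @export
read_crossings <- function(path) {
  tab <- data.table::fread(path)
  hcols <- grep("^h_[0-9]+$", names(tab), value = TRUE)
  vcols <- grep("^v_[0-9]+$", names(tab), value = TRUE)
  grid <- as.numeric(sub("h_", "", hcols)) / 1000
  meta <- tab[, setdiff(names(tab), c(hcols, vcols, ".threshold")),
              with = FALSE]
  new_crossing_set(meta, as.matrix(tab[, hcols, with = FALSE]),
                   as.matrix(tab[, vcols, with = FALSE]), grid,
                   tab$.threshold[1])
}
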