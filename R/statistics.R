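#' Residualized partial correlation
#'
#' Computes the correlation between `target` and `predictor` after removing
#' the best linear prediction of `target` from the conditioning variables
#' (ordinary least squares with intercept): the target is residualized, then
#' Pearson-correlated with the predictor. This is the confound-control
#' construction used throughout the crossing analyses (conditioning on
#' initial heading, tunnel position and/or flight time).
#'
#' The confidence interval is obtained by bootstrap resampling whole
#' trajectories (2.5-97.5 percentiles), since crossings within a trajectory
#' are not independent. The p-value uses the t transform of the correlation
#' with `n_eff - 2 - n_conditioners` degrees of freedom, where `n_eff`
#' defaults to the number of rows but can be set to the number of unique
#' trajectories for a conservative trajectory-level test.
#'
#' @param target,predictor Numeric vectors of equal length.
#' @param conditioners Optional numeric matrix (one column per conditioning
#'   variable) or vector.
#' @param traj Optional trajectory ids (same length) for the trajectory-level
#'   bootstrap; rows are resampled independently if omitted.
#' @param n_boot Bootstrap replicates (default 1000); `0` skips the CI.
#' @param n_eff Effective sample size for the p-value (default `length(target)`).
#' @param conf Confidence level.
#' @param seed Optional seed for the bootstrap.
#' @return List with `estimate`, `ci` (length 2), `p`, `df`, `n`.
#' @export
partial_correlation <- function(target, predictor, conditioners = NULL,
                                traj = NULL, n_boot = 1000, n_eff = NULL,
                                conf = 0.95, seed = NULL) {
  target <- as.numeric(target); predictor <- as.numeric(predictor)
  n <- length(target)
  if (!is.null(conditioners)) {
    conditioners <- as.matrix(conditioners)
    stopifnot(nrow(conditioners) == n)
  }
  k <- if (is.null(conditioners)) 0L else ncol(conditioners)
  stopifnot(length(predictor) == n, n >= 3 + k,
            all(is.finite(target)), all(is.finite(predictor)))
  est_fun <- function(y, p, z) {
    r <- if (is.null(z)) y else {
      X <- cbind(1, z)
      stats::lm.fit(X, y)$residuals
    }
    if (stats::sd(r) < 1e-12 * (abs(mean(y)) + 1))
      stop("undefined partial correlation: residual is constant")
    stats::cor(r, p)
  }
  est <- est_fun(target, predictor, conditioners)
  ne <- if (is.null(n_eff)) n else n_eff
  df <- ne - 2L - k
  p <- if (df >= 1) {
    tt <- est * sqrt(df / max(1 - est^2, 1e-15))
    2 * stats::pt(-abs(tt), df)
  } else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    groups <- if (is.null(traj)) as.character(seq_len(n)) else
      as.character(traj)
    idx_by <- split(seq_len(n), groups)
    ng <- length(idx_by)
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- unlist(idx_by[sample.int(ng, ng, replace = TRUE)],
                     use.names = FALSE)
      tryCatch(est_fun(target[take], predictor[take],
                       if (is.null(conditioners)) NULL
                       else conditioners[take, , drop = FALSE]),
               error = function(e) NA_real_)
    }, 0)
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE))
  }
  list(estimate = est, ci = ci, p = p, df = df, n = n)
}

# pick the grid column nearest a requested timepoint
grid_column <- function(cs, timepoint) {
  j <- which.min(abs(cs$grid - timepoint))
  tol <- if (length(cs$grid) > 1) 0.5 * max(diff(cs$grid)) else 1e-9
  if (abs(cs$grid[j] - timepoint) > tol + 1e-12)
    stop("timepoint beyond the heading grid")
  j
}

#' Concentration dependence of post-crossing heading
#'
#' For each requested post-peak time, the partial correlation between the
#' peak concentration `c_peak` and the heading `h(t)`, conditioned on the
#' wind-axis position `x0` and the initial heading `h0` (with trajectory
#' bootstrap CI). A negative curve means higher concentrations trigger
#' stronger upwind turns. At `t = 0`, `h(0)` equals `h0`, so the residual is
#' constant and the correlation undefined; such timepoints are reported as
#' `NA` with `defined = FALSE`.
#'
#' @param cs A [crossing_set] (exclusions already applied).
#' @param timepoints Post-peak times, seconds.
#' @param n_boot,seed Bootstrap controls (see [partial_correlation()]).
#' @return data.table: time, estimate, ci_lo, ci_hi, p, n, defined.
#' @export
heading_concentration_curve <- function(cs, timepoints = seq(0.1, 1, 0.1),
                                        n_boot = 1000, seed = NULL) {
  stopifnot(inherits(cs, "crossing_set"))
  rows <- lapply(timepoints, function(tp) {
    j <- grid_column(cs, tp)
    ok <- cs$valid[, j] & !is.na(cs$meta$h0)
    res <- tryCatch(
      partial_correlation(cs$h[ok, j], cs$meta$c_peak[ok],
                          cbind(x0 = cs$meta$x0[ok], h0 = cs$meta$h0[ok]),
                          traj = cs$meta$traj_id[ok], n_boot = n_boot,
                          seed = seed),
      error = function(e) NULL)
    if (is.null(res)) {
      data.table::data.table(time = tp, estimate = NA_real_,
                             ci_lo = NA_real_, ci_hi = NA_real_,
                             p = NA_real_, n = sum(ok), defined = FALSE)
    } else {
      data.table::data.table(time = tp, estimate = res$estimate,
                             ci_lo = res$ci[1], ci_hi = res$ci[2],
                             p = res$p, n = res$n, defined = TRUE)
    }
  })
  data.table::rbindlist(rows)
}

# least-squares fit of the binary / threshold-linear models at a fixed
# threshold grid; returns both fits and their SSE minima
fit_threshold_models_impl <- function(h, h0, x0, cpk, n_grid) {
  qs <- stats::quantile(cpk, seq(0.01, 0.99, length.out = n_grid),
                        names = FALSE)
  qs <- unique(qs)
  best <- list(bin = list(sse = Inf), tl = list(sse = Inf))
  for (cth in qs) {
    theta <- as.numeric(cpk >= cth)
    Xb <- cbind(h0 = h0, x0 = x0, icpt = 1, theta = theta)
    fb <- stats::lm.fit(Xb, h)
    sseb <- sum(fb$residuals^2)
    if (sseb < best$bin$sse)
      best$bin <- list(sse = sseb, c_th = cth, coef = fb$coefficients)
    Xt <- cbind(Xb, ctheta = cpk * theta)
    ft <- stats::lm.fit(Xt, h)
    sset <- sum(ft$residuals^2)
    if (sset < best$tl$sse)
      best$tl <- list(sse = sset, c_th = cth, coef = ft$coefficients)
  }
  best
}

#' Binary vs. threshold-linear concentration-response models
#'
#' Fits the two nested models of the post-crossing heading
#' `h(t) = a_h h0 + a_x x0 + h_< + h_> Theta(c_peak - c_th)` (binary) and
#' `h(t) = a_h h0 + a_x x0 + h_< + (h_> + a_c c_peak) Theta(c_peak - c_th)`
#' (threshold-linear), both by minimizing squared prediction error: `c_th`
#' by grid search over the 1st-99th percentiles of the observed `c_peak`
#' (default 100 steps, with per-grid ordinary least squares for the linear
#' coefficients), and compares them with an F-test whose sample size is the
#' number of unique trajectories rather than the number of crossings -- a
#' conservative choice since each trajectory yields multiple, dependent
#' crossings.
#'
#' @param cs A [crossing_set] (exclusions applied).
#' @param timepoint Response timepoint, seconds (0.3 by default; 0.5 is the
#'   convention for the mosquito-style configuration).
#' @param n_grid Number of `c_th` grid values.
#' @return Object of class `threshold_model_cmp`: list with `binary` and
#'   `threshold_linear` fits (coefficients, `c_th`, `sse`), `F`, `p`
#'   (trajectory-level df), `p_crossing_df` (the anticonservative
#'   crossing-level alternative), `n_crossings`, `n_trajectories`.
#' @export
fit_threshold_models <- function(cs, timepoint = 0.3, n_grid = 100) {
  stopifnot(inherits(cs, "crossing_set"))
  j <- grid_column(cs, timepoint)
  ok <- cs$valid[, j] & !is.na(cs$meta$h0)
  h <- cs$h[ok, j]
  h0 <- cs$meta$h0[ok]; x0 <- cs$meta$x0[ok]; cpk <- cs$meta$c_peak[ok]
  n_traj <- length(unique(cs$meta$traj_id[ok]))
  n_cross <- sum(ok)
  # larger model has 6 parameters (a_h, a_x, h_<, h_>, a_c, c_th)
  if (n_traj - 6 < 1)
    stop("too few trajectories for the F-test (need more than 6)")
  best <- fit_threshold_models_impl(h, h0, x0, cpk, n_grid)
  f_p <- function(n) {
    df2 <- n - 6
    Fstat <- (best$bin$sse - best$tl$sse) / (best$tl$sse / df2)
    list(F = Fstat, p = stats::pf(Fstat, 1, df2, lower.tail = FALSE))
  }
  ft <- f_p(n_traj)
  fc <- f_p(n_cross)
  name_coef <- function(cf, tl) {
    out <- c(a_h = unname(cf["h0"]), a_x = unname(cf["x0"]),
             h_below = unname(cf["icpt"]), h_above = unname(cf["theta"]))
    if (tl) out <- c(out, a_c = unname(cf["ctheta"]))
    out
  }
  structure(list(
    binary = list(coef = name_coef(best$bin$coef, FALSE),
                  c_th = best$bin$c_th, sse = best$bin$sse),
    threshold_linear = list(coef = name_coef(best$tl$coef, TRUE),
                            c_th = best$tl$c_th, sse = best$tl$sse),
    F = ft$F, p = ft$p, p_crossing_df = fc$p,
    n_crossings = n_cross, n_trajectories = n_traj,
    timepoint = cs$grid[j]),
    class = "threshold_model_cmp")
}

#' @export
print.threshold_model_cmp <- function(x, ...) {
  cat(sprintf(
    "threshold models at t = %g s: SSE %.4g (binary) vs %.4g (threshold-linear)\n",
    x$timepoint, x$binary$sse, x$threshold_linear$sse))
  cat(sprintf("F = %.3f, p = %.4g (df from %d trajectories, %d crossings)\n",
              x$F, x$p, x$n_trajectories, x$n_crossings))
  invisible(x)
}

# Welch two-sample t-test from group summaries with substituted sample sizes
welch_from_summaries <- function(m1, v1, n1, m2, v2, n2) {
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Early vs. late history-dependence analysis
#'
#' The heading change `Delta h(t) = h(t) - h0` of each crossing is corrected
#' for geometric and fatigue confounds by subtracting, at every timepoint,
#' the best linear prediction from the wind-axis position `x0` and the
#' flight time since takeoff `T` (fitted with intercept over all crossings
#' pooled, regardless of crossing number). The residual `h*(t)` therefore
#' averages to zero over the pooled crossings by construction. Crossings are
#' grouped into early (crossing number in `early`, default 1-2) and late
#' (all others, i.e. 3+), and compared at each timepoint with a Welch t-test
#' whose group sample sizes are the numbers of unique trajectories (not
#' crossings), a conservative substitution since one trajectory often
#' contributes several crossings to a group.
#'
#' A positive late-minus-early difference means later crossings turn less
#' upwind (more crosswind) than early ones.
#'
#' @param cs A [crossing_set] (exclusions applied).
#' @param early Crossing numbers forming the early group.
#' @param use_crossing_counts If `TRUE`, use crossing counts instead of
#'   unique-trajectory counts in the t-test (anticonservative alternative).
#' @return Object of class `history_analysis`: data.table `by_time` with
#'   per-timepoint group means, SEs, difference, p-value and group sizes,
#'   plus the fitted confound coefficients (`coef`, one row per timepoint).
#' @export
history_dependence <- function(cs, early = c(1, 2),
                               use_crossing_counts = FALSE) {
  stopifnot(inherits(cs, "crossing_set"))
  is_early <- cs$meta$crossing_number %in% early
  dh <- delta_h(cs)
  nt <- length(cs$grid)
  rows <- vector("list", nt)
  coefs <- matrix(NA_real_, nt, 3,
                  dimnames = list(NULL, c("icpt", "x0", "T")))
  for (j in seq_len(nt)) {
    ok <- cs$valid[, j] & !is.na(dh[, j])
    if (sum(ok) < 4) next
    X <- cbind(1, cs$meta$x0[ok], cs$meta$T[ok])
    fitj <- stats::lm.fit(X, dh[ok, j])
    hstar <- fitj$residuals
    coefs[j, ] <- fitj$coefficients
    e <- is_early[ok]
    traj_ok <- cs$meta$traj_id[ok]
    ne_tr <- length(unique(traj_ok[e]))
    nl_tr <- length(unique(traj_ok[!e]))
    if (sum(e) < 2 || sum(!e) < 2) next
    if (ne_tr < 2 || nl_tr < 2)
      stop("a history group contains a single trajectory")
    n1 <- if (use_crossing_counts) sum(e) else ne_tr
    n2 <- if (use_crossing_counts) sum(!e) else nl_tr
    w <- welch_from_summaries(mean(hstar[!e]), stats::var(hstar[!e]), n2,
                              mean(hstar[e]), stats::var(hstar[e]), n1)
    rows[[j]] <- data.table::data.table(
      time = cs$grid[j],
      mean_early = mean(hstar[e]), se_early = sqrt(stats::var(hstar[e]) / n1),
      mean_late = mean(hstar[!e]), se_late = sqrt(stats::var(hstar[!e]) / n2),
      diff_late_early = mean(hstar[!e]) - mean(hstar[e]),
      p = w$p, pooled_mean = mean(hstar),
      n_early = sum(e), n_late = sum(!e),
      ntraj_early = ne_tr, ntraj_late = nl_tr)
  }
  structure(list(by_time = data.table::rbindlist(rows[!vapply(rows, is.null, TRUE)]),
                 coef = coefs, early = early,
                 use_crossing_counts = use_crossing_counts),
            class = "history_analysis")
}

#' @export
print.history_analysis <- function(x, ...) {
  bt <- x$by_time
  if (nrow(bt) == 0) { cat("history_analysis: no usable timepoints\n"); return(invisible(x)) }
  sig <- bt$time[bt$p < 0.05]
  cat(sprintf(
    "history_analysis: %d timepoints; mean late-early difference %.2f deg; p < 0.05 at %d/%d timepoints\n",
    nrow(bt), mean(bt$diff_late_early), length(sig), nrow(bt)))
  invisible(x)
}

# valid-aware time-average of Delta h over a window
window_average_dh <- function(cs, window) {
  sel <- cs$grid >= window[1] - 1e-12 & cs$grid <= window[2] + 1e-12
  if (!any(sel)) stop("window outside the heading grid")
  dh <- delta_h(cs)[, sel, drop = FALSE]
  v <- cs$valid[, sel, drop = FALSE]
  dh[!v] <- NA_real_
  rowMeans(dh, na.rm = TRUE)
}

#' Partial correlation of crossing number with the post-crossing turn
#'
#' Correlates the crossing number with the heading change time-averaged over
#' a post-crossing window (default 350-450 ms), conditioned on the wind-axis
#' position `x0` and flight time `T`, with degrees of freedom from the
#' unique-trajectory count. Crossings with number above `max_number`
#' (default 5) are excluded as rare. A positive correlation means later
#' crossings produce weaker upwind (more crosswind) turns.
#'
#' @param cs A [crossing_set] (exclusions applied).
#' @param window Averaging window, seconds.
#' @param max_number Largest crossing number retained.
#' @param n_boot,seed Bootstrap controls for the CI.
#' @return As [partial_correlation()].
#' @export
crossing_number_partial_corr <- function(cs, window = c(0.35, 0.45),
                                         max_number = 5, n_boot = 1000,
                                         seed = NULL) {
  stopifnot(inherits(cs, "crossing_set"))
  avg <- window_average_dh(cs, window)
  ok <- is.finite(avg) & cs$meta$crossing_number <= max_number
  partial_correlation(avg[ok], cs$meta$crossing_number[ok],
                      cbind(x0 = cs$meta$x0[ok], T = cs$meta$T[ok]),
                      traj = cs$meta$traj_id[ok], n_boot = n_boot,
                      n_eff = length(unique(cs$meta$traj_id[ok])),
                      seed = seed)
}
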