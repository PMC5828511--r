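#' Occupancy heatmap of trajectory positions
#'
#' Bins all timepoints of all trajectories into an x-y histogram (z
#' marginalized) over the tunnel cross-section, normalized to sum to 1. No
#' crossing exclusions are applied: every recorded timepoint counts.
#'
#' @param trajs Trajectory list.
#' @param tunnel A [wind_tunnel()].
#' @param bin Bin size in metres (default 2 cm, matching the infotaxis
#'   lattice).
#' @return Object of class `occupancy`: `counts` (normalized matrix, x by
#'   y), `x_breaks`, `y_breaks`, `x_marginal`.
#' @export
occupancy_heatmap <- function(trajs, tunnel = wind_tunnel(), bin = 0.02) {
  trajs <- as_traj_list(trajs)
  xs <- unlist(lapply(trajs, function(tr) tr$positions[, 1]))
  ys <- unlist(lapply(trajs, function(tr) tr$positions[, 2]))
  xb <- seq(0, tunnel$extent[1] + bin, by = bin)
  yb <- seq(-tunnel$extent[2] / 2, tunnel$extent[2] / 2 + bin, by = bin)
  ix <- pmin(pmax(findInterval(xs, xb, rightmost.closed = TRUE), 1),
             length(xb) - 1)
  iy <- pmin(pmax(findInterval(ys, yb, rightmost.closed = TRUE), 1),
             length(yb) - 1)
  counts <- matrix(0, length(xb) - 1, length(yb) - 1)
  tab <- table(ix, iy)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.numeric(tab)
  counts <- counts / sum(counts)
  structure(list(counts = counts, x_breaks = xb, y_breaks = yb,
                 x_marginal = rowSums(counts)),
            class = "occupancy")
}

#' @export
print.occupancy <- function(x, ...) {
  xm <- x$x_marginal
  mode_x <- (x$x_breaks[which.max(xm)] + x$x_breaks[which.max(xm) + 1]) / 2
  cat(sprintf("occupancy: %d x %d bins, x-mode at %.2f m\n",
              nrow(x$counts), ncol(x$counts), mode_x))
  invisible(x)
}

default_run_config <- function() {
  list(schema = 1L,
       tunnel = list(extent = c(1.3, 0.3, 0.3), wind_speed = 0.4,
                     end_margin = 0.30),
       plume = list(centerline = c(0, 0), sigma0 = 0.02, widen_rate = 0,
                    c_max = 1, threshold = 0.1),
       walker = list(tau = 0.42, eta = 1.9, b = 0.25, dt = 0.01),
       seed = 1L)
}

resolve_config <- function(config = NULL) {
  base <- default_run_config()
  if (!is.null(config)) base <- utils::modifyList(base, config)
  base
}

config_objects <- function(cfg) {
  list(tunnel = do.call(wind_tunnel, cfg$tunnel),
       plume = do.call(gaussian_plume, cfg$plume),
       walker = do.call(walker_params, cfg$walker))
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  man <- c(cfg, extra)
  write_config(man, file.path(out_dir, "config.yaml"))
}

#' Pipeline stage: generate a synthetic dataset
#'
#' Writes `trajectories.csv` (standard trajectory table), a ground-truth
#' sidecar `ground_truth.yaml` recording the injected effect sizes, and the
#' resolved `config.yaml` into `out_dir`. Deterministic given the config.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Optional named list overriding the default configuration;
#'   an `effects` entry is passed to [synthetic_effects()].
#' @return The trajectory list, invisibly.
#' @export
pc_synth <- function(out_dir, config = NULL) {
  cfg <- resolve_config(config)
  obj <- config_objects(cfg)
  eff_args <- cfg$effects %||% list()
  if (is.null(eff_args$seed)) eff_args$seed <- cfg$seed
  eff <- do.call(synthetic_effects, eff_args)
  trajs <- generate_dataset(eff, obj$tunnel, obj$plume, obj$walker)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
  write_config(attr(trajs, "ground_truth"),
               file.path(out_dir, "ground_truth.yaml"))
  write_manifest(cfg, out_dir, list(stage = "synth"))
  invisible(trajs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline stage: simulate a tracking model
#'
#' Simulates a batch of trajectories from one of the three tracking
#' strategies and writes the standard trajectory table plus the resolved
#' configuration. For `"centerline"` the upwind gain defaults to
#' [calibrate_upwind_gain()]; for `"infotaxis"` the internal plume model
#' takes `D`, `R_emit` and the tunnel wind speed from the configuration.
#'
#' @param model `"surge-cast"`, `"centerline"` or `"infotaxis"`.
#' @param n_traj Number of trajectories.
#' @inheritParams pc_synth
#' @export
pc_simulate <- function(model = c("surge-cast", "centerline", "infotaxis"),
                        n_traj, out_dir, config = NULL) {
  model <- match.arg(model)
  cfg <- resolve_config(config)
  obj <- config_objects(cfg)
  trajs <- if (model == "infotaxis") {
    it <- cfg$infotaxis %||% list()
    lat <- infotaxis_lattice(obj$tunnel, it$spacing %||% 0.02)
    mod <- infotaxis_model(D = it$D %||% 0.09,
                           R_emit = it$R_emit %||% 1000,
                           V = obj$tunnel$wind_speed,
                           a_det = it$a_det %||% 0.002,
                           dt = it$dt %||% (lat$spacing / 0.4))
    simulate_batch_infotaxis(n_traj, mod, obj$plume, obj$tunnel, lat,
                             seed = cfg$seed)
  } else if (model == "centerline") {
    k_star <- cfg$k_star %||% calibrate_upwind_gain()
    simulate_batch(n_traj, "centerline", obj$walker, obj$tunnel, obj$plume,
                   seed = cfg$seed, k_star = k_star)
  } else {
    simulate_batch(n_traj, "surge-cast", obj$walker, obj$tunnel, obj$plume,
                   seed = cfg$seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectories(trajs, file.path(out_dir, "trajectories.csv"))
  write_manifest(cfg, out_dir, list(stage = "simulate", model = model,
                                    n_traj = n_traj))
  invisible(trajs)
}

#' Pipeline stage: crossing analyses
#'
#' Extracts crossings from a trajectory table, applies the exclusion rules
#' and runs one of the crossing analyses, writing a tidy CSV
#' (`results.csv`: analysis, timepoint, group, estimate, se, p) and a JSON
#' summary (`summary.json`).
#'
#' @param analysis One of `"conc-curve"`, `"threshold-models"`, `"history"`,
#'   `"crossing-number"`, `"threshold-scan"`.
#' @param traj_path Path to a trajectory CSV (see [write_trajectories()]).
#' @inheritParams pc_synth
#' @return The analysis result object, invisibly.
#' @export
pc_analyze <- function(analysis = c("conc-curve", "threshold-models",
                                    "history", "crossing-number",
                                    "threshold-scan"),
                       traj_path, out_dir, config = NULL) {
  analysis <- match.arg(analysis)
  cfg <- resolve_config(config)
  obj <- config_objects(cfg)
  trajs <- read_trajectories(traj_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  pol <- exclusion_policy(end_margin = obj$tunnel$end_margin)
  csx <- function() apply_exclusions(
    extract_crossings(trajs, obj$plume$threshold), pol, obj$tunnel)
  tidy <- NULL
  result <- switch(analysis,
    "conc-curve" = {
      r <- heading_concentration_curve(csx(),
                                       n_boot = cfg$n_boot %||% 1000)
      tidy <- data.table::data.table(analysis = analysis, timepoint = r$time,
                                     group = "all", estimate = r$estimate,
                                     se = (r$ci_hi - r$ci_lo) / 4, p = r$p)
      r
    },
    "threshold-models" = {
      r <- fit_threshold_models(csx(), timepoint = cfg$timepoint %||% 0.3)
      tidy <- data.table::data.table(
        analysis = analysis, timepoint = r$timepoint,
        group = c("binary", "threshold-linear"),
        estimate = c(r$binary$sse, r$threshold_linear$sse),
        se = NA_real_, p = r$p)
      r
    },
    "history" = {
      r <- history_dependence(csx())
      bt <- r$by_time
      tidy <- data.table::rbindlist(list(
        data.table::data.table(analysis = analysis, timepoint = bt$time,
                               group = "early", estimate = bt$mean_early,
                               se = bt$se_early, p = bt$p),
        data.table::data.table(analysis = analysis, timepoint = bt$time,
                               group = "late", estimate = bt$mean_late,
                               se = bt$se_late, p = bt$p)))
      r
    },
    "crossing-number" = {
      r <- crossing_number_partial_corr(csx(),
                                        n_boot = cfg$n_boot %||% 1000)
      tidy <- data.table::data.table(analysis = analysis, timepoint = 0.4,
                                     group = "all", estimate = r$estimate,
                                     se = diff(r$ci) / 4, p = r$p)
      r
    },
    "threshold-scan" = {
      cands <- cfg$candidates %||%
        (obj$plume$threshold * c(0.25, 0.5, 1, 2, 4, 8))
      r <- threshold_scan(trajs, sort(cands),
                          cfg$capture_threshold %||%
                            (obj$plume$threshold / 4),
                          policy = pol, tunnel = obj$tunnel)
      tidy <- data.table::data.table(analysis = analysis,
                                     timepoint = NA_real_,
                                     group = as.character(r$scores$candidate),
                                     estimate = r$scores$score,
                                     se = r$scores$se, p = NA_real_)
      r
    })
  data.table::fwrite(tidy, file.path(out_dir, "results.csv"))
  summ <- list(analysis = analysis, n_trajectories = length(trajs),
               seed = cfg$seed)
  if (analysis == "threshold-models")
    summ <- c(summ, list(F = result$F, p = result$p))
  if (analysis == "crossing-number")
    summ <- c(summ, list(estimate = result$estimate, p = result$p))
  if (analysis == "threshold-scan")
    summ <- c(summ, list(elbow = result$elbow))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, out_dir, list(stage = "analyze", analysis = analysis))
  invisible(result)
}

#' Pipeline stage: hybrid mixing analysis
#'
#' @param sc_path,it_path Trajectory CSVs for the surge-cast and infotaxis
#'   pools.
#' @param target Target late-minus-early difference, degrees.
#' @inheritParams pc_synth
#' @export
pc_hybrid <- function(sc_path, it_path, target, out_dir, config = NULL) {
  cfg <- resolve_config(config)
  obj <- config_objects(cfg)
  pol <- exclusion_policy(end_margin = obj$tunnel$end_margin)
  cs_sc <- apply_exclusions(
    extract_crossings(read_trajectories(sc_path), obj$plume$threshold),
    pol, obj$tunnel)
  cs_it <- apply_exclusions(
    extract_crossings(read_trajectories(it_path), obj$plume$threshold),
    pol, obj$tunnel)
  res <- match_mixing_fraction(cs_sc, cs_it, target,
                               n_pairings = cfg$n_pairings %||% 100,
                               seed = cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::data.table(pairing = seq_along(res$P_star),
                                            P_star = res$P_star),
                     file.path(out_dir, "p_star.csv"))
  jsonlite::write_json(list(mean = res$mean, sd = res$sd, target = target,
                            window = res$window, seed = cfg$seed),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, out_dir, list(stage = "hybrid", target = target))
  invisible(res)
}

#' Pipeline stage: occupancy heatmap
#'
#' @param traj_path Trajectory CSV.
#' @param bin Bin size, metres.
#' @inheritParams pc_synth
#' @export
pc_heatmap <- function(traj_path, out_dir, bin = 0.02, config = NULL) {
  cfg <- resolve_config(config)
  obj <- config_objects(cfg)
  occ <- occupancy_heatmap(read_trajectories(traj_path), obj$tunnel, bin)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.table::as.data.table(occ$counts)
  data.table::setnames(tab, sprintf("y_%03d", seq_len(ncol(occ$counts))))
  data.table::fwrite(cbind(data.table::data.table(
    x_lo = occ$x_breaks[-length(occ$x_breaks)]), tab),
    file.path(out_dir, "heatmap.csv"))
  write_manifest(cfg, out_dir, list(stage = "heatmap", bin = bin))
  invisible(occ)
}
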