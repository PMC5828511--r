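#' 2D Gaussian belief over the plume centreline
#'
#' The centerline-inferring agent maintains a Gaussian posterior over the
#' plume centreline position `(y*, z*)` with diagonal covariance. Each plume
#' crossing provides a noisy observation of the centreline (the crossing
#' location), combined by the conjugate Gaussian update; between updates the
#' mean relaxes exponentially to `(0, 0)` and the covariance back to the
#' prior with memory timescale `tau_m`. Defaults follow the standard
#' configuration: likelihood variance `(2 m)^2` per axis, prior variance
#' `(5 m)^2` per axis, `tau_m = 10` s.
#'
#' @param mean Length-2 belief mean `(y*, z*)`, metres.
#' @param var Length-2 current posterior variances (diagonal of K), m^2.
#' @param prior_var Length-2 diagonal of the prior covariance K0, m^2.
#' @param obs_var Length-2 diagonal of the likelihood covariance K_s, m^2.
#' @param tau_m Memory decay timescale, seconds.
#' @return Object of class `centerline_belief`.
#' @export
centerline_belief <- function(mean = c(0, 0), var = c(25, 25),
                              prior_var = c(25, 25), obs_var = c(4, 4),
                              tau_m = 10) {
  stopifnot(length(mean) == 2, length(var) == 2, length(prior_var) == 2,
            length(obs_var) == 2, all(var > 0), all(prior_var > 0),
            all(obs_var > 0), tau_m > 0)
  structure(list(mean = as.numeric(mean), var = as.numeric(var),
                 prior_var = as.numeric(prior_var),
                 obs_var = as.numeric(obs_var), tau_m = tau_m),
            class = "centerline_belief")
}

#' @export
print.centerline_belief <- function(x, ...) {
  cat(sprintf(
    "centerline_belief: mean (%.3f, %.3f) m, var (%.3g, %.3g) m^2, |K| = %.3g m^4\n",
    x$mean[1], x$mean[2], x$var[1], x$var[2], prod(x$var)))
  invisible(x)
}

#' Bayesian update of the centreline belief
#'
#' First applies memory decay over the elapsed interval (mean relaxes toward
#' `(0, 0)`, covariance toward the prior, both with timescale `tau_m`), then
#' the conjugate Gaussian update with the crossing location as observation:
#' `K_post = (K_prior^-1 + K_s^-1)^-1`,
#' `mean_post = K_post (K_prior^-1 mean_prior + K_s^-1 obs)`.
#'
#' @param belief A [centerline_belief()].
#' @param observation Length-2 crossing location `(y_n, z_n)`, metres.
#' @param elapsed Time since the last update, seconds (`>= 0`).
#' @return Updated [centerline_belief()].
#' @examples
#' b <- centerline_belief()
#' update_centerline_belief(b, c(1.0, 0.1), elapsed = 0)
#' @export
update_centerline_belief <- function(belief, observation, elapsed = 0) {
  stopifnot(inherits(belief, "centerline_belief"), length(observation) == 2,
            all(is.finite(observation)), is.finite(elapsed), elapsed >= 0)
  g <- exp(-elapsed / belief$tau_m)
  m <- belief$mean * g
  v <- belief$prior_var + (belief$var - belief$prior_var) * g
  if (any(v <= 0)) stop("non-positive-definite belief covariance")
  post_v <- 1 / (1 / v + 1 / belief$obs_var)
  post_m <- post_v * (m / v + as.numeric(observation) / belief$obs_var)
  centerline_belief(mean = post_m, var = post_v,
                    prior_var = belief$prior_var, obs_var = belief$obs_var,
                    tau_m = belief$tau_m)
}

#' Decay-only evolution of the centreline belief
#'
#' Applies the memory decay without an observation: after `t >> tau_m` the
#' belief returns to the prior (mean `(0, 0)`, covariance K0).
#'
#' @inheritParams update_centerline_belief
#' @export
decay_centerline_belief <- function(belief, elapsed) {
  g <- exp(-elapsed / belief$tau_m)
  centerline_belief(mean = belief$mean * g,
                    var = belief$prior_var + (belief$var - belief$prior_var) * g,
                    prior_var = belief$prior_var, obs_var = belief$obs_var,
                    tau_m = belief$tau_m)
}
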