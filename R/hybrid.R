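#' Hybrid surge-cast / infotaxis crossings
#'
#' Builds a hybrid crossing pool by pairing each infotaxis crossing with a
#' uniformly random surge-cast crossing of the same crossing number and
#' forming the convex combination of their heading-change time courses,
#' `Delta h_hybrid(t) = P/100 * Delta h_surge-cast(t) +
#' (1 - P/100) * Delta h_infotaxis(t)`.
#' The hybrid crossing inherits the infotaxis crossing's number (and hence
#' its early/late label); its validity mask is the conjunction of the two
#' parents'.
#'
#' @param cs_sc Surge-cast [crossing_set].
#' @param cs_it Infotaxis [crossing_set] (must share the same grid).
#' @param P Mixing percentage in `[0, 100]` (share of surge-cast).
#' @param seed Optional pairing seed.
#' @return List of class `hybrid_crossings`: `dh` (crossings x timepoints
#'   heading-change matrix), `valid`, `crossing_number`, `pairing` (chosen
#'   surge-cast row per infotaxis crossing), `grid`, `P`.
#' @export
make_hybrid_crossings <- function(cs_sc, cs_it, P, seed = NULL) {
  stopifnot(inherits(cs_sc, "crossing_set"), inherits(cs_it, "crossing_set"),
            isTRUE(all.equal(cs_sc$grid, cs_it$grid)),
            is.finite(P), P >= 0, P <= 100)
  if (!is.null(seed)) set.seed(seed)
  pairing <- pair_by_crossing_number(cs_sc, cs_it)
  hybrid_from_pairing(cs_sc, cs_it, pairing, P)
}

pair_by_crossing_number <- function(cs_sc, cs_it) {
  sc_by_n <- split(seq_len(nrow(cs_sc$meta)), cs_sc$meta$crossing_number)
  need <- unique(cs_it$meta$crossing_number)
  miss <- setdiff(as.character(need), names(sc_by_n))
  if (length(miss))
    stop("no surge-cast counterpart for crossing number(s): ",
         paste(miss, collapse = ", "))
  vapply(cs_it$meta$crossing_number, function(nn) {
    pool <- sc_by_n[[as.character(nn)]]
    pool[sample.int(length(pool), 1)]
  }, 0L)
}

hybrid_from_pairing <- function(cs_sc, cs_it, pairing, P) {
  w <- P / 100
  dh_sc <- delta_h(cs_sc)[pairing, , drop = FALSE]
  dh_it <- delta_h(cs_it)
  structure(list(dh = w * dh_sc + (1 - w) * dh_it,
                 valid = cs_sc$valid[pairing, , drop = FALSE] & cs_it$valid,
                 crossing_number = cs_it$meta$crossing_number,
                 pairing = pairing, grid = cs_it$grid, P = P),
            class = "hybrid_crossings")
}

# late-minus-early difference of window-averaged Delta h for a dh matrix
late_early_diff <- function(dh, valid, crossing_number, grid, window,
                            early = c(1, 2)) {
  sel <- grid >= window[1] - 1e-12 & grid <= window[2] + 1e-12
  d <- dh[, sel, drop = FALSE]
  v <- valid[, sel, drop = FALSE]
  d[!v] <- NA_real_
  avg <- rowMeans(d, na.rm = TRUE)
  ok <- is.finite(avg)
  e <- crossing_number[ok] %in% early
  if (!any(e) || all(e)) return(NA_real_)
  mean(avg[ok][!e]) - mean(avg[ok][e])
}

#' Late-minus-early difference of a crossing pool
#'
#' Window-averaged (default 0.3-0.8 s post-crossing) heading change,
#' compared between late (crossing number 3+) and early (1-2) crossings.
#' Positive values mean later crossings are more crosswind.
#'
#' @param cs A [crossing_set] or `hybrid_crossings`.
#' @param window Averaging window, seconds.
#' @param early Early crossing numbers.
#' @export
pool_history_difference <- function(cs, window = c(0.3, 0.8),
                                    early = c(1, 2)) {
  if (inherits(cs, "hybrid_crossings"))
    late_early_diff(cs$dh, cs$valid, cs$crossing_number, cs$grid, window,
                    early)
  else
    late_early_diff(delta_h(cs), cs$valid, cs$meta$crossing_number,
                    cs$grid, window, early)
}

#' Find the mixing percentage matching a target history difference
#'
#' For each of `n_pairings` random same-crossing-number pairings, the
#' late-minus-early difference of the hybrid pool is an exactly linear
#' function of the mixing percentage P (linearity of the convex combination
#' and of group means), so the P minimizing the distance to `target` has a
#' closed form, clipped to `[0, 100]`. Returns the distribution of the
#' per-pairing optimum.
#'
#' @param cs_sc,cs_it Surge-cast and infotaxis [crossing_set]s.
#' @param target Target late-minus-early difference, degrees (an input: the
#'   original analyses matched the empirical fly value, which depends on the
#'   dataset at hand).
#' @param window Averaging window, seconds (default 0.3-0.8 s).
#' @param n_pairings Number of random pairings.
#' @param seed RNG seed.
#' @param early Early crossing numbers.
#' @return Object of class `hybrid_match`: list with `P_star` (per-pairing
#'   optima), `mean`, `sd`, `d_it` and `d_sc` (the endpoint differences).
#' @export
match_mixing_fraction <- function(cs_sc, cs_it, target, window = c(0.3, 0.8),
                                  n_pairings = 100, seed = NULL,
                                  early = c(1, 2)) {
  stopifnot(is.finite(target))
  if (!is.null(seed)) set.seed(seed)
  d_it <- pool_history_difference(cs_it, window, early)
  if (!is.finite(d_it)) stop("infotaxis pool has no early/late contrast")
  ps <- numeric(n_pairings)
  d_scs <- numeric(n_pairings)
  for (b in seq_len(n_pairings)) {
    pairing <- pair_by_crossing_number(cs_sc, cs_it)
    # endpoint differences under the pairing's shared validity mask; the
    # hybrid difference is exactly linear between them:
    # difference(P) = d0 + (P/100) (d100 - d0)
    hyb0 <- hybrid_from_pairing(cs_sc, cs_it, pairing, 0)
    hyb100 <- hybrid_from_pairing(cs_sc, cs_it, pairing, 100)
    d0 <- late_early_diff(hyb0$dh, hyb0$valid, hyb0$crossing_number,
                          hyb0$grid, window, early)
    d100 <- late_early_diff(hyb100$dh, hyb100$valid, hyb100$crossing_number,
                            hyb100$grid, window, early)
    slope <- d100 - d0
    if (abs(slope) < 1e-12)
      stop("hybrid difference does not depend on P (identical pools)")
    ps[b] <- min(100, max(0, 100 * (target - d0) / slope))
    d_scs[b] <- d100
  }
  structure(list(P_star = ps, mean = mean(ps), sd = stats::sd(ps),
                 d_it = d_it, d_sc = d_scs, target = target,
                 window = window),
            class = "hybrid_match")
}

#' @export
print.hybrid_match <- function(x, ...) {
  cat(sprintf(
    "hybrid_match: P* = %.1f%% +/- %.1f%% surge-cast over %d pairings (target %.2f deg)\n",
    x$mean, x$sd, length(x$P_star), x$target))
  invisible(x)
}
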