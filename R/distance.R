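#' Distance specification for IICR curve fitting
#'
#' @param kind `"omega"` for the coalescence-density-weighted distance,
#'   `"visual"` for the plain sum of absolute node differences (which, on a
#'   log-distributed grid, tracks the perceived difference between the
#'   log-scale plots).
#' @param omega Positive weight-shifting exponent applied to the target's
#'   coalescence-time density when building the weights; `omega < 1` damps
#'   the density (shifting weight toward ancient times), `omega > 1`
#'   exaggerates it.  Default 1.
#' @param range Optional `c(g_min, g_max)` restricting the fit: grid
#'   intervals whose right endpoint falls outside the range are dropped
#'   from the sum (and the weights renormalized over the kept intervals).
#' @return An object of class `"distance_spec"`.
#' @export
distance_spec <- function(kind = c("omega", "visual"), omega = 1,
                          range = NULL) {
  kind <- match.arg(kind)
  if (!is.finite(omega) || omega <= 0) stop("omega must be positive")
  if (!is.null(range)) {
    range <- as.numeric(range)
    if (length(range) != 2L || range[1] >= range[2])
      stop("range must be c(g_min, g_max) with g_min < g_max")
  }
  structure(list(kind = kind, omega = omega, range = range),
            class = "distance_spec")
}

#' Reconstruct the coalescence-time density of a stepwise IICR
#'
#' Inverts the survival identity `P(T2 > t) = exp(-int_0^t dx / IICR(x))`
#' on the step representation: with `S_j = exp(sum_{k<=j} (tau_{k-1} -
#' tau_k)/y_k)` the implied survival at `tau_j`, the density at a node is
#' the survival divided by the IICR value there.  The curve is
#' right-continuous, so interior nodes use the value of the interval to
#' their right (`f0(tau_j) = S_j / y_{j+1}`, `f0(0) = 1/y_1`); the last
#' node uses its own interval's value.
#'
#' @param target A [stepwise_iicr()].
#' @return Numeric vector `f0(tau_0), ..., f0(tau_I)` (length I + 1), all
#'   positive, with a nonincreasing implied survival factor.
#' @export
reconstruct_density <- function(target) {
  stopifnot(inherits(target, "stepwise_iicr"))
  y <- target$values
  tau <- target$grid
  if (any(y <= 0)) stop("IICR values must be positive")
  I <- length(y)
  s_fac <- exp(cumsum((tau[-(I + 1L)] - tau[-1]) / y)) # survival at tau_1..tau_I
  surv <- c(1, s_fac)
  surv / c(y, y[I])
}

#' Discretized distance weights
#'
#' `w(tau_j) = f0(tau_j)^omega / sum_k f0(tau_k)^omega` — the normalization
#' divides by the plain sum of the supplied values (no interval-width
#' factor).
#'
#' @param f0 Positive density values at the grid nodes.
#' @param omega Positive weight-shifting exponent.
#' @return Weights of the same length, positive and summing to 1.
#' @export
compute_weights <- function(f0, omega = 1) {
  if (!length(f0) || all(f0 == 0)) stop("f0 must contain positive values")
  if (any(f0 < 0)) stop("f0 must be nonnegative")
  w <- f0^omega
  w / sum(w)
}

# candidate IICR values at given (target-scale) times
eval_candidate <- function(candidate, t, scaled_target = FALSE) {
  if (inherits(candidate, "stepwise_iicr")) return(eval_stepwise(candidate, t))
  if (inherits(candidate, "scaled_demography")) {
    r <- iicr_curve_raw(candidate$base, t / (2 * candidate$N))
    return(candidate$N * r$iicr)
  }
  if (inherits(candidate, "island_demography")) {
    if (scaled_target)
      stop("scaled target needs a scaled_demography or curve candidate")
    return(iicr_curve_raw(candidate, t)$iicr)
  }
  if (is.function(candidate)) return(candidate(t))
  stop("candidate must be a demography, a stepwise_iicr or a function")
}

# which intervals enter the sum: whole intervals inside [g_min, g_max]
kept_intervals <- function(target, spec) {
  left <- target$grid[-length(target$grid)]
  right <- target$grid[-1]
  keep <- rep(TRUE, length(right))
  if (!is.null(spec$range))
    keep <- left >= spec$range[1] & right <= spec$range[2]
  if (!any(keep)) stop("the range restriction excludes every interval")
  keep
}

#' Weighted and visual distances between IICR curves
#'
#' `distance_omega()` computes
#' `sum_j |y_j - IICR_phi(tau_j)| w(tau_{j-1}) (tau_j - tau_{j-1})`, the
#' first-degree discretization of the density-weighted L1 distance: the
#' candidate is evaluated at the right endpoint of each interval while the
#' weight uses the left endpoint.  Weights are the [compute_weights()] of
#' the target's reconstructed density at the left endpoints, normalized
#' over exactly the intervals kept by the range restriction.
#' `distance_visual()` is the plain sum of absolute node differences.
#'
#' @param target A [stepwise_iicr()].
#' @param candidate An [island_demography()], [scaled_demography()],
#'   [stepwise_iicr()] or function of time, evaluated at the target's grid.
#' @param spec A [distance_spec()].
#' @return Nonnegative scalar; 0 iff the curves agree at every kept node.
#' @export
distance_omega <- function(target, candidate,
                           spec = distance_spec("omega")) {
  stopifnot(inherits(target, "stepwise_iicr"))
  keep <- kept_intervals(target, spec)
  f0 <- reconstruct_density(target)
  I <- length(target$values)
  w_left <- f0[seq_len(I)]^spec$omega # f0 at tau_0 .. tau_{I-1}
  w_left <- w_left[keep] / sum(w_left[keep])
  tau <- target$grid
  v <- eval_candidate(candidate, tau[-1][keep], target$scaled)
  sum(abs(target$values[keep] - v) * w_left * diff(tau)[keep])
}

#' @rdname distance_omega
#' @export
distance_visual <- function(target, candidate,
                            spec = distance_spec("visual")) {
  stopifnot(inherits(target, "stepwise_iicr"))
  keep <- kept_intervals(target, spec)
  v <- eval_candidate(candidate, target$grid[-1][keep], target$scaled)
  sum(abs(target$values[keep] - v))
}

#' @rdname distance_omega
#' @export
iicr_distance <- function(target, candidate, spec = distance_spec()) {
  if (spec$kind == "omega") distance_omega(target, candidate, spec)
  else distance_visual(target, candidate, spec)
}

# Per-interval factor |y_j - v_j| is multiplied by in the objective:
# weight * width for the omega distance, 1 for visual, 0 for dropped
# intervals.  Precomputed once per inference target.
distance_wdt <- function(target, spec) {
  keep <- kept_intervals(target, spec)
  I <- length(target$values)
  wdt <- numeric(I)
  if (spec$kind == "omega") {
    f0 <- reconstruct_density(target)
    w <- f0[seq_len(I)]^spec$omega
    wdt[keep] <- w[keep] / sum(w[keep]) * diff(target$grid)[keep]
  } else {
    wdt[keep] <- 1
  }
  wdt
}
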