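#' Lumped transition-rate matrix of one stationary component
#'
#' For a sample of two lineages in a symmetric n-island component with total
#' migration rate `M` and relative deme size `s`, the coalescent lumps (by
#' exchangeability of the demes) into three states: S (both lineages in the
#' same deme), D (different demes) and C (coalesced, absorbing).  Rates are
#' in units of 1/(2N generations): S loses mass to C at rate `1/s` and to D
#' at rate `M`; D returns to S at rate `M/(n-1)`.
#'
#' @param n Number of islands (>= 2).
#' @param M Total migration rate received by an island (> 0).
#' @param s Relative deme size (> 0).
#' @return A 3x3 generator matrix with dimnames `c("S", "D", "C")`.
#' @examples
#' build_rate_matrix(2, 1, 1)
#' @export
build_rate_matrix <- function(n, M, s = 1) {
  if (n < 2) stop("n must be >= 2 (the D -> S rate is undefined otherwise)")
  if (M <= 0 || s <= 0) stop("M and s must be positive")
  q <- matrix(0, 3, 3, dimnames = list(c("S", "D", "C"), c("S", "D", "C")))
  q["S", ] <- c(-(1 / s + M), M, 1 / s)
  q["D", ] <- c(M / (n - 1), -M / (n - 1), 0)
  q
}

#' Log-spaced discretization grid
#'
#' Returns `tau_0 = 0` followed by `I` points in geometric progression from
#' `t_min` to `t_max` (both included), the discretization on which stepwise
#' IICR curves are represented.
#'
#' @param t_min,t_max Positive interval endpoints, `t_min < t_max`.
#' @param I Number of nonzero grid points (>= 2).
#' @return Numeric vector of length `I + 1`, strictly increasing from 0.
#' @examples
#' log_grid(0.01, 100, 5)
#' @export
log_grid <- function(t_min, t_max, I = 64L) {
  if (!(t_min > 0 && t_max > t_min)) stop("need 0 < t_min < t_max")
  if (I < 2L) stop("I must be >= 2")
  c(0, 10^seq(log10(t_min), log10(t_max), length.out = I))
}

iicr_curve_raw <- function(d, times) {
  .cpp_iicr_curve(d$n, d$event_times, d$migration_rates, d$deme_sizes,
                  times)
}

#' Survival and density of the pairwise coalescence time
#'
#' Propagates the lumped-chain state distribution (started with both
#' lineages in the same deme, the sampling configuration of one diploid
#' individual) through the consecutive components by matrix exponentials,
#' returning `P(T2 > t)` and the density `f(t)` at each time.  The density
#' is obtained directly as (mass on S) / s of the active component rather
#' than by numerical differentiation.
#'
#' @param d An [island_demography()].
#' @param t Vector of nonnegative times (2N generations).
#' @return A data frame with columns `t`, `p_same`, `p_diff`, `survival`,
#'   `density`.
#' @export
survival_and_density <- function(d, t) {
  stopifnot(inherits(d, "island_demography"))
  if (any(t < 0)) stop("t must be nonnegative")
  o <- order(t)
  r <- iicr_curve_raw(d, t[o])
  out <- data.frame(t = t[o], p_same = r$p_same, p_diff = r$p_diff,
                    survival = r$survival, density = r$density)
  out[order(o), , drop = FALSE]
}

#' Stepwise IICR curve
#'
#' A discretized IICR: a grid `tau_0 = 0 < tau_1 < ... < tau_I` and values
#' `y_1..y_I` with `IICR(t) = y_j` on `[tau_{j-1}, tau_j)`.  This is the
#' universal exchange format: exact curves, empirical curves and scaled
#' PSMC output all take this form.
#'
#' @param grid Strictly increasing time grid starting at 0 (length I + 1).
#' @param values Positive values `y_1..y_I` (length I).
#' @param scaled `FALSE` for dimensionless curves in 2N-generation units,
#'   `TRUE` for curves in generations / haploid size.
#' @return An object of class `"stepwise_iicr"`.
#' @export
stepwise_iicr <- function(grid, values, scaled = FALSE) {
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) != length(values) + 1L)
    stop("grid must have one more point than values")
  if (grid[1] != 0) stop("grid must start at tau_0 = 0")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (length(values) < 1L || any(!is.finite(values)) || any(values <= 0))
    stop("values must be positive and finite")
  structure(list(grid = grid, values = values, scaled = isTRUE(scaled)),
            class = "stepwise_iicr")
}

#' @export
print.stepwise_iicr <- function(x, ...) {
  I <- length(x$values)
  cat("Stepwise IICR (", if (x$scaled) "scaled, generations"
      else "unscaled, 2N generations", "), ", I, " intervals on [",
      format(x$grid[2]), ", ", format(x$grid[I + 1]), "]\n", sep = "")
  cat("  values: ", paste(signif(utils::head(x$values, 5), 4),
                          collapse = ", "),
      if (I > 5) ", ...", "\n", sep = "")
  invisible(x)
}

#' Exact IICR of a piecewise n-island model
#'
#' Evaluates `IICR(t) = P(T2 > t) / f(t)` at the right endpoints of a
#' discretization grid.  The values are exact to machine precision (matrix
#' exponentials of the 2x2 transient block in closed form); the step curve
#' is only a discretization of the smooth underlying function.
#'
#' @param d An [island_demography()].
#' @param grid Discretization grid from [log_grid()] (first element 0).
#' @return A [stepwise_iicr()] (unscaled).
#' @examples
#' d <- island_demography(2, migration_rates = 1)
#' exact_iicr(d, log_grid(0.01, 100, 8))
#' @export
exact_iicr <- function(d, grid = log_grid(1e-2, 1e2, 64L)) {
  stopifnot(inherits(d, "island_demography"))
  if (grid[1] != 0 || any(diff(grid) <= 0))
    stop("grid must start at 0 and be strictly increasing")
  tau <- grid[-1]
  r <- iicr_curve_raw(d, tau)
  if (any(r$density <= 0) || any(!is.finite(r$iicr)))
    stop("coalescence density underflows on this grid; ",
         "use a smaller t_max")
  stepwise_iicr(grid, r$iicr, scaled = FALSE)
}

#' Scale an IICR curve by a reference deme size
#'
#' `sIICR(g) = N * IICR(g / 2N)`: times move to generations (factor 2N) and
#' values to haploid size (factor N), making model curves comparable to
#' scaled PSMC output.
#'
#' @param curve An unscaled [stepwise_iicr()].
#' @param N Positive reference deme size (haploid genes).
#' @return A scaled [stepwise_iicr()].
#' @export
scale_iicr <- function(curve, N) {
  stopifnot(inherits(curve, "stepwise_iicr"))
  if (curve$scaled) stop("curve is already scaled")
  if (!is.finite(N) || N <= 0) stop("N must be positive")
  stepwise_iicr(curve$grid * 2 * N, curve$values * N, scaled = TRUE)
}

#' @rdname scale_iicr
#' @param curve,N As above; `unscale_iicr()` inverts the transform.
#' @export
unscale_iicr <- function(curve, N) {
  stopifnot(inherits(curve, "stepwise_iicr"))
  if (!curve$scaled) stop("curve is already unscaled")
  if (!is.finite(N) || N <= 0) stop("N must be positive")
  stepwise_iicr(curve$grid / (2 * N), curve$values / N, scaled = FALSE)
}

#' Simulate pairwise coalescence times
#'
#' Gillespie simulation of the lumped piecewise chain started in state S:
#' within a component, holding times are exponential with the state's total
#' exit rate; a holding time that would cross a component boundary is
#' truncated there and redrawn under the next component's rates (exact by
#' the memoryless property).
#'
#' @param d An [island_demography()].
#' @param n_draws Number of independent T2 draws.
#' @param seed Optional integer seed.
#' @return An object of class `"t2_sample"`: list with `draws` (2N
#'   generations) and `demography`.
#' @export
simulate_t2 <- function(d, n_draws, seed = NULL) {
  stopifnot(inherits(d, "island_demography"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- .cpp_simulate_t2(d$n, d$event_times, d$migration_rates,
                            d$deme_sizes, as.integer(n_draws))
  structure(list(draws = draws, demography = d), class = "t2_sample")
}

#' @export
print.t2_sample <- function(x, ...) {
  cat("T2 sample:", length(x$draws), "draws, mean",
      format(mean(x$draws), digits = 4), "(2N generations)\n")
  invisible(x)
}

#' Empirical IICR from simulated coalescence times
#'
#' Builds a stepwise IICR from a T2 sample via the Kaplan-Meier survival
#' estimator (with no censoring this is the empirical survival function
#' `S^(t)`).  On each grid interval the IICR value is the discrete
#' survival-to-density-mass ratio
#' `y_j = S^(tau_{j-1}) * (tau_j - tau_{j-1}) / (S^(tau_{j-1}) - S^(tau_j))`.
#' Intervals in which no coalescence was observed (zero denominator) yield
#' no value of their own: they are merged into the following output step,
#' whose value is still computed from its own interval's endpoints.
#' Trailing empty intervals are dropped.
#'
#' @param sample A [simulate_t2()] result (or any list with `$draws`).
#' @param grid Discretization grid (first element 0).
#' @return A [stepwise_iicr()] (unscaled).
#' @export
empirical_iicr <- function(sample, grid = log_grid(1e-2, 1e2, 64L)) {
  draws <- if (is.list(sample)) sample$draws else sample
  if (length(draws) < 1L) stop("empty T2 sample")
  if (grid[1] != 0 || any(diff(grid) <= 0))
    stop("grid must start at 0 and be strictly increasing")
  s_grid <- vapply(grid, function(ti) mean(draws > ti), 0)
  I <- length(grid) - 1L
  ds <- s_grid[-(I + 1L)] - s_grid[-1]
  keep <- which(ds > 0)
  if (!length(keep))
    stop("no coalescences observed inside the grid")
  y <- s_grid[keep] * (grid[keep + 1L] - grid[keep]) / ds[keep]
  stepwise_iicr(c(0, grid[keep + 1L]), y, scaled = FALSE)
}

#' Read and write stepwise IICR curves
#'
#' TSV files have columns `time_left`, `time_right`, `iicr`; JSON files
#' store `grid`, `values` and `scaled`.  Both round-trip losslessly (TSV at
#' full double precision).
#'
#' @param curve A [stepwise_iicr()].
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else TSV).
#' @return `read_iicr()` returns the curve; writers return `path`
#'   invisibly.
#' @export
write_iicr <- function(curve, path) {
  stopifnot(inherits(curve, "stepwise_iicr"))
  I <- length(curve$values)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(grid = curve$grid, values = curve$values,
                              scaled = curve$scaled),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(time_left = format(curve$grid[-(I + 1L)], digits = 17),
                     time_right = format(curve$grid[-1], digits = 17),
                     iicr = format(curve$values, digits = 17))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_iicr
#' @param scaled Used when reading TSV (which does not carry the flag).
#' @export
read_iicr <- function(path, scaled = FALSE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(stepwise_iicr(x$grid, x$values, scaled = isTRUE(x$scaled)))
  }
  df <- read.table(path, header = TRUE, sep = "\t")
  stepwise_iicr(c(df$time_left[1], df$time_right), df$iicr, scaled = scaled)
}

# Evaluate a stepwise curve at arbitrary times.  Grid nodes take their own
# interval's value (left-open lookup), so evaluating a curve at its right
# endpoints returns the y_j themselves and self-distances vanish; times
# beyond the grid take the last value.
eval_stepwise <- function(curve, t) {
  idx <- findInterval(t, curve$grid, left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(curve$values)] <- length(curve$values)
  curve$values[idx]
}
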