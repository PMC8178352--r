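#' Piecewise-stationary symmetric n-island demography
#'
#' Describes a history with `n` islands (demes) of constant relative size in
#' which the total migration rate `M` received by an island (and optionally
#' the relative deme size `s`) changes at `gamma >= 0` event times.  Time is
#' measured in units of 2N generations; with `gamma` events there are
#' `c = gamma + 1` components (maximal intervals of constant parameters),
#' component `i` being active on `[t_i, t_{i+1})` (with `t_0 = 0`).
#'
#' @param n Integer number of islands, at least 2.
#' @param event_times Numeric vector of `gamma` strictly increasing positive
#'   event times, in units of 2N generations.  May be empty (stationary
#'   model).
#' @param migration_rates Numeric vector of `gamma + 1` positive migration
#'   rates, one per component.  `M` is the total rate at which an island
#'   receives migrants, i.e. `(n - 1)` times the pairwise rate.
#' @param deme_sizes Numeric vector of `gamma + 1` positive relative deme
#'   sizes (default all 1).
#' @return An object of class `"island_demography"`.
#' @examples
#' d <- island_demography(10, event_times = 1, migration_rates = c(5, 0.5))
#' d
#' @seealso [scaled_demography()], [exact_iicr()], [validate_demography()]
#' @export
island_demography <- function(n, event_times = numeric(), migration_rates,
                              deme_sizes = rep(1, length(event_times) + 1L)) {
  n <- as.integer(n)
  event_times <- as.numeric(event_times)
  migration_rates <- as.numeric(migration_rates)
  deme_sizes <- as.numeric(deme_sizes)
  gamma <- length(event_times)
  if (length(migration_rates) != gamma + 1L)
    stop("need ", gamma + 1L, " migration rates for ", gamma, " events")
  if (length(deme_sizes) != gamma + 1L)
    stop("need ", gamma + 1L, " deme sizes for ", gamma, " events")
  d <- structure(
    list(n = n, event_times = event_times,
         migration_rates = migration_rates, deme_sizes = deme_sizes),
    class = "island_demography")
  stop_if_malformed(d)
  d
}

# structural sanity (hard errors); bound violations are data, see
# validate_demography()
stop_if_malformed <- function(d) {
  if (is.na(d$n) || d$n < 2L) stop("n must be an integer >= 2")
  if (any(!is.finite(d$event_times)) || any(d$event_times <= 0))
    stop("event times must be positive and finite")
  if (length(d$event_times) > 1L && any(diff(d$event_times) <= 0))
    stop("event times must be strictly increasing")
  if (any(!is.finite(d$migration_rates)) || any(d$migration_rates <= 0))
    stop("migration rates must be positive")
  if (any(!is.finite(d$deme_sizes)) || any(d$deme_sizes <= 0))
    stop("deme sizes must be positive")
  invisible(d)
}

#' @export
print.island_demography <- function(x, ...) {
  c_ <- length(x$migration_rates)
  cat("Piecewise-stationary n-island demography\n")
  cat("  islands n:", x$n, "  components:", c_, "\n")
  if (c_ > 1L)
    cat("  event times (2N gen):", paste(signif(x$event_times, 4),
                                         collapse = ", "), "\n")
  cat("  migration rates M:", paste(signif(x$migration_rates, 4),
                                    collapse = ", "), "\n")
  if (any(x$deme_sizes != 1))
    cat("  deme sizes s:", paste(signif(x$deme_sizes, 4),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Attach a reference deme size to a demography
#'
#' The unscaled model is dimensionless; a reference size `N` (number of
#' haploid genes corresponding to local size 1) converts model time to
#' generations and IICR values to haploid size, see [scale_iicr()].
#'
#' @param N Positive reference deme size, in haploid genes.
#' @param base An [island_demography()].
#' @return An object of class `"scaled_demography"`.
#' @export
scaled_demography <- function(N, base) {
  stopifnot(inherits(base, "island_demography"))
  if (!is.finite(N) || N <= 0) stop("N must be positive")
  structure(list(N = as.numeric(N), base = base),
            class = "scaled_demography")
}

#' @export
print.scaled_demography <- function(x, ...) {
  cat("Scaled (reference deme size N =", format(x$N), "haploid genes)\n")
  print(x$base)
  invisible(x)
}

#' Parameter-space bounds
#'
#' Closed intervals bounding each model parameter, used both to validate
#' demographies and as the constraint box of the inference search.  Setting
#' `s_range = c(1, 1)` (the default) fixes all deme sizes to 1 and reduces
#' the space to `2 * gamma + 2` free parameters.
#'
#' @param n_range Integer interval for the number of islands (min >= 2).
#' @param t_range Interval for event times (2N generations), or a
#'   `gamma x 2` matrix of per-event intervals.
#' @param M_range Interval for migration rates, or a `(gamma+1) x 2` matrix.
#' @param s_range Interval for deme sizes, or a `(gamma+1) x 2` matrix;
#'   default `c(1, 1)`.
#' @param N_range Optional interval for the reference size (scaled fits).
#' @param gamma Number of demographic events the bounds apply to.
#' @return An object of class `"param_bounds"`.
#' @examples
#' param_bounds(c(2, 50), c(0.1, 50), c(0.05, 50), gamma = 2)
#' @export
param_bounds <- function(n_range, t_range = NULL, M_range, s_range = c(1, 1),
                         N_range = NULL, gamma = if (is.null(t_range)) 0L
                                         else nrow(as_ranges(t_range, 1L))) {
  gamma <- as.integer(gamma)
  if (gamma < 0L) stop("gamma must be >= 0")
  b <- structure(list(
    n_range = c(as.integer(n_range[1]), as.integer(n_range[2])),
    t_ranges = if (gamma > 0L) as_ranges(t_range, gamma) else
      matrix(numeric(), 0L, 2L),
    M_ranges = as_ranges(M_range, gamma + 1L),
    s_ranges = as_ranges(s_range, gamma + 1L),
    N_range = if (is.null(N_range)) NULL else as.numeric(N_range),
    gamma = gamma), class = "param_bounds")
  check_bounds(b)
  b
}

as_ranges <- function(x, k) {
  if (is.matrix(x)) {
    if (ncol(x) != 2L || nrow(x) != k)
      stop("range matrix must be ", k, " x 2")
    return(matrix(as.numeric(x), k, 2L))
  }
  matrix(as.numeric(x), k, 2L, byrow = TRUE)
}

check_bounds <- function(b) {
  bad <- function(r) any(r[, 1] > r[, 2])
  if (b$n_range[1] < 2L) stop("n_range: lower bound must be >= 2")
  if (b$n_range[1] > b$n_range[2]) stop("n_range: inverted interval")
  if (nrow(b$t_ranges) && (bad(b$t_ranges) || any(b$t_ranges[, 1] <= 0)))
    stop("t_range: intervals must be positive and ordered")
  if (bad(b$M_ranges) || any(b$M_ranges[, 1] <= 0))
    stop("M_range: intervals must be positive and ordered")
  if (bad(b$s_ranges) || any(b$s_ranges[, 1] <= 0))
    stop("s_range: intervals must be positive and ordered")
  if (!is.null(b$N_range) &&
      (b$N_range[1] > b$N_range[2] || b$N_range[1] <= 0))
    stop("N_range: interval must be positive and ordered")
  invisible(b)
}

#' @export
print.param_bounds <- function(x, ...) {
  cat("Parameter bounds (gamma =", x$gamma, "events)\n")
  cat("  n in [", x$n_range[1], ",", x$n_range[2], "]\n")
  if (x$gamma > 0L)
    cat("  t_i in [", paste(apply(x$t_ranges, 1, function(r)
      paste0(format(r[1]), "; ", format(r[2]))), collapse = "], ["), "]\n")
  cat("  M_i in [", paste(apply(x$M_ranges, 1, function(r)
    paste0(format(r[1]), "; ", format(r[2]))), collapse = "], ["), "]\n")
  if (!is.null(x$N_range))
    cat("  N in [", x$N_range[1], ",", x$N_range[2], "]\n")
  invisible(x)
}

#' Check a demography against parameter bounds
#'
#' Returns descriptions of the violated constraints; an empty character
#' vector means the demography lies inside the bounded parameter space.
#' Violations are data, not errors, so batch pipelines can record them.
#'
#' @param d An [island_demography()].
#' @param b A [param_bounds()] with matching `gamma`.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_demography <- function(d, b) {
  stopifnot(inherits(d, "island_demography"), inherits(b, "param_bounds"))
  v <- character()
  gamma <- length(d$event_times)
  if (gamma != b$gamma)
    return(sprintf("gamma mismatch: demography has %d events, bounds %d",
                   gamma, b$gamma))
  if (d$n < max(2L, b$n_range[1])) v <- c(v, "n below n_min")
  if (d$n > b$n_range[2]) v <- c(v, "n above n_max")
  if (gamma > 1L && any(diff(d$event_times) <= 0))
    v <- c(v, "event_times not increasing")
  for (i in seq_len(gamma)) {
    if (d$event_times[i] <= 0) v <- c(v, sprintf("t_%d not positive", i))
    else if (d$event_times[i] < b$t_ranges[i, 1] ||
             d$event_times[i] > b$t_ranges[i, 2])
      v <- c(v, sprintf("t_%d outside bounds", i))
  }
  for (i in seq_len(gamma + 1L)) {
    if (d$migration_rates[i] <= 0)
      v <- c(v, sprintf("M_%d not positive", i - 1L))
    else if (d$migration_rates[i] < b$M_ranges[i, 1] ||
             d$migration_rates[i] > b$M_ranges[i, 2])
      v <- c(v, sprintf("M_%d outside bounds", i - 1L))
    if (d$deme_sizes[i] <= 0)
      v <- c(v, sprintf("s_%d not positive", i - 1L))
    else if (d$deme_sizes[i] < b$s_ranges[i, 1] ||
             d$deme_sizes[i] > b$s_ranges[i, 2])
      v <- c(v, sprintf("s_%d outside bounds", i - 1L))
  }
  v
}

#' Sample random demographic scenarios (continuous strategy)
#'
#' Draws `L` independent scenarios from a bounded parameter space: `n`
#' discrete-uniform on its integer range, each event time log-uniform (base
#' 10) in its interval with the `gamma` drawn times then sorted ascending,
#' and each migration rate and deme size uniform in its interval.  The
#' log-uniform time prior reflects the log-scale distribution of information
#' in an IICR curve.
#'
#' @param b A [param_bounds()].
#' @param gamma Number of events; defaults to `b$gamma`.
#' @param L Number of scenarios.
#' @param seed Optional integer seed for reproducibility.
#' @return List of `L` [island_demography()] objects.
#' @export
sample_continuous <- function(b, gamma = b$gamma, L, seed = NULL) {
  stopifnot(inherits(b, "param_bounds"), L >= 1)
  if (gamma != b$gamma) stop("gamma does not match the bounds object")
  if (!is.null(seed)) set.seed(seed)
  n_values <- seq.int(b$n_range[1], b$n_range[2])
  lapply(seq_len(L), function(j) {
    n <- n_values[sample.int(length(n_values), 1L)]
    t <- if (gamma > 0L)
      sort(10^runif(gamma, log10(b$t_ranges[, 1]), log10(b$t_ranges[, 2])))
    else numeric()
    M <- runif(gamma + 1L, b$M_ranges[, 1], b$M_ranges[, 2])
    s <- runif(gamma + 1L, b$s_ranges[, 1], b$s_ranges[, 2])
    island_demography(n, t, M, s)
  })
}

#' Sample random demographic scenarios (discrete strategy)
#'
#' Draws `L` distinct tuples uniformly without replacement from the
#' Cartesian product of finite per-parameter value sets, sorts the event
#' times, and rejects scenarios in which two consecutive components share
#' the same migration rate (such histories are indistinguishable from a
#' model with one fewer event) or in which two event times coincide.
#'
#' @param n_set,t_set,M_set,s_set Finite sets of admissible values.
#' @param gamma Number of events.
#' @param L Number of distinct scenarios to return.
#' @param seed Optional integer seed.
#' @return List of `L` [island_demography()] objects.
#' @export
sample_discrete <- function(n_set = c(2, 5, 10, 15, 20),
                            t_set = c(1/10, 1/2, 1, 2, 5, 10, 20, 50),
                            M_set = c(1/10, 1/5, 1/2, 1, 2, 5, 10, 20, 50),
                            s_set = 1, gamma = 2L, L, seed = NULL) {
  stopifnot(L >= 1)
  if (!is.null(seed)) set.seed(seed)
  k_size <- length(n_set) * length(t_set)^gamma *
    length(M_set)^(gamma + 1L) * length(s_set)^(gamma + 1L)
  pick <- function(set, k) set[sample.int(length(set), k, replace = TRUE)]
  draw_one <- function() {
    list(n = pick(n_set, 1L),
         t = if (gamma > 0L) sort(pick(t_set, gamma)) else numeric(),
         M = pick(M_set, gamma + 1L),
         s = pick(s_set, gamma + 1L))
  }
  admissible <- function(x) {
    (gamma == 0L || !anyDuplicated(x$t)) &&
      all(diff(x$M) != 0 | gamma == 0L)
  }
  seen <- character()
  out <- vector("list", L)
  got <- 0L
  attempts <- 0L
  max_attempts <- max(10000L, 200L * L)
  while (got < L) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("L = ", L, " exceeds the number of admissible tuples (|K| = ",
           k_size, " before rejection)")
    x <- draw_one()
    if (!admissible(x)) next
    key <- paste(x$n, paste(x$t, collapse = ","), paste(x$M, collapse = ","),
                 paste(x$s, collapse = ","), sep = "|")
    if (key %in% seen) {
      # without replacement: skip duplicates, but fail fast if the space
      # cannot possibly hold L distinct admissible tuples
      if (L > k_size)
        stop("L = ", L, " exceeds |K| = ", k_size)
      next
    }
    seen <- c(seen, key)
    got <- got + 1L
    out[[got]] <- island_demography(x$n, x$t, x$M, x$s)
  }
  out
}

#' Read or write a scenario file
#'
#' Scenarios are stored as JSON objects with keys `n`, `event_times`,
#' `migration_rates`, `deme_sizes` and optionally `N`; the round trip is
#' exact.
#'
#' @param d An [island_demography()] or [scaled_demography()].
#' @param path File path.
#' @return `read_scenario()` returns the demography; `write_scenario()`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(d, path) {
  if (inherits(d, "scaled_demography")) {
    x <- c(list(N = d$N), unclass(d$base))
  } else {
    stopifnot(inherits(d, "island_demography"))
    x <- unclass(d)
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- island_demography(x$n, as.numeric(x$event_times %||% numeric()),
                         x$migration_rates, x$deme_sizes)
  if (!is.null(x$N)) scaled_demography(x$N, d) else d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
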