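#' Settings for the multi-round inference search
#'
#' The search minimizes the distance between the target and the exact model
#' IICR over the bounded parameter space with differential evolution (DE),
#' organized in *rounds*: each round is one complete DE convergence cycle
#' (followed by a Nelder-Mead polish of its best member), and from the
#' second round on one member of the initial population is seeded with the
#' best vector found so far, so the best distance never increases across
#' rounds.  Rounds stop once the distance falls below `tolerance_eps` (and
#' at least `min_rounds` rounds have run) or at `max_rounds`.
#'
#' @param c Number of components (`gamma = c - 1` events).
#' @param bounds A [param_bounds()] with `gamma = c - 1`; deme sizes must
#'   be fixed (`s_range = c(1, 1)`), leaving `2c` free parameters (plus the
#'   reference size for scaled fits).
#' @param distance A [distance_spec()].
#' @param max_rounds,min_rounds Round budget; defaults 500 and 1.
#' @param tolerance_eps Distance below which the search is declared
#'   converged.  Defaults to `1e-10` for unscaled targets and `1e-7` for
#'   scaled ones (meaningful only for exact targets, where the distance can
#'   genuinely reach zero).
#' @param de DE hyper-parameters: `pop_mult` (population = `pop_mult` x
#'   dimension), `mutation` (dither range for F), `recombination`
#'   (crossover probability), `maxiter` (generation cap per round), `tol`
#'   (relative energy-spread convergence threshold), `strategy`
#'   (`"best1bin"` or `"rand1bin"`), `n_polish` (how many top population
#'   members get the Nelder-Mead polish each round).
#' @param scaled `TRUE` to fit a reference size `N` as well (target in
#'   generations); requires `bounds$N_range`.
#' @param seed Optional integer seed making [infer()] deterministic.
#' @return An object of class `"inference_settings"`.
#' @export
inference_settings <- function(c, bounds, distance = distance_spec(),
                               max_rounds = 500L, min_rounds = 1L,
                               tolerance_eps = if (scaled) 1e-7 else 1e-10,
                               de = list(), scaled = FALSE, seed = NULL) {
  stopifnot(inherits(bounds, "param_bounds"),
            inherits(distance, "distance_spec"))
  c <- as.integer(c)
  if (c < 1L) stop("c must be >= 1")
  if (bounds$gamma != c - 1L)
    stop("bounds must have gamma = c - 1 = ", c - 1L)
  if (any(bounds$s_ranges[, 1] != 1) || any(bounds$s_ranges[, 2] != 1))
    stop("the optimizer fixes deme sizes to 1; set s_range = c(1, 1)")
  if (scaled && is.null(bounds$N_range))
    stop("scaled inference needs bounds with an N_range")
  if (max_rounds < min_rounds || min_rounds < 1L)
    stop("need max_rounds >= min_rounds >= 1")
  if (tolerance_eps <= 0) stop("tolerance_eps must be positive")
  de_def <- list(pop_mult = 15L, mutation = c(0.5, 1), recombination = 0.7,
                 maxiter = 1000L, tol = 0.01, strategy = "rand1bin",
                 n_polish = 3L)
  de_def[names(de)] <- de
  structure(list(c = c, bounds = bounds, distance = distance,
                 max_rounds = as.integer(max_rounds),
                 min_rounds = as.integer(min_rounds),
                 tolerance_eps = tolerance_eps, de = de_def,
                 scaled = isTRUE(scaled), seed = seed),
            class = "inference_settings")
}

# Encoded search box: [n, log10 t_1..t_gamma, M_0..M_gamma, (log10 N)].
# For scaled fits the event-time coordinates (and hence the t bounds) are
# in generations, so the box stays fixed while N varies.  The n coordinate
# spans half a unit beyond the integer range so rounding gives every
# admissible integer equal mass.
encoded_bounds <- function(settings) {
  b <- settings$bounds
  gamma <- settings$c - 1L
  lower <- c(b$n_range[1] - 0.49,
             if (gamma > 0L) log10(b$t_ranges[, 1]),
             b$M_ranges[, 1])
  upper <- c(b$n_range[2] + 0.49,
             if (gamma > 0L) log10(b$t_ranges[, 2]),
             b$M_ranges[, 2])
  if (settings$scaled) {
    lower <- c(lower, log10(b$N_range[1]))
    upper <- c(upper, log10(b$N_range[2]))
  }
  list(lower = lower, upper = upper)
}

#' Encode a demography as an optimizer vector, and back
#'
#' The continuous representation used by the search: the number of islands
#' as a continuous coordinate (rounded to the nearest integer in range on
#' decode), event times in log10 space (sorted on decode, so the objective
#' is symmetric under permutation of the time coordinates), migration
#' rates linear, and — for scaled fits — log10 of the reference size, with
#' the time coordinates then expressed in generations (`2 N t`).
#' Deme sizes are fixed to 1.
#'
#' @param d An [island_demography()] or [scaled_demography()].
#' @param scaled Whether the vector carries a reference-size coordinate.
#' @return `encode()`: numeric vector of length `2c` (+1 if scaled);
#'   `decode()`: the demography.
#' @export
encode <- function(d, scaled = inherits(d, "scaled_demography")) {
  force(scaled)
  N <- NULL
  if (inherits(d, "scaled_demography")) {
    N <- d$N
    d <- d$base
  }
  stopifnot(inherits(d, "island_demography"))
  if (scaled && is.null(N))
    stop("scaled encoding needs a scaled_demography")
  t_coord <- if (scaled) d$event_times * 2 * N else d$event_times
  x <- c(d$n, log10(t_coord), d$migration_rates)
  if (scaled) x <- c(x, log10(N))
  x
}

#' @rdname encode
#' @param x Encoded vector.
#' @param c Number of components.
#' @param bounds A [param_bounds()] used to clamp the integer `n`.
#' @export
decode <- function(x, c, bounds, scaled = FALSE) {
  gamma <- c - 1L
  if (length(x) != 2L * gamma + 2L + scaled)
    stop("vector length must be ", 2L * gamma + 2L + scaled)
  n <- min(max(floor(x[1] + 0.5), bounds$n_range[1]), bounds$n_range[2])
  N <- if (scaled) 10^x[2L * gamma + 3L] else 1
  t <- if (gamma > 0L) sort(10^x[1L + seq_len(gamma)]) else numeric()
  # exact ties can arise when several time coordinates are clamped to the
  # same bound; a zero-length component is meaningless, so nudge apart
  for (i in seq_len(gamma)[-1])
    if (t[i] <= t[i - 1L]) t[i] <- t[i - 1L] * (1 + 1e-12)
  if (scaled) t <- t / (2 * N)
  M <- x[gamma + 1L + seq_len(gamma + 1L)]
  d <- island_demography(n, t, M, rep(1, gamma + 1L))
  if (scaled) scaled_demography(N, d) else d
}

#' Inference objective
#'
#' Distance between the target and the exact IICR of the demography decoded
#' from `x` (scaled IICR when `settings$scaled`).  Deterministic in `x`;
#' numerical failure of the propagation returns a large finite penalty so
#' the optimizer can continue.
#'
#' @param x Encoded parameter vector.
#' @param target A [stepwise_iicr()].
#' @param settings An [inference_settings()].
#' @return Nonnegative scalar.
#' @export
objective <- function(x, target, settings) {
  stopifnot(inherits(target, "stepwise_iicr"),
            inherits(settings, "inference_settings"))
  wdt <- distance_wdt(target, settings$distance)
  .cpp_objective(x, settings$c, settings$bounds$n_range[1],
                 settings$bounds$n_range[2], settings$scaled,
                 target$grid[-1], target$values, wdt)
}

#' Fit a piecewise n-island model to a target IICR
#'
#' Runs the multi-round differential-evolution search described in
#' [inference_settings()] and returns the best demography found, the
#' achieved distance, and the per-round trace.
#'
#' @param target A [stepwise_iicr()] (scaled iff `settings$scaled`).
#' @param settings An [inference_settings()].
#' @return An object of class `"iicr_fit"`: list with `best` (the inferred
#'   [island_demography()] or [scaled_demography()]), `distance_achieved`,
#'   `rounds_used`, `trace` (best distance after each round, nonincreasing),
#'   `converged`, and `encoded` (the best raw vector).
#' @examples
#' \donttest{
#' truth <- island_demography(5, 1, c(2, 0.5))
#' target <- exact_iicr(truth)
#' b <- param_bounds(c(2, 50), c(0.05, 100), c(0.02, 100), gamma = 1)
#' fit <- infer(target, inference_settings(2, b, max_rounds = 20, seed = 1))
#' fit$best
#' }
#' @export
infer <- function(target, settings) {
  stopifnot(inherits(target, "stepwise_iicr"),
            inherits(settings, "inference_settings"))
  if (target$scaled != settings$scaled)
    stop("target scale flag (", target$scaled,
         ") does not match settings$scaled (", settings$scaled, ")")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  eb <- encoded_bounds(settings)
  dim <- length(eb$lower)
  np <- max(4L, as.integer(settings$de$pop_mult) * dim)
  tau <- target$grid[-1]
  y <- target$values
  wdt <- distance_wdt(target, settings$distance)
  b <- settings$bounds
  obj_one <- function(x) {
    x <- pmin(pmax(x, eb$lower), eb$upper)
    .cpp_objective(x, settings$c, b$n_range[1], b$n_range[2],
                   settings$scaled, tau, y, wdt)
  }
  polish <- function(x, val) {
    for (r in 1:4) {
      o <- optim(x, obj_one, method = "Nelder-Mead",
                 control = list(maxit = 300L * dim, reltol = 1e-15))
      x_new <- pmin(pmax(o$par, eb$lower), eb$upper)
      if (o$value >= val * 0.5 || o$value < settings$tolerance_eps) {
        if (o$value < val) {
          x <- x_new
          val <- o$value
        }
        break
      }
      x <- x_new
      val <- o$value
    }
    list(par = x, value = val)
  }
  best_x <- NULL
  best_val <- Inf
  trace <- numeric(0)
  rounds <- 0L
  converged <- FALSE
  strategy <- match.arg(settings$de$strategy, c("rand1bin", "best1bin"))
  while (rounds < settings$max_rounds) {
    rounds <- rounds + 1L
    r <- .cpp_de_round(eb$lower, eb$upper, np, settings$de$recombination,
                       settings$de$mutation[1], settings$de$mutation[2],
                       as.integer(settings$de$maxiter), settings$de$tol, 0,
                       if (is.null(best_x)) numeric() else best_x,
                       if (strategy == "best1bin") 1L else 0L,
                       as.integer(settings$de$n_polish),
                       settings$c, b$n_range[1], b$n_range[2],
                       settings$scaled, tau, y, wdt)
    for (k in seq_len(nrow(r$top))) {
      p <- polish(r$top[k, ], r$top_values[k])
      if (p$value < best_val) {
        best_val <- p$value
        best_x <- p$par
      }
    }
    # local refinement: a second, shrunken-box DE centred on the round's
    # incumbent cracks the multimodal fine structure that a simplex search
    # alone cannot
    if (best_val > settings$tolerance_eps) {
      half <- (eb$upper - eb$lower) / 16
      lo_l <- pmax(eb$lower, best_x - half)
      up_l <- pmin(eb$upper, best_x + half)
      rl <- .cpp_de_round(lo_l, up_l, max(16L, 6L * dim),
                          settings$de$recombination,
                          settings$de$mutation[1], settings$de$mutation[2],
                          as.integer(settings$de$maxiter),
                          settings$de$tol, 0, best_x, 0L, 2L,
                          settings$c, b$n_range[1], b$n_range[2],
                          settings$scaled, tau, y, wdt)
      for (k in seq_len(nrow(rl$top))) {
        p <- polish(rl$top[k, ], rl$top_values[k])
        if (p$value < best_val) {
          best_val <- p$value
          best_x <- p$par
        }
      }
    }
    # degeneracy-aware restarts: when two consecutive migration rates are
    # similar, the event between them is nearly unidentifiable and the
    # search tends either to park it at a bound with an arbitrary rate or
    # to wedge a sliver component into an unrelated transition.  Restart
    # the local search from a solution with each consecutive pair of
    # rates collapsed (to the left value, the right value, or their mean
    # — the neighbour fills delete a sliver outright) and the freed event
    # time swept across its range; if the true history has contrasted
    # rates these starts lose, and if it is near-degenerate they slide
    # into the flat valley.
    fill_restarts <- function(x0) {
      out <- list(par = x0, value = obj_one(x0))
      val0 <- out$value
      d0 <- decode(x0, settings$c, b, settings$scaled)
      base_d <- if (settings$scaled) d0$base else d0
      for (e in seq_len(settings$c - 1L)) {
        mv <- base_d$migration_rates
        fills <- unique(c(mv[e], mv[e + 1L], mean(mv[c(e, e + 1L)])))
        for (m_fill in fills) for (q in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
          lt <- (1 - q) * log10(b$t_ranges[e, 1]) +
            q * log10(b$t_ranges[e, 2])
          cand <- base_d
          cand$migration_rates[c(e, e + 1L)] <- m_fill
          cand$event_times[e] <- if (settings$scaled)
            10^lt / (2 * d0$N) else 10^lt
          x_try <- tryCatch({
            cd <- island_demography(cand$n, sort(cand$event_times),
                                    cand$migration_rates)
            if (settings$scaled)
              encode(scaled_demography(d0$N, cd))
            else encode(cd)
          }, error = function(e) NULL)
          if (is.null(x_try)) next
          # one cheap simplex descent per candidate; the winner gets the
          # full polish below
          o <- optim(x_try, obj_one, method = "Nelder-Mead",
                     control = list(maxit = 150L * dim, reltol = 1e-13))
          if (o$value < out$value)
            out <- list(par = pmin(pmax(o$par, eb$lower), eb$upper),
                        value = o$value)
        }
      }
      if (out$value < val0) {
        p <- polish(out$par, out$value)
        if (p$value < out$value) out <- p
      }
      out
    }
    if (best_val > settings$tolerance_eps && settings$c >= 2L) {
      fr <- fill_restarts(best_x)
      if (fr$value < best_val) {
        best_val <- fr$value
        best_x <- fr$par
      }
    }
    # stratified fixed-n exploration: the continuous relaxation of the
    # integer dimension can settle on a wrong island count whose basin
    # outscores every locally reachable alternative; one DE per round with
    # n pinned (cycling outward from the incumbent's n) revisits the
    # integer dimension explicitly, and the collapse restarts are applied
    # to its solution even when it does not beat the incumbent — the
    # rescue path may start from a worse basin with the right n.  Run as
    # a rescue stage: only once the regular stages stop improving.
    stalled <- length(trace) &&
      !(best_val < tail(trace, 1) * (1 - 1e-6))
    if (stalled && best_val > settings$tolerance_eps &&
        b$n_range[2] > b$n_range[1]) {
      inc_n <- decode(best_x, settings$c, b, settings$scaled)
      inc_n <- if (settings$scaled) inc_n$base$n else inc_n$n
      all_n <- seq.int(b$n_range[1], b$n_range[2])
      ordered_n <- all_n[order(abs(all_n - inc_n), all_n)]
      n_try <- ordered_n[(rounds - 1L) %% length(ordered_n) + 1L]
      lo_n <- eb$lower
      up_n <- eb$upper
      lo_n[1] <- n_try - 0.49
      up_n[1] <- n_try + 0.49
      rn <- .cpp_de_round(lo_n, up_n, np, settings$de$recombination,
                          settings$de$mutation[1], settings$de$mutation[2],
                          as.integer(settings$de$maxiter),
                          settings$de$tol, 0, numeric(), 0L, 1L,
                          settings$c, b$n_range[1], b$n_range[2],
                          settings$scaled, tau, y, wdt)
      pn <- polish(rn$par, rn$value)
      if (pn$value < best_val) {
        best_val <- pn$value
        best_x <- pn$par
      }
      if (settings$c >= 2L) {
        fn <- fill_restarts(pn$par)
        if (fn$value < best_val) {
          best_val <- fn$value
          best_x <- fn$par
        }
      }
    }
    trace <- c(trace, best_val)
    if (best_val <= settings$tolerance_eps &&
        rounds >= settings$min_rounds) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    best = decode(best_x, settings$c, b, settings$scaled),
    distance_achieved = best_val, rounds_used = rounds, trace = trace,
    converged = converged, encoded = best_x, settings = settings),
    class = "iicr_fit")
}

#' Preset inference bounds for human PSMC curves
#'
#' The bounds used for the human analyses: `n` in 2..100, event times
#' between 400 and 400,000 generations (10 thousand to 10 million years at
#' 25 years per generation), migration rates in \[1/20, 20\], deme sizes
#' fixed to 1, and a reference size `N` in \[100, 10000\] haploid genes.
#' Intended for scaled fits of PSMC targets; the time bounds are in
#' generations, as scaled fits require.
#'
#' @param gamma Number of demographic events (`c - 1`).
#' @return A [param_bounds()] with an `N_range`.
#' @export
human_bounds <- function(gamma) {
  param_bounds(c(2, 100), t_range = c(4e2, 4e5), M_range = c(1 / 20, 20),
               s_range = c(1, 1), N_range = c(1e2, 1e4), gamma = gamma)
}

#' @export
print.iicr_fit <- function(x, ...) {
  cat("IICR model fit: distance", format(x$distance_achieved, digits = 4),
      "after", x$rounds_used, "round(s)",
      if (x$converged) "(converged)" else "(round budget reached)", "\n")
  print(x$best)
  invisible(x)
}
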