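#' Parse a PSMC output file
#'
#' Reads the text output of Li & Durbin's PSMC and extracts, from the final
#' iteration's block (the block following the last `RD` line, i.e. the
#' converged EM round), the `TR` line (theta0 and rho0) and the `RS` lines
#' (discretization times in 2N0 units and relative-size multipliers
#' lambda_k), plus the `-p` pattern from the `PA` line when present.
#' Unknown and comment lines are skipped.
#'
#' @param path Path to a `.psmc` file.
#' @return An object of class `"psmc_output"`: list with `theta0`, `rho0`,
#'   `intervals` (data frame with columns `t`, `lambda`), `pattern`,
#'   `n_iterations`.
#' @export
read_psmc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rd <- grep("^RD\\t|^RD ", lines)
  if (!length(rd)) stop("not a PSMC output: no RD lines in ", path)
  block <- lines[rd[length(rd)]:length(lines)]
  num <- function(tok, what, ln) {
    v <- suppressWarnings(as.numeric(tok))
    if (any(is.na(v)))
      stop("non-numeric ", what, " field in line: ", ln)
    v
  }
  tr <- grep("^TR\\t|^TR ", block, value = TRUE)
  if (!length(tr)) stop("final PSMC block has no TR line")
  tr_tok <- strsplit(tr[1], "[ \t]+")[[1]]
  theta0 <- num(tr_tok[2], "TR", tr[1])
  rho0 <- num(tr_tok[3], "TR", tr[1])
  rs <- grep("^RS\\t|^RS ", block, value = TRUE)
  if (!length(rs)) stop("final PSMC block has no RS lines")
  iv <- t(vapply(rs, function(ln) {
    tok <- strsplit(ln, "[ \t]+")[[1]]
    if (length(tok) < 4L) stop("truncated RS line: ", ln)
    num(tok[3:4], "RS", ln)
  }, numeric(2)))
  intervals <- data.frame(t = iv[, 1], lambda = iv[, 2], row.names = NULL)
  if (is.unsorted(intervals$t)) stop("RS times are not nondecreasing")
  if (any(intervals$lambda <= 0)) stop("RS lambda values must be positive")
  pa <- grep("^PA\\t|^PA ", block, value = TRUE)
  pattern <- if (length(pa)) strsplit(pa[1], "[ \t]+")[[1]][2] else NA_character_
  structure(list(theta0 = theta0, rho0 = rho0, intervals = intervals,
                 pattern = pattern, n_iterations = length(rd)),
            class = "psmc_output")
}

#' @rdname read_psmc
#' @param p A `psmc_output` (for building test fixtures and round trips).
#' @param path Output path.
#' @export
write_psmc <- function(p, path) {
  stopifnot(inherits(p, "psmc_output"))
  # emit every iteration block so the last-block rule is exercised;
  # earlier blocks carry placeholder values
  blocks <- character()
  for (i in seq_len(max(1L, p$n_iterations))) {
    last <- i == max(1L, p$n_iterations)
    th <- if (last) p$theta0 else p$theta0 * 1.5
    rh <- if (last) p$rho0 else p$rho0 * 1.5
    lam <- if (last) p$intervals$lambda else rep(1, nrow(p$intervals))
    blocks <- c(blocks,
                sprintf("RD\t%d", i - 1L),
                sprintf("TR\t%.17g\t%.17g", th, rh),
                sprintf("RS\t%d\t%.17g\t%.17g",
                        seq_len(nrow(p$intervals)) - 1L,
                        p$intervals$t, lam),
                if (!is.na(p$pattern)) sprintf("PA\t%s", p$pattern),
                "//")
  }
  writeLines(blocks, path)
  invisible(path)
}

#' @export
print.psmc_output <- function(x, ...) {
  cat("PSMC output: theta0 =", format(x$theta0), ", rho0 =",
      format(x$rho0), ",", nrow(x$intervals), "intervals,",
      x$n_iterations, "iteration(s)\n")
  invisible(x)
}

#' Scaling constants for PSMC output
#'
#' @param mu Per-base per-generation mutation rate (default 1.25e-8, the
#'   human rate used throughout).
#' @param bin_size Bases per PSMC bin (default 100).
#' @param generation_time Years per generation (default 25); carried as
#'   metadata for time-axis conversion to years, not used in the scaling
#'   itself.
#' @return An object of class `"scaling_constants"`.
#' @export
scaling_constants <- function(mu = 1.25e-8, bin_size = 100,
                              generation_time = 25) {
  if (mu <= 0 || bin_size <= 0 || generation_time <= 0)
    stop("scaling constants must be positive")
  structure(list(mu = mu, bin_size = bin_size,
                 generation_time = generation_time),
            class = "scaling_constants")
}

#' Scale PSMC output into an IICR curve
#'
#' Converts the dimensionless PSMC discretization into a scaled stepwise
#' IICR directly usable as an inference target: `N0 = theta0 / (4 mu
#' bin_size)`, times become `2 N0 t_k` generations and values `N0
#' lambda_k` haploid genes.  The unbounded last PSMC interval is closed by
#' extending the last time by the ratio of the final two times.
#'
#' @param p A [read_psmc()] result.
#' @param k A [scaling_constants()].
#' @return List with `curve` (a scaled [stepwise_iicr()]) and `N0`.
#' @export
scale_psmc <- function(p, k = scaling_constants()) {
  stopifnot(inherits(p, "psmc_output"), inherits(k, "scaling_constants"))
  if (p$theta0 <= 0) stop("theta0 must be positive")
  N0 <- p$theta0 / (4 * k$mu * k$bin_size)
  t <- p$intervals$t
  lam <- p$intervals$lambda
  if (t[1] != 0) {
    t <- c(0, t)
    lam <- c(lam[1], lam)
  }
  K <- length(t)
  if (K < 3L) stop("need at least two PSMC intervals")
  right_edge <- t[K] * t[K] / t[K - 1L]
  grid <- 2 * N0 * c(t, right_edge)
  list(curve = stepwise_iicr(grid, N0 * lam, scaled = TRUE), N0 = N0)
}

fmt_num <- function(x) {
  vapply(x, function(v) format(v, digits = 10, scientific = FALSE,
                               trim = TRUE), "")
}

#' Emit the ms command simulating a scaled island demography
#'
#' Builds the command line for Hudson's ms that simulates pairs of
#' sequences under the given scaled demography: `theta = 4 mu L N`,
#' `rho = theta / rho_ratio`, an island structure flag `-I n 2 0 ... 0 M_0`
#' (the two sampled lineages in one deme), and one `-eM t/2 M_i` flag per
#' demographic event.  Two unit conventions are bridged here: ms measures
#' time in 4N generations while the model uses 2N generations, so event
#' times are halved; and from the structured-coalescent construction the
#' per-generation migrant fraction m satisfies 4N m = M, so the model's
#' total migration rate M is numerically ms's migration parameter and is
#' passed through unchanged.
#'
#' @param d A [scaled_demography()] (deme sizes must all be 1).
#' @param nreps Number of independent replicates (chromosomes).
#' @param seq_len Sequence length L in base pairs.
#' @param mu Per-base per-generation mutation rate.
#' @param rho_ratio `theta / rho`; default 5.
#' @return The command as a single string.
#' @examples
#' d <- scaled_demography(1000, island_demography(10, migration_rates = 1))
#' ms_command(d, nreps = 30, seq_len = 1e8)
#' @export
ms_command <- function(d, nreps, seq_len, mu = 1.25e-8, rho_ratio = 5) {
  stopifnot(inherits(d, "scaled_demography"))
  base <- d$base
  if (any(base$deme_sizes != 1))
    stop("ms command emission supports deme sizes fixed to 1 only")
  theta <- 4 * mu * seq_len * d$N
  rho <- theta / rho_ratio
  parts <- c("ms", "2", fmt_num(nreps),
             "-t", fmt_num(theta), "-r", fmt_num(rho), fmt_num(seq_len),
             "-p", "8",
             "-I", fmt_num(base$n),
             "2", rep("0", base$n - 1L),
             fmt_num(base$migration_rates[1]))
  for (i in seq_along(base$event_times))
    parts <- c(parts, "-eM", fmt_num(base$event_times[i] / 2),
               fmt_num(base$migration_rates[i + 1L]))
  paste(parts, collapse = " ")
}

#' Export connectivity graphs
#'
#' A connectivity graph is the step function `t -> M(t)` of a demography:
#' the times at which migration changes plotted against the migration
#' rates.  Writes one TSV row per component: `scenario_id` (0-based),
#' `t_left`, `t_right` (`Inf` sentinel for the last component), `M`.
#'
#' @param d An [island_demography()], [scaled_demography()], or list of
#'   them.
#' @param path Output TSV path.
#' @return The data frame written, invisibly.
#' @export
export_connectivity_graph <- function(d, path) {
  if (inherits(d, "island_demography") || inherits(d, "scaled_demography"))
    d <- list(d)
  rows <- do.call(rbind, lapply(seq_along(d), function(i) {
    di <- d[[i]]
    if (inherits(di, "scaled_demography")) di <- di$base
    stopifnot(inherits(di, "island_demography"))
    edges <- c(0, di$event_times, Inf)
    data.frame(scenario_id = i - 1L,
               t_left = edges[-length(edges)],
               t_right = edges[-1],
               M = di$migration_rates)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' @rdname export_connectivity_graph
#' @export
read_connectivity_graph <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
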