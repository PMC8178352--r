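# Independent closed form for stationary n-island models: base eigen() on
# the 2x2 transient block of the lumped chain.  Deliberately separate from
# the package's propagation path.
stationary_oracle <- function(n, M, s, t) {
  A <- rbind(c(-(1 / s + M), M), c(M / (n - 1), -M / (n - 1)))
  e <- eigen(A)
  Vi <- solve(e$vectors)
  out <- t(vapply(t, function(ti) {
    E <- e$vectors %*% diag(exp(e$values * ti)) %*% Vi
    p <- as.numeric(c(1, 0) %*% E)
    c(survival = sum(p), density = p[1] / s)
  }, c(survival = 0, density = 0)))
  data.frame(t = t, survival = out[, 1], density = out[, 2],
             iicr = out[, 1] / out[, 2])
}

# small well-separated fixtures used across tests
fixture_c2 <- function() island_demography(10, 1, c(5, 0.5))
fixture_c3 <- function() island_demography(5, c(0.5, 5), c(2, 20, 0.8))

# inference box for targets on the default [1e-2, 1e2] grid: wider than
# the sampling hull, with the time range kept inside the observed window
wide_bounds <- function(gamma) {
  param_bounds(c(2, 50), t_range = c(0.05, 80), M_range = c(0.05, 100),
               gamma = gamma)
}
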