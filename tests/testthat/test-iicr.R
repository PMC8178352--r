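test_that("rate matrix carries the lumped-chain rates", {
  q <- build_rate_matrix(2, 1, 1)
  expect_equal(unname(q), rbind(c(-2, 1, 1), c(1, -1, 0), c(0, 0, 0)))
  q2 <- build_rate_matrix(10, 5, 2)
  expect_equal(unname(q2["S", ]), c(-5.5, 5, 0.5))
  expect_equal(unname(q2["D", ]), c(5 / 9, -5 / 9, 0))
  # generator property on a lattice
  for (n in c(2, 7, 30)) for (M in c(0.1, 3)) for (s in c(0.5, 1, 4))
    expect_equal(rowSums(build_rate_matrix(n, M, s)), c(S = 0, D = 0, C = 0))
  expect_error(build_rate_matrix(1, 1, 1), "n must be")
})

test_that("log_grid is geometric with both endpoints", {
  g <- log_grid(0.01, 100, 5)
  expect_equal(g[1], 0)
  expect_equal(g[-1], c(0.01, 0.1, 1, 10, 100))
  expect_equal(log_grid(3, 8, 2), c(0, 3, 8))
  expect_error(log_grid(1, 1, 4), "t_min < t_max")
})

test_that("survival/density start at (1, 1/s0) and conserve probability", {
  d <- island_demography(5, c(0.4, 2), c(1, 10, 0.2), c(2, 1, 1))
  r <- survival_and_density(d, c(0, 0.1, 0.5, 1, 3, 10))
  expect_equal(r$survival[1], 1)
  expect_equal(r$density[1], 1 / 2) # 1/s_0
  expect_true(all(diff(r$survival) < 0))
  # three-state distribution sums to 1: pC recovered by conservation must
  # stay in [0, 1] and (pS + pD + pC) == 1 by construction; check the
  # propagated pair stays a subprobability vector to 1e-12
  expect_true(all(r$p_same >= -1e-12 & r$p_diff >= -1e-12))
  expect_true(all(r$p_same + r$p_diff <= 1 + 1e-12))
  expect_error(survival_and_density(d, -1), "nonnegative")
})

test_that("exact IICR matches the eigendecomposition closed form", {
  g <- log_grid(1e-2, 1e2, 64)
  for (n in c(2, 5, 10, 20)) for (M in c(0.1, 1, 10, 50)) {
    d <- island_demography(n, migration_rates = M)
    expect_lt(max(abs(exact_iicr(d, g)$values -
                        stationary_oracle(n, M, 1, g[-1])$iicr)), 1e-10)
  }
  # small-t limit: IICR -> s_0
  d <- island_demography(4, migration_rates = 0.7)
  expect_equal(exact_iicr(d, c(0, 1e-8, 1))$values[1], 1, tolerance = 1e-6)
  # n=2, M=1 plateau at (3+sqrt(5))/2
  d2 <- island_demography(2, migration_rates = 1)
  expect_equal(tail(exact_iicr(d2, log_grid(0.01, 100, 32))$values, 1),
               (3 + sqrt(5)) / 2, tolerance = 1e-9)
})

test_that("migration limits bracket the IICR", {
  # strong migration: panmictic limit n*s away from t = 0
  d <- island_demography(5, migration_rates = 1000)
  v <- exact_iicr(d, log_grid(0.1, 10, 16))$values
  expect_true(all(abs(v - 5) / 5 < 0.01))
  # weak migration: early IICR at the single-deme value s
  dw <- island_demography(5, migration_rates = 1e-6)
  vw <- exact_iicr(dw, log_grid(0.01, 1, 8))$values
  expect_true(all(abs(vw - 1) < 0.01))
})

test_that("a spurious event with unchanged parameters leaves the IICR fixed", {
  g <- log_grid(1e-2, 1e2, 64)
  base <- island_demography(8, 2, c(3, 0.4))
  padded <- island_demography(8, c(0.7, 2), c(3, 3, 0.4))
  expect_lt(max(abs(exact_iicr(base, g)$values -
                      exact_iicr(padded, g)$values)), 1e-12)
})

test_that("scaling is sIICR(g) = N IICR(g/2N) and inverts exactly", {
  cur <- stepwise_iicr(c(0, 1), 1)
  sc <- scale_iicr(cur, 1000)
  expect_equal(sc$grid, c(0, 2000))
  expect_equal(sc$values, 1000)
  expect_true(sc$scaled)
  d <- fixture_c2()
  cur2 <- exact_iicr(d)
  # bit-exact inversion when 2N is a power of two; equal to rounding
  # otherwise
  expect_identical(unscale_iicr(scale_iicr(cur2, 1024), 1024), cur2)
  expect_equal(unscale_iicr(scale_iicr(cur2, 1234.5), 1234.5), cur2)
  sc3 <- scale_iicr(cur2, 0.5)
  expect_equal(sc3$grid, cur2$grid)
  expect_equal(sc3$values, cur2$values * 0.5)
  expect_error(scale_iicr(cur2, -1), "positive")
  expect_error(scale_iicr(sc, 10), "already scaled")
})

test_that("T2 simulation matches the chain it claims to simulate", {
  # isolation limit: exponential with rate 1/s
  iso <- simulate_t2(island_demography(2, migration_rates = 1e-6),
                     1e4, seed = 7)
  se <- stats::sd(iso$draws) / sqrt(length(iso$draws))
  expect_lt(abs(mean(iso$draws) - 1), 3 * se)
  # stationary n=2, M=1: empirical survival inside binomial 99% CI of the
  # closed form at a few times
  d <- island_demography(2, migration_rates = 1)
  s2 <- simulate_t2(d, 2e4, seed = 11)
  for (t0 in c(0.5, 1, 2)) {
    p <- stationary_oracle(2, 1, 1, t0)$survival
    phat <- mean(s2$draws > t0)
    half <- 2.576 * sqrt(p * (1 - p) / length(s2$draws))
    expect_lt(abs(phat - p), half + 1e-12)
  }
  # seeded reproducibility
  expect_identical(simulate_t2(d, 100, seed = 3)$draws,
                   simulate_t2(d, 100, seed = 3)$draws)
})

test_that("empirical IICR handles point masses and empty tails", {
  # all draws at 1, grid [0, 0.5, 1.5]: y_2 = 1 * (1.5-0.5) / (1-0) = 1
  emp <- empirical_iicr(list(draws = rep(1, 50)), c(0, 0.5, 1.5))
  expect_equal(emp$values, 1)
  expect_equal(emp$grid, c(0, 1.5)) # empty first interval merged forward
  # grid far beyond max(draws): trailing intervals dropped silently
  emp2 <- empirical_iicr(list(draws = stats::runif(200, 0.1, 1)),
                         log_grid(0.05, 1e4, 24))
  expect_lt(tail(emp2$grid, 1), 1e4)
  expect_true(all(is.finite(emp2$values)))
  expect_error(empirical_iicr(list(draws = numeric())), "empty")
})

test_that("empirical IICR converges to the exact curve", {
  d <- island_demography(2, migration_rates = 1)
  # window chosen so the per-interval hazard mass stays small: the ratio
  # estimator's discretization bias is first order in hazard x width
  grid <- log_grid(0.05, 2, 32)
  s2 <- simulate_t2(d, 1e5, seed = 19)
  emp <- empirical_iicr(s2, grid)
  ex <- exact_iicr(d, grid)
  # compare on intervals holding >= 100 coalescences
  counts <- vapply(seq_along(emp$values), function(j)
    sum(s2$draws >= emp$grid[j] & s2$draws < emp$grid[j + 1]), 0)
  ex_at <- iicrinfer:::eval_stepwise(ex, emp$grid[-1] - 1e-12)
  rel <- abs(emp$values - ex_at) / ex_at
  expect_true(all(rel[counts >= 100] < 0.10))
})

test_that("stepwise curves round-trip through TSV and JSON", {
  cur <- exact_iicr(fixture_c3(), log_grid(0.02, 80, 20))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_iicr(cur, tsv)
  write_iicr(cur, js)
  expect_equal(read_iicr(tsv), cur)
  expect_equal(read_iicr(js), cur)
})
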