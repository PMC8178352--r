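test_that("density reconstruction inverts the survival identity", {
  g <- log_grid(0.01, 100, 32)
  # constant IICR 1 => unit-rate exponential density at the nodes
  f0 <- reconstruct_density(stepwise_iicr(g, rep(1, 32)))
  expect_equal(f0, exp(-g))
  # constant IICR C => exponential with mean C, integrating to ~1
  C <- 3.7
  f0c <- reconstruct_density(stepwise_iicr(g, rep(C, 32)))
  expect_equal(f0c, exp(-g / C) / C)
  wide <- log_grid(1e-3, 100, 400)
  f0w <- reconstruct_density(stepwise_iicr(wide, rep(C, 400)))
  mass <- sum(f0w[-length(f0w)] * diff(wide))
  expect_equal(mass, 1, tolerance = 0.05)
  # first node uses the first interval's value
  tg <- stepwise_iicr(c(0, 1, 2), c(2, 1))
  expect_equal(reconstruct_density(tg)[1], 1 / 2)
  # implied survival factor nonincreasing
  y <- c(5, 2, 0.5, 1, 4)
  f0v <- reconstruct_density(stepwise_iicr(c(0, 0.1, 0.5, 1, 3, 9), y))
  surv <- f0v * c(y, y[5])
  expect_true(all(diff(surv) <= 1e-15))
})

test_that("weights normalize and respond to omega as documented", {
  f0 <- c(0.8, 0.2)
  expect_equal(compute_weights(f0, 1), c(0.8, 0.2))
  expect_equal(compute_weights(f0, 2), c(16 / 17, 1 / 17))
  expect_equal(sum(compute_weights(stats::runif(20), 1.3)), 1)
  # omega -> 0: uniform weights
  expect_equal(compute_weights(f0, 1e-9), c(0.5, 0.5), tolerance = 1e-6)
  # increasing omega shifts cumulative mass toward small tau for a
  # decreasing density
  f0d <- exp(-log_grid(0.01, 50, 16))[1:16]
  halves <- vapply(c(0.2, 0.5, 1, 2, 4), function(om)
    sum(compute_weights(f0d, om)[1:8]), 0)
  expect_true(all(diff(halves) >= 0))
  expect_error(compute_weights(c(0, 0)), "positive")
})

test_that("omega distance reproduces the hand-computed example", {
  tg <- stepwise_iicr(c(0, 1, 2), c(2, 1))
  one <- function(t) rep(1, length(t))
  expect_equal(distance_omega(tg, one), (1 / 2) / (1 / 2 + exp(-0.5)))
  # identity candidate: zero distance
  expect_equal(distance_omega(tg, tg), 0)
  # restriction to the second interval removes the mismatch
  expect_equal(distance_omega(tg, one, distance_spec("omega",
                                                     range = c(1, 2))), 0)
  expect_error(distance_omega(tg, one, distance_spec("omega",
                                                     range = c(5, 6))),
               "excludes")
})

test_that("visual distance is the plain node-difference sum", {
  tg <- stepwise_iicr(c(0, 1, 2), c(2, 1))
  expect_equal(distance_visual(tg, function(t) rep(1, length(t))), 1)
  expect_equal(distance_visual(tg, tg), 0)
  # constant offset at every node adds c per node
  g <- log_grid(0.1, 10, 8)
  t2 <- stepwise_iicr(g, rep(2, 8))
  expect_equal(distance_visual(t2, function(t) rep(2.5, length(t))),
               0.5 * 8)
})

test_that("range restriction renormalizes the kept weights", {
  # with the plain-sum weight normalization, restricting to a window and
  # renormalizing must reproduce the hand formula on the kept intervals
  g <- c(0, 0.5, 1, 2, 4)
  tg <- stepwise_iicr(g, c(2, 1.5, 1, 0.8))
  one <- function(t) rep(1, length(t))
  f0 <- reconstruct_density(tg)
  w_all <- f0[1:4]
  keep <- 2:3 # intervals [0.5,1) and [1,2)
  w <- w_all[keep] / sum(w_all[keep])
  expected <- sum(abs(tg$values[keep] - 1) * w * diff(g)[keep])
  got <- distance_omega(tg, one, distance_spec("omega", range = c(0.5, 2)))
  expect_equal(got, expected)
})

test_that("distances treat demography candidates via the exact engine", {
  d <- fixture_c2()
  tg <- exact_iicr(d)
  expect_lt(distance_omega(tg, d), 1e-14)
  expect_lt(distance_visual(tg, d), 1e-10)
  other <- island_demography(3, migration_rates = 1)
  expect_gt(distance_omega(tg, other), 0)
  expect_equal(iicr_distance(tg, d, distance_spec("omega")),
               distance_omega(tg, d))
})
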