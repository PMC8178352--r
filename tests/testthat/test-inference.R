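test_that("encode/decode round-trips and normalizes", {
  b <- wide_bounds(2)
  d <- fixture_c3()
  x <- encode(d)
  expect_equal(decode(x, 3, b), d)
  # unsorted time coordinates decode to sorted times
  x_sw <- x
  x_sw[2:3] <- x_sw[3:2]
  expect_equal(decode(x_sw, 3, b), d)
  # n rounds to the nearest integer in range
  x_n <- x
  x_n[1] <- 9.6
  expect_identical(decode(x_n, 3, b)$n, 10L)
  x_lo <- x
  x_lo[1] <- -3
  expect_identical(decode(x_lo, 3, b)$n, 2L)
  # scaled round trip carries N and generation-time coordinates
  sdem <- scaled_demography(1500, d)
  bs <- param_bounds(c(2, 50), t_range = c(4e2, 4e5),
                     M_range = c(0.05, 100), N_range = c(1e2, 1e4),
                     gamma = 2)
  expect_equal(decode(encode(sdem), 3, bs, scaled = TRUE), sdem)
})

test_that("objective is a deterministic self-distance-zero function", {
  d <- fixture_c2()
  target <- exact_iicr(d)
  st <- inference_settings(2, wide_bounds(1))
  x <- encode(d)
  expect_lt(objective(x, target, st), 1e-12)
  # permuted time coordinates give the same value
  d3 <- fixture_c3()
  t3 <- exact_iicr(d3)
  st3 <- inference_settings(3, wide_bounds(2))
  x3 <- encode(d3)
  x3p <- x3
  x3p[2:3] <- x3p[3:2]
  expect_identical(objective(x3, t3, st3), objective(x3p, t3, st3))
  # nonnegative on random vectors
  eb <- iicrinfer:::encoded_bounds(st3)
  set.seed(1)
  for (i in 1:20) {
    x_r <- stats::runif(length(eb$lower), eb$lower, eb$upper)
    expect_gte(objective(x_r, t3, st3), 0)
  }
})

test_that("inference settings validate their invariants", {
  b <- wide_bounds(1)
  expect_error(inference_settings(2, wide_bounds(2)), "gamma")
  expect_error(inference_settings(2, b, max_rounds = 1, min_rounds = 5),
               "min_rounds")
  expect_error(inference_settings(2, b, tolerance_eps = 0), "positive")
  bs <- param_bounds(c(2, 50), t_range = c(0.1, 50), M_range = c(0.1, 50),
                     s_range = c(0.5, 2), gamma = 1)
  expect_error(inference_settings(2, bs), "deme sizes")
})

test_that("a vacuous tolerance converges after min_rounds", {
  target <- exact_iicr(fixture_c2())
  st <- inference_settings(2, wide_bounds(1), tolerance_eps = 1e6,
                           min_rounds = 2, max_rounds = 10, seed = 4)
  fit <- infer(target, st)
  expect_true(fit$converged)
  expect_identical(fit$rounds_used, 2L)
})

test_that("inference is deterministic under a fixed seed", {
  target <- exact_iicr(fixture_c2())
  st <- inference_settings(2, wide_bounds(1), max_rounds = 3,
                           tolerance_eps = 1e-3, seed = 123)
  f1 <- infer(target, st)
  f2 <- infer(target, st)
  expect_identical(f1$encoded, f2$encoded)
  expect_identical(f1$trace, f2$trace)
})

test_that("the per-round trace never increases and ends at the result", {
  target <- exact_iicr(fixture_c3())
  st <- inference_settings(3, wide_bounds(2), max_rounds = 6,
                           tolerance_eps = 1e-14, seed = 9)
  fit <- infer(target, st)
  expect_true(all(diff(fit$trace) <= 0))
  expect_identical(fit$distance_achieved, tail(fit$trace, 1))
  expect_identical(fit$rounds_used, length(fit$trace))
})

test_that("stationary targets are recovered to tolerance", {
  # c = 1: closed-form identifiable optimum, distance driven below eps
  b0 <- param_bounds(c(2, 50), M_range = c(0.02, 100), gamma = 0)
  for (sc in list(c(5, 0.5), c(12, 3))) {
    d <- island_demography(sc[1], migration_rates = sc[2])
    fit <- infer(exact_iicr(d), inference_settings(1, b0, seed = sc[1]))
    expect_true(fit$converged)
    expect_identical(fit$best$n, as.integer(sc[1]))
    expect_equal(fit$best$migration_rates, sc[2], tolerance = 1e-6)
  }
})
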