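test_that("nRMSD is the range-normalized root-mean-square error", {
  expect_equal(nrmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmsd(c(0, 10), c(0, 5)), sqrt(12.5) / 10)
  # scale invariance
  tr <- c(2, 7, 4)
  inf <- c(2.5, 6, 5)
  expect_equal(nrmsd(tr * 13, inf * 13), nrmsd(tr, inf))
  # all-equal true values fall back to the common absolute value
  expect_equal(nrmsd(c(5, 5), c(4, 6)), 1 / 5)
  expect_error(nrmsd(numeric(), numeric()), "nonempty")
})

test_that("component matching flags constructed swaps only", {
  d <- fixture_c3()
  m <- match_components(d, d)
  expect_identical(m$mapping, c(1L, 2L))
  expect_false(any(m$misassigned))
  # inferred t1 sits at true t2 and carries true M2's value: swap flagged
  swapped <- island_demography(5, c(4.5, 6), c(2, 0.8, 20))
  ms <- match_components(d, swapped)
  expect_identical(ms$mapping[1], 2L)
  expect_true(any(ms$misassigned))
  # stationary models have nothing to match
  d1 <- island_demography(3, migration_rates = 1)
  m1 <- match_components(d1, d1)
  expect_length(m1$mapping, 0L)
})

test_that("validation batches are reproducible and score recovery", {
  b0 <- param_bounds(c(2, 50), M_range = c(0.02, 100), gamma = 0)
  st <- inference_settings(1, b0, max_rounds = 20)
  rep1 <- run_validation(4, st,
                         sampling_bounds = param_bounds(c(2, 20),
                                                        M_range = c(0.1, 50),
                                                        gamma = 0),
                         seed = 99)
  expect_s3_class(rep1, "validation_report")
  # exact stationary targets: identifiable, all runs converge below eps
  expect_true(all(rep1$distances <= st$tolerance_eps))
  expect_equal(rep1$scores$nrmsd[rep1$scores$parameter == "n"], 0)
  # reproducibility under the master seed
  rep2 <- run_validation(4, st,
                         sampling_bounds = param_bounds(c(2, 20),
                                                        M_range = c(0.1, 50),
                                                        gamma = 0),
                         seed = 99)
  expect_equal(rep1$scores, rep2$scores)
  expect_equal(rep1$distances, rep2$distances)
})

test_that("inference bounds must contain the sampling bounds", {
  narrow <- param_bounds(c(2, 10), M_range = c(0.5, 5), gamma = 0)
  wide_s <- param_bounds(c(2, 20), M_range = c(0.1, 50), gamma = 0)
  st <- inference_settings(1, narrow, max_rounds = 2)
  expect_error(run_validation(2, st, sampling_bounds = wide_s, seed = 1),
               "contain")
})

test_that("t-sim targets cannot beat exact targets on average", {
  set.seed(5)
  b <- param_bounds(c(2, 50), t_range = c(0.05, 100),
                    M_range = c(0.05, 100), gamma = 1)
  sb <- param_bounds(c(2, 20), t_range = c(0.2, 20), M_range = c(0.2, 20),
                     gamma = 1)
  st <- inference_settings(2, b, max_rounds = 8, tolerance_eps = 1e-8)
  r_exact <- run_validation(3, st, sampling_bounds = sb, seed = 21,
                            target_type = "exact")
  r_tsim <- run_validation(3, st, sampling_bounds = sb, seed = 21,
                           target_type = "tsim", draws = 2e4)
  m_rows <- grepl("^M_", r_exact$scores$parameter)
  expect_lte(mean(r_exact$scores$nrmsd[m_rows]),
             mean(r_tsim$scores$nrmsd[m_rows]) + 0.05)
})
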