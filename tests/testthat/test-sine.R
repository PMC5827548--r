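omega10 <- 2 * pi / 100

test_that("noise-free generating parameters are recovered to 1e-6", {
  t <- bin_centers()
  y <- 0.5 + 0.3 * sin(omega10 * t + 1.0)
  f <- fit_sine(y, t, n_starts = 20, seed = 1)
  expect_equal(f$alpha0, 0.5, tolerance = 1e-6)
  expect_equal(f$alpha1, 0.3, tolerance = 1e-6)
  expect_equal(f$phi, 1.0, tolerance = 1e-6)
  expect_lt(f$sse, 1e-12)
  expect_true(f$converged)
})

test_that("constant input takes the degenerate-fit convention", {
  f <- fit_sine(rep(0.4, 10))
  expect_equal(f$alpha1, 0)
  expect_equal(f$phi, 0)
  expect_equal(f$sse, 0)
  expect_equal(f$r2, 0)
  expect_equal(f$adj_r2, 0)
})

test_that("preconditions: length match, enough points, positive omega", {
  expect_error(fit_sine(rep(0.1, 9), bin_centers()), "length")
  expect_error(fit_sine(c(1, 2, 3, NA, NA, NA, NA, NA, NA, 4)), "5 non-missing")
  expect_error(fit_sine(rnorm(10), omega = -1), "omega")
})

test_that("fits respect the amplitude and phase constraints", {
  withr::with_seed(11, {
    for (i in 1:25) {
      y <- rnorm(10)
      f <- fit_sine(y, n_starts = 8, seed = i)
      expect_gte(f$alpha1, 0)
      expect_true(f$phi > -pi && f$phi <= pi)
      expect_lte(f$adj_r2, f$r2)
      if (f$r2 < 1) expect_lt(f$adj_r2, f$r2)
    }
  })
})

test_that("the optimizer matches the closed-form linearization optimum", {
  withr::with_seed(3, {
    for (i in 1:30) {
      y <- rnorm(10)
      miss <- sample(c(0, 2), 1)
      if (miss > 0) y[sample(10, miss)] <- NA
      f <- fit_sine(y, n_starts = 10, seed = i)
      o <- linear_sine_oracle(y, bin_centers(), omega10)
      expect_equal(f$sse, o$sse, tolerance = 1e-8)
      expect_equal(f$alpha1, unname(o$alpha1), tolerance = 1e-5)
    }
  })
})

test_that("fit sse never beats but always reaches the 51^3 grid oracle", {
  withr::with_seed(17, {
    for (i in 1:20) {
      y <- rnorm(10, sd = runif(1, 0.3, 2))
      f <- fit_sine(y, n_starts = 20, seed = i)
      expect_lte(f$sse, grid_sse_oracle(y, bin_centers(), omega10) + 1e-8)
    }
  })
})

test_that("more starts never worsen the objective", {
  withr::with_seed(23, {
    y <- rnorm(10)
    sse <- vapply(c(1, 5, 20, 50),
                  function(k) fit_sine(y, n_starts = k, seed = 9)$sse,
                  numeric(1))
    expect_true(all(diff(sse) <= 1e-12))
  })
})

test_that("phase wrapping and sign conventions are consistent", {
  t <- bin_centers()
  y <- 0.2 + 0.4 * sin(omega10 * t + 2.9)       # optimum near the +pi seam
  f <- fit_sine(y, t, n_starts = 30, seed = 2)
  expect_equal(f$alpha1, 0.4, tolerance = 1e-6)
  expect_equal(f$phi, 2.9, tolerance = 1e-6)
  # -a1 sin(wt + phi) == a1 sin(wt + phi + pi): negative lobe comes back
  # as a positive amplitude with shifted phase
  y2 <- -0.4 * sin(omega10 * t + 1.0)
  f2 <- fit_sine(y2, t, n_starts = 30, seed = 2)
  expect_equal(f2$alpha1, 0.4, tolerance = 1e-6)
  expect_equal(f2$phi, 1.0 - pi, tolerance = 1e-6)  # phi + pi wrapped
})

test_that("cohort fits carry one row per participant and condition", {
  tr <- simulate_cohort(4, session_plan(), seed = 2)
  std <- standardize_rates(detection_rates(tr))
  fits <- fit_sine_cohort(std, n_starts = 5, seed = 1)
  expect_equal(nrow(fits), 8)
  expect_setequal(fits$condition, c("sham", "otcs"))
  expect_true(all(fits$alpha1 >= 0))
  expect_true(all(fits$n_points == 10))
})

test_that("compare_conditions contracts: identity, df, errors", {
  tr <- simulate_cohort(6, session_plan(), seed = 6)
  std <- standardize_rates(detection_rates(tr))
  fits <- fit_sine_cohort(std, n_starts = 5, seed = 1)
  fs <- fits[fits$condition == "sham", ]
  fo <- fits[fits$condition == "otcs", ]
  cmp_id <- compare_conditions(fs, fs)
  expect_equal(cmp_id$amplitude$t, 0)
  expect_lt(cmp_id$amplitude$bf10, 1)
  cmp <- compare_conditions(fs, fo)
  expect_equal(cmp$amplitude$df, 5)
  expect_error(compare_conditions(fs, fo[1:2, ]), "equal length")
})
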