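obs0 <- observer_params(lapse = 0, fatigue_slope = 0, condition_offset = 0,
                        no_response_rate = 0)

trial_row <- function(soa = 25, lum = 50, trial = 1) {
  data.frame(catch = FALSE, luminance = lum, pulse_soa = soa, trial = trial,
             condition = "sham", order = "sham_first")
}

test_that("p_hit is 0.5 at threshold with no modulation", {
  expect_equal(p_hit(trial_row(), obs0), 0.5)
})

test_that("p_hit is flat across phase when the entrainment amplitude is 0", {
  p <- vapply(seq(0, 99, by = 7), function(s) p_hit(trial_row(soa = s), obs0),
              numeric(1))
  expect_equal(diff(range(p)), 0)
})

test_that("entrainment peaks and troughs follow the sine's sign", {
  obs <- observer_params(lapse = 0, fatigue_slope = 0, condition_offset = 0,
                         no_response_rate = 0, entrain_amp = 0.5,
                         entrain_phase = 0)
  p25 <- p_hit(trial_row(soa = 25), obs, entrain_on = TRUE)
  p75 <- p_hit(trial_row(soa = 75), obs, entrain_on = TRUE)
  expect_gt(p25 - p75, 0)
  # entrain_on = FALSE suppresses the term even with A > 0 (sham contract)
  expect_equal(p_hit(trial_row(soa = 25), obs, entrain_on = FALSE), 0.5)
})

test_that("catch trials are rejected by p_hit", {
  tr <- trial_row(); tr$catch <- TRUE
  expect_error(p_hit(tr, obs0), "catch")
})

test_that("lapse scales the hit ceiling and fatigue drifts log-odds", {
  obs <- observer_params(lapse = 0.1, fatigue_slope = 0, condition_offset = 0,
                         no_response_rate = 0)
  expect_equal(p_hit(trial_row(lum = 500), obs), 0.9, tolerance = 1e-6)
  obs_f <- observer_params(lapse = 0, fatigue_slope = -0.01,
                           condition_offset = 0, no_response_rate = 0)
  expect_lt(p_hit(trial_row(trial = 100), obs_f), p_hit(trial_row(), obs_f))
})

test_that("simulated cohorts have the counterbalanced study structure", {
  plan <- session_plan()
  tr <- simulate_cohort(4, plan, seed = 1)
  expect_equal(nrow(tr), 4 * 2 * 384)
  ord <- unique(tr[c("participant_id", "order")])
  expect_equal(sum(ord$order == "sham_first"), 2)
  expect_setequal(unique(tr$condition), c("sham", "otcs"))
  expect_length(validate_trials(tr), 0)
  expect_error(simulate_cohort(3, plan, seed = 1), "even")
  expect_silent(tr3 <- simulate_cohort(2, tiny_plan(), seed = 1))
})

test_that("identical seeds reproduce the trial table exactly", {
  plan <- tiny_plan()
  expect_identical(simulate_cohort(2, plan, seed = 42),
                   simulate_cohort(2, plan, seed = 42))
  expect_false(identical(simulate_cohort(2, plan, seed = 42)$response,
                         simulate_cohort(2, plan, seed = 43)$response))
})

test_that("empirical hit rates are binomially consistent with p_hit", {
  # homogeneous observers at threshold: every scored trial has p = 0.5
  pop <- observer_population(threshold_sd = 0, slope_cv = 1e-9, calib_sd = 0,
                             lapse = 0, fatigue_slope = 0,
                             condition_offset = 0, no_response_rate = 0)
  plan <- tiny_plan(n_blocks = 2L, trials_per_block = 256L,
                    catch_fraction = 0)
  tr <- simulate_cohort(4, plan, pop, seed = 8)
  n <- nrow(tr)
  phat <- mean(tr$response == "hit")
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

test_that("entrained cohorts show the generating sinusoid in their bin rates", {
  pop <- observer_population(threshold_sd = 0, slope_cv = 1e-9, calib_sd = 0,
                             lapse = 0, fatigue_slope = 0,
                             condition_offset = 0, no_response_rate = 0,
                             entrain_phase = 0.8)
  plan <- tiny_plan(n_blocks = 3L, trials_per_block = 512L,
                    catch_fraction = 0)
  tr <- simulate_cohort(4, plan, pop, entrain_amp = 1.0, seed = 9)
  ot <- tr[tr$condition == "otcs" & tr$response %in% c("hit", "miss"), ]
  rate <- tapply(ot$response == "hit", bin_index(ot$pulse_soa), mean)
  expected <- sin(2 * pi * bin_centers() / 100 + 0.8)
  expect_gt(cor(as.numeric(rate), expected), 0.9)
  # sham rates stay flat: no spurious phase structure from the scheduler
  sh <- tr[tr$condition == "sham" & tr$response %in% c("hit", "miss"), ]
  rate_sh <- tapply(sh$response == "hit", bin_index(sh$pulse_soa), mean)
  expect_lt(diff(range(rate_sh)), 0.12)
})
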