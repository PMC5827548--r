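test_that("baseline correction zeroes the pre-target mean everywhere", {
  rec <- synth_eeg_recording(n_trials = 12, noise_sd = 2, seed = 1)
  ep <- epoch_and_clean(rec$data, rec$events, rec$sfreq, eog = NULL)
  bsel <- ep$times >= -300 & ep$times < 0
  bl <- apply(ep$data[, , bsel], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-9))
})

test_that("two-stage amplitude rejection tags trials at the right stage", {
  rec <- synth_eeg_recording(n_trials = 10, alpha_amp = 5, blink_amp = 0,
                             noise_sd = 0, seed = 2)
  # a 1500-uV spike in trial 3 trips stage 1; a 700-uV spike in trial 6
  # survives stage 1 but not the 500-uV stage-2 check
  rec$data[1, rec$events[3] + 10] <- 1500
  rec$data[2, rec$events[6] + 20] <- 700
  ep <- epoch_and_clean(rec$data, rec$events, rec$sfreq, eog = NULL)
  expect_equal(ep$rejected$stage[3], "stage1")
  expect_equal(ep$rejected$stage[6], "stage2")
  expect_true(all(ep$rejected$stage[-c(3, 6)] == "none"))
})

test_that("a flat recording yields zero-valued epochs and no rejections", {
  n_samp <- 5000
  cont <- matrix(0, 3, n_samp)
  ep <- epoch_and_clean(cont, c(1500, 3000), sfreq = 250, eog = NULL)
  expect_true(all(ep$data == 0))
  expect_false(any(ep$rejected$rejected))
})

test_that("events too close to the recording edge are flagged, not fatal", {
  cont <- matrix(0, 2, 1000)
  ep <- epoch_and_clean(cont, c(10, 500), sfreq = 250, eog = NULL)
  expect_equal(ep$rejected$stage, c("edge", "none"))
})

test_that("rejection is monotone in the threshold", {
  rec <- synth_eeg_recording(n_trials = 30, noise_sd = 40, blink_amp = 600,
                             seed = 3)
  n_rej <- vapply(c(200, 500, 1200), function(th)
    sum(epoch_and_clean(rec$data, rec$events, rec$sfreq, reject1 = 2 * th,
                        reject2 = th, eog = NULL)$rejected$rejected),
    numeric(1))
  expect_true(all(diff(n_rej) <= 0))
})

test_that("an exactly proportional EOG contamination is removed", {
  # EEG channel = 2 x vertical EOG exactly
  n_tr <- 8; n_s <- 100
  withr::with_seed(4, veog <- matrix(rnorm(n_tr * n_s, sd = 50), n_tr))
  eog <- array(0, c(n_tr, 2, n_s))
  eog[, 1, ] <- veog
  eog[, 2, ] <- matrix(rnorm(n_tr * n_s), n_tr)   # independent horizontal
  arr <- array(0, c(n_tr, 1, n_s))
  arr[, 1, ] <- 2 * veog
  res <- gratton_correct(arr, eog)
  expect_equal(unname(res$propagation[1, 1]), 2, tolerance = 1e-6)
  expect_lt(max(abs(res$data)), 1e-6 * max(abs(arr)))
})

test_that("uncontaminated EEG passes through almost unchanged", {
  n_tr <- 40; n_s <- 200
  withr::with_seed(5, {
    eeg <- array(rnorm(n_tr * 2 * n_s), c(n_tr, 2, n_s))
    eog <- array(rnorm(n_tr * 2 * n_s, sd = 50), c(n_tr, 2, n_s))
  })
  res <- gratton_correct(eeg, eog)
  expect_lt(max(abs(res$propagation)), 0.02)
  expect_gt(cor(as.vector(res$data), as.vector(eeg)), 0.99)
})

test_that("an injected propagation factor of 0.35 is recovered within 0.02", {
  rec <- synth_eeg_recording(n_trials = 100, n_channels = 2, noise_sd = 5,
                             blink_prop = c(0.35, 0.35), seed = 6)
  ep <- epoch_and_clean(rec$data, rec$events, rec$sfreq,
                       eog = rec$eog)
  expect_equal(unname(ep$propagation[, "eog1"]), c(0.35, 0.35),
               tolerance = 0.02 / 0.35)
})

test_that("blink-contaminated epochs come back to the clean sinusoid", {
  rec <- synth_eeg_recording(n_trials = 40, n_channels = 3, noise_sd = 0,
                             alpha_amp = 10, seed = 7)
  ep <- epoch_and_clean(rec$data, rec$events, rec$sfreq, eog = rec$eog)
  # rebuild the clean reference epochs, baseline-corrected the same way
  keep <- !ep$rejected$rejected
  i0 <- round(-800 / 1000 * rec$sfreq); i1 <- round(1000 / 1000 * rec$sfreq)
  bsel <- ep$times >= -300 & ep$times < 0
  err <- sig <- 0
  for (tr in which(keep)) {
    ref <- rec$clean[, rec$events[tr] + (i0:i1), drop = FALSE]
    ref <- ref - rowMeans(ref[, bsel, drop = FALSE])
    got <- ep$data[tr, , ]
    err <- err + sum((got - ref)^2)
    sig <- sig + sum(ref^2)
  }
  expect_lt(sqrt(err / sig), 0.05)    # RMS error < 5% of signal RMS
})

test_that("zero-variance EOG is an error", {
  arr <- array(rnorm(5 * 1 * 50), c(5, 1, 50))
  eog <- array(0, c(5, 2, 50))
  expect_error(gratton_correct(arr, eog), "variance")
})
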