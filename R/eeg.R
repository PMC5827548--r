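# Epoching, baseline correction, two-stage amplitude rejection and
# regression-based (Gratton-style) ocular correction, exercised on
# synthetic recordings — no real EEG is required anywhere in the package.

#' Synthetic EEG recording with ocular artifacts
#'
#' Generates a continuous multichannel recording for testing the cleaning
#' chain: an alpha-band (10-Hz) sinusoid with per-trial random phase,
#' optional 1/f background noise, and blink templates (300-ms raised-cosine
#' deflections) on the EOG channels that propagate into each EEG channel
#' with known coefficients `blink_prop` — the ground truth that
#' [gratton_correct()] must recover.
#'
#' @param n_trials number of events.
#' @param n_channels EEG channels.
#' @param sfreq sampling rate (Hz).
#' @param alpha_amp amplitude of the 10-Hz signal (uV).
#' @param noise_sd SD of the 1/f noise (uV); 0 for a noise-free fixture.
#' @param blink_amp blink amplitude on the vertical EOG (uV).
#' @param blink_rate probability a trial contains a blink.
#' @param blink_prop numeric vector (`n_channels`) of EOG-to-EEG
#'   propagation coefficients.
#' @param epoch_gap spacing between events (ms).
#' @param seed integer seed.
#' @return A list: `data` (channels x samples, uV), `eog` (2 x samples),
#'   `events` (sample indices of target onsets), `sfreq`, `channel_names`,
#'   `blink_prop`, and `clean` (channels x samples signal without artifacts
#'   or noise).
#' @export
synth_eeg_recording <- function(n_trials = 60, n_channels = 4, sfreq = 250,
                                alpha_amp = 10, noise_sd = 0,
                                blink_amp = 200, blink_rate = 0.5,
                                blink_prop = seq(0.1, 0.4,
                                                 length.out = n_channels),
                                epoch_gap = 2200, seed = 1) {
  stopifnot(length(blink_prop) == n_channels)
  gap_s <- round(epoch_gap / 1000 * sfreq)
  n_samp <- gap_s * (n_trials + 1L)
  events <- gap_s * seq_len(n_trials)
  withr::with_seed(as.integer(seed), {
    tsec <- (seq_len(n_samp) - 1) / sfreq
    clean <- matrix(0, n_channels, n_samp)
    for (tr in seq_len(n_trials)) {
      i <- (events[tr] - gap_s + 1):min(events[tr] + gap_s - 1, n_samp)
      ph <- runif(1, -pi, pi)
      seg <- alpha_amp * sin(2 * pi * 10 * tsec[i] + ph)
      for (ch in seq_len(n_channels)) clean[ch, i] <- seg
    }
    # blink template: 300-ms raised cosine
    tpl_len <- round(0.3 * sfreq)
    tpl <- blink_amp * (1 - cos(2 * pi * seq_len(tpl_len) / tpl_len)) / 2
    veog <- numeric(n_samp)
    for (tr in seq_len(n_trials)) {
      if (runif(1) < blink_rate) {
        at <- events[tr] + sample(seq(-gap_s %/% 2, gap_s %/% 3), 1)
        i <- at:min(at + tpl_len - 1, n_samp)
        veog[i] <- veog[i] + tpl[seq_along(i)]
      }
    }
    # horizontal EOG: correlated with blinks but never collinear (its own
    # saccade-like noise keeps the regression design full rank)
    heog <- 0.2 * veog + rnorm(n_samp, 0, max(noise_sd, 1))
    data <- clean + outer(blink_prop, veog)
    if (noise_sd > 0) {
      # 1/f noise: cumulative-sum-shaped spectrum, scaled to noise_sd
      for (ch in seq_len(n_channels)) {
        x <- cumsum(rnorm(n_samp))
        x <- (x - mean(x)) / sd(x) * noise_sd
        data[ch, ] <- data[ch, ] + x
      }
    }
  })
  list(data = data, eog = rbind(veog = veog, heog = heog), events = events,
       sfreq = sfreq,
       channel_names = sprintf("ch%02d", seq_len(n_channels)),
       blink_prop = blink_prop, clean = clean)
}

# slice continuous (channels x samples) into trials x channels x samples
extract_epochs <- function(continuous, events, window, sfreq) {
  i0 <- round(window[1] / 1000 * sfreq)
  i1 <- round(window[2] / 1000 * sfreq)
  idx <- i0:i1
  n_ch <- nrow(continuous)
  ok <- events + i0 >= 1 & events + i1 <= ncol(continuous)
  arr <- array(NA_real_, c(length(events), n_ch, length(idx)))
  for (tr in which(ok))
    arr[tr, , ] <- continuous[, events[tr] + idx, drop = FALSE]
  list(data = arr, times = idx / sfreq * 1000, in_bounds = ok)
}

# subtract the per-trial, per-channel mean over the baseline window
apply_baseline <- function(arr, times, baseline) {
  bsel <- times >= baseline[1] & times < baseline[2]
  bl <- apply(arr[, , bsel, drop = FALSE], c(1, 2), mean)
  sweep(arr, c(1, 2), bl)
}

#' Epoch and clean a continuous recording
#'
#' The full cleaning chain, in the stage order of the otCS study's
#' description: per-trial pre-target baseline subtraction, rejection of
#' trials with any absolute voltage above `reject1` (1000 uV), epoching to
#' the analysis window, regression-based ocular correction
#' ([gratton_correct()]), a second baseline subtraction with the same
#' pre-target window, and a final rejection at `reject2` (500 uV).
#' `mode = "conventional"` instead runs epoch, baseline, reject, correct,
#' re-baseline, reject — the more usual ordering; for these linear stages
#' the two give identical epochs and differ only in bookkeeping. Events too
#' close to the recording edge are flagged (`edge`), not an error.
#'
#' @param continuous channels x samples matrix (uV).
#' @param events sample indices of the alignment event (target onset).
#' @param sfreq sampling rate (Hz).
#' @param window epoch window around the event, `c(-800, 1000)` ms.
#' @param baseline baseline window, `c(-300, 0)` ms.
#' @param reject1,reject2 absolute-voltage thresholds (uV) for the
#'   pre-correction and post-correction rejection stages.
#' @param eog 2 x samples EOG matrix aligned with `continuous`; `NULL`
#'   skips ocular correction.
#' @param mode `"narrative"` (the study-description stage order) or `"conventional"`.
#' @param channel_names optional channel labels.
#' @return An object of class `epoch_set`: `data` (trials x channels x
#'   samples, cleaned), `times` (ms), `channel_names`, `sfreq`, `rejected`
#'   (`data.frame` with per-trial `rejected` flag and `stage` tag in
#'   `edge`, `stage1`, `stage2`, `none`), and `propagation` (per-channel
#'   EOG regression coefficients, when corrected).
#' @export
epoch_and_clean <- function(continuous, events, sfreq,
                            window = c(-800, 1000), baseline = c(-300, 0),
                            reject1 = 1000, reject2 = 500, eog = NULL,
                            mode = c("narrative", "conventional"),
                            channel_names = NULL) {
  mode <- match.arg(mode)
  check_pos(sfreq, "sfreq")
  ep <- extract_epochs(continuous, events, window, sfreq)
  n_tr <- length(events)
  stage <- rep("none", n_tr)
  stage[!ep$in_bounds] <- "edge"

  arr <- apply_baseline(ep$data, ep$times, baseline)

  # stage 1: amplitude rejection before ocular correction
  peak <- apply(abs(arr), 1, max, na.rm = FALSE)
  s1 <- !is.na(peak) & peak > reject1 & stage == "none"
  stage[s1] <- "stage1"

  prop <- NULL
  if (!is.null(eog)) {
    eo <- extract_epochs(eog, events, window, sfreq)
    eo_arr <- apply_baseline(eo$data, eo$times, baseline)
    keep <- stage == "none"
    gc <- gratton_correct_array(arr[keep, , , drop = FALSE],
                                eo_arr[keep, , , drop = FALSE])
    arr[keep, , ] <- gc$data
    prop <- gc$propagation
    # second baseline with the same pre-target window
    arr[keep, , ] <- apply_baseline(arr[keep, , , drop = FALSE],
                                    ep$times, baseline)
  }

  peak2 <- apply(abs(arr), 1, max)
  s2 <- !is.na(peak2) & peak2 > reject2 & stage == "none"
  stage[s2] <- "stage2"

  out <- list(data = arr, times = ep$times,
              channel_names = channel_names %||%
                sprintf("ch%02d", seq_len(dim(arr)[2])),
              sfreq = sfreq,
              rejected = data.frame(trial = seq_len(n_tr),
                                    rejected = stage != "none",
                                    stage = stage, stringsAsFactors = FALSE),
              propagation = prop, mode = mode)
  class(out) <- "epoch_set"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch set:", d[1], "trials x", d[2], "channels x", d[3], "samples",
      sprintf("(%.0f-%.0f ms, %g Hz)\n", min(x$times), max(x$times), x$sfreq))
  rej <- table(x$rejected$stage[x$rejected$rejected])
  if (length(rej))
    cat("  rejected:", paste(sprintf("%s=%d", names(rej), rej),
                             collapse = ", "), "\n")
  invisible(x)
}

# core regression on trials x channels x samples arrays
gratton_correct_array <- function(arr, eog_arr) {
  n_tr <- dim(arr)[1]; n_ch <- dim(arr)[2]; n_eog <- dim(eog_arr)[2]
  if (n_tr < 2) abort_invalid("need >= 2 trials for ocular correction")
  # subtract event-related averages so the regression sees artifact, not ERP
  erp <- apply(arr, c(2, 3), mean)
  eog_erp <- apply(eog_arr, c(2, 3), mean)
  X <- matrix(aperm(sweep(eog_arr, c(2, 3), eog_erp), c(3, 1, 2)),
              ncol = n_eog)                      # (samples*trials) x n_eog
  if (any(apply(X, 2, var) == 0))
    abort_invalid("EOG channel with zero variance")
  Y <- matrix(aperm(sweep(arr, c(2, 3), erp), c(3, 1, 2)), ncol = n_ch)
  b <- tryCatch(solve(crossprod(X), crossprod(X, Y)),   # n_eog x n_ch
                error = function(e)
                  abort_invalid("EOG channels are collinear; cannot attribute propagation"))
  # subtract scaled raw EOG from each trial
  Xraw <- matrix(aperm(eog_arr, c(3, 1, 2)), ncol = n_eog)
  Yc <- matrix(aperm(arr, c(3, 1, 2)), ncol = n_ch) - Xraw %*% b
  corrected <- aperm(array(Yc, c(dim(arr)[3], n_tr, n_ch)), c(2, 3, 1))
  prop <- t(b)
  colnames(prop) <- paste0("eog", seq_len(n_eog))
  list(data = corrected, propagation = prop)
}

#' Regression-based ocular correction of epochs
#'
#' Gratton-style correction: event-related averages are subtracted from
#' both EEG and EOG, per-channel propagation coefficients are estimated by
#' least squares of the average-subtracted EEG on the average-subtracted
#' EOG (both channels jointly), and the scaled raw EOG is subtracted from
#' every trial. One coefficient per (channel, EOG channel) pair; no
#' separate blink/saccade partition.
#'
#' @param epochs an `epoch_set`, or a trials x channels x samples array.
#' @param eog trials x n_eog x samples array of EOG epochs.
#' @return For an array input, a list `data` (corrected array) and
#'   `propagation` (channels x n_eog coefficients); for an `epoch_set`, the
#'   corrected `epoch_set` with `propagation` attached.
#' @export
gratton_correct <- function(epochs, eog) {
  if (inherits(epochs, "epoch_set")) {
    res <- gratton_correct_array(epochs$data, eog)
    epochs$data <- res$data
    epochs$propagation <- res$propagation
    epochs
  } else {
    gratton_correct_array(epochs, eog)
  }
}
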