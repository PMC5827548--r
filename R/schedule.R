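#' Session plan for the target detection task
#'
#' Describes one experimental session of the masked target detection task:
#' block structure, catch-trial fraction, the set of fixation-to-target
#' onset asynchronies (tSOAs), per-event durations, and the stimulation
#' pulse train. Defaults reproduce the study design: 3 blocks of 128
#' trials, 20% catch trials, eight tSOAs between 200 and 408.33 ms, an
#' 8.33-ms target with a constant 41.7-ms target-mask SOA, a 1000-ms
#' response window, and 2.5-ms stimulation pulses every 100 ms (10 Hz).
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials in each block.
#' @param catch_fraction fraction of target-absent (catch) trials per block,
#'   in `[0, 1)`. The per-block catch count is fixed at
#'   `round(catch_fraction * trials_per_block)` (26 for the defaults) rather
#'   than drawn per trial, which stabilizes detection-rate denominators.
#' @param tsoa_set possible fixation-to-target SOAs (ms).
#' @param fixation_dur fixation cross duration (ms).
#' @param target_dur target duration (ms).
#' @param mask_soa target-to-mask SOA (ms).
#' @param response_window response deadline after mask offset (ms).
#' @param pulse_period stimulation pulse period (ms); 100 ms = 10 Hz.
#' @param pulse_width stimulation pulse width (ms); must be < `pulse_period`.
#'
#' @return An object of class `session_plan`.
#' @seealso [build_schedule()], [pulse_to_target_soa()]
#' @export
#' @examples
#' plan <- session_plan()
#' plan$n_blocks * plan$trials_per_block # 384 trials
session_plan <- function(n_blocks = 3L,
                         trials_per_block = 128L,
                         catch_fraction = 0.2,
                         tsoa_set = c(200, 225, 266.66, 283.33, 300,
                                      341.66, 374.99, 408.33),
                         fixation_dur = 400,
                         target_dur = 8.33,
                         mask_soa = 41.7,
                         response_window = 1000,
                         pulse_period = 100,
                         pulse_width = 2.5) {
  plan <- structure(
    list(n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         catch_fraction = catch_fraction,
         tsoa_set = as.numeric(tsoa_set),
         fixation_dur = fixation_dur,
         target_dur = target_dur,
         mask_soa = mask_soa,
         response_window = response_window,
         pulse_period = pulse_period,
         pulse_width = pulse_width),
    class = "session_plan")
  validate_session_plan(plan)
  plan
}

#' Validate a session plan
#'
#' Checks every field of a [session_plan()]: positive durations and counts,
#' `catch_fraction` in `[0, 1)`, a non-empty `tsoa_set`, and
#' `pulse_period > pulse_width`. Errors name the offending field.
#'
#' @param plan a `session_plan`.
#' @return `plan`, invisibly, if valid.
#' @export
validate_session_plan <- function(plan) {
  if (!inherits(plan, "session_plan"))
    abort_invalid("`plan` must be a session_plan object", field = "plan")
  for (f in c("n_blocks", "trials_per_block", "fixation_dur", "target_dur",
              "mask_soa", "response_window", "pulse_period", "pulse_width"))
    check_pos(plan[[f]], f)
  cf <- plan$catch_fraction
  if (!is.numeric(cf) || length(cf) != 1L || is.na(cf) || cf < 0 || cf >= 1)
    abort_invalid("`catch_fraction` must lie in [0, 1)", field = "catch_fraction")
  if (length(plan$tsoa_set) == 0L || any(!is.finite(plan$tsoa_set)) ||
      any(plan$tsoa_set <= 0))
    abort_invalid("`tsoa_set` must be a non-empty vector of positive durations",
                  field = "tsoa_set")
  if (plan$pulse_period <= plan$pulse_width)
    abort_invalid("`pulse_period` must exceed `pulse_width`", field = "pulse_period")
  invisible(plan)
}

#' @export
print.session_plan <- function(x, ...) {
  cat("Session plan:", x$n_blocks, "blocks x", x$trials_per_block, "trials,",
      sprintf("%.0f%%", 100 * x$catch_fraction), "catch trials\n")
  cat("  tSOA set (ms):", paste(x$tsoa_set, collapse = ", "), "\n")
  cat("  pulse train:", x$pulse_width, "ms pulses every", x$pulse_period,
      "ms (", round(1000 / x$pulse_period, 1), "Hz )\n")
  invisible(x)
}

#' Pulse-to-target stimulus onset asynchrony
#'
#' Time from the most recent stimulation pulse to target onset — the phase
#' proxy used for phase binning. Computed as
#' `(target_onset - pulse_phase0) mod period`, with the half-open convention
#' `[0, period)`: a target coincident with a pulse has SOA 0.
#'
#' @param target_onset target onset time (ms), on the same clock as the
#'   pulse train. May be a vector.
#' @param pulse_phase0 time of the (a) pulse defining the train's phase (ms).
#' @param period pulse period (ms), > 0.
#' @return Pulse-to-target SOA(s) in `[0, period)`.
#' @export
#' @examples
#' pulse_to_target_soa(350, 0, 100)    # 50
#' pulse_to_target_soa(408.33, 0, 100) # 8.33
pulse_to_target_soa <- function(target_onset, pulse_phase0 = 0, period = 100) {
  check_pos(period, "period")
  soa <- (target_onset - pulse_phase0) %% period
  # floating-point residue at the right edge collapses to 0
  soa[soa >= period] <- 0
  soa
}

#' Build a randomized trial schedule
#'
#' Generates the full trial list for one session: `n_blocks *
#' trials_per_block` trials, with exactly `round(catch_fraction *
#' trials_per_block)` catch trials randomly positioned within each block and
#' tSOAs drawn uniformly (with replacement) from `plan$tsoa_set`. The
#' stimulation pulse train is phase-locked to block onset (phase 0 at each
#' block start), runs continuously through the block, and each trial's
#' pulse-to-target SOA is derived from the cumulative trial timeline.
#' Identical `(plan, seed)` give a byte-identical schedule.
#'
#' @param plan a [session_plan()].
#' @param seed integer seed controlling catch positions and tSOA draws.
#' @param participant_id,condition,order labels copied into every row.
#' @return A `data.frame` with one row per trial and columns
#'   `participant_id`, `condition`, `order`, `block`, `trial` (1-based index
#'   within block), `tsoa`, `catch`, `target_onset` (ms from block start),
#'   `pulse_soa` (ms, in `[0, pulse_period)`), `luminance`, `response`, `rt`
#'   (the last three `NA` — responses are attached by an observer or a real
#'   session).
#' @export
#' @examples
#' sched <- build_schedule(session_plan(), seed = 1)
#' nrow(sched)            # 384
#' sum(sched$catch)       # 78 = 3 x 26
build_schedule <- function(plan, seed,
                           participant_id = "p01",
                           condition = "sham",
                           order = "sham_first") {
  validate_session_plan(plan)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_invalid("`seed` must be a single integer", field = "seed")

  sch <- withr::with_seed(as.integer(seed), schedule_core(plan))
  data.frame(
    participant_id = participant_id, condition = condition, order = order,
    block = sch$block, trial = sch$trial, tsoa = sch$tsoa,
    catch = sch$catch, target_onset = sch$target_onset,
    pulse_soa = sch$pulse_soa,
    luminance = NA_real_, response = NA_character_, rt = NA_real_,
    stringsAsFactors = FALSE)
}

# draws one session's schedule from the *current* RNG stream; callers seed
schedule_core <- function(plan) {
  n <- plan$trials_per_block
  nb <- plan$n_blocks
  n_catch <- round(plan$catch_fraction * n)
  catch <- logical(nb * n); tsoa <- onset <- numeric(nb * n)
  for (b in seq_len(nb)) {
    idx <- (b - 1L) * n + seq_len(n)
    cb <- rep(FALSE, n)
    if (n_catch > 0) cb[sample.int(n, n_catch)] <- TRUE
    ts <- sample(plan$tsoa_set, n, replace = TRUE)
    # trial timeline: fixation, blank until target, mask at mask_soa after
    # target onset, then the response window; trials abut within the block
    trial_dur <- plan$fixation_dur + ts + plan$mask_soa +
      plan$target_dur + plan$response_window
    trial_start <- cumsum(c(0, trial_dur[-n]))
    catch[idx] <- cb
    tsoa[idx] <- ts
    onset[idx] <- trial_start + plan$fixation_dur + ts
  }
  list(block = rep(seq_len(nb), each = n), trial = rep(seq_len(n), nb),
       tsoa = tsoa, catch = catch, target_onset = onset,
       pulse_soa = pulse_to_target_soa(onset, 0, plan$pulse_period))
}

#' Read / write trial tables
#'
#' Trial tables round-trip as comma-separated text with a header row and one
#' trial per row; a missing `rt` is an empty field.
#'
#' @param trials a trial `data.frame` as produced by [build_schedule()] or
#'   [simulate_cohort()].
#' @param path file path.
#' @return `read_trials()` returns the trial `data.frame`; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character",
                                condition = "character",
                                order = "character",
                                response = "character"))
  tr$catch <- as.logical(tr$catch)
  tr$response[!is.na(tr$response) & tr$response == ""] <- NA_character_
  tr
}

#' Validate a trial table against the expected schema
#'
#' Checks the column set, condition/order/response labels, that `pulse_soa`
#' lies in `[0, period)`, and that catch trials never carry hit/miss
#' responses. Returns an itemized character vector of problems (empty when
#' valid); `must_pass = TRUE` turns problems into an error.
#'
#' @param trials trial `data.frame`.
#' @param period pulse period (ms) used to bound `pulse_soa`.
#' @param must_pass error on problems instead of returning them.
#' @return Character vector of problems, invisibly when empty.
#' @export
validate_trials <- function(trials, period = 100, must_pass = FALSE) {
  problems <- character()
  need <- c("participant_id", "condition", "order", "block", "trial",
            "tsoa", "catch", "pulse_soa", "luminance", "response", "rt")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    problems <- c(problems, paste("missing columns:",
                                  paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    if (!all(trials$condition %in% c("sham", "otcs")))
      problems <- c(problems, "condition labels must be 'sham' or 'otcs'")
    if (!all(trials$order %in% c("sham_first", "otcs_first")))
      problems <- c(problems, "order labels must be 'sham_first' or 'otcs_first'")
    bad_resp <- setdiff(unique(trials$response[!is.na(trials$response)]),
                        c("hit", "miss", "false_alarm", "correct_rejection",
                          "no_response"))
    if (length(bad_resp))
      problems <- c(problems, paste("unknown response labels:",
                                    paste(bad_resp, collapse = ", ")))
    if (any(trials$pulse_soa < 0 | trials$pulse_soa >= period))
      problems <- c(problems, sprintf("pulse_soa outside [0, %g)", period))
    if (any(trials$catch & trials$response %in% c("hit", "miss")))
      problems <- c(problems, "catch trials carry hit/miss responses")
  }
  if (must_pass && length(problems))
    abort_invalid(paste0("invalid trial table:\n  - ",
                         paste(problems, collapse = "\n  - ")))
  if (length(problems)) problems else invisible(character())
}
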