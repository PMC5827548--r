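#' Adaptive 3-up/1-down luminance staircase
#'
#' State of a transformed up-down staircase that adjusts target luminance
#' toward a criterion detection rate: every hit lowers the luminance by
#' `step_down`, and three *consecutive* misses raise it by `step_up`
#' (misses must raise luminance for a detection task). With the shipped
#' step-size ratio `step_up / step_down = 7` the procedure's equilibrium
#' detection rate is 0.5: at the balance point the expected downward
#' movement per trial, `p * step_down`, equals the upward movement,
#' `q^3 / (1 + q + q^2) * step_up` with `q = 1 - p` (the completion rate of
#' miss triples in the run-counter Markov chain), and equality at `p = 0.5`
#' requires a 7:1 ratio. See `system.file("scripts",
#' "calibrate_staircase.R", package = "phasedetect")` for the derivation
#' plus a Monte-Carlo check.
#'
#' @param level current luminance (arbitrary units).
#' @param step_down luminance decrement applied on each hit.
#' @param step_up luminance increment applied after 3 consecutive misses.
#' @param floor,ceiling luminance bounds; the level is clamped to them.
#' @return An object of class `staircase_state` with fields `level`,
#'   `run_counter`, `step_up`, `step_down`, `floor`, `ceiling`, `reversals`
#'   (levels at direction changes) and `last_direction`.
#' @export
staircase_state <- function(level = 60, step_down = 0.1, step_up = 0.7,
                            floor = 0, ceiling = 100) {
  check_pos(step_down, "step_down")
  check_pos(step_up, "step_up")
  if (!(floor <= level && level <= ceiling))
    abort_invalid("`level` must lie in [floor, ceiling]", field = "level")
  structure(
    list(level = level, run_counter = 0L, step_up = step_up,
         step_down = step_down, floor = floor, ceiling = ceiling,
         reversals = numeric(), last_direction = "none"),
    class = "staircase_state")
}

#' @export
print.staircase_state <- function(x, ...) {
  cat("3-up/1-down staircase: level", signif(x$level, 4),
      "| run counter", x$run_counter,
      "|", length(x$reversals), "reversals\n")
  invisible(x)
}

#' Update a staircase after a scored target-present trial
#'
#' A hit lowers the level by `step_down` and resets the consecutive-miss
#' counter; a miss increments the counter, and when it reaches 3 the level
#' rises by `step_up` and the counter resets. The level is clamped to
#' `[floor, ceiling]`, and the pre-move level is appended to `reversals`
#' whenever the direction of movement changes. Catch trials and trials
#' without a valid response must not be passed in — they do not update the
#' staircase.
#'
#' @param state a [staircase_state()].
#' @param hit logical: was the target detected?
#' @return The updated `staircase_state`.
#' @export
#' @examples
#' s <- staircase_state(level = 10, step_down = 1, step_up = 7)
#' staircase_update(s, hit = TRUE)$level # 9
staircase_update <- function(state, hit) {
  stopifnot(inherits(state, "staircase_state"))
  if (is.na(hit)) abort_invalid("`hit` must be TRUE or FALSE", field = "hit")
  move <- 0
  if (hit) {
    move <- -state$step_down
    state$run_counter <- 0L
  } else {
    state$run_counter <- state$run_counter + 1L
    if (state$run_counter >= 3L) {
      move <- state$step_up
      state$run_counter <- 0L
    }
  }
  if (move != 0) {
    dir <- if (move > 0) "up" else "down"
    if (state$last_direction != "none" && state$last_direction != dir)
      state$reversals <- c(state$reversals, state$level)
    state$last_direction <- dir
    state$level <- min(max(state$level + move, state$floor), state$ceiling)
  }
  state
}

#' Converged luminance from a staircase run
#'
#' Two estimators of the staircase's converged level: the mean of the last
#' `n_last_reversals` reversal levels (default), or — `mode =
#' "trailing_trials"` — the mean level over the last `n_trailing` trials of
#' the trajectory, the analogue of averaging luminance over the final
#' blocks of a session.
#'
#' @param trajectory a `data.frame` from [run_staircase()] (needs columns
#'   `level` and `reversal`), or a numeric vector of reversal levels when
#'   `mode = "reversals"`.
#' @param n_last_reversals number of trailing reversals to average.
#' @param mode `"reversals"` or `"trailing_trials"`.
#' @param n_trailing number of trailing trials in `"trailing_trials"` mode.
#' @return The converged luminance (scalar).
#' @export
converged_level <- function(trajectory, n_last_reversals = 8,
                            mode = c("reversals", "trailing_trials"),
                            n_trailing = 256) {
  mode <- match.arg(mode)
  if (mode == "reversals") {
    revs <- if (is.data.frame(trajectory)) {
      trajectory$level[trajectory$reversal]
    } else as.numeric(trajectory)
    if (length(revs) < n_last_reversals)
      abort_invalid(sprintf(
        "need at least %d reversals, have %d", n_last_reversals, length(revs)))
    mean(tail(revs, n_last_reversals))
  } else {
    if (!is.data.frame(trajectory) || nrow(trajectory) < n_trailing)
      abort_invalid(sprintf("need at least %d trials in the trajectory",
                            n_trailing))
    mean(tail(trajectory$level, n_trailing))
  }
}

#' Logistic psychometric observer
#'
#' Hit probability for a target at luminance `L`:
#' `(1 - lapse) * plogis(slope * (L - threshold))` — 0.5 at threshold when
#' `lapse = 0`.
#'
#' @param luminance stimulus luminance.
#' @param threshold luminance at the psychometric inflection.
#' @param slope logistic steepness per luminance unit.
#' @param lapse stimulus-independent miss probability.
#' @return Hit probability/probabilities.
#' @export
psychometric_hit_prob <- function(luminance, threshold = 50, slope = 0.3,
                                  lapse = 0) {
  (1 - lapse) * stats::plogis(slope * (luminance - threshold))
}

#' Simulate a staircase run against a logistic observer
#'
#' Runs the 3-up/1-down staircase for `n_trials` scored target-present
#' trials against a [psychometric_hit_prob()] observer, recording the full
#' trajectory. Deterministic given `(state, observer parameters, seed)`.
#'
#' @param n_trials number of scored trials.
#' @param state initial [staircase_state()].
#' @param threshold,slope,lapse observer parameters.
#' @param seed integer seed.
#' @return A `data.frame` with columns `trial`, `level` (luminance shown on
#'   that trial), `hit`, `reversal` (did this trial's move reverse
#'   direction).
#' @export
#' @examples
#' traj <- run_staircase(500, seed = 1)
#' mean(traj$hit[301:500]) # near 0.5
run_staircase <- function(n_trials, state = staircase_state(),
                          threshold = 50, slope = 0.3, lapse = 0,
                          seed = 1) {
  level <- hit <- numeric(n_trials)
  reversal <- logical(n_trials)
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_trials)) {
      level[i] <- state$level
      p <- psychometric_hit_prob(state$level, threshold, slope, lapse)
      hit[i] <- runif(1) < p
      n_rev <- length(state$reversals)
      state <- staircase_update(state, hit[i] > 0)
      reversal[i] <- length(state$reversals) > n_rev
    }
  })
  data.frame(trial = seq_len(n_trials), level = level,
             hit = as.logical(hit), reversal = reversal)
}

#' Equilibrium detection rate of the 3-up/1-down rule
#'
#' Small-step balance point of the staircase: the detection rate `p` at
#' which the expected downward movement `p * step_down` equals the expected
#' upward movement `(1-p)^3 / (1 + (1-p) + (1-p)^2) * step_up`. For the
#' shipped 7:1 ratio the root is exactly 0.5.
#'
#' @param step_up,step_down staircase step sizes.
#' @return Equilibrium hit rate in (0, 1).
#' @export
staircase_equilibrium <- function(step_up = 0.7, step_down = 0.1) {
  f <- function(p) {
    q <- 1 - p
    p * step_down - q^3 / (1 + q + q^2) * step_up
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
}
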