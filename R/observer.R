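#' Parametric observer for the target detection task
#'
#' Generative model of one participant's detection behavior. Hit
#' probability on target-present trials is a lapse-adjusted logistic of a
#' linear predictor on the log-odds scale:
#'
#' \deqn{\eta = s\,(L - \theta) + A \sin(2\pi\,\mathrm{SOA}/T + \varphi)
#'   + \beta_{fat}\,(trial-1) + \beta_{seq}\,[second\ condition]}
#'
#' with luminance `L`, threshold `\theta`, slope `s`, entrainment amplitude
#' `A` (zero unless the condition is phase-locked), entrainment phase
#' `\varphi`, a within-block fatigue drift, and a sequence bonus for the
#' second-performed condition; `p = (1 - lapse) * plogis(eta)`. Putting the
#' entrainment term on the log-odds scale keeps `p` in (0, 1) for any `A`;
#' the sinusoidal model downstream is nevertheless fit on the (standardized)
#' rate scale, as in the analysis it feeds — that scale mismatch is
#' deliberate and realistic. Catch trials bypass this model entirely: they
#' produce a false alarm with probability `guess_fa`.
#'
#' @param threshold luminance at the psychometric inflection.
#' @param slope logistic steepness (per luminance unit), > 0.
#' @param lapse stimulus-independent miss probability, in `[0, 1)`.
#' @param guess_fa false-alarm probability on catch trials.
#' @param entrain_amp phase-locked modulation amplitude `A` (log-odds), >= 0.
#' @param entrain_phase entrainment phase (radians, in `(-pi, pi]`).
#' @param fatigue_slope log-odds drift per trial within a block (negative =
#'   fatigue; the drift resets at each block start).
#' @param condition_offset log-odds bonus in the second-performed condition
#'   (the sequence effect).
#' @param no_response_rate probability a trial yields no valid response,
#'   independent of the stimulus.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(threshold = 50, slope = 0.3, lapse = 0.02,
                            guess_fa = 0.05, entrain_amp = 0,
                            entrain_phase = 0, fatigue_slope = -0.003,
                            condition_offset = 0.2,
                            no_response_rate = 0.02) {
  check_pos(slope, "slope")
  for (f in c("lapse", "guess_fa", "no_response_rate")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v >= 1)
      abort_invalid(sprintf("`%s` must lie in [0, 1)", f), field = f)
  }
  if (entrain_amp < 0)
    abort_invalid("`entrain_amp` must be >= 0", field = "entrain_amp")
  structure(
    list(threshold = threshold, slope = slope, lapse = lapse,
         guess_fa = guess_fa, entrain_amp = entrain_amp,
         entrain_phase = wrap_angle(entrain_phase),
         fatigue_slope = fatigue_slope, condition_offset = condition_offset,
         no_response_rate = no_response_rate),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("Observer: threshold", x$threshold, "| slope", x$slope,
      "| lapse", x$lapse, "\n")
  cat("  entrainment A =", x$entrain_amp, "| phase",
      signif(x$entrain_phase, 3), "rad\n")
  cat("  fatigue", x$fatigue_slope, "log-odds/trial | sequence bonus",
      x$condition_offset, "| FA rate", x$guess_fa, "\n")
  invisible(x)
}

#' Hit probability for target-present trials
#'
#' Evaluates the observer's hit probability for one or more target-present
#' trials (see [observer_params()] for the model). Catch trials are a
#' precondition violation: their false alarms are governed by `guess_fa`
#' directly, not by this psychometric model.
#'
#' @param trial one or more trial rows (needs `catch`, `luminance`,
#'   `pulse_soa`, `trial`, and — for the sequence term — `condition`,
#'   `order`).
#' @param params an [observer_params()].
#' @param entrain_on logical: include the phase-locked term? (The sham
#'   condition has it off regardless of `entrain_amp`.)
#' @param period pulse period (ms) converting `pulse_soa` to phase.
#' @return Hit probabilities in (0, 1).
#' @export
#' @examples
#' obs <- observer_params(lapse = 0, fatigue_slope = 0, no_response_rate = 0)
#' tr <- data.frame(catch = FALSE, luminance = 50, pulse_soa = 25, trial = 1,
#'                  condition = "sham", order = "sham_first")
#' p_hit(tr, obs, entrain_on = FALSE) # 0.5 at threshold
p_hit <- function(trial, params, entrain_on = FALSE, period = 100) {
  stopifnot(inherits(params, "observer_params"))
  if (any(trial$catch))
    abort_invalid("p_hit() is defined for target-present trials only; catch trials use `guess_fa`")
  eta <- params$slope * (trial$luminance - params$threshold)
  if (entrain_on && params$entrain_amp > 0)
    eta <- eta + params$entrain_amp *
      sin(2 * pi * trial$pulse_soa / period + params$entrain_phase)
  eta <- eta + params$fatigue_slope * (trial$trial - 1)
  if (!is.null(trial$condition) && !is.null(trial$order)) {
    second <- (trial$order == "sham_first" & trial$condition == "otcs") |
              (trial$order == "otcs_first" & trial$condition == "sham")
    eta <- eta + params$condition_offset * second
  }
  (1 - params$lapse) * stats::plogis(eta)
}

#' Population specification for simulated cohorts
#'
#' Distributional specification from which per-participant [observer_params()] are
#' drawn: thresholds are jittered across participants
#' (`N(threshold_mean, threshold_sd)`), slopes are log-normal around
#' `slope_mean`, and the session luminance is the participant's threshold
#' plus a `N(0, calib_sd)` staircase-calibration error, held constant across
#' both experimental conditions (as when luminance is fixed from an earlier
#' staircased run). Remaining parameters are shared across the cohort.
#'
#' @param threshold_mean,threshold_sd population mean/SD of thresholds.
#' @param slope_mean,slope_cv mean and coefficient of variation of slopes.
#' @param calib_sd SD of the luminance calibration error (luminance units).
#' @param ... overrides passed to each participant's [observer_params()]
#'   (e.g. `lapse`, `fatigue_slope`, `condition_offset`, `entrain_phase`).
#' @return An object of class `observer_population`.
#' @export
observer_population <- function(threshold_mean = 50, threshold_sd = 5,
                                slope_mean = 0.3, slope_cv = 0.2,
                                calib_sd = 1, ...) {
  structure(
    list(threshold_mean = threshold_mean, threshold_sd = threshold_sd,
         slope_mean = slope_mean, slope_cv = slope_cv, calib_sd = calib_sd,
         overrides = list(...)),
    class = "observer_population")
}

#' Simulate a counterbalanced sham/otCS cohort
#'
#' Generates the full trial-level dataset of a simulated experiment:
#' `n_participants` observers (parameters drawn from `population`), each
#' performing both conditions with exactly half the cohort in each
#' counterbalancing order. The sham condition always has entrainment off;
#' the otCS condition carries amplitude `entrain_amp`. Responses are
#' Bernoulli draws from [p_hit()] (target-present) or `guess_fa` (catch),
#' with no-response trials inserted at the observer's `no_response_rate`
#' and log-normal response times attached to responded trials. Fully
#' reproducible from `seed`.
#'
#' @param n_participants cohort size; must be even for exact
#'   counterbalancing unless `allow_odd = TRUE` (which leaves the extra
#'   participant in the sham-first group).
#' @param plan a [session_plan()].
#' @param population an [observer_population()].
#' @param entrain_amp log-odds entrainment amplitude `A` of the otCS
#'   condition (sham is always 0).
#' @param seed integer master seed.
#' @param allow_odd permit odd `n_participants`.
#' @return A trial `data.frame` (one row per trial,
#'   `n_participants * 2 * n_blocks * trials_per_block` rows) in the
#'   [build_schedule()] schema with `luminance`, `response` and `rt` filled.
#' @export
#' @examples
#' trials <- simulate_cohort(4, session_plan(), seed = 1)
#' nrow(trials) # 4 * 2 * 384
simulate_cohort <- function(n_participants = 36, plan = session_plan(),
                            population = observer_population(),
                            entrain_amp = 0, seed = 1, allow_odd = FALSE) {
  if (n_participants %% 2 != 0 && !allow_odd)
    abort_invalid("`n_participants` must be even for exact counterbalancing (or set allow_odd = TRUE)",
                  field = "n_participants")
  stopifnot(inherits(population, "observer_population"))
  validate_session_plan(plan)
  seed <- as.integer(seed)

  orders <- rep(c("sham_first", "otcs_first"), length.out = n_participants)
  pop <- population
  n_per <- plan$n_blocks * plan$trials_per_block
  sessions <- vector("list", n_participants * 2L)

  withr::with_seed(seed, {
    # per-participant parameter draws, then the 2 x n_participants sessions,
    # all from one master stream
    params_list <- lapply(seq_len(n_participants), function(i) {
      th <- rnorm(1, pop$threshold_mean, pop$threshold_sd)
      sl <- rlnorm(1, log(pop$slope_mean) - pop$slope_cv^2 / 2, pop$slope_cv)
      lum <- th + rnorm(1, 0, pop$calib_sd)
      args <- c(list(threshold = th, slope = sl, entrain_amp = entrain_amp),
                pop$overrides)
      list(params = do.call(observer_params, args), luminance = lum)
    })
    k <- 0L
    for (i in seq_len(n_participants)) {
      obs <- params_list[[i]]$params
      lum <- params_list[[i]]$luminance
      for (cond in c("sham", "otcs")) {
        k <- k + 1L
        sch <- schedule_core(plan)
        tp <- !sch$catch
        eta <- obs$slope * (lum - obs$threshold) +
          obs$fatigue_slope * (sch$trial - 1)
        if (cond == "otcs" && obs$entrain_amp > 0)
          eta <- eta + obs$entrain_amp *
            sin(2 * pi * sch$pulse_soa / plan$pulse_period + obs$entrain_phase)
        second <- (orders[i] == "sham_first") == (cond == "otcs")
        if (second) eta <- eta + obs$condition_offset
        p <- (1 - obs$lapse) * stats::plogis(eta)
        hit <- runif(n_per) < p
        fa <- runif(n_per) < obs$guess_fa
        response <- ifelse(tp, ifelse(hit, "hit", "miss"),
                           ifelse(fa, "false_alarm", "correct_rejection"))
        response[runif(n_per) < obs$no_response_rate] <- "no_response"
        responded <- response %in% c("hit", "false_alarm")
        rt <- ifelse(responded, rlnorm(n_per, log(450), 0.2), NA_real_)
        sessions[[k]] <- list(pid = i, cond = cond, ord = orders[i],
                              sch = sch, lum = lum, response = response,
                              rt = rt)
      }
    }
  })

  pull <- function(what, fn = `[[`)
    unlist(lapply(sessions, fn, what), use.names = FALSE)
  res <- data.frame(
    participant_id = rep(sprintf("p%02d", pull("pid")), each = n_per),
    condition = rep(pull("cond"), each = n_per),
    order = rep(pull("ord"), each = n_per),
    block = pull(NULL, function(s, w) s$sch$block),
    trial = pull(NULL, function(s, w) s$sch$trial),
    tsoa = pull(NULL, function(s, w) s$sch$tsoa),
    catch = pull(NULL, function(s, w) s$sch$catch),
    target_onset = pull(NULL, function(s, w) s$sch$target_onset),
    pulse_soa = pull(NULL, function(s, w) s$sch$pulse_soa),
    luminance = rep(pull("lum"), each = n_per),
    response = pull("response"),
    rt = pull("rt"),
    stringsAsFactors = FALSE)
  res
}
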