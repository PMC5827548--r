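# End-to-end pipeline: trial table -> binned rates -> standardization ->
# mixed ANOVAs (both error modes) -> per-participant sine fits -> condition
# comparison -> time-course ANOVA with post-hocs; plus the simulation
# harness measuring type-I error, power and parameter recovery.

#' Default pipeline configuration
#'
#' All analysis knobs in one plain list, overridable via `...` or a YAML
#' key-value file ([read_config()]). Fields: `bin_width` and `pulse_period`
#' (ms) for phase binning, `normalize` (`"z"`, `"center"` or `"none"`),
#' `error_mode` (`"stratified"` or `"pooled"`), `n_starts` and `seed` for
#' the sine fits, `prior_scale` for the Bayes factor, `timecourse_bin_size`
#' (consecutive trials per time bin), and `alpha` (rejection criterion of
#' the operating-characteristics harness).
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(bin_width = 10, pulse_period = 100, normalize = "z",
              error_mode = "stratified", n_starts = 50, seed = 1,
              prior_scale = sqrt(2) / 2, timecourse_bin_size = 32,
              alpha = 0.05)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    abort_invalid(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML key-value file with a subset of the config fields.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full behavioral analysis pipeline
#'
#' Executes the complete analysis sequence on a trial table: phase binning
#' ([detection_rates()]), within participant x condition standardization
#' ([standardize_rates()]), the mixed ANOVA in both error modes on the raw
#' and (when normalizing) the standardized rates, per-participant
#' fixed-frequency sine fits on the standardized rates
#' ([fit_sine_cohort()]), the amplitude / fit-quality condition comparison
#' with its Bayes factors ([compare_conditions()], [dp_signed_rank()]), and
#' the time-course repeated-measures ANOVA over consecutive-trial bins with
#' Mauchly/Greenhouse-Geisser machinery and Holm post-hocs. With an
#' `out_dir` the results are serialized to JSON (every statistic plus the
#' configuration and its hash) and summary figures are written.
#'
#' @param trials trial `data.frame` (schema of [build_schedule()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for `results.json` and figures.
#' @return An object of class `pipeline_result`: list with `binned`
#'   (standardized `binned_rates`), `fits`, `comparison`,
#'   `anova_raw_stratified`, `anova_raw_pooled`, `anova_std_stratified`,
#'   `anova_std_pooled` (the last two `NULL` when `normalize = "none"`),
#'   `timecourse`, `timecourse_anova`, `posthoc`, `dp_fit_quality`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(trials, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_trials(trials, period = config$pulse_period, must_pass = TRUE)
  if (length(unique(trials$participant_id)) < 5)
    abort_invalid("the pipeline needs >= 5 participants (the signed-rank and sphericity stages are undefined below that)")

  rates <- detection_rates(trials, config$bin_width, config$pulse_period)
  std <- if (config$normalize == "none") {
    rates$z <- rates$rate
    rates
  } else standardize_rates(rates, method = config$normalize)

  # mixed ANOVA needs the order label per participant
  ord <- unique(trials[c("participant_id", "order")])
  long_raw <- merge(rates, ord, by = "participant_id")
  long_raw$value <- long_raw$rate
  long_std <- merge(std, ord, by = "participant_id")
  long_std$value <- long_std$z

  an_raw_strat <- mixed_anova(long_raw, "stratified")
  an_raw_pool <- mixed_anova(long_raw, "pooled")
  an_std_strat <- an_std_pool <- NULL
  if (config$normalize != "none") {
    an_std_strat <- mixed_anova(long_std, "stratified")
    an_std_pool <- mixed_anova(long_std, "pooled")
  }

  fits <- fit_sine_cohort(std, config$bin_width, config$pulse_period,
                          n_starts = config$n_starts, seed = config$seed)
  fits <- fits[order(fits$participant_id, fits$condition), ]
  fs <- fits[fits$condition == "sham", ]
  fo <- fits[fits$condition == "otcs", ]
  comparison <- compare_conditions(fs, fo, prior_scale = config$prior_scale)
  dp <- dp_signed_rank(fo$adj_r2 - fs$adj_r2, seed = config$seed)

  tc <- timecourse_rates(trials, config$timecourse_bin_size)
  tc_an <- rm_anova(tc, within = c("condition", "time_bin"), dv = "rate")
  ph <- posthoc_pairwise(tc, "time_bin", dv = "rate")

  res <- list(binned = std, fits = fits, comparison = comparison,
              anova_raw_stratified = an_raw_strat,
              anova_raw_pooled = an_raw_pool,
              anova_std_stratified = an_std_strat,
              anova_std_pooled = an_std_pool,
              timecourse = tc, timecourse_anova = tc_an, posthoc = ph,
              dp_fit_quality = dp,
              config = config, config_hash = rlang::hash(config))
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result (config", substr(x$config_hash, 1, 8), ")\n\n")
  print(x$comparison)
  cat("\nTime-course ANOVA:\n")
  print(x$timecourse_anova)
  invisible(x)
}

#' Serialize a pipeline result
#'
#' Writes `results.json` (all statistics, dfs, epsilons, Bayes factors and
#' the generating configuration plus its hash) and, when ggplot2 devices
#' are usable, the two summary figures: the bin-rate profile with fitted
#' sinusoids per condition and the time-course rates.
#'
#' @param res a `pipeline_result`.
#' @param out_dir directory (created if absent).
#' @param figures also write PNG figures.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir, figures = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- list(
    config = unclass(res$config), config_hash = res$config_hash,
    amplitude_comparison = res$comparison$amplitude,
    fit_quality = c(res$comparison$fit_quality,
                    list(posterior_p_h0 = res$dp_fit_quality$posterior_p_h0,
                         mc_error = res$dp_fit_quality$mc_error)),
    anova_raw_stratified = as.data.frame(res$anova_raw_stratified),
    anova_raw_pooled = as.data.frame(res$anova_raw_pooled),
    anova_std_stratified = if (!is.null(res$anova_std_stratified))
      as.data.frame(res$anova_std_stratified),
    anova_std_pooled = if (!is.null(res$anova_std_pooled))
      as.data.frame(res$anova_std_pooled),
    timecourse_anova = as.data.frame(res$timecourse_anova),
    posthoc = res$posthoc,
    fits = res$fits)
  jsonlite::write_json(ser, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (figures) {
    try({
      grDevices::png(file.path(out_dir, "bin_profile.png"), 900, 600)
      print(plot_bin_profile(res$binned, res$fits))
      grDevices::dev.off()
      grDevices::png(file.path(out_dir, "timecourse.png"), 900, 600)
      print(plot_timecourse(res$timecourse))
      grDevices::dev.off()
    }, silent = TRUE)
  }
  invisible(out_dir)
}

# lean inner loop of the simulation harness: the pipeline stages feeding the
# amplitude comparison only (no ANOVAs, no figures)
amplitude_test_once <- function(n_participants, plan, population,
                                entrain_amp, seed, n_starts = 3) {
  trials <- simulate_cohort(n_participants, plan, population,
                            entrain_amp = entrain_amp, seed = seed)
  rates <- detection_rates(trials, period = plan$pulse_period)
  std <- standardize_rates(rates)
  fits <- fit_sine_cohort(std, period = plan$pulse_period,
                          n_starts = n_starts, seed = seed)
  fits <- fits[order(fits$participant_id, fits$condition), ]
  fs <- fits[fits$condition == "sham", ]
  fo <- fits[fits$condition == "otcs", ]
  tt <- paired_t(fo$alpha1, fs$alpha1)
  list(t = tt$t, p = tt$p,
       mean_a1_otcs = mean(fo$alpha1), mean_a1_sham = mean(fs$alpha1),
       phi_otcs = fo$phi)
}

#' Operating characteristics of the amplitude test
#'
#' Simulation-based evaluation of the pipeline's inferential behavior: for
#' each entrainment amplitude `A` in `amps`, simulates `n_sims`
#' counterbalanced cohorts (sham always `A = 0`, otCS carrying `A`), runs
#' the pipeline's amplitude path (bin, standardize, sine fits, paired t on
#' `alpha1`), and records the rejection rate at `alpha`, the mean bias of
#' the otCS amplitude estimates relative to each run's mean sham amplitude,
#' and the RMSE. `A = 0` rows measure the type-I error; the rejection rate
#' should be statistically flat at `alpha` there and non-decreasing in `A`.
#'
#' @param amps entrainment amplitudes (log-odds scale) to sweep; the
#'   default covers null through saturating modulation.
#' @param n_sims simulated cohorts per amplitude (>= 100 for usable
#'   Monte-Carlo error).
#' @param n_participants cohort size.
#' @param plan a [session_plan()].
#' @param population an [observer_population()].
#' @param seed integer master seed.
#' @param alpha two-sided rejection criterion.
#' @param n_starts sine-fit starts inside the loop.
#' @param progress print a line per amplitude.
#' @return `data.frame` with one row per amplitude: `A`, `n_sims`,
#'   `rejection_rate`, `mc_se` (binomial Monte-Carlo SE of the rejection
#'   rate), `mean_amp_diff` (mean otCS - sham fitted amplitude),
#'   `rmse_amp_diff`, `mean_p`.
#' @export
operating_characteristics <- function(amps = c(0, 0.1, 0.25, 0.5, 1.0),
                                      n_sims = 100, n_participants = 36,
                                      plan = session_plan(),
                                      population = observer_population(),
                                      seed = 1, alpha = 0.05,
                                      n_starts = 3, progress = FALSE) {
  if (n_sims < 100) abort_invalid("`n_sims` must be >= 100", field = "n_sims")
  seed <- as.integer(seed)
  rows <- lapply(seq_along(amps), function(ai) {
    A <- amps[ai]
    ps <- diffs <- numeric(n_sims)
    for (s in seq_len(n_sims)) {
      r <- amplitude_test_once(n_participants, plan, population, A,
                               seed = (seed + 1000003L * ai + s) %%
                                 .Machine$integer.max,
                               n_starts = n_starts)
      ps[s] <- r$p
      diffs[s] <- r$mean_a1_otcs - r$mean_a1_sham
    }
    rej <- mean(ps < alpha)
    if (progress)
      message(sprintf("A = %.2f: rejection %.3f", A, rej))
    data.frame(A = A, n_sims = n_sims, rejection_rate = rej,
               mc_se = sqrt(rej * (1 - rej) / n_sims),
               mean_amp_diff = mean(diffs),
               rmse_amp_diff = sqrt(mean(diffs^2)),
               mean_p = mean(ps))
  })
  do.call(rbind, rows)
}

#' Null p-value distribution of the amplitude test
#'
#' Replicates the pipeline's amplitude comparison on cohorts simulated with
#' no entrainment (`A = 0`) and returns the p-values — the raw material for
#' type-I-error and uniformity checks.
#'
#' @inheritParams operating_characteristics
#' @param n_reps number of null replicates.
#' @return Numeric vector of `n_reps` two-sided p-values.
#' @export
null_pvalues <- function(n_reps = 1000, n_participants = 36,
                         plan = session_plan(),
                         population = observer_population(), seed = 1,
                         n_starts = 3) {
  seed <- as.integer(seed)
  vapply(seq_len(n_reps), function(s)
    amplitude_test_once(n_participants, plan, population, 0,
                        seed = (seed + 7L * s) %% .Machine$integer.max,
                        n_starts = n_starts)$p,
    numeric(1))
}
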