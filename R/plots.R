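# Summary figures (ggplot2)

#' Bin-rate profile with fitted sinusoids
#'
#' Group-mean standardized detection rate per 10-ms phase bin and
#' condition, with each condition's sinusoid evaluated at the group-mean
#' fit parameters overlaid.
#'
#' @param binned standardized `binned_rates` table (column `z`).
#' @param fits fit table from [fit_sine_cohort()].
#' @param width,period bin geometry (ms).
#' @return A ggplot object.
#' @export
plot_bin_profile <- function(binned, fits, width = 10, period = 100) {
  ctr <- bin_centers(width, period)
  agg <- aggregate(z ~ bin + condition, binned, mean)
  agg$t <- ctr[agg$bin + 1L]
  se <- aggregate(z ~ bin + condition, binned,
                  function(v) sd(v) / sqrt(length(v)))
  agg$se <- se$z[match(paste(agg$bin, agg$condition),
                       paste(se$bin, se$condition))]
  tt <- seq(0, period, length.out = 200)
  curves <- do.call(rbind, lapply(split(fits, fits$condition), function(f) {
    # mean curve: average the fitted sinusoids via their linear form
    b1 <- mean(f$alpha1 * cos(f$phi)); b2 <- mean(f$alpha1 * sin(f$phi))
    data.frame(condition = f$condition[1], t = tt,
               z = mean(f$alpha0) + b1 * sin(2 * pi / period * tt) +
                 b2 * cos(2 * pi / period * tt))
  }))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$t, y = .data$z,
                                    colour = .data$condition)) +
    ggplot2::geom_line(data = curves, linewidth = 0.8) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$z - .data$se,
                                          ymax = .data$z + .data$se)) +
    ggplot2::labs(x = "pulse-to-target SOA (ms)",
                  y = "standardized detection rate",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Time-course of detection rates
#'
#' Group-mean detection rate per consecutive-trial bin and condition with
#' standard-error bars; vertical lines mark block boundaries for the
#' default 12 x 32-trial layout.
#'
#' @param tc table from [timecourse_rates()].
#' @param block_every draw a block boundary every this many bins (`NA`
#'   for none).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(tc, block_every = 4) {
  agg <- aggregate(rate ~ time_bin + condition, tc, mean)
  se <- aggregate(rate ~ time_bin + condition, tc,
                  function(v) sd(v) / sqrt(length(v)))
  agg$se <- se$rate[match(paste(agg$time_bin, agg$condition),
                          paste(se$time_bin, se$condition))]
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$time_bin, y = .data$rate,
                                         colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rate - .data$se,
                                          ymax = .data$rate + .data$se)) +
    ggplot2::labs(x = "consecutive-trial bin", y = "detection rate",
                  colour = "condition") +
    ggplot2::theme_minimal()
  if (!is.na(block_every)) {
    bounds <- seq(block_every, max(agg$time_bin) - 1, by = block_every) + 0.5
    p <- p + ggplot2::geom_vline(xintercept = bounds, linetype = "dotted",
                                 colour = "grey50")
  }
  p
}
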