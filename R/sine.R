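#' Bin-center times for the phase bins
#'
#' Midpoints of the `period/width` half-open phase bins: 5, 15, ..., 95 ms
#' for the defaults — the abscissae at which the sinusoid is fit.
#'
#' @param width,period bin width and pulse period (ms).
#' @return Numeric vector of bin-center times (ms).
#' @export
bin_centers <- function(width = 10, period = 100) {
  seq(width / 2, period - width / 2, by = width)
}

#' Constrained fixed-frequency sine fit to standardized bin rates
#'
#' Fits \deqn{x(t) = \alpha_0 + \alpha_1 \sin(\omega t + \varphi)} to the
#' (standardized) detection rates of the phase bins by nonlinear least
#' squares with the frequency fixed at one cycle per pulse period
#' (`omega = 2*pi/100` rad/ms, i.e. 10 Hz) and the constraints
#' `alpha1 >= 0`, `phi` in `(-pi, pi]`. The optimizer is multistart
#' bounded L-BFGS-B with an analytic gradient; one start is seeded from the
#' exact linearization `a0 + b1 sin(wt) + b2 cos(wt)` (ordinary least
#' squares, then `alpha1 = sqrt(b1^2 + b2^2)`, `phi = atan2(b2, b1)`), the
#' remaining `n_starts - 1` are random. Missing bins are dropped; at least
#' 5 non-missing points are required (> number of free parameters + 1).
#'
#' A constant input is degenerate: by convention it returns `alpha1 = 0`,
#' `phi = 0`, `sse = 0`, and `r2 = adj_r2 = 0`. For non-degenerate input,
#' `r2 = 1 - sse/sst` and `adj_r2 = 1 - (1 - r2) (n-1)/(n-p-1)` with
#' `p = 3` free parameters (`omega` is fixed and not counted).
#'
#' @param y standardized rates at the bin centers (length-10 by default;
#'   `NA`s allowed).
#' @param t bin-center times (ms).
#' @param omega fixed angular frequency (rad/ms).
#' @param n_starts number of optimization starts.
#' @param seed integer seed for the random starts.
#' @return An object of class `sine_fit`: a list with `alpha0`, `alpha1`,
#'   `phi`, `omega`, `sse`, `r2`, `adj_r2`, `n_points`, `converged`.
#' @export
#' @examples
#' t <- bin_centers()
#' y <- 0.5 + 0.3 * sin(2 * pi / 100 * t + 1.0)
#' f <- fit_sine(y)
#' c(f$alpha1, f$phi) # 0.3, 1.0
fit_sine <- function(y, t = bin_centers(), omega = 2 * pi / 100,
                     n_starts = 50, seed = 1) {
  check_pos(omega, "omega")
  ok <- !is.na(y)
  if (length(y) != length(t))
    abort_invalid("`y` and `t` must have equal length")
  if (sum(ok) < 5)
    abort_invalid(sprintf("need >= 5 non-missing points, have %d", sum(ok)))
  yy <- y[ok]; tt <- t[ok]
  n <- length(yy)
  s <- sin(omega * tt); co <- cos(omega * tt)
  sst <- sum((yy - mean(yy))^2)

  if (sst == 0) {             # degenerate constant input, convention
    fit <- list(alpha0 = yy[1], alpha1 = 0, phi = 0, omega = omega,
                sse = 0, r2 = 0, adj_r2 = 0, n_points = n, converged = TRUE)
    class(fit) <- "sine_fit"
    return(fit)
  }

  obj <- function(par) {
    r <- yy - par[1] - par[2] * sin(omega * tt + par[3])
    sum(r * r)
  }
  grad <- function(par) {
    sn <- sin(omega * tt + par[3])
    r <- yy - par[1] - par[2] * sn
    c(-2 * sum(r),
      -2 * sum(r * sn),
      -2 * par[2] * sum(r * cos(omega * tt + par[3])))
  }

  # deterministic start from the exact linearization
  X <- cbind(1, s, co)
  b <- solve(crossprod(X), crossprod(X, yy))
  seed_start <- c(b[1], sqrt(b[2]^2 + b[3]^2), atan2(b[3], b[2]))

  starts <- list(seed_start)
  if (n_starts > 1) {
    rs <- withr::with_seed(as.integer(seed), {
      m <- mean(yy); sdev <- sd(yy)
      lapply(seq_len(n_starts - 1), function(i)
        c(rnorm(1, m, sdev), runif(1, 0, 2 * sdev), runif(1, -pi, pi)))
    })
    starts <- c(starts, rs)
  }

  best <- NULL; best_sse <- Inf; any_conv <- FALSE
  for (st in starts) {
    # phi explores [-2pi, 2pi] so minima near +/-pi are reachable; wrapped after
    res <- optim(st, obj, grad, method = "L-BFGS-B",
                 lower = c(-Inf, 0, -2 * pi), upper = c(Inf, Inf, 2 * pi),
                 control = list(factr = 10, maxit = 200))
    if (res$convergence == 0) any_conv <- TRUE
    if (res$value < best_sse) { best_sse <- res$value; best <- res }
  }

  a0 <- best$par[1]; a1 <- best$par[2]; phi <- wrap_angle(best$par[3])
  if (a1 < 0) { a1 <- -a1; phi <- wrap_angle(phi + pi) }   # defensive; bound keeps a1 >= 0
  sse <- best$value
  r2 <- 1 - sse / sst
  p <- 3
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  fit <- list(alpha0 = a0, alpha1 = a1, phi = phi, omega = omega,
              sse = sse, r2 = r2, adj_r2 = adj_r2, n_points = n,
              converged = any_conv)
  class(fit) <- "sine_fit"
  fit
}

#' @export
print.sine_fit <- function(x, ...) {
  cat(sprintf(
    "Sine fit (omega = %.4f rad/ms): a0 = %.4f, a1 = %.4f, phi = %.4f rad\n",
    x$omega, x$alpha0, x$alpha1, x$phi))
  cat(sprintf("  sse = %.5g, R2 = %.3f, adj R2 = %.3f, n = %d, converged: %s\n",
              x$sse, x$r2, x$adj_r2, x$n_points, x$converged))
  invisible(x)
}

#' Sine fits for every participant x condition
#'
#' Applies [fit_sine()] to the standardized bin rates of each participant
#' and condition in a `binned_rates` table (column `z`; see
#' [standardize_rates()]).
#'
#' @param rates standardized `binned_rates` table.
#' @param width,period bin geometry (ms), defining bin centers and `omega`.
#' @inheritParams fit_sine
#' @return A `data.frame` with one row per participant x condition:
#'   `participant_id`, `condition`, `alpha0`, `alpha1`, `phi`, `sse`, `r2`,
#'   `adj_r2`, `n_points`, `converged`.
#' @export
fit_sine_cohort <- function(rates, width = 10, period = 100,
                            n_starts = 50, seed = 1) {
  if (is.null(rates$z))
    abort_invalid("`rates` must carry a `z` column; run standardize_rates() first")
  omega <- 2 * pi / period
  tctr <- bin_centers(width, period)
  key <- paste(rates$participant_id, rates$condition, sep = "\r")
  groups <- split(seq_len(nrow(rates)), key)
  num <- vapply(groups, function(i) {
    o <- i[order(rates$bin[i])]
    f <- fit_sine(rates$z[o], tctr[rates$bin[o] + 1L], omega = omega,
                  n_starts = n_starts, seed = seed)
    c(f$alpha0, f$alpha1, f$phi, f$sse, f$r2, f$adj_r2, f$n_points,
      f$converged)
  }, numeric(8))
  ids <- do.call(rbind, strsplit(names(groups), "\r", fixed = TRUE))
  out <- data.frame(participant_id = ids[, 1], condition = ids[, 2],
                    alpha0 = num[1, ], alpha1 = num[2, ], phi = num[3, ],
                    sse = num[4, ], r2 = num[5, ], adj_r2 = num[6, ],
                    n_points = as.integer(num[7, ]),
                    converged = num[8, ] > 0, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compare sine-fit amplitude and fit quality between conditions
#'
#' The condition contrast of the sinusoidal analysis: a paired Student's
#' t-test on the fitted amplitudes `alpha1` (with the JZS default-Cauchy
#' Bayes factor attached) and a Wilcoxon signed-rank test on the adjusted
#' R-squared values.
#'
#' @param fits_sham,fits_otcs equal-length paired fit tables (rows aligned
#'   by participant) from [fit_sine_cohort()], or vectors/lists of
#'   `sine_fit` objects.
#' @param prior_scale Cauchy prior width for the Bayes factor.
#' @return A list of class `sine_comparison`: `amplitude` (`t`, `df`, `p`,
#'   `mean_diff`, `bf10`), `fit_quality` (`z`, `p` from the signed-rank
#'   test), and `n` pairs.
#' @export
compare_conditions <- function(fits_sham, fits_otcs, prior_scale = sqrt(2) / 2) {
  pull <- function(f, what) {
    if (is.data.frame(f)) f[[what]]
    else vapply(f, function(x) x[[what]], numeric(1))
  }
  a1_s <- pull(fits_sham, "alpha1"); a1_o <- pull(fits_otcs, "alpha1")
  r2_s <- pull(fits_sham, "adj_r2"); r2_o <- pull(fits_otcs, "adj_r2")
  if (length(a1_s) != length(a1_o))
    abort_invalid("paired fit lists must have equal length")
  n <- length(a1_s)
  tt <- if (all(a1_o == a1_s)) {
    # identical amplitude lists: a zero-variance difference of zeros is the
    # exact null, t = 0 by continuity
    list(t = 0, df = n - 1L, p = 1)
  } else paired_t(a1_o, a1_s)
  bf <- jzs_bf_paired(tt$t, n = n, prior_scale = prior_scale)$bf10
  d <- r2_o - r2_s
  wt <- if (all(d == 0)) list(z = 0, p = 1, n = 0L) else
    wilcoxon_signed_rank(d)
  out <- list(
    amplitude = list(t = tt$t, df = tt$df, p = tt$p,
                     mean_diff = mean(a1_o - a1_s), bf10 = bf),
    fit_quality = list(z = wt$z, p = wt$p),
    n = length(a1_s))
  class(out) <- "sine_comparison"
  out
}

#' @export
print.sine_comparison <- function(x, ...) {
  cat(sprintf("Amplitude (alpha1), otCS - sham: t(%d) = %.3f, p = %.3f, BF10 = %.3f\n",
              x$amplitude$df, x$amplitude$t, x$amplitude$p, x$amplitude$bf10))
  cat(sprintf("Fit quality (adj R2): Z = %.3f, p = %.3f  (n = %d pairs)\n",
              x$fit_quality$z, x$fit_quality$p, x$n))
  invisible(x)
}
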