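# Shared fixtures and independent oracles. Oracle code here is written
# against the model definitions directly and never calls the package's
# optimizer/implementation internals.

# a small, fast session plan for tests that only need structure
tiny_plan <- function(n_blocks = 1L, trials_per_block = 64L, ...) {
  session_plan(n_blocks = n_blocks, trials_per_block = trials_per_block, ...)
}

# hand-buildable trial table; bins/hits given directly
toy_trials <- function(bins, hits, catch_n = 0, no_resp_n = 0,
                       participant = "p01", condition = "sham",
                       order = "sham_first") {
  n <- length(bins) + catch_n + no_resp_n
  soa <- c(bins * 10 + 5, rep(2, catch_n + no_resp_n))
  resp <- c(ifelse(hits == 1, "hit", "miss"),
            rep("correct_rejection", catch_n), rep("no_response", no_resp_n))
  data.frame(participant_id = participant, condition = condition,
             order = order, block = 1L, trial = seq_len(n),
             tsoa = 200, catch = c(rep(FALSE, length(bins)),
                                   rep(TRUE, catch_n), rep(FALSE, no_resp_n)),
             target_onset = soa, pulse_soa = soa, luminance = 50,
             response = resp, rt = NA_real_, stringsAsFactors = FALSE)
}

# dense grid-search oracle for the constrained sine fit: minimum SSE over a
# 51^3 lattice of (alpha0, alpha1, phi), evaluated in closed form from the
# sufficient statistics for each phi
grid_sse_oracle <- function(y, t, omega, n_grid = 51) {
  ok <- !is.na(y)
  yy <- y[ok]; tt <- t[ok]
  n <- length(yy)
  a0g <- seq(mean(yy) - 2 * sd(yy), mean(yy) + 2 * sd(yy), length.out = n_grid)
  a1g <- seq(0, 2.5 * sd(yy), length.out = n_grid)
  phig <- seq(-pi, pi, length.out = n_grid)
  sy2 <- sum(yy^2); sy <- sum(yy)
  best <- Inf
  for (phi in phig) {
    s <- sin(omega * tt + phi)
    sys <- sum(yy * s); ss <- sum(s); ss2 <- sum(s^2)
    # sse(a0,a1) = sy2 - 2 a0 sy - 2 a1 sys + n a0^2 + 2 a0 a1 ss + a1^2 ss2
    m <- sy2 - 2 * outer(a0g * sy, a1g * sys, `+`) +
      n * a0g^2 + 2 * outer(a0g, a1g) * ss + rep(a1g^2 * ss2, each = n_grid)
    best <- min(best, min(m))
  }
  best
}

# unconstrained closed-form optimum of the fixed-frequency sine model via
# the linear basis (1, sin wt, cos wt); amplitude from the linear solution
# is always >= 0, so this is also the constrained optimum
linear_sine_oracle <- function(y, t, omega) {
  ok <- !is.na(y)
  X <- cbind(1, sin(omega * t[ok]), cos(omega * t[ok]))
  fit <- lm.fit(X, y[ok])
  b <- fit$coefficients
  list(alpha0 = b[1], alpha1 = sqrt(b[2]^2 + b[3]^2),
       phi = atan2(b[3], b[2]), sse = sum(fit$residuals^2))
}

# independent JZS oracle: marginalize over effect size delta with a
# noncentral-t likelihood and Cauchy prior (a different formulation and a
# different quadrature than the package's scale-mixture g-integral)
jzs_oracle <- function(t, n, r = sqrt(2) / 2) {
  nu <- n - 1
  f <- function(d) dt(t, nu, ncp = d * sqrt(n)) * dcauchy(d, 0, r)
  # trapezoid on a wide fixed grid
  d <- seq(-15, 15, length.out = 40001)
  h <- d[2] - d[1]
  v <- suppressWarnings(f(d))
  alt <- h * (sum(v) - (v[1] + v[length(v)]) / 2)
  alt / dt(t, nu)
}
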