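#' Paired Student's t-test
#'
#' Thin wrapper over [stats::t.test()] for paired samples:
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`, two-sided p. A
#' zero-variance difference vector is an error (the statistic is
#' undefined).
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return A list with `t`, `df`, `p`, `mean_diff`.
#' @export
#' @examples
#' paired_t(c(2, 3, 4), c(1, 1, 1)) # t = 2*sqrt(3), df = 2
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    abort_invalid("`x` and `y` must be paired vectors of equal length >= 2")
  d <- x - y
  if (sd(d) == 0)
    abort_invalid("differences have zero variance; the paired t statistic is undefined")
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences with the conventions fixed so
#' the Z statistic is reproducible bit-for-bit: zeros are dropped
#' (Wilcoxon convention), ranks of `|d|` use midranks for ties, the
#' normal approximation uses the tie-corrected variance
#' `n(n+1)(2n+1)/24 - sum(t^3 - t)/48` and **no** continuity correction,
#' and `Z = (W - n(n+1)/4) / sd` where `W` is the positive-rank sum. For
#' `n <= max_exact` non-zero differences an exact two-sided p is also
#' computed by enumerating all `2^n` sign assignments of the observed
#' ranks.
#'
#' @param d numeric vector of paired differences (length >= 5 after zero
#'   removal).
#' @param max_exact largest n for which the exact enumeration is run.
#' @return A list with `z`, `p` (normal approximation), `w` (positive-rank
#'   sum), `n` (non-zero differences), and `p_exact` (`NA` when
#'   `n > max_exact`).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(-2, -1, 1, 2, -3, 3))$z # 0
wilcoxon_signed_rank <- function(d, max_exact = 12) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort_invalid("all differences are zero")
  if (n < 5) abort_invalid("need >= 5 non-zero differences")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(z))
  p <- min(p, 1)
  p_exact <- NA_real_
  if (n <= max_exact) {
    # enumerate all sign assignments of the observed (mid)ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p_exact <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
  }
  list(z = z, p = p, w = w, n = n, p_exact = p_exact)
}

#' Holm step-down adjustment
#'
#' Familywise-error control by Holm's step-down procedure, via
#' [stats::p.adjust()]: sorted p-values are multiplied by `m, m-1, ...`,
#' monotonicity is enforced by running maxima, and values are clipped at 1.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    abort_invalid("`pvals` must lie in [0, 1]", field = "pvals")
  p.adjust(pvals, method = "holm")
}
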