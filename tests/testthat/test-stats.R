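test_that("paired t matches the hand formula and stats::t.test", {
  tt <- paired_t(c(2, 3, 4), c(1, 1, 1))      # d = 1, 2, 3
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  withr::with_seed(2, {
    x <- rnorm(36); y <- rnorm(36)
    mine <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic))
    expect_equal(mine$df, 35)
    expect_equal(mine$p, ref$p.value)
  })
  expect_error(paired_t(1:5, 1:5), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("holm adjustment follows the step-down rule", {
  # sorted: .01*3=.03, .03*2=.06, .04*1=.04 -> running max -> .06
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(0.03, 4)), rep(0.12, 4))
  expect_equal(holm_adjust(c(0.5, 0.9)), c(1, 1))  # running-max monotonicity
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("signed-rank Z is zero for sign-symmetric differences", {
  w <- wilcoxon_signed_rank(c(-2, -1, 1, 2, -3, 3))
  expect_equal(w$z, 0)
  expect_equal(w$p, 1)
})

test_that("zeros are dropped and small n gets an exact enumeration", {
  w <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3, -1, 4, -2))
  expect_equal(w$n, 6)
  expect_false(is.na(w$p_exact))
  # with no ties the exact p matches stats::wilcox.test's exact p
  d <- c(1.2, -0.7, 2.1, 3.3, -1.6, 0.4, 2.8, -2.2)
  mine <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, exact = TRUE)
  expect_equal(mine$p_exact, ref$p.value, tolerance = 1e-12)
  # and the approximation matches wilcox.test without continuity correction
  ref2 <- wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(mine$p, ref2$p.value, tolerance = 1e-12)
  # away from the null center the approximation is tight at n = 8
  w8 <- wilcoxon_signed_rank(c(2.5, 1.4, -0.8, 3.1, 2.2, -1.7, 0.9, 1.8))
  expect_lt(abs(w8$p - w8$p_exact), 0.05)
})

test_that("shifting differences upward raises the positive-rank sum", {
  d <- c(-3, -1, 0.5, 1.5, 2, -0.2, 0.8)
  w1 <- wilcoxon_signed_rank(d)
  w2 <- wilcoxon_signed_rank(d + 1)
  expect_gt(w2$w, w1$w)
  expect_gt(w2$z, w1$z)
})

test_that("signed-rank preconditions", {
  expect_error(wilcoxon_signed_rank(rep(0, 6)), "zero")
  expect_error(wilcoxon_signed_rank(c(0, 0, 1, 2)), ">= 5")
})

null_mixed_data <- function(n = 36, k_bin = 10, seed = 1) {
  d <- expand.grid(participant_id = sprintf("p%02d", 1:n),
                   condition = c("sham", "otcs"), bin = 0:(k_bin - 1),
                   stringsAsFactors = FALSE)
  d$order <- ifelse(as.integer(sub("p", "", d$participant_id)) <= n / 2,
                    "sham_first", "otcs_first")
  withr::with_seed(seed, d$value <- rnorm(nrow(d)))
  d
}

test_that("pooled mixed ANOVA reproduces the published df structure", {
  tb <- as.data.frame(mixed_anova(null_mixed_data(), "pooled"))
  expect_equal(unique(tb$df_den), 646)
  expect_equal(tb$df_num[tb$effect == "condition:order"], 1)
  expect_setequal(tb$effect,
                  c("condition", "bin", "condition:bin", "condition:order",
                    "bin:order", "condition:bin:order"))
})

test_that("stratified mixed ANOVA tests each effect in its own stratum", {
  tb <- as.data.frame(mixed_anova(null_mixed_data(), "stratified"))
  co <- tb[tb$effect == "order:condition", ]
  expect_equal(c(co$df_num, co$df_den), c(1, 34))
  expect_equal(tb$df_den[tb$effect == "bin"], 306)   # (n-2) x 9
  expect_equal(tb$df_den[tb$effect == "order"], 34)
})

test_that("balanced SS decompositions close to the total SS", {
  d <- null_mixed_data(n = 12, k_bin = 5, seed = 3)
  for (mode in c("pooled", "stratified")) {
    tb <- mixed_anova(d, mode)
    tot <- sum(as.data.frame(tb)$ss) + sum(attr(tb, "residuals")$ss)
    expect_equal(tot, attr(tb, "total_ss"), tolerance = 1e-8)
  }
})

test_that("unbalanced input errors and names the offending cell", {
  d <- null_mixed_data(n = 6, k_bin = 3)
  expect_error(mixed_anova(d[-1, ], "pooled"), "unbalanced")
})

test_that("RM-ANOVA yields the published bin-effect dfs and GG correction", {
  d <- expand.grid(participant_id = sprintf("p%02d", 1:36),
                   time_bin = sprintf("t%02d", 1:12), stringsAsFactors = FALSE)
  withr::with_seed(5, d$value <- rnorm(nrow(d)))
  tb <- as.data.frame(rm_anova(d, within = "time_bin"))
  expect_equal(c(tb$df_num, tb$df_den), c(11, 385))
  expect_equal(tb$df_num_gg, tb$gg_epsilon * 11)
  expect_equal(tb$df_den_gg, tb$gg_epsilon * 385)
  expect_gte(tb$gg_epsilon, 1 / 11)
  expect_lte(tb$gg_epsilon, 1)
})

test_that("two-level within factors trivially satisfy sphericity", {
  d <- expand.grid(participant_id = sprintf("p%02d", 1:10),
                   condition = c("a", "b"), stringsAsFactors = FALSE)
  withr::with_seed(6, d$value <- rnorm(nrow(d)))
  tb <- as.data.frame(rm_anova(d, within = "condition"))
  expect_equal(tb$mauchly_w, 1)
  expect_equal(tb$gg_epsilon, 1)
  expect_error(rm_anova(transform(d, condition = "a"), within = "condition"),
               "2 levels")
})

test_that("Mauchly W and GG epsilon match the base-R mlm machinery", {
  d <- expand.grid(participant_id = sprintf("p%02d", 1:20),
                   b = sprintf("b%d", 1:6), stringsAsFactors = FALSE)
  withr::with_seed(7, d$value <- rnorm(nrow(d)) +
                     rep(rnorm(20), 6) * rep(seq(0, 2, length.out = 6),
                                             each = 20))
  tb <- as.data.frame(rm_anova(d, within = "b"))
  wide <- reshape(d, timevar = "b", idvar = "participant_id",
                  direction = "wide")
  mlmfit <- lm(as.matrix(wide[, -1]) ~ 1)
  mt <- mauchly.test(mlmfit, X = ~1)
  expect_equal(tb$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
  # mauchly.test uses a higher-order expansion for p; the first-order
  # chi-square approximation must sit close to it
  expect_equal(tb$mauchly_p, mt$p.value, tolerance = 0.05)
  ca <- car::Anova(mlmfit, idata = data.frame(b = factor(1:6)), idesign = ~b)
  cs <- summary(ca, multivariate = FALSE)
  expect_equal(tb$gg_epsilon, unname(cs$pval.adjustments[1, "GG eps"]),
               tolerance = 1e-10)
})

test_that("two-within RM-ANOVA covers the condition x time-bin design", {
  d <- expand.grid(participant_id = sprintf("p%02d", 1:36),
                   condition = c("sham", "otcs"),
                   time_bin = sprintf("t%02d", 1:12), stringsAsFactors = FALSE)
  withr::with_seed(8, d$value <- rnorm(nrow(d)))
  tb <- as.data.frame(rm_anova(d, within = c("condition", "time_bin")))
  expect_equal(tb$df_den[tb$effect == "condition"], 35)
  expect_equal(tb$df_den[tb$effect == "time_bin"], 385)
  expect_equal(tb$df_num[tb$effect == "condition:time_bin"], 11)
  inter <- tb[tb$effect == "condition:time_bin", ]
  expect_equal(inter$df_num_gg, inter$gg_epsilon * 11)
})

test_that("the condition test is calibrated on null data", {
  ps <- vapply(1:100, function(s) {
    d <- null_mixed_data(n = 10, k_bin = 4, seed = 100 + s)
    tb <- as.data.frame(mixed_anova(d, "stratified"))
    tb$p[tb$effect == "condition"]
  }, numeric(1))
  # Binomial(100, 0.05) within 3 sigma, and p-values roughly uniform
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 100))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("posthoc pairwise table is Holm-adjusted and complete", {
  d <- expand.grid(participant_id = sprintf("p%02d", 1:8),
                   time_bin = sprintf("t%d", 1:4), stringsAsFactors = FALSE)
  withr::with_seed(9, d$value <- rnorm(nrow(d)))
  ph <- posthoc_pairwise(d, "time_bin")
  expect_equal(nrow(ph), choose(4, 2))
  expect_true(all(ph$p_holm >= ph$p))
  expect_equal(ph$df, rep(7, 6))
})
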