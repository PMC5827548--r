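# ANOVA machinery: balanced mixed / repeated-measures designs, with
# Mauchly's sphericity test and Greenhouse-Geisser correction computed from
# the orthonormal-contrast covariance of the within-subject scores.

# orthonormal contrasts spanning the (k-1)-dim space orthogonal to the mean
ortho_contrasts <- function(k) {
  qr.Q(qr(stats::contr.helmert(k)))          # k x (k-1), orthonormal columns
}

# balanced-design check: every participant x factor-level cell equally filled
check_balanced <- function(data, participant, facs) {
  tab <- table(data[c(participant, facs)])
  if (length(unique(as.vector(tab))) != 1L || any(tab == 0)) {
    bad <- which(tab != stats::median(tab), arr.ind = TRUE)[1, , drop = TRUE]
    lab <- paste(mapply(function(d, i) dimnames(tab)[[d]][i],
                        seq_along(bad), bad), collapse = " / ")
    abort_invalid(paste("design is unbalanced; offending cell:", lab))
  }
  invisible(TRUE)
}

# Per-subject contrast scores of a within effect. `effect_facs` is the
# subset of within factors defining the effect (main effect: one factor,
# averaging over the others; interaction: Kronecker product of contrasts).
within_scores <- function(data, participant, within, effect_facs, dv) {
  means <- aggregate(data[[dv]],
                     data[c(participant, effect_facs)], mean)
  names(means)[ncol(means)] <- ".value"
  lv <- lapply(effect_facs, function(f) sort(unique(as.character(means[[f]]))))
  names(lv) <- effect_facs
  # order cells: last factor fastest, matching kronecker() layout
  ord <- do.call(order, c(means[c(participant, effect_facs)]))
  means <- means[ord, ]
  subj <- sort(unique(as.character(means[[participant]])))
  k <- prod(vapply(lv, length, integer(1)))
  Y <- matrix(means$.value, nrow = length(subj), ncol = k, byrow = TRUE)
  C <- Reduce(kronecker, lapply(lv, function(l) ortho_contrasts(length(l))))
  Y %*% C                                      # subjects x d contrast scores
}

# Mauchly W / chi-square p and Greenhouse-Geisser epsilon from contrast
# scores, with the covariance pooled within `groups` (between-subject cells).
sphericity_stats <- function(scores, groups = NULL) {
  d <- ncol(scores)
  n <- nrow(scores)
  if (d < 2) return(list(w = 1, p = NA_real_, epsilon = 1))
  if (is.null(groups)) groups <- rep(1L, n)
  g <- length(unique(groups))
  centered <- scores
  for (gr in unique(groups)) {
    i <- groups == gr
    centered[i, ] <- sweep(scores[i, , drop = FALSE], 2,
                           colMeans(scores[i, , drop = FALSE]))
  }
  df_cov <- n - g
  if (df_cov < 1)            # too few subjects to estimate the covariance
    return(list(w = NA_real_, p = NA_real_, epsilon = NA_real_))
  S <- crossprod(centered) / df_cov
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  epsilon <- sum(ev)^2 / (d * sum(ev^2))
  if (df_cov < d)            # singular covariance: W degenerate, eps still defined
    return(list(w = NA_real_, p = NA_real_, epsilon = epsilon))
  w <- prod(ev) / (mean(ev))^d
  # chi-square approximation with the standard small-sample factor
  f <- 1 - (2 * d^2 + d + 2) / (6 * d * df_cov)
  chi2 <- -f * df_cov * log(max(w, .Machine$double.xmin))
  df_chi <- d * (d + 1) / 2 - 1
  p <- pchisq(chi2, df_chi, lower.tail = FALSE)
  list(w = w, p = p, epsilon = epsilon)
}

# assemble one anova_table row
anova_row <- function(effect, ss, df_num, df_den, f, p,
                      w = NA, w_p = NA, eps = NA) {
  data.frame(effect = effect, ss = ss, df_num = df_num, df_den = df_den,
             F = f, p = p, mauchly_w = w, mauchly_p = w_p, gg_epsilon = eps,
             df_num_gg = if (is.na(eps)) NA_real_ else eps * df_num,
             df_den_gg = if (is.na(eps)) NA_real_ else eps * df_den,
             p_gg = if (is.na(eps) || is.na(f)) NA_real_ else
               stats::pf(f, eps * df_num, eps * df_den, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# pull (ss, df, F, p) rows out of a summary.aovlist / summary.aov,
# plus the residual SS/df of every error stratum
harvest_aov <- function(sm) {
  out <- list()
  resid <- list()
  strata <- if (inherits(sm, "summary.aovlist")) sm else list(sm)
  for (si in seq_along(strata)) {
    st <- strata[[si]]
    tab <- as.data.frame(st[[1]])
    res_i <- grepl("Residuals", rownames(tab))
    df_den <- if (any(res_i)) tab$Df[res_i] else NA_real_
    if (any(res_i))
      resid[[length(resid) + 1L]] <- data.frame(
        stratum = names(strata)[si] %||% "residual",
        df = tab$Df[res_i], ss = tab$`Sum Sq`[res_i])
    for (r in rownames(tab)[!res_i]) {
      rr <- tab[r, ]
      out[[length(out) + 1L]] <- list(
        effect = gsub(" ", "", r), ss = rr$`Sum Sq`, df_num = rr$Df,
        df_den = df_den,
        F = if (is.null(rr$`F value`)) NA_real_ else rr$`F value`,
        p = if (is.null(rr$`Pr(>F)`)) NA_real_ else rr$`Pr(>F)`)
    }
  }
  list(rows = out,
       residuals = if (length(resid)) do.call(rbind, resid) else NULL)
}

#' Mixed ANOVA for the phase-bin detection rates
#'
#' Balanced mixed-design ANOVA with stimulation `condition` and phase `bin`
#' as within-subject factors, counterbalancing `order` as a between-subject
#' factor, and participants as the random blocking variable. Two error
#' models are provided:
#'
#' * `"stratified"` (conventional split-plot): each within effect is tested
#'   against its own participant-interaction error stratum, e.g. the
#'   condition x order interaction on df (1, n - 2).
#' * `"pooled"`: participants enter as an additive blocking factor and all
#'   remaining variation forms a single residual, so every effect shares
#'   one denominator — df `N - 1 - (n-1) - (k_c k_b - 1) - (k_c - 1) -
#'   (k_b - 1) - (k_c - 1)(k_b - 1)`, which is 646 for the 36-participant,
#'   2-condition, 10-bin, 2-order design. This reproduces the df structure
#'   of analyses that pool the within-subject error strata.
#'
#' Sum-of-squares are the standard balanced-design decompositions (via
#' [stats::aov()]). For within effects with more than 2 levels the table
#' carries Mauchly's W (covariance pooled within order groups), its
#' chi-square p, the Greenhouse-Geisser epsilon, and epsilon-corrected dfs
#' and p.
#'
#' @param data long `data.frame` with columns for participant, order,
#'   condition, bin, and the response value (one row per cell).
#' @param error_mode `"stratified"` or `"pooled"`.
#' @param dv,participant,order,condition,bin column names.
#' @return An `anova_table`: one row per effect with `ss`, `df_num`,
#'   `df_den`, `F`, `p`, `mauchly_w`, `mauchly_p`, `gg_epsilon`,
#'   `df_num_gg`, `df_den_gg`, `p_gg`.
#' @export
mixed_anova <- function(data, error_mode = c("stratified", "pooled"),
                        dv = "value", participant = "participant_id",
                        order = "order", condition = "condition",
                        bin = "bin") {
  error_mode <- match.arg(error_mode)
  d <- data.frame(value = data[[dv]],
                  participant = factor(data[[participant]]),
                  order = factor(data[[order]]),
                  condition = factor(data[[condition]]),
                  bin = factor(data[[bin]]))
  if (any(is.na(d$value))) abort_invalid("`value` contains missing cells")
  check_balanced(d, "participant", c("condition", "bin"))

  if (error_mode == "stratified") {
    fit <- aov(value ~ order * condition * bin +
                 Error(participant / (condition * bin)), data = d)
    hv <- harvest_aov(summary(fit))
    rows <- hv$rows
    residuals <- hv$residuals
  } else {
    fit <- aov(value ~ participant + condition * bin + condition:order +
                 bin:order + condition:bin:order, data = d)
    hv <- harvest_aov(summary(fit))
    # participant is the blocking factor, not a reported effect
    blk <- Filter(function(r) r$effect == "participant", hv$rows)
    rows <- Filter(function(r) r$effect != "participant", hv$rows)
    residuals <- hv$residuals
    if (length(blk))
      residuals <- rbind(residuals,
                         data.frame(stratum = "participant_block",
                                    df = blk[[1]]$df_num, ss = blk[[1]]$ss))
  }

  kc <- nlevels(d$condition); kb <- nlevels(d$bin)
  groups <- with(unique(d[c("participant", "order")]),
                 setNames(as.character(order), as.character(participant)))
  sph <- list()
  for (eff in list(c("condition"), c("bin"), c("condition", "bin"))) {
    klev <- prod(vapply(eff, function(f) nlevels(d[[f]]), integer(1)))
    nm <- paste(eff, collapse = ":")
    if (klev > 2) {
      sc <- within_scores(d, "participant", c("condition", "bin"), eff, "value")
      subj <- sort(unique(as.character(d$participant)))
      sph[[nm]] <- sphericity_stats(sc, groups[subj])
    } else sph[[nm]] <- list(w = 1, p = NA_real_, epsilon = 1)
  }

  tab <- do.call(rbind, lapply(rows, function(r) {
    base <- sub(":order$", "", sub("^order:", "", r$effect))
    s <- sph[[base]]
    if (is.null(s)) anova_row(r$effect, r$ss, r$df_num, r$df_den, r$F, r$p)
    else anova_row(r$effect, r$ss, r$df_num, r$df_den, r$F, r$p,
                   s$w, s$p, s$epsilon)
  }))
  attr(tab, "error_mode") <- error_mode
  attr(tab, "residuals") <- residuals
  attr(tab, "total_ss") <- sum((d$value - mean(d$value))^2)
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Repeated-measures ANOVA with sphericity correction
#'
#' Within-subject ANOVA for one or two within factors on a balanced
#' complete design: each effect is tested against its participant x effect
#' error stratum ([stats::aov()] with an `Error(participant/...)`
#' specification). For every within effect with more than 2 levels the
#' table reports Mauchly's W with its chi-square p, the Greenhouse-Geisser
#' epsilon from the eigenvalues of the orthonormal-contrast covariance, and
#' the epsilon-corrected dfs (`eps * df`) and p. Two-level effects have
#' `W = 1`, `eps = 1` (sphericity trivially holds).
#'
#' @param data long `data.frame`, one row per participant x within-cell.
#' @param within character vector of 1 or 2 within-factor column names
#'   (e.g. `"time_bin"`, or `c("condition", "time_bin")`).
#' @param dv,participant column names of the response and participant id.
#' @return An `anova_table` (see [mixed_anova()]).
#' @export
#' @examples
#' d <- expand.grid(participant_id = factor(1:6), b = factor(1:4))
#' d$value <- rnorm(nrow(d))
#' rm_anova(d, within = "b")
rm_anova <- function(data, within, dv = "value",
                     participant = "participant_id") {
  if (length(within) < 1 || length(within) > 2)
    abort_invalid("`within` must name 1 or 2 within-subject factors")
  d <- data.frame(value = data[[dv]],
                  participant = factor(data[[participant]]))
  for (f in within) {
    v <- factor(data[[f]])
    if (nlevels(v) < 2)
      abort_invalid(sprintf("factor `%s` has fewer than 2 levels", f))
    d[[f]] <- v
  }
  if (any(is.na(d$value))) abort_invalid("`value` contains missing cells")
  check_balanced(d, "participant", within)

  rhs <- paste(within, collapse = " * ")
  form <- as.formula(sprintf(
    "value ~ %s + Error(participant / (%s))", rhs, rhs))
  hv <- harvest_aov(summary(aov(form, data = d)))
  rows <- hv$rows

  effects <- if (length(within) == 1) list(within) else
    list(within[1], within[2], within)
  sph <- list()
  for (eff in effects) {
    klev <- prod(vapply(eff, function(f) nlevels(d[[f]]), integer(1)))
    nm <- paste(eff, collapse = ":")
    sph[[nm]] <- if (klev > 2) {
      sphericity_stats(within_scores(d, "participant", within, eff, "value"))
    } else list(w = 1, p = NA_real_, epsilon = 1)
  }

  tab <- do.call(rbind, lapply(rows, function(r) {
    s <- sph[[r$effect]]
    if (is.null(s)) anova_row(r$effect, r$ss, r$df_num, r$df_den, r$F, r$p)
    else anova_row(r$effect, r$ss, r$df_num, r$df_den, r$F, r$p,
                   s$w, s$p, s$epsilon)
  }))
  attr(tab, "error_mode") <- "stratified"
  attr(tab, "residuals") <- hv$residuals
  attr(tab, "total_ss") <- sum((d$value - mean(d$value))^2)
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' @export
print.anova_table <- function(x, ...) {
  cat("ANOVA (", attr(x, "error_mode"), " error model)\n", sep = "")
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 5); df$F <- signif(df$F, 4)
  df$p <- signif(df$p, 3)
  keep <- c("effect", "ss", "df_num", "df_den", "F", "p")
  extra <- !is.na(df$gg_epsilon) & df$gg_epsilon < 1
  if (any(extra))
    keep <- c(keep, "mauchly_w", "gg_epsilon", "df_num_gg", "df_den_gg", "p_gg")
  for (cc in intersect(keep, c("mauchly_w", "gg_epsilon", "df_num_gg",
                               "df_den_gg", "p_gg")))
    df[[cc]] <- signif(df[[cc]], 3)
  print(df[keep], row.names = FALSE)
  invisible(x)
}

#' Holm-adjusted pairwise post-hoc comparisons of time bins
#'
#' Pairwise paired t-tests between levels of a within factor (e.g. the 12
#' consecutive-trial time bins), Holm-adjusted over the family.
#'
#' @param data long `data.frame`.
#' @param within column name of the within factor.
#' @param dv,participant column names.
#' @param levels_subset optionally restrict to these levels.
#' @return `data.frame` with `level_a`, `level_b`, `mean_a`, `mean_b`, `t`,
#'   `df`, `p`, `p_holm`, sorted by adjusted p.
#' @export
posthoc_pairwise <- function(data, within, dv = "value",
                             participant = "participant_id",
                             levels_subset = NULL) {
  f <- factor(data[[within]])
  lv <- levels(f)
  if (!is.null(levels_subset)) lv <- intersect(lv, as.character(levels_subset))
  # average within participant x level across any other factors
  m <- aggregate(data[[dv]], list(participant = data[[participant]],
                                  level = f), mean)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- m$x[m$level == pr[1]][order(m$participant[m$level == pr[1]])]
    b <- m$x[m$level == pr[2]][order(m$participant[m$level == pr[2]])]
    tt <- tryCatch(paired_t(a, b),
                   error = function(e) list(t = NA, df = NA, p = NA))
    data.frame(level_a = pr[1], level_b = pr[2],
               mean_a = mean(a), mean_b = mean(b),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p)
  out[order(out$p_holm), ]
}
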