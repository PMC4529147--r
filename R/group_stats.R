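#' Filter trials by response time
#'
#' Removes anticipations and time-outs: trials with RT outside
#' `[lo_ms, hi_ms]` (200-2000 ms by default) are excluded and the excluded
#' fraction reported.
#'
#' @param trials Trial data frame with columns `rt_ms` and (optionally)
#'   `participant_id`.
#' @param lo_ms,hi_ms Inclusive RT bounds in milliseconds.
#' @return List with `kept` (filtered table) and `excluded_fraction`.
#' @export
filter_rts <- function(trials, lo_ms = 200, hi_ms = 2000) {
  stopifnot(is.data.frame(trials), "rt_ms" %in% names(trials))
  if (any(!is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0))
    stop_domain("`rt_ms` must be positive and finite")
  keep <- trials$rt_ms >= lo_ms & trials$rt_ms <= hi_ms
  kept <- trials[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop_domain("RT filter removed every trial")
  if ("participant_id" %in% names(trials)) {
    lost <- setdiff(unique(trials$participant_id),
                    unique(kept$participant_id))
    if (length(lost))
      stop_domain("RT filter removed all trials of participant(s): %s",
                  paste(lost, collapse = ", "))
  }
  list(kept = kept, excluded_fraction = 1 - nrow(kept) / nrow(trials))
}

check_groups <- function(values, groups, min_per_group = 2L) {
  stopifnot(length(values) == length(groups))
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2L)
    stop_domain("need at least 2 groups")
  sizes <- table(g)
  if (any(sizes < min_per_group))
    stop_domain("group(s) %s have fewer than %d members (degrees of freedom undefined)",
                paste(names(sizes)[sizes < min_per_group], collapse = ", "),
                min_per_group)
  g
}

#' One-way ANOVA with eta-squared effect size
#'
#' Classical fixed-effects one-way analysis of variance from first
#' principles (explicit sums of squares), with
#' `eta2 = SS_between / SS_total`. When the within-group sum of squares is
#' exactly zero (degenerate perfect separation) `F = Inf`, `p = 0` and
#' `eta2 = 1`.
#'
#' @param values Numeric response, one per participant.
#' @param groups Group labels, at least 2 groups with 2 members each.
#' @return List: `F`, `df_between`, `df_within`, `p`, `eta2`, plus the
#'   sums of squares `ss_between`, `ss_within`.
#' @export
oneway_anova_eta2 <- function(values, groups) {
  g <- check_groups(values, groups)
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tabulate(g)
  ss_b <- sum(ns * (means - grand)^2)
  ss_w <- sum((values - means[g])^2)
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  if (ss_w == 0) {
    F <- Inf; p <- 0
  } else {
    F <- (ss_b / df_b) / (ss_w / df_w)
    p <- stats::pf(F, df_b, df_w, lower.tail = FALSE)
  }
  list(F = F, df_between = df_b, df_within = df_w, p = p,
       eta2 = if (ss_b + ss_w == 0) 0 else ss_b / (ss_b + ss_w),
       ss_between = ss_b, ss_within = ss_w)
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All pairwise two-sample t-tests (pooled variance by default, Welch by
#' flag), with p-values multiplied by the number of pairs and capped at 1.
#' When the labels are (a subset of) low/medium/high, pairs are ordered
#' low < medium < high and `mean_diff` is first-listed minus second-listed.
#'
#' @inheritParams oneway_anova_eta2
#' @param var_equal Pooled-variance t-tests (default); `FALSE` for Welch.
#' @return Data frame: `group1`, `group2`, `mean_diff`, `se`, `t`, `df`,
#'   `p`, `p_adjusted`.
#' @export
bonferroni_pairwise <- function(values, groups, var_equal = TRUE) {
  g <- check_groups(values, groups)
  canon <- c("low", "medium", "high")
  levs <- levels(g)
  if (all(levs %in% canon)) levs <- canon[canon %in% levs]
  pairs <- utils::combn(levs, 2)
  n_pairs <- ncol(pairs)
  rows <- lapply(seq_len(n_pairs), function(i) {
    a <- values[g == pairs[1, i]]
    b <- values[g == pairs[2, i]]
    n1 <- length(a); n2 <- length(b)
    md <- mean(a) - mean(b)
    if (var_equal) {
      sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
        (n1 + n2 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      v1 <- stats::var(a) / n1; v2 <- stats::var(b) / n2
      se <- sqrt(v1 + v2)
      df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    }
    if (se == 0) {
      tt <- if (md == 0) 0 else sign(md) * Inf
    } else tt <- md / se
    p <- 2 * stats::pt(-abs(tt), df)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               mean_diff = md, se = se, t = tt, df = df, p = p,
               p_adjusted = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regress metacognitive sensitivity on cortisol reactivity
#'
#' Ordinary least squares of per-participant type-2 AUC on cortisol
#' concentration at C2. Reports the squared correlation `r2`, the
#' standardised slope `beta_std = slope * sd(C2) / sd(AUC)` (equal to the
#' Pearson correlation in simple regression, hence in \[-1, 1\]), its
#' t-statistic on `n - 2` degrees of freedom, and the two-sided p-value.
#'
#' @param auc Numeric vector of per-participant AUC values.
#' @param c2 Numeric vector of C2 cortisol concentrations (nmol/l).
#' @return List: `r2`, `beta_std`, `t`, `df`, `p`, `slope`, `intercept`,
#'   `n`.
#' @export
regress_auc_on_cortisol <- function(auc, c2) {
  stopifnot(length(auc) == length(c2))
  n <- length(auc)
  if (n < 4L) stop_domain("need at least 4 participants (got %d)", n)
  if (stats::sd(c2) == 0 || stats::sd(auc) == 0)
    stop_domain("zero variance in C2 or AUC; regression undefined")
  slope <- stats::cov(c2, auc) / stats::var(c2)
  intercept <- mean(auc) - slope * mean(c2)
  r <- stats::cor(c2, auc)
  r2 <- r^2
  df <- n - 2L
  if (1 - r2 < .Machine$double.eps) {
    tt <- sign(r) * Inf; p <- 0
  } else {
    tt <- r * sqrt(df / (1 - r2))
    p <- 2 * stats::pt(-abs(tt), df)
  }
  list(r2 = r2, beta_std = r, t = tt, df = df, p = p,
       slope = slope, intercept = intercept, n = n)
}

#' Mixed (split-plot) ANOVA for pre/post designs
#'
#' Two-way mixed analysis of variance with one two-level within-subject
#' factor (time: pre vs post) and one between-subject factor (group).
#' Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`, matching the convention of
#' repeated-measures reporting. With only two within-subject levels
#' sphericity holds trivially, so no Greenhouse-Geisser correction is
#' needed.
#'
#' Degenerate cases follow fixed conventions: a zero time sum of squares
#' gives `F_time = 0`; a zero interaction sum of squares gives
#' `F_interaction = 0`; a zero within-subject error with a non-zero effect
#' gives `F = Inf`, `p = 0`.
#'
#' @param pre,post Numeric vectors, one paired observation per participant.
#' @param groups Between-subject labels, at least 2 per group.
#' @return List: `F_time`, `df_time`, `df_error_within`, `p_time`,
#'   `eta2p_time`, `F_interaction`, `df_interaction`, `p_interaction`,
#'   `eta2p_interaction`, `F_group`, `p_group`, `eta2p_group`.
#' @export
rm_anova_prepost <- function(pre, post, groups) {
  if (length(pre) != length(post) || length(pre) != length(groups))
    stop_domain("`pre`, `post` and `groups` must pair up one row per participant")
  if (any(!is.finite(pre)) || any(!is.finite(post)))
    stop_domain("`pre`/`post` contain missing values; pairing incomplete")
  g <- check_groups(pre, groups)
  n <- length(pre); G <- nlevels(g); T <- 2L
  y <- c(pre, post)
  time <- rep(1:2, each = n)
  subj_mean <- (pre + post) / 2
  grand <- mean(y)
  grp_mean <- tapply(subj_mean, g, mean)           # per-group mean over time
  time_mean <- tapply(y, time, mean)
  cell_mean <- tapply(y, list(rep(g, 2), time), mean)
  ns <- tabulate(g)

  ss_total <- sum((y - grand)^2)
  ss_subj_total <- T * sum((subj_mean - grand)^2)
  ss_group <- T * sum(ns * (grp_mean - grand)^2)
  ss_subj_err <- ss_subj_total - ss_group
  ss_time <- n * sum((time_mean - grand)^2)
  ss_int <- sum(ns * (cell_mean - outer(grp_mean, rep(1, T)) -
                        outer(rep(1, G), time_mean) + grand)^2)
  ss_err_w <- ss_total - ss_subj_total - ss_time - ss_int
  ss_err_w <- max(ss_err_w, 0)                     # guard rounding

  df_time <- T - 1L
  df_int <- (G - 1L) * (T - 1L)
  df_err_w <- (n - G) * (T - 1L)
  df_group <- G - 1L
  df_err_b <- n - G

  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_eff <= .Machine$double.eps * max(1, ss_total))
      return(list(F = 0, p = 1))
    if (ss_err <= .Machine$double.eps * max(1, ss_total))
      return(list(F = Inf, p = 0))
    F <- (ss_eff / df_eff) / (ss_err / df_err)
    list(F = F, p = stats::pf(F, df_eff, df_err, lower.tail = FALSE))
  }
  eta2p <- function(ss_eff, ss_err)
    if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)

  ft <- f_of(ss_time, df_time, ss_err_w, df_err_w)
  fi <- f_of(ss_int, df_int, ss_err_w, df_err_w)
  fg <- f_of(ss_group, df_group, ss_subj_err, df_err_b)
  list(F_time = ft$F, df_time = df_time, df_error_within = df_err_w,
       p_time = ft$p, eta2p_time = eta2p(ss_time, ss_err_w),
       F_interaction = fi$F, df_interaction = df_int,
       p_interaction = fi$p, eta2p_interaction = eta2p(ss_int, ss_err_w),
       F_group = fg$F, df_group = df_group, df_error_between = df_err_b,
       p_group = fg$p, eta2p_group = eta2p(ss_group, ss_subj_err))
}
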