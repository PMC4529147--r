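#' Windowed standard deviation of a heart-rate trace
#'
#' Heart-rate variability is summarised as the sample standard deviation
#' (denominator n - 1) of heart rate inside consecutive non-overlapping
#' windows (1 minute by default). A trailing partial window is discarded.
#'
#' @param trace Data frame with uniformly sampled columns `time_s`
#'   (seconds) and `bpm` (beats/min); one participant.
#' @param window_s Window length in seconds (default 60).
#' @return Data frame (class `hrv_series`): `window` (1-based index),
#'   `start_s`, `sd_bpm`.
#' @export
windowed_sd <- function(trace, window_s = 60L) {
  stopifnot(is.data.frame(trace), all(c("time_s", "bpm") %in% names(trace)))
  window_s <- check_count(window_s, "window_s", lower = 1L)
  n <- nrow(trace)
  if (n < 2L) stop_domain("heart-rate trace too short")
  dt <- diff(trace$time_s)
  if (any(abs(dt - dt[1]) > 1e-8 * max(1, dt[1])))
    stop_domain("heart-rate trace must be uniformly sampled")
  if (any(trace$bpm <= 0)) stop_domain("bpm must be positive throughout")
  per_window <- round(window_s / dt[1])
  if (per_window < 2L)
    stop_domain("fewer than 2 samples per %d s window at this sampling rate",
                window_s)
  n_win <- n %/% per_window
  if (n_win < 1L)
    stop_domain("trace shorter than one %d s window", window_s)
  idx <- rep(seq_len(n_win), each = per_window)
  kept <- seq_len(n_win * per_window)
  sds <- as.numeric(tapply(trace$bpm[kept], idx, stats::sd))
  out <- data.frame(window = seq_len(n_win),
                    start_s = trace$time_s[1] + (seq_len(n_win) - 1L) * window_s,
                    sd_bpm = sds)
  class(out) <- c("hrv_series", "data.frame")
  out
}

#' Smooth a windowed-SD series with locally weighted regression
#'
#' Applies locally weighted linear regression (LOESS, degree 1, tricube
#' weights) over window time, evaluated at every window, so the output has
#' the same length as the input. Local-linear smoothing reproduces exactly
#' linear series and shrinks isolated spikes.
#'
#' @param series An `hrv_series` from [windowed_sd()] (or any data frame
#'   with `start_s` and `sd_bpm`).
#' @param span LOESS span in (0, 1]: fraction of windows in each local
#'   neighbourhood. Default 0.3. The neighbourhood must cover at least 3
#'   points.
#' @return The series with `sd_bpm` replaced by its smoothed values.
#' @export
smooth_series <- function(series, span = 0.3) {
  stopifnot(is.data.frame(series),
            all(c("start_s", "sd_bpm") %in% names(series)))
  check_number(span, "span", lower = 0, upper = 1, strict_lower = TRUE)
  n <- nrow(series)
  if (n < 5L) stop_domain("need at least 5 windows to smooth (got %d)", n)
  if (floor(span * n) < 3L)
    stop_domain("span %.2f covers fewer than 3 of %d windows", span, n)
  fit <- stats::loess(sd_bpm ~ start_s, data = series, span = span,
                      degree = 1, family = "gaussian",
                      surface = "direct")
  out <- series
  out$sd_bpm <- as.numeric(stats::predict(fit, newdata = series))
  out
}

#' Windowed-SD matrix for a multi-participant heart-rate table
#'
#' Convenience wrapper applying [windowed_sd()] (and optionally
#' [smooth_series()]) to each participant of a long heart-rate table, and
#' aligning the results on a common window grid.
#'
#' @param heart_rate Long data frame: `participant_id`, `time_s`, `bpm`.
#' @param window_s Window length, seconds.
#' @param span LOESS span passed to [smooth_series()], or `NULL` to skip
#'   smoothing.
#' @return Numeric matrix, windows x participants, with participant ids as
#'   (sorted) column names.
#' @export
hrv_matrix <- function(heart_rate, window_s = 60L, span = 0.3) {
  stopifnot(all(c("participant_id", "time_s", "bpm") %in% names(heart_rate)))
  ids <- sort(unique(heart_rate$participant_id))
  cols <- lapply(ids, function(id) {
    s <- windowed_sd(heart_rate[heart_rate$participant_id == id, ], window_s)
    if (!is.null(span)) s <- smooth_series(s, span = span)
    s$sd_bpm
  })
  n_win <- unique(vapply(cols, length, integer(1)))
  if (length(n_win) != 1L)
    stop_domain("participants have unequal window counts; trim traces to a common grid")
  matrix(unlist(cols), nrow = n_win, dimnames = list(NULL, ids))
}

#' Two-group bootstrap cluster test on windowed heart-rate variability
#'
#' For each one-minute window, the group-mean windowed SD is bootstrapped
#' by resampling participants with replacement within each group
#' (`n_boot` replicates). Per-group 95% bands are the 2.5/97.5 percentiles
#' of the bootstrap group means; the per-window two-sided p-value is twice
#' the smaller tail fraction of the bootstrap group-mean *difference*
#' falling on the opposite side of 0, floored at `1/n_boot` and capped at
#' 1. Clusters are maximal runs of consecutive windows with `p < alpha`.
#'
#' Participants are resampled (rather than windows) to respect
#' within-participant autocorrelation; columns are sorted by name before
#' resampling so the result is invariant to participant ordering.
#'
#' @param group1,group2 Numeric matrices (windows x participants) on a
#'   common window grid, e.g. from [hrv_matrix()]; at least 2 participants
#'   each.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param alpha Cluster-entry significance level (default 0.05).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return An object of class `hrv_cluster_test`: list with `per_window`
#'   (data frame: `window`, group means, per-group and difference band
#'   bounds, `p`) and `clusters` (data frame `start_window`, `end_window`),
#'   plus `alpha` and `n_boot`.
#' @export
group_cluster_test <- function(group1, group2, n_boot = 5000L, alpha = 0.05,
                               seed = NULL) {
  group1 <- as.matrix(group1); group2 <- as.matrix(group2)
  if (nrow(group1) != nrow(group2))
    stop_domain("window grids differ between groups (%d vs %d windows)",
                nrow(group1), nrow(group2))
  if (ncol(group1) < 2L || ncol(group2) < 2L)
    stop_domain("each group needs at least 2 participants")
  n_boot <- check_count(n_boot, "n_boot", lower = 1L)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (!is.null(colnames(group1))) group1 <- group1[, order(colnames(group1)), drop = FALSE]
  if (!is.null(colnames(group2))) group2 <- group2[, order(colnames(group2)), drop = FALSE]
  with_seed(seed, {
    boot_group_means <- function(mat) {
      n <- ncol(mat)
      # resampling with replacement == multinomial weights over participants
      w <- stats::rmultinom(n_boot, n, rep(1 / n, n)) / n      # n x n_boot
      mat %*% w                                                # W x n_boot
    }
    b1 <- boot_group_means(group1)
    b2 <- boot_group_means(group2)
    diff_b <- b1 - b2
    qs <- function(m) apply(m, 1, stats::quantile,
                            probs = c(0.025, 0.975), names = FALSE)
    q1 <- qs(b1); q2 <- qs(b2); qd <- qs(diff_b)
    pr_le <- rowMeans(diff_b <= 0)
    pr_ge <- rowMeans(diff_b >= 0)
    p <- pmax(pmin(1, 2 * pmin(pr_le, pr_ge)), 1 / n_boot)
    sig <- p < alpha
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    clusters <- data.frame(start_window = starts[runs$values],
                           end_window = ends[runs$values])
    per_window <- data.frame(
      window = seq_len(nrow(group1)),
      mean_group1 = rowMeans(group1),
      mean_group2 = rowMeans(group2),
      band1_low = q1[1, ], band1_high = q1[2, ],
      band2_low = q2[1, ], band2_high = q2[2, ],
      diff_low = qd[1, ], diff_high = qd[2, ],
      p = p)
    structure(list(per_window = per_window, clusters = clusters,
                   alpha = alpha, n_boot = n_boot),
              class = "hrv_cluster_test")
  })
}

#' @export
print.hrv_cluster_test <- function(x, ...) {
  cat(sprintf("HRV bootstrap cluster test (%d replicates, alpha = %.2f)\n",
              x$n_boot, x$alpha))
  if (nrow(x$clusters) == 0L) {
    cat("  no significant clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster %d: windows %d-%d\n", i,
                  x$clusters$start_window[i], x$clusters$end_window[i]))
  }
  invisible(x)
}
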