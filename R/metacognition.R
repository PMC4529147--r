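#' Bin confidence ratings on the half-range scale
#'
#' Assigns each confidence rating in \[0.5, 1\] to one of `k` ordered bins,
#' with bin `k` the most confident.
#'
#' `equal_width` partitions \[0.5, 1\] into `k` half-open intervals
#' `[e_i, e_{i+1})`, the last closed at 1 so that confidence 1.0 is
#' scorable. `equal_count` places the inner edges at the `i/k` empirical
#' quantiles (linear interpolation) and assigns values equal to an edge to
#' the lower bin.
#'
#' @param confidence Numeric vector of ratings in \[0.5, 1\].
#' @param k Number of bins, at least 2. Default 5.
#' @param mode `"equal_width"` (default) or `"equal_count"`.
#' @return Integer vector of bin labels in `1..k`, with the edges attached
#'   as attribute `"edges"`.
#' @export
bin_confidence <- function(confidence, k = 5L,
                           mode = c("equal_width", "equal_count")) {
  mode <- match.arg(mode)
  k <- check_count(k, "k", lower = 2L)
  if (length(confidence) < 1L)
    stop_domain("`confidence` must contain at least one rating")
  if (any(!is.finite(confidence)) ||
      any(confidence < 0.5) || any(confidence > 1))
    stop_domain("confidence ratings must lie in [0.5, 1]")
  if (mode == "equal_width") {
    edges <- seq(0.5, 1, length.out = k + 1L)
    bins <- findInterval(confidence, edges, rightmost.closed = TRUE)
  } else {
    inner <- stats::quantile(confidence, probs = seq_len(k - 1L) / k,
                             type = 7, names = FALSE)
    # left-open intervals: a value equal to an edge drops to the lower bin
    bins <- 1L + findInterval(confidence, inner, left.open = TRUE)
    edges <- c(0.5, inner, 1)
  }
  structure(as.integer(bins), edges = edges)
}

#' Type-2 ROC curve and AUC (metacognitive sensitivity)
#'
#' Builds the empirical type-2 receiver operating characteristic: sweeping
#' a criterion from the most to the least confident bin, the hit rate is
#' the cumulative fraction of *correct* trials at or above the criterion
#' and the false-alarm rate the cumulative fraction of *incorrect* trials.
#' The curve is anchored at (0,0) and (1,1) and its area computed by the
#' trapezoidal rule. An AUC of 0.5 means confidence carries no information
#' about accuracy; 1 means confidence perfectly separates correct from
#' incorrect decisions.
#'
#' Participants with zero incorrect (or zero correct) trials have no
#' defined type-2 ROC; an explicit error is raised rather than returning a
#' degenerate value, because silent defaults would bias group comparisons.
#'
#' @param correct Logical vector: first-order accuracy per trial.
#' @param confidence Numeric vector of ratings in \[0.5, 1\].
#' @param k,mode Binning, as in [bin_confidence()].
#' @param participant_id Identifier used in error messages.
#' @return An object of class `type2_roc`: list with `points` (data frame
#'   `false_alarm_rate`, `hit_rate`, anchored), `auc`, `n_correct`,
#'   `n_incorrect`, `bin_edges`, `k`, `mode`.
#' @examples
#' set.seed(1)
#' conf <- runif(400, 0.5, 1)
#' corr <- runif(400) < conf          # confidence is diagnostic
#' type2_roc(corr, conf)$auc
#' @export
type2_roc <- function(correct, confidence, k = 5L,
                      mode = c("equal_width", "equal_count"),
                      participant_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.logical(correct), length(correct) == length(confidence))
  who <- if (is.null(participant_id)) "" else sprintf(" for participant '%s'",
                                                      participant_id)
  n_correct <- sum(correct)
  n_incorrect <- sum(!correct)
  if (n_correct == 0L || n_incorrect == 0L)
    stop_domain("type-2 AUC undefined%s: needs at least one correct and one incorrect trial",
                who)
  bins <- bin_confidence(confidence, k = k, mode = mode)
  tab_c <- tabulate(bins[correct], nbins = k)
  tab_i <- tabulate(bins[!correct], nbins = k)
  # hit[j], fa[j]: fraction of trials in bin >= j (criterion at bin j)
  hit <- rev(cumsum(rev(tab_c))) / n_correct
  fa <- rev(cumsum(rev(tab_i))) / n_incorrect
  pts <- data.frame(false_alarm_rate = c(0, fa[k:1]),
                    hit_rate = c(0, hit[k:1]))
  auc <- trapezoid_auc(pts$false_alarm_rate, pts$hit_rate)
  structure(
    list(points = pts, auc = auc,
         n_correct = n_correct, n_incorrect = n_incorrect,
         bin_edges = attr(bins, "edges"), k = k, mode = mode),
    class = "type2_roc")
}

trapezoid_auc <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.type2_roc <- function(x, ...) {
  cat(sprintf("Type-2 ROC (%d bins, %s): AUC = %.3f  [%d correct / %d incorrect trials]\n",
              x$k, x$mode, x$auc, x$n_correct, x$n_incorrect))
  invisible(x)
}

#' Confidence calibration metrics
#'
#' Calibration compares the average confidence report with long-run
#' accuracy; a gap near zero means the observer is well calibrated, a
#' positive gap overconfidence.
#'
#' @inheritParams type2_roc
#' @return List with `mean_confidence`, `accuracy`, and
#'   `calibration_gap = mean_confidence - accuracy` (in \[-0.5, 0.5\]).
#' @export
calibration_metrics <- function(correct, confidence) {
  stopifnot(is.logical(correct), length(correct) == length(confidence),
            length(correct) >= 1L)
  mc <- mean(confidence)
  acc <- mean(correct)
  list(mean_confidence = mc, accuracy = acc, calibration_gap = mc - acc)
}

#' Permutation null distribution of the type-2 AUC
#'
#' Shuffles confidence ratings against correctness `n_perm` times and
#' recomputes the AUC, giving the null distribution under independence of
#' confidence and accuracy (mean 0.5 as permutations grow).
#'
#' @inheritParams type2_roc
#' @param n_perm Number of permutations (0 returns an empty vector).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return Numeric vector of `n_perm` null AUC values.
#' @export
permutation_null_auc <- function(correct, confidence, n_perm, k = 5L,
                                 mode = c("equal_width", "equal_count"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  n_perm <- check_count(n_perm, "n_perm", lower = 0L)
  if (n_perm == 0L) return(numeric(0))
  with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      type2_roc(correct, sample(confidence), k = k, mode = mode)$auc
    }, numeric(1))
  })
}

#' Per-participant metacognition scores for a trial table
#'
#' Applies [calibration_metrics()] and [type2_roc()] to each participant in
#' a long trial table (columns `participant_id`, `correct`, `confidence`,
#' `rt_ms`).
#'
#' @param trials Trial data frame as produced by [simulate_cohort()].
#' @param k,mode Binning, as in [bin_confidence()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `n_trials`, `accuracy`, `mean_confidence`, `calibration_gap`,
#'   `mean_rt_ms`, `auc`, `k`, `bin_mode`.
#' @export
score_participants <- function(trials, k = 5L,
                               mode = c("equal_width", "equal_count")) {
  mode <- match.arg(mode)
  stopifnot(all(c("participant_id", "correct", "confidence") %in% names(trials)))
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    cm <- calibration_metrics(tr$correct, tr$confidence)
    roc <- type2_roc(tr$correct, tr$confidence, k = k, mode = mode,
                     participant_id = id)
    data.frame(participant_id = id,
               n_trials = nrow(tr),
               accuracy = cm$accuracy,
               mean_confidence = cm$mean_confidence,
               calibration_gap = cm$calibration_gap,
               mean_rt_ms = if ("rt_ms" %in% names(tr)) mean(tr$rt_ms) else NA_real_,
               auc = roc$auc,
               k = k, bin_mode = mode,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
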