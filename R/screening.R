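#' Classify participants into stress-reactivity groups from cortisol panels
#'
#' Cortisol concentration at the post-stress peak sample (C2, 10 minutes
#' after stress induction) indexes each participant's reactivity to the
#' stressor. Participants strictly above the `high_pct` empirical
#' percentile of the cohort's C2 distribution are labelled `high`, those
#' strictly below the `low_pct` percentile `low`, those inside the
#' `mid_band` percentile band (inclusive) `medium`, and everyone else
#' `unassigned`. Percentiles use empirical quantiles with linear
#' interpolation (R type 7), so labels are invariant under any strictly
#' increasing rescaling of the assay.
#'
#' The responder flag applies the conventional salivary-cortisol criterion:
#' an increase of at least `responder_threshold` nmol/l over baseline
#' (C2 - C0 >= 1.1 by default, inclusive).
#'
#' @param cortisol Data frame with one row per participant containing
#'   `participant_id` and the sample columns named in `baseline_col` and
#'   `c2_col` (nmol/l).
#' @param high_pct,low_pct Percentile cut-offs for the high and low groups.
#' @param mid_band Length-2 percentile band (inclusive) for the medium
#'   group, default `c(40, 60)` — an operationalisation of "around the
#'   median".
#' @param responder_threshold Minimum C2 - C0 increase (nmol/l) to count as
#'   a cortisol responder.
#' @param baseline_col,c2_col Names of the baseline and peak sample columns.
#' @return Data frame with `participant_id`, `c2_nmol_l`,
#'   `cortisol_increase`, `group` (factor low/medium/high/unassigned), and
#'   `responder`.
#' @examples
#' panel <- data.frame(participant_id = paste0("p", 1:8),
#'                     C0 = rep(4, 8), C2 = c(3, 4, 5, 6, 7, 8, 9, 12))
#' assign_reactivity_groups(panel)
#' @export
assign_reactivity_groups <- function(cortisol, high_pct = 75, low_pct = 25,
                                     mid_band = c(40, 60),
                                     responder_threshold = 1.1,
                                     baseline_col = "C0", c2_col = "C2") {
  stopifnot(is.data.frame(cortisol))
  for (col in c("participant_id", baseline_col, c2_col))
    if (!col %in% names(cortisol))
      stop_domain("cortisol table lacks column '%s'", col)
  if (nrow(cortisol) < 4L)
    stop_domain("need at least 4 cortisol profiles for percentile-based grouping (got %d)",
                nrow(cortisol))
  check_number(low_pct, "low_pct", lower = 0, upper = 100)
  check_number(high_pct, "high_pct", lower = low_pct, upper = 100)
  if (length(mid_band) != 2L || mid_band[1] > mid_band[2])
    stop_domain("`mid_band` must be an increasing percentile pair")
  c2 <- cortisol[[c2_col]]
  c0 <- cortisol[[baseline_col]]
  if (any(c2 <= 0) || any(c0 <= 0))
    stop_domain("cortisol concentrations must be positive")
  group <- rep("unassigned", length(c2))
  if (stats::var(c2) == 0) {
    warning("all C2 concentrations identical; no participant can strictly exceed a percentile, all unassigned",
            call. = FALSE)
  } else {
    q <- stats::quantile(c2, probs = c(low_pct, high_pct, mid_band) / 100,
                         type = 7, names = FALSE)
    group[c2 > q[2]] <- "high"
    group[c2 < q[1]] <- "low"
    group[group == "unassigned" & c2 >= q[3] & c2 <= q[4]] <- "medium"
  }
  data.frame(participant_id = cortisol$participant_id,
             c2_nmol_l = c2,
             cortisol_increase = c2 - c0,
             group = factor(group,
                            levels = c("low", "medium", "high", "unassigned")),
             responder = responder_status(c0, c2,
                                          threshold = responder_threshold),
             stringsAsFactors = FALSE)
}

#' Cortisol responder criterion
#'
#' A participant is a cortisol responder when the stress-induced increase
#' over baseline reaches the criterion: `C2 - C0 >= threshold` (default
#' 1.1 nmol/l, inclusive).
#'
#' @param c0 Baseline cortisol concentration(s), nmol/l.
#' @param c2 Post-stress concentration(s), nmol/l.
#' @param threshold Minimum increase, nmol/l.
#' @return Logical vector.
#' @examples
#' responder_status(c0 = 8.56, c2 = 10.70)  # increase 2.14 -> TRUE
#' responder_status(c0 = 4.29, c2 = 4.50)   # increase 0.21 -> FALSE
#' @export
responder_status <- function(c0, c2, threshold = 1.1) {
  stopifnot(length(c0) == length(c2))
  # tolerance keeps increases computed as differences (e.g. 6.1 - 5.0)
  # from falling below an exactly-met criterion through rounding
  (c2 - c0) >= threshold - 1e-9
}
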