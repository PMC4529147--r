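#' Configuration of the 1-up 2-down interleaved staircase calibration
#'
#' The calibration stage adapts stimulus contrast with two interleaved
#' transformed (1-up 2-down) staircases: two consecutive correct responses
#' lower the contrast by one multiplicative step, every error raises it by
#' one step. The rule converges on the contrast where
#' `P(correct)^2 = 0.5`, i.e. 70.7% correct.
#'
#' @param start_levels Length-2 positive vector: starting contrast of the
#'   initially ascending staircase (below the expected threshold) and of the
#'   descending staircase (above it).
#' @param step_factor Multiplicative contrast step, `> 1`. Default 1.26
#'   (0.1 log10 units), fixed over trials.
#' @param n_trials_total Even total trial count shared by the two
#'   staircases under strict alternation (default 120, i.e. 60 each).
#' @param n_reversals_for_threshold Reversals averaged per staircase when
#'   estimating the threshold (default 6; the two staircases' reversals are
#'   pooled, giving 12 values).
#' @param min_level,max_level Contrast bounds; adaptive moves are clamped
#'   into `[min_level, max_level]`.
#'
#' @return An object of class `staircase_config`.
#' @seealso [run_calibration()], [staircase_update()]
#' @export
staircase_config <- function(start_levels = c(0.015, 0.09),
                             step_factor = 1.26,
                             n_trials_total = 120L,
                             n_reversals_for_threshold = 6L,
                             min_level = 0.001,
                             max_level = 0.5) {
  if (!is.numeric(start_levels) || length(start_levels) != 2L ||
      any(start_levels <= 0))
    stop_domain("`start_levels` must be two positive contrasts")
  if (start_levels[1] >= start_levels[2])
    stop_domain("`start_levels` must be (ascending start) < (descending start)")
  check_number(step_factor, "step_factor", lower = 1, strict_lower = TRUE)
  n_trials_total <- check_count(n_trials_total, "n_trials_total", lower = 2L)
  if (n_trials_total %% 2L != 0L)
    stop_domain("`n_trials_total` must be even (two interleaved staircases)")
  n_reversals_for_threshold <-
    check_count(n_reversals_for_threshold, "n_reversals_for_threshold", lower = 1L)
  check_number(min_level, "min_level", lower = 0, strict_lower = TRUE)
  check_number(max_level, "max_level", lower = min_level, strict_lower = TRUE)
  structure(
    list(start_levels = as.numeric(start_levels),
         step_factor = step_factor,
         n_trials_total = n_trials_total,
         n_reversals_for_threshold = n_reversals_for_threshold,
         min_level = min_level,
         max_level = max_level),
    class = "staircase_config")
}

#' Initial state of a single staircase
#'
#' @param start_level Starting contrast, inside the config bounds.
#' @param cfg A [staircase_config()].
#' @return An object of class `staircase_state` with fields
#'   `current_level`, `consecutive_correct`, `last_move`,
#'   `reversal_levels`, `trials_run`.
#' @export
staircase_state <- function(start_level, cfg) {
  stopifnot(inherits(cfg, "staircase_config"))
  check_number(start_level, "start_level",
               lower = cfg$min_level, upper = cfg$max_level)
  structure(
    list(current_level = start_level,
         consecutive_correct = 0L,
         last_move = "none",
         reversal_levels = numeric(0),
         trials_run = 0L),
    class = "staircase_state")
}

#' Advance a 1-up 2-down staircase by one trial
#'
#' Update rule: an incorrect response multiplies the level by
#' `step_factor` (up) and resets the correct counter; a correct response
#' with counter 0 only arms the counter; a correct response with counter 1
#' divides the level by `step_factor` (down) and resets. A move whose
#' direction differs from the previous move records the pre-move level as a
#' reversal. Moves are clamped to the config bounds; a fully clamped move
#' (level already at a bound) neither counts as a reversal nor updates the
#' move direction.
#'
#' @param state A [staircase_state()].
#' @param correct Logical: was the response correct?
#' @param cfg A [staircase_config()].
#' @return The updated `staircase_state`.
#' @export
staircase_update <- function(state, correct, cfg) {
  stopifnot(inherits(state, "staircase_state"),
            inherits(cfg, "staircase_config"),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  lvl <- state$current_level
  move <- "none"
  new <- lvl
  if (!correct) {
    new <- lvl * cfg$step_factor
    move <- "up"
    state$consecutive_correct <- 0L
  } else if (state$consecutive_correct == 0L) {
    state$consecutive_correct <- 1L
  } else {
    new <- lvl / cfg$step_factor
    move <- "down"
    state$consecutive_correct <- 0L
  }
  if (move != "none") {
    new <- clamp(new, cfg$min_level, cfg$max_level)
    if (new != lvl) {                      # fully clamped moves are no-ops
      if (state$last_move != "none" && move != state$last_move)
        state$reversal_levels <- c(state$reversal_levels, lvl)
      state$last_move <- move
      state$current_level <- new
    }
  }
  state$trials_run <- state$trials_run + 1L
  state
}

#' A logistic psychometric function observer for calibration
#'
#' Returns a response model in which the probability of a correct 2IFC
#' response is a logistic function of log contrast:
#' `P(c) = guess + (1 - guess - lapse) * plogis(slope * (log c - log threshold))`.
#' At `c = threshold` (lapse 0) performance is 75% correct; the 1-up 2-down
#' fixed point sits at 70.7%.
#'
#' @param threshold Contrast at the logistic midpoint-above-guess.
#' @param slope Positive logistic slope on the log-contrast axis.
#' @param guess Lower asymptote (0.5 for 2IFC).
#' @param lapse Lapse rate shrinking the upper asymptote.
#' @return A function `f(contrast)` giving `P(correct)`, usable as the
#'   `observer` argument of [run_calibration()].
#' @export
logistic_psychometric <- function(threshold, slope = 2, guess = 0.5, lapse = 0) {
  check_number(threshold, "threshold", lower = 0, strict_lower = TRUE)
  check_number(slope, "slope", lower = 0, strict_lower = TRUE)
  check_number(guess, "guess", lower = 0, upper = 1)
  check_number(lapse, "lapse", lower = 0, upper = 0.5)
  force(threshold); force(slope); force(guess); force(lapse)
  function(contrast) {
    guess + (1 - guess - lapse) *
      stats::plogis(slope * (log(contrast) - log(threshold)))
  }
}

#' Run the interleaved staircase calibration and estimate threshold
#'
#' Runs two 1-up 2-down staircases — one starting below the expected
#' threshold (initially ascending), one above (initially descending) —
#' interleaved by strict alternation for `cfg$n_trials_total` trials. The
#' threshold is the arithmetic mean of the last
#' `cfg$n_reversals_for_threshold` reversal levels of each staircase,
#' pooled.
#'
#' @param observer Either an [observer_params()] object (responses simulated
#'   from the signal-detection model) or a function `f(contrast)` returning
#'   `P(correct)` (e.g. [logistic_psychometric()]).
#' @param cfg A [staircase_config()].
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return An object of class `calibration`: a list with
#'   `threshold_contrast`, a per-trial data frame `trials`
#'   (`trial`, `staircase`, `level`, `correct`), and `reversals`, the
#'   reversal levels per staircase.
#' @examples
#' cal <- run_calibration(logistic_psychometric(0.04), staircase_config(),
#'                        seed = 7)
#' cal$threshold_contrast
#' @export
run_calibration <- function(observer, cfg = staircase_config(), seed = NULL) {
  stopifnot(inherits(cfg, "staircase_config"))
  p_correct <-
    if (inherits(observer, "observer_params")) {
      function(contrast) {
        p <- stats::pnorm(observer$sensitivity_scale * contrast)
        (1 - observer$lapse_rate) * p + observer$lapse_rate / 2
      }
    } else if (is.function(observer)) {
      observer
    } else {
      stop_domain("`observer` must be observer_params or a P(correct) function")
    }
  with_seed(seed, {
    states <- list(ascending = staircase_state(cfg$start_levels[1], cfg),
                   descending = staircase_state(cfg$start_levels[2], cfg))
    n <- cfg$n_trials_total
    level <- numeric(n); correct <- logical(n); which_sc <- character(n)
    for (t in seq_len(n)) {
      sc <- if (t %% 2L == 1L) "ascending" else "descending"
      lvl <- states[[sc]]$current_level
      ok <- stats::runif(1) < p_correct(lvl)
      states[[sc]] <- staircase_update(states[[sc]], ok, cfg)
      level[t] <- lvl; correct[t] <- ok; which_sc[t] <- sc
    }
    k <- cfg$n_reversals_for_threshold
    rev_tail <- lapply(states, function(s) {
      r <- s$reversal_levels
      if (length(r) < k) NULL else utils::tail(r, k)
    })
    short <- names(rev_tail)[vapply(rev_tail, is.null, logical(1))]
    if (length(short))
      stop_domain(
        "calibration failed: %s staircase reached fewer than %d reversals",
        paste(short, collapse = " and "), k)
    structure(
      list(threshold_contrast = mean(unlist(rev_tail)),
           trials = data.frame(trial = seq_len(n), staircase = which_sc,
                               level = level, correct = correct,
                               stringsAsFactors = FALSE),
           reversals = lapply(states, `[[`, "reversal_levels"),
           config = cfg),
      class = "calibration")
  })
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("Staircase calibration: %d trials, threshold contrast %.4f\n",
              nrow(x$trials), x$threshold_contrast))
  cat(sprintf("  reversals: ascending %d, descending %d\n",
              length(x$reversals$ascending), length(x$reversals$descending)))
  invisible(x)
}
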