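#' Generative parameters of a simulated 2IFC observer
#'
#' Defines a signal-detection observer for a two-interval forced-choice
#' (2IFC) contrast-discrimination task with confidence ratings. On each
#' trial the observer draws first-order evidence `e ~ Normal(d(c), 1)` with
#' discriminability `d(c) = sensitivity_scale * c` for stimulus contrast
#' `c`; the interval decision is correct iff `e > 0` (lapse trials respond
#' uniformly at random). Confidence is read out from the same decision
#' variable corrupted by late Gaussian noise:
#' `confidence = plogis(confidence_slope * |e + m|)` with
#' `m ~ Normal(0, metacog_noise)`, which maps onto the half-range
#' probability scale \[0.5, 1\]. Raising `metacog_noise` degrades the
#' diagnosticity of confidence (type-2 sensitivity) while leaving
#' first-order accuracy untouched — the dissociation the analysis pipeline
#' is designed to detect.
#'
#' @param sensitivity_scale Positive slope of the linear contrast-to-d'
#'   transducer.
#' @param metacog_noise Non-negative SD of the late noise added to the
#'   decision variable before the confidence readout.
#' @param lapse_rate Probability in \[0, 0.1\] of a random interval response.
#' @param confidence_slope Positive slope of the evidence-to-confidence
#'   logistic mapping.
#' @param rt_location_ms,rt_scale_ms Location (median, ms) and log-scale of
#'   the log-normal response-time model. The defaults place about 4% of RT
#'   mass outside the \[200, 2000\] ms analysis window so the RT filter is
#'   exercised.
#'
#' @return An object of class `observer_params`.
#' @seealso [simulate_trials()], [simulate_cohort()]
#' @examples
#' obs <- observer_params(sensitivity_scale = 16, metacog_noise = 0.5)
#' trials <- simulate_trials(obs, contrast = 0.06, n = 20, seed = 1)
#' mean(trials$correct)
#' @export
observer_params <- function(sensitivity_scale = 16,
                            metacog_noise = 0,
                            lapse_rate = 0.02,
                            confidence_slope = 1.5,
                            rt_location_ms = 700,
                            rt_scale_ms = 0.55) {
  check_number(sensitivity_scale, "sensitivity_scale", lower = 0, strict_lower = TRUE)
  check_number(metacog_noise, "metacog_noise", lower = 0)
  check_number(lapse_rate, "lapse_rate", lower = 0, upper = 0.1)
  check_number(confidence_slope, "confidence_slope", lower = 0, strict_lower = TRUE)
  check_number(rt_location_ms, "rt_location_ms", lower = 0, strict_lower = TRUE)
  check_number(rt_scale_ms, "rt_scale_ms", lower = 0, strict_lower = TRUE)
  structure(
    list(sensitivity_scale = sensitivity_scale,
         metacog_noise = metacog_noise,
         lapse_rate = lapse_rate,
         confidence_slope = confidence_slope,
         rt_location_ms = rt_location_ms,
         rt_scale_ms = rt_scale_ms),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("2IFC observer:\n")
  cat(sprintf("  sensitivity_scale : %.3g\n", x$sensitivity_scale))
  cat(sprintf("  metacog_noise     : %.3g\n", x$metacog_noise))
  cat(sprintf("  lapse_rate        : %.3g\n", x$lapse_rate))
  cat(sprintf("  confidence_slope  : %.3g\n", x$confidence_slope))
  cat(sprintf("  RT ~ lognormal(median %.0f ms, sdlog %.2f)\n",
              x$rt_location_ms, x$rt_scale_ms))
  invisible(x)
}

#' Simulate confidence-rated 2IFC trials
#'
#' Vectorised trial generator for the observer defined by
#' [observer_params()]. Draw order is fixed (targets, evidence, lapses,
#' lapse responses, metacognitive noise, RTs) so that, under a common seed,
#' changing `metacog_noise` alone leaves the first-order evidence — and
#' therefore accuracy — bit-identical.
#'
#' @param params An [observer_params()] object.
#' @param contrast Positive stimulus contrast (Michelson units).
#' @param n Number of trials.
#' @param participant_id Identifier written into the trial table.
#' @param n_blocks Number of equal blocks the trials are labelled with.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param trial_offset Added to `trial_index` (for appending to earlier runs).
#'
#' @return A data frame with one row per trial: `participant_id`,
#'   `trial_index`, `block`, `target_interval`, `response_interval`,
#'   `correct`, `rt_ms`, `confidence`, `contrast`.
#' @export
simulate_trials <- function(params, contrast, n, participant_id = "sim",
                            n_blocks = 1L, seed = NULL, trial_offset = 0L) {
  stopifnot(inherits(params, "observer_params"))
  check_number(contrast, "contrast", lower = 0, strict_lower = TRUE)
  n <- check_count(n, "n", lower = 1L)
  n_blocks <- check_count(n_blocks, "n_blocks", lower = 1L)
  with_seed(seed, {
    d <- params$sensitivity_scale * contrast
    target <- sample(c(1L, 2L), n, replace = TRUE)
    e <- stats::rnorm(n, mean = d, sd = 1)
    lapse <- stats::runif(n) < params$lapse_rate
    lapse_resp <- sample(c(1L, 2L), n, replace = TRUE)
    m <- stats::rnorm(n, 0, params$metacog_noise)
    rt <- stats::rlnorm(n, meanlog = log(params$rt_location_ms),
                        sdlog = params$rt_scale_ms)
    response <- ifelse(e > 0, target, 3L - target)
    response[lapse] <- lapse_resp[lapse]
    confidence <- stats::plogis(params$confidence_slope * abs(e + m))
    idx <- seq_len(n) + as.integer(trial_offset)
    block <- as.integer(ceiling(seq_len(n) / (n / n_blocks)))
    data.frame(participant_id = participant_id,
               trial_index = idx,
               block = block,
               target_interval = target,
               response_interval = as.integer(response),
               correct = response == target,
               rt_ms = rt,
               confidence = confidence,
               contrast = contrast,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a single 2IFC trial
#'
#' Convenience wrapper around [simulate_trials()] with `n = 1`.
#'
#' @inheritParams simulate_trials
#' @return A one-row trial data frame.
#' @export
simulate_trial <- function(params, contrast, participant_id = "sim",
                           seed = NULL) {
  simulate_trials(params, contrast, n = 1L,
                  participant_id = participant_id, seed = seed)
}
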