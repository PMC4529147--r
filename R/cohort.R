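#' Design of a synthetic stress-reactivity cohort
#'
#' Describes the generative world of a simulated experiment: three
#' stress-reactivity groups (low/medium/high) of `n_per_group` participants
#' each. Per participant the generator produces (i) a seven-sample salivary
#' cortisol panel C0..C6 whose post-stress peak C2 is drawn around the
#' group mean, (ii) a staircase-calibrated contrast threshold followed by
#' `n_trials_main` confidence-rated 2IFC trials at that fixed contrast,
#' and (iii) a uniformly sampled heart-rate trace whose per-minute SD is
#' elevated for the high-reactivity group in configurable windows.
#'
#' Metacognitive noise is a deterministic increasing function of the
#' participant's C2 concentration,
#' `metacog_noise = max(0, cortisol_auc_slope * (C2 - 2))`,
#' so higher cortisol reactivity degrades metacognitive sensitivity while
#' first-order accuracy stays pinned near the staircase target. Setting
#' `cortisol_auc_slope = 0` yields a null world with no systematic group
#' difference in AUC.
#'
#' Group-level cortisol defaults (peaks 4.5/7.3/10.7 nmol/l, increases over
#' baseline 0.21/1.45/2.14 nmol/l, SDs 0.79/0.95/1.4) reproduce the
#' screening structure of the emulated study population.
#'
#' @param n_per_group Participants per reactivity group (>= 2).
#' @param group_cortisol_peaks Strictly increasing named vector of C2 group
#'   means (low, medium, high), nmol/l.
#' @param cortisol_auc_slope Slope of the C2-to-metacognitive-noise link
#'   (0 = null model). Default 0.12 per nmol/l.
#' @param seed Master integer seed; every participant draws from a derived
#'   stream, so regeneration is bit-identical and adding participants does
#'   not perturb existing ones.
#' @param group_c2_sd Within-group SD of C2 per group, nmol/l.
#' @param group_increase Mean C2 - C0 increase per group, nmol/l (baseline
#'   is `peak - increase`).
#' @param baseline_sd SD of the individual baseline C0, nmol/l.
#' @param sample_times_min Seven sampling times, minutes from session
#'   start, strictly increasing; sample 3 (index `c2_index`) is C2,
#'   10 minutes after stress induction.
#' @param c2_index Which of the 7 samples is the reactivity peak C2
#'   (1-based; default 3, i.e. column `C2` under 0-based naming).
#' @param n_trials_main,n_blocks Main-task trial count and block count.
#' @param observer Base [observer_params()] shared by all participants
#'   (metacognitive noise is overridden per participant; sensitivity gets
#'   individual log-normal jitter `sensitivity_jitter_sd`).
#' @param sensitivity_jitter_sd SD of log sensitivity across participants.
#' @param staircase [staircase_config()] for the calibration stage.
#' @param hr List of heart-rate generator settings: `duration_s`, `hz`,
#'   `mean_bpm`, `sd_bpm` (baseline within-window SD), `high_sd_delta`
#'   (extra SD for the high group inside `elevated_windows`),
#'   `elevated_windows` (1-based one-minute window indices).
#' @param stai List: `pre_mean`, `pre_sd`, `post_shift`, `post_sd` for the
#'   simulated state-anxiety questionnaire totals (consumed as plain
#'   numbers downstream).
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_per_group = 9L,
                        group_cortisol_peaks = c(low = 4.5, medium = 7.3,
                                                 high = 10.7),
                        cortisol_auc_slope = 0.12,
                        seed = 1L,
                        group_c2_sd = c(low = 0.79, medium = 0.95, high = 1.4),
                        group_increase = c(low = 0.21, medium = 1.45,
                                           high = 2.14),
                        baseline_sd = 0.6,
                        sample_times_min = c(0, 20, 30, 40, 50, 65, 80),
                        c2_index = 3L,
                        n_trials_main = 320L,
                        n_blocks = 8L,
                        observer = observer_params(),
                        sensitivity_jitter_sd = 0.15,
                        staircase = staircase_config(),
                        hr = list(duration_s = 2400L, hz = 1, mean_bpm = 78,
                                  sd_bpm = 6.2, high_sd_delta = 1.1,
                                  elevated_windows = 1:8),
                        stai = list(pre_mean = 36, pre_sd = 6,
                                    post_shift = 7.6, post_sd = 4)) {
  n_per_group <- check_count(n_per_group, "n_per_group", lower = 0L)
  if (n_per_group < 2L)
    stop_domain("n_per_group must be >= 2: group statistics are undefined for singleton groups")
  if (length(group_cortisol_peaks) != 3L ||
      any(diff(group_cortisol_peaks) <= 0) || any(group_cortisol_peaks <= 0))
    stop_domain("`group_cortisol_peaks` must be three strictly increasing positive values (low, medium, high)")
  check_number(cortisol_auc_slope, "cortisol_auc_slope")
  seed <- check_count(seed, "seed")
  if (length(sample_times_min) != 7L || any(diff(sample_times_min) <= 0))
    stop_domain("`sample_times_min` must be 7 strictly increasing times")
  c2_index <- check_count(c2_index, "c2_index", lower = 1L)
  if (c2_index > 7L) stop_domain("`c2_index` must be in 1..7")
  n_trials_main <- check_count(n_trials_main, "n_trials_main", lower = 1L)
  n_blocks <- check_count(n_blocks, "n_blocks", lower = 1L)
  stopifnot(inherits(observer, "observer_params"),
            inherits(staircase, "staircase_config"))
  structure(
    list(n_per_group = n_per_group,
         group_cortisol_peaks = group_cortisol_peaks,
         cortisol_auc_slope = cortisol_auc_slope,
         seed = seed,
         group_c2_sd = group_c2_sd,
         group_increase = group_increase,
         baseline_sd = baseline_sd,
         sample_times_min = sample_times_min,
         c2_index = c2_index,
         n_trials_main = n_trials_main,
         n_blocks = n_blocks,
         observer = observer,
         sensitivity_jitter_sd = sensitivity_jitter_sd,
         staircase = staircase,
         hr = hr,
         stai = stai),
    class = "cohort_spec")
}

# C2 -> metacognitive noise link; the 2 nmol/l floor keeps low-reactivity
# baselines near the noise-free observer.
noise_from_c2 <- function(c2, slope) pmax(0, slope * (c2 - 2))

simulate_cortisol_samples <- function(spec, group, seed) {
  with_seed(seed, {
    peak <- spec$group_cortisol_peaks[[group]]
    inc <- spec$group_increase[[group]]
    c0 <- max(0.5, peak - inc + stats::rnorm(1, 0, spec$baseline_sd))
    c2 <- max(0.5, stats::rnorm(1, peak, spec$group_c2_sd[[group]]))
    tt <- spec$sample_times_min
    t2 <- tt[spec$c2_index]
    conc <- numeric(7)
    conc[1] <- c0
    conc[spec$c2_index] <- c2
    # rise toward the peak, then exponential recovery toward baseline
    for (i in seq_len(7)[-c(1, spec$c2_index)]) {
      base <- if (tt[i] < t2) {
        c0 + (c2 - c0) * (tt[i] - tt[1]) / (t2 - tt[1])
      } else {
        c0 + (c2 - c0) * exp(-(tt[i] - t2) / 25)
      }
      conc[i] <- max(0.05, base + stats::rnorm(1, 0, 0.3))
    }
    conc
  })
}

simulate_hr_trace <- function(spec, group, participant_id, seed) {
  with_seed(seed, {
    hz <- spec$hr$hz
    n <- round(spec$hr$duration_s * hz)
    t_s <- (seq_len(n) - 1L) / hz
    window <- floor(t_s / 60) + 1L
    sd_t <- rep(spec$hr$sd_bpm, n)
    if (group == "high")
      sd_t[window %in% spec$hr$elevated_windows] <-
        spec$hr$sd_bpm + spec$hr$high_sd_delta
    bpm <- spec$hr$mean_bpm + stats::rnorm(n, 0, sd_t)
    bpm <- pmax(bpm, 30)                       # physiological floor
    data.frame(participant_id = participant_id, time_s = t_s, bpm = bpm,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full stress-reactivity cohort
#'
#' Generates, for every participant of a [cohort_spec()], the cortisol
#' panel, the staircase calibration, the main confidence task and the
#' heart-rate trace, under per-participant seed streams derived from the
#' master seed (regeneration is bit-identical).
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: list of data frames
#' \describe{
#'   \item{trials}{main-task trials (one row per trial, see
#'     [simulate_trials()]).}
#'   \item{cortisol}{wide panel: `participant_id`, `C0`..`C6` (nmol/l).}
#'   \item{heart_rate}{long trace: `participant_id`, `time_s`, `bpm`.}
#'   \item{participants}{generative truth per participant:
#'     `participant_id`, `group`, `c2_nmol_l`, `metacog_noise`,
#'     `sensitivity_scale`, `threshold_contrast`, `stai_pre`, `stai_post`.}
#' }
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_per_group = 2, seed = 42))
#' head(coh$participants)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("low", "medium", "high")
  n_total <- 3L * spec$n_per_group
  seeds <- participant_seeds(spec$seed, n_total)
  trials <- vector("list", n_total)
  hr <- vector("list", n_total)
  cort <- matrix(NA_real_, n_total, 7)
  info <- vector("list", n_total)
  i <- 0L
  for (g in groups) {
    for (j in seq_len(spec$n_per_group)) {
      i <- i + 1L
      pid <- sprintf("%s%02d", g, j)
      conc <- simulate_cortisol_samples(spec, g, stage_seed(seeds[i], 1L))
      c2 <- conc[spec$c2_index]
      obs <- spec$observer
      obs$metacog_noise <- noise_from_c2(c2, spec$cortisol_auc_slope)
      obs$sensitivity_scale <- with_seed(stage_seed(seeds[i], 2L),
        obs$sensitivity_scale *
          exp(stats::rnorm(1, 0, spec$sensitivity_jitter_sd)))
      cal <- run_calibration(obs, spec$staircase,
                             seed = stage_seed(seeds[i], 3L))
      trials[[i]] <- simulate_trials(obs, cal$threshold_contrast,
                                     n = spec$n_trials_main,
                                     participant_id = pid,
                                     n_blocks = spec$n_blocks,
                                     seed = stage_seed(seeds[i], 4L))
      hr[[i]] <- simulate_hr_trace(spec, g, pid, stage_seed(seeds[i], 5L))
      stai <- with_seed(stage_seed(seeds[i], 6L), {
        pre <- round(stats::rnorm(1, spec$stai$pre_mean, spec$stai$pre_sd))
        post <- round(pre + spec$stai$post_shift +
                        stats::rnorm(1, 0, spec$stai$post_sd))
        c(clamp(pre, 20, 80), clamp(post, 20, 80))
      })
      cort[i, ] <- conc
      info[[i]] <- data.frame(participant_id = pid, group = g,
                              c2_nmol_l = c2,
                              metacog_noise = obs$metacog_noise,
                              sensitivity_scale = obs$sensitivity_scale,
                              threshold_contrast = cal$threshold_contrast,
                              stai_pre = stai[1], stai_post = stai[2],
                              stringsAsFactors = FALSE)
    }
  }
  participants <- do.call(rbind, info)
  cortisol <- data.frame(participant_id = participants$participant_id,
                         cort, stringsAsFactors = FALSE)
  names(cortisol)[-1] <- paste0("C", 0:6)
  structure(
    list(trials = do.call(rbind, trials),
         cortisol = cortisol,
         heart_rate = do.call(rbind, hr),
         participants = participants,
         spec = spec),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%d per group), %d main trials each\n",
              nrow(x$participants), x$spec$n_per_group, x$spec$n_trials_main))
  cat(sprintf("  master seed %d, cortisol-AUC slope %.3g\n",
              x$spec$seed, x$spec$cortisol_auc_slope))
  invisible(x)
}

#' Write the three cohort tables as CSV
#'
#' Writes `trials.csv`, `cortisol.csv`, `heart_rate.csv` and
#' `participants.csv` (UTF-8, header row, "." decimal separator) into
#' `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "cortisol.csv",
                            "heart_rate.csv", "participants.csv"))
  utils::write.csv(cohort$trials, paths[1], row.names = FALSE)
  utils::write.csv(cohort$cortisol, paths[2], row.names = FALSE)
  utils::write.csv(cohort$heart_rate, paths[3], row.names = FALSE)
  utils::write.csv(cohort$participants, paths[4], row.names = FALSE)
  invisible(paths)
}
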