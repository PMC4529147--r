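#' Pipeline configuration
#'
#' Bundles every stage's settings: the synthetic cohort design, the
#' confidence binning, the RT analysis window, the screening thresholds,
#' and the HRV cluster-test parameters. The configuration round-trips
#' losslessly through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param seed Master integer seed; overrides `cohort$seed` so one number
#'   drives the whole run.
#' @param cohort A [cohort_spec()].
#' @param binning List: `k` (bins, default 5) and `mode`
#'   (`"equal_width"` or `"equal_count"`).
#' @param rt_bounds Inclusive RT analysis window, ms.
#' @param screening List: `high_pct`, `low_pct`, `mid_band`,
#'   `responder_threshold` (see [assign_reactivity_groups()]).
#' @param hrv List: `window_s`, `span`, `n_boot`, `alpha` (see
#'   [group_cluster_test()]).
#' @param out_dir Default output directory for [run_pipeline()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_spec(),
                            binning = list(k = 5L, mode = "equal_width"),
                            rt_bounds = c(200, 2000),
                            screening = list(high_pct = 75, low_pct = 25,
                                             mid_band = c(40, 60),
                                             responder_threshold = 1.1),
                            hrv = list(window_s = 60L, span = 0.3,
                                       n_boot = 5000L, alpha = 0.05),
                            out_dir = "stressmeta-out") {
  seed <- check_count(seed, "seed")
  stopifnot(inherits(cohort, "cohort_spec"))
  cohort$seed <- seed
  check_count(binning$k, "binning$k", lower = 2L)
  binning$mode <- match.arg(binning$mode, c("equal_width", "equal_count"))
  if (length(rt_bounds) != 2L || rt_bounds[1] >= rt_bounds[2])
    stop_domain("`rt_bounds` must be an increasing (lo, hi) pair in ms")
  structure(
    list(seed = seed, cohort = cohort, binning = binning,
         rt_bounds = as.numeric(rt_bounds), screening = screening,
         hrv = hrv, out_dir = out_dir),
    class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$observer <- unclass(x$cohort$observer)
  x$cohort$staircase <- unclass(x$cohort$staircase)
  # named atomic vectors lose their names as JSON arrays; store as objects
  for (f in c("group_cortisol_peaks", "group_c2_sd", "group_increase"))
    x$cohort[[f]] <- as.list(x$cohort[[f]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- x$cohort
  spec <- cohort_spec(
    n_per_group = co$n_per_group,
    group_cortisol_peaks = unlist(co$group_cortisol_peaks),
    cortisol_auc_slope = co$cortisol_auc_slope,
    seed = co$seed,
    group_c2_sd = unlist(co$group_c2_sd),
    group_increase = unlist(co$group_increase),
    baseline_sd = co$baseline_sd,
    sample_times_min = co$sample_times_min,
    c2_index = co$c2_index,
    n_trials_main = co$n_trials_main,
    n_blocks = co$n_blocks,
    observer = do.call(observer_params, co$observer),
    sensitivity_jitter_sd = co$sensitivity_jitter_sd,
    staircase = do.call(staircase_config, co$staircase),
    hr = co$hr,
    stai = co$stai)
  pipeline_config(seed = x$seed, cohort = spec, binning = x$binning,
                  rt_bounds = x$rt_bounds, screening = x$screening,
                  hrv = x$hrv, out_dir = x$out_dir)
}

#' Group-level analysis of a scored cohort
#'
#' Runs the statistical stage on per-participant summaries: one-way ANOVA
#' of AUC on reactivity group with eta squared, Bonferroni pairwise
#' post-hocs, OLS regression of AUC on C2 cortisol, and — when STAI
#' pre/post totals are present — the mixed pre/post ANOVA.
#'
#' @param summary Per-participant data frame with columns `group`, `auc`,
#'   `c2_nmol_l`, and optionally `stai_pre`, `stai_post`.
#' @return List with components `anova_auc`, `posthoc`, `regression`, and
#'   (optionally) `stai_prepost`.
#' @export
analyze_groups <- function(summary) {
  stopifnot(all(c("group", "auc", "c2_nmol_l") %in% names(summary)))
  res <- list(
    anova_auc = oneway_anova_eta2(summary$auc, summary$group),
    posthoc = bonferroni_pairwise(summary$auc, summary$group),
    regression = regress_auc_on_cortisol(summary$auc, summary$c2_nmol_l))
  if (all(c("stai_pre", "stai_post") %in% names(summary)))
    res$stai_prepost <- rm_anova_prepost(summary$stai_pre, summary$stai_post,
                                         summary$group)
  res
}

#' Run the full simulate-screen-score-HRV-analyze pipeline
#'
#' Executes every stage in order, writing each stage's artifact into
#' `out_dir`: the cohort CSVs, the screening assignments, the
#' per-participant summary, the HRV per-window results and cluster
#' summary, the analysis results bundle, and a deterministic manifest
#' (package version, seed, config fingerprint, record counts, collected
#' warnings). Rerunning with the same configuration is bit-identical; no
#' wall-clock information enters the outputs.
#'
#' The HRV cluster test contrasts the high-reactivity group against the
#' collapsed low+medium groups, using the cohort's generative labels.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the results bundle: list with `cohort`,
#'   `assignments`, `summary`, `excluded_fraction`, `hrv`, `analysis`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %-9s done (%.1f s)", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  write_cohort(cohort, out_dir)

  assignments <- stage("screen", assign_reactivity_groups(
    cohort$cortisol,
    high_pct = config$screening$high_pct,
    low_pct = config$screening$low_pct,
    mid_band = unlist(config$screening$mid_band),
    responder_threshold = config$screening$responder_threshold))
  utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)

  summary <- stage("score", {
    flt <- filter_rts(cohort$trials, config$rt_bounds[1], config$rt_bounds[2])
    sc <- score_participants(flt$kept, k = config$binning$k,
                             mode = config$binning$mode)
    sc <- merge(sc, cohort$participants[, c("participant_id", "group",
                                            "c2_nmol_l", "threshold_contrast",
                                            "stai_pre", "stai_post")],
                by = "participant_id", sort = TRUE)
    attr(sc, "excluded_fraction") <- flt$excluded_fraction
    sc
  })
  excluded_fraction <- attr(summary, "excluded_fraction")
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  hrv_res <- stage("hrv", {
    mat <- hrv_matrix(cohort$heart_rate, window_s = config$hrv$window_s,
                      span = config$hrv$span)
    high_ids <- cohort$participants$participant_id[
      cohort$participants$group == "high"]
    g1 <- mat[, colnames(mat) %in% high_ids, drop = FALSE]
    g2 <- mat[, !colnames(mat) %in% high_ids, drop = FALSE]
    group_cluster_test(g1, g2, n_boot = config$hrv$n_boot,
                       alpha = config$hrv$alpha,
                       seed = stage_seed(config$seed, 101L))
  })
  utils::write.csv(hrv_res$per_window, file.path(out_dir, "hrv_windows.csv"),
                   row.names = FALSE)
  jsonlite::write_json(hrv_res$clusters, file.path(out_dir, "hrv_clusters.json"),
                       dataframe = "rows", digits = NA)

  analysis <- stage("analyze", analyze_groups(summary))
  analysis$excluded_fraction <- excluded_fraction
  jsonlite::write_json(analysis, file.path(out_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")

  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    package = "stressmeta",
    version = as.character(utils::packageVersion("stressmeta")),
    seed = config$seed,
    config_fingerprint = text_fingerprint(readLines(cfg_path)),
    n_participants = nrow(cohort$participants),
    n_trials = nrow(cohort$trials),
    excluded_fraction = excluded_fraction,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, assignments = assignments,
                 summary = summary, excluded_fraction = excluded_fraction,
                 hrv = hrv_res, analysis = analysis, manifest = manifest))
}
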