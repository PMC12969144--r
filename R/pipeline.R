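# End-to-end orchestration: simulate a cohort, preprocess, epoch, and run
# the full set of group analyses.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default: 20 Hz analysis
#' rate, 3 SD atypicality threshold, reaction-time bounds 0.2-3 s, epoch
#' window (-8, +4) s, 4000 surrogate iterations at 99% max-over-time
#' confidence, 4000 cluster randomizations with a 250 ms minimum cluster,
#' per-sample cluster-forming alpha 0.05, and slope windows (-2, -1) /
#' (+1, +2) s. Simulation defaults define the emulated study conditions:
#' per-participant mean cycle durations uniform in 3.5-4.2 s, preferred
#' onset phase pi, and condition concentrations kappa (experiment 1:
#' SHORT = 3, LONG = 1).
#'
#' @param experiment experiment id (1, 2, 3).
#' @param n_participants cohort size.
#' @param n_trials trials per participant.
#' @param seed master seed; every stage derives an independent substream.
#' @param fs simulated respiration sampling rate, Hz.
#' @param kappa named condition concentrations (NULL = per-experiment
#'   default).
#' @param contrast length-2 character, conditions to compare (NULL =
#'   per-experiment default).
#' @param n_surrogate,surrogate_conf surrogate iterations and confidence.
#' @param n_rand cluster / angular randomizations.
#' @param do_surrogate compute the surrogate threshold (the costliest
#'   stage).
#' @param ... overrides for any other field.
#' @return a `run_config` list; `config_hash` is embedded in all outputs.
#' @export
run_config <- function(experiment = 1, n_participants = 27, n_trials = 800,
                       seed = 1, fs = 250, kappa = NULL, contrast = NULL,
                       n_surrogate = 4000, surrogate_conf = 0.99,
                       n_rand = 4000, do_surrogate = FALSE, ...) {
  if (is.null(kappa))
    kappa <- switch(as.character(experiment),
                    "1" = c(SHORT = 3, LONG = 1),
                    "2" = c(high = 2, low = 2),
                    "3" = c(high = 2.5, low = 1.5))
  if (is.null(contrast))
    contrast <- switch(as.character(experiment),
                       "1" = c("SHORT", "LONG"),
                       c("high", "low"))
  cfg <- list(experiment = experiment, n_participants = n_participants,
              n_trials = n_trials, seed = seed, fs = fs, kappa = kappa,
              contrast = contrast,
              mu = pi, cycle_mean_range_s = c(3.5, 4.2), cycle_cv = 0.12,
              inhale_fraction = 0.4, kappa_jitter_sd = 0.15,
              fs_out = 20, z_thresh = 3,
              rt_min_s = 0.2, rt_max_s = 3.0,
              deadline_required = experiment == 1,
              window_s = c(-8, 4), min_trials = 10,
              n_surrogate = n_surrogate, surrogate_conf = surrogate_conf,
              n_rand = n_rand, alpha_form = 0.05, min_cluster_s = 0.25,
              slope_pre = c(-2, -1), slope_post = c(1, 2),
              plvs_probe_t = 2, do_surrogate = do_surrogate)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Simulate and analyze a single participant
#'
#' Simulation, preprocessing, trial filtering and epoching for one
#' participant under a [run_config()]. Per-participant physiology (mean
#' cycle duration, a mild multiplicative jitter on kappa) is drawn from a
#' participant-keyed substream of the master seed.
#'
#' @param config a [run_config()].
#' @param pid participant id (integer).
#' @return list with `trials`, `cycles`, `epochs`, per-condition plvs
#'   traces (`plvs`), slopes, onset-phase circular means, mean cycle
#'   durations, behavior summaries, and trial counts.
#' @export
run_participant <- function(config, pid) {
  set.seed(derive_seed(config$seed, pid, "physiology"))
  cyc_mean <- stats::runif(1, config$cycle_mean_range_s[1],
                           config$cycle_mean_range_s[2])
  kap <- config$kappa * exp(stats::rnorm(length(config$kappa), 0,
                                         config$kappa_jitter_sd))
  names(kap) <- names(config$kappa)
  paradigm <- paradigm_spec(config$experiment, n_trials = config$n_trials)
  coupling <- coupling_spec(mu = config$mu, kappa = kap,
                            cycle_mean_s = cyc_mean,
                            cycle_cv = config$cycle_cv,
                            inhale_fraction = config$inhale_fraction)
  sim <- simulate_participant(paradigm, coupling,
                              default_behavior_spec(config$experiment),
                              fs = config$fs,
                              seed = derive_seed(config$seed, pid, "sim"))
  cycles <- segment_cycles(sim$trace)
  cycles <- flag_atypical(cycles, sim$trace, z_thresh = config$z_thresh)
  phase <- compute_phase(cycles, fs_out = config$fs_out)
  trials <- filter_trials(sim$trials, cycles,
                          rt_min_s = config$rt_min_s,
                          rt_max_s = config$rt_max_s,
                          deadline_required = config$deadline_required)
  epochs <- epoch_phase(phase, trials, window_s = config$window_s)

  conds <- config$contrast
  per_cond <- lapply(conds, function(cc) {
    e <- epochs_by_condition(epochs, cc)
    tr <- trials[trials$included & trials$condition == cc, , drop = FALSE]
    pv <- plvs(e, min_trials = config$min_trials)
    i0 <- which.min(abs(e$time_s))
    cm <- circ_mean(e$phase[e$valid[, i0], i0])
    list(plvs = pv,
         slope = plvs_slope(pv, pre_window = config$slope_pre,
                            post_window = config$slope_post),
         plvs_probe = plvs_at(pv, config$plvs_probe_t),
         onset_angle = cm$mean_angle,
         mean_duration = mean(tr$cycle_duration_s, na.rm = TRUE),
         mean_rt = mean(tr$rt_s, na.rm = TRUE),
         accuracy = mean(tr$correct, na.rm = TRUE),
         n_trials = nrow(tr))
  })
  names(per_cond) <- conds
  list(trials = trials, cycles = cycles, epochs = epochs,
       by_condition = per_cond, n_included = sum(trials$included))
}

#' Run the full pipeline over a simulated cohort
#'
#' Simulates `n_participants` end to end, then runs the group analyses:
#' condition contrast of plvs traces via the cluster-based sign-flip
#' permutation test, plvs-slope paired t test, angular difference
#' randomization test on trial-averaged onset phases, cycle-duration
#' contrast, Spearman correlations of respiratory vs behavioral condition
#' differences, and (optionally) the time-shift surrogate threshold for
#' the group-mean plvs. Deterministic given the config (all randomness is
#' keyed by the master seed, participant id and procedure name).
#'
#' @param config a [run_config()].
#' @param keep_participants keep the full per-participant objects
#'   (epochs, cycles) in the result; off by default to save memory.
#' @return a `pipeline_result` list; see [make_report()].
#' @export
run_pipeline <- function(config, keep_participants = FALSE) {
  stopifnot(inherits(config, "run_config"))
  conds <- config$contrast
  parts <- lapply(seq_len(config$n_participants),
                  function(p) run_participant(config, p))
  Tn <- length(parts[[1]]$epochs$time_s)
  time_s <- parts[[1]]$epochs$time_s

  get_cond <- function(field, cc) {
    vapply(parts, function(pp) pp$by_condition[[cc]][[field]], numeric(1))
  }
  plvs_mat <- lapply(conds, function(cc) {
    t(vapply(parts, function(pp) as.numeric(pp$by_condition[[cc]]$plvs),
             numeric(Tn)))
  })
  names(plvs_mat) <- conds

  cluster <- cluster_permutation(plvs_mat[[1]], plvs_mat[[2]], time_s,
                                 n_rand = config$n_rand,
                                 alpha_form = config$alpha_form,
                                 min_cluster_s = config$min_cluster_s,
                                 seed = derive_seed(config$seed, "cluster"))
  slope_test <- paired_t(get_cond("slope", conds[1]),
                         get_cond("slope", conds[2]))
  ang <- wrap_angle(get_cond("onset_angle", conds[1]) -
                      get_cond("onset_angle", conds[2]))
  angular <- angular_difference_test(ang, n_rand = config$n_rand,
                                     seed = derive_seed(config$seed, "angular"))
  durations <- duration_contrast(get_cond("mean_duration", conds[1]),
                                 get_cond("mean_duration", conds[2]))
  plvs_diff <- get_cond("plvs_probe", conds[1]) - get_cond("plvs_probe", conds[2])
  dur_diff <- get_cond("mean_duration", conds[1]) -
    get_cond("mean_duration", conds[2])
  rt_diff <- get_cond("mean_rt", conds[1]) - get_cond("mean_rt", conds[2])
  acc_diff <- get_cond("accuracy", conds[1]) - get_cond("accuracy", conds[2])
  correlations <- list(
    plvs_vs_rt = diff_correlation(plvs_diff, rt_diff),
    plvs_vs_accuracy = diff_correlation(plvs_diff, acc_diff),
    duration_vs_rt = diff_correlation(dur_diff, rt_diff),
    duration_vs_accuracy = diff_correlation(dur_diff, acc_diff))

  surrogate <- NULL
  if (isTRUE(config$do_surrogate)) {
    surrogate <- surrogate_threshold(lapply(parts, `[[`, "epochs"),
                                     n_iter = config$n_surrogate,
                                     conf = config$surrogate_conf,
                                     min_trials = config$min_trials,
                                     seed = derive_seed(config$seed, "surrogate"))
  }

  behavior <- data.frame(
    condition = conds,
    mean_rt_s = vapply(conds, function(cc) mean(get_cond("mean_rt", cc)), 0),
    accuracy = vapply(conds, function(cc) mean(get_cond("accuracy", cc)), 0),
    mean_cycle_s = vapply(conds, function(cc) mean(get_cond("mean_duration", cc)), 0),
    row.names = NULL)
  rt_test <- paired_t(get_cond("mean_rt", conds[1]),
                      get_cond("mean_rt", conds[2]))

  structure(list(
    config = config, config_hash = config_hash(config), time_s = time_s,
    plvs = plvs_mat,
    group_plvs = lapply(plvs_mat, colMeans),
    cluster = cluster, slope_test = slope_test,
    slopes = stats::setNames(lapply(conds, function(cc) get_cond("slope", cc)), conds),
    angular = angular, angular_diffs = ang,
    durations = durations, behavior = behavior, rt_test = rt_test,
    correlations = correlations, surrogate = surrogate,
    n_included = vapply(parts, `[[`, 0, "n_included"),
    participants = if (keep_participants) parts else NULL),
    class = "pipeline_result")
}

boot_ci <- function(x, n_boot = 2000, conf = 0.95, seed = 7) {
  set.seed(seed)
  b <- vapply(seq_len(n_boot),
              function(i) mean(x[sample.int(length(x), replace = TRUE)]), 0)
  stats::quantile(b, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
}

#' Human-readable report of a pipeline run
#'
#' Group means with 95% percentile bootstrap confidence intervals, cluster
#' listings, slope and angular tests, duration contrasts and difference
#' correlations.
#'
#' @param results a `pipeline_result` from [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(results) {
  stopifnot(inherits(results, "pipeline_result"))
  conds <- results$config$contrast
  fmt_test <- function(x) {
    if (isTRUE(x$degenerate)) return("t undefined (zero-variance differences)")
    sprintf("t = %.3f, p = %.4g, Cohen's D = %.3f (n = %d)",
            x$t, x$p, x$cohens_d, x$n)
  }
  lines <- c(
    sprintf("respiratory alignment report [experiment %d, %d participants, config %s]",
            results$config$experiment, results$config$n_participants,
            results$config_hash),
    sprintf("retained trials per participant: %.1f (range %d-%d)",
            mean(results$n_included), min(results$n_included),
            max(results$n_included)),
    "",
    "behavior (group means):")
  for (i in seq_len(nrow(results$behavior))) {
    b <- results$behavior[i, ]
    lines <- c(lines, sprintf("  %-6s RT %.3f s, accuracy %.3f, cycle %.2f s",
                              b$condition, b$mean_rt_s, b$accuracy,
                              b$mean_cycle_s))
  }
  lines <- c(lines, sprintf("reaction-time contrast (%s - %s): %s",
                            conds[1], conds[2], fmt_test(results$rt_test)), "")
  for (cc in conds) {
    ci <- boot_ci(results$slopes[[cc]])
    lines <- c(lines, sprintf("plvs slope %-6s mean %.3f, 95%% bootstrap CI [%.3f, %.3f]",
                              cc, mean(results$slopes[[cc]]), ci[1], ci[2]))
  }
  lines <- c(lines, sprintf("slope contrast: %s", fmt_test(results$slope_test)), "")
  cl <- results$cluster$clusters
  if (nrow(cl) == 0) {
    lines <- c(lines, "cluster test: no significant clusters")
  } else {
    lines <- c(lines, sprintf("cluster test (%d randomizations):",
                              results$cluster$n_randomizations))
    for (i in seq_len(nrow(cl)))
      lines <- c(lines, sprintf("  cluster %d: %.2f to %.2f s, sum t = %.1f, p = %.4g, Cohen's D = %.2f",
                                i, cl$t_start_s[i], cl$t_end_s[i], cl$sum_t[i],
                                cl$p[i], cl$cohens_d[i]))
  }
  a <- results$angular
  lines <- c(lines, "",
             sprintf("angular difference (%s - %s): mean %.3f rad, 95%% percentile CI [%.3f, %.3f], p = %.3f",
                     conds[1], conds[2], a$mean_diff, a$ci[1], a$ci[2], a$p),
             sprintf("cycle-duration contrast: %s", fmt_test(results$durations)),
             "difference correlations (Spearman):")
  for (nm in names(results$correlations)) {
    co <- results$correlations[[nm]]
    lines <- c(lines, sprintf("  %-22s r = %+.3f, p = %.3f", nm, co$r, co$p))
  }
  if (!is.null(results$surrogate)) {
    s <- results$surrogate
    lines <- c(lines, "",
               sprintf("surrogate threshold (%d iterations, %.0f%% max-corrected): %.4f; %d/%d time points significant",
                       s$n_iter, 100 * s$conf, s$threshold,
                       sum(s$significant), length(s$significant)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
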