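# Synthetic paradigm schedules, respiration traces with controllable
# task alignment, and behavioral outcomes.

#' Paradigm specification
#'
#' Timing and condition structure of the three task paradigms: a blocked
#' response-deadline experiment (experiment 1: fixed 1 s fixation before
#' each stimulus, inter-trial intervals uniform in 3.5-4 s, first half of
#' trials under a LONG deadline and the second half under a SHORT one) and
#' two cued-value experiments (experiments 2-3: a 3 s countdown cue before
#' each stimulus, ITIs uniform in 1.7-2.8 s, trial-wise high/low value with
#' high:low ratio 1:2.33; experiment 2 crosses value with an independent
#' easy/hard difficulty label, experiment 3 links difficulty to value).
#'
#' @param experiment experiment id, 1, 2 or 3.
#' @param n_trials number of trials (> 0). Defaults to the paradigm's full
#'   length (800, 660, 630).
#' @param pre_stimulus_s fixed cue/fixation duration before stimulus onset.
#' @param iti_range_s length-2 numeric, uniform ITI bounds in seconds.
#' @param response_window_s duration of the stimulus + response epoch that
#'   separates stimulus onset from the following ITI.
#' @param value_ratio high:low value frequency expressed as the low/high
#'   ratio (1:`value_ratio`).
#' @param lead_in_s quiet recording before the first fixation, so that
#'   pre-onset epochs are covered.
#' @return an object of class `paradigm_spec`.
#' @export
paradigm_spec <- function(experiment = 1,
                          n_trials = NULL,
                          pre_stimulus_s = NULL,
                          iti_range_s = NULL,
                          response_window_s = NULL,
                          value_ratio = 2.33,
                          lead_in_s = 12) {
  if (!experiment %in% 1:3) stop("experiment must be 1, 2 or 3")
  defaults <- switch(as.character(experiment),
    "1" = list(n = 800, pre = 1.0, iti = c(3.5, 4.0), resp = 1.0),
    "2" = list(n = 660, pre = 3.0, iti = c(1.7, 2.8), resp = 2.3),
    "3" = list(n = 630, pre = 3.0, iti = c(1.7, 2.8), resp = 2.3))
  spec <- list(
    experiment = experiment,
    n_trials = if (is.null(n_trials)) defaults$n else as.integer(n_trials),
    pre_stimulus_s = if (is.null(pre_stimulus_s)) defaults$pre else pre_stimulus_s,
    iti_range_s = if (is.null(iti_range_s)) defaults$iti else iti_range_s,
    response_window_s = if (is.null(response_window_s)) defaults$resp else response_window_s,
    value_ratio = value_ratio,
    lead_in_s = lead_in_s)
  if (spec$n_trials <= 0) stop("invalid spec: n_trials must be positive")
  if (length(spec$iti_range_s) != 2 || spec$iti_range_s[1] > spec$iti_range_s[2])
    stop("invalid spec: iti_range_s must be (low, high) with low <= high")
  if (spec$pre_stimulus_s < 0 || spec$response_window_s < 0 || spec$value_ratio <= 0)
    stop("invalid spec: negative timing or non-positive value ratio")
  class(spec) <- "paradigm_spec"
  spec
}

#' Generate a trial schedule
#'
#' Draws stimulus onset times and condition labels for one participant.
#' Successive onsets are separated by the stimulus/response epoch, an ITI
#' draw, and the fixed pre-stimulus period. Experiment 1 presents the LONG
#' deadline in the first half of trials and SHORT in the second half;
#' experiments 2-3 assign high/low value independently per trial (ratio
#' 1:`value_ratio`), so the condition sequence is unpredictable from trial
#' history.
#'
#' @param spec a [paradigm_spec()].
#' @param seed integer seed.
#' @return a trial table: `trial`, `onset_s`, `condition` (and `difficulty`
#'   for experiments 2-3), with empty behavioral columns `rt_s`, `correct`,
#'   `responded`.
#' @export
gen_schedule <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "paradigm_spec"))
  set.seed(seed)
  n <- spec$n_trials
  iti <- stats::runif(n, spec$iti_range_s[1], spec$iti_range_s[2])
  # iti[k] precedes the fixation of trial k+1; the draw before trial 1 is
  # replaced by the lead-in
  step <- spec$response_window_s + iti + spec$pre_stimulus_s
  onset <- spec$lead_in_s + spec$pre_stimulus_s + c(0, cumsum(step[-n]))
  if (spec$experiment == 1) {
    condition <- rep(c("LONG", "SHORT"), c(ceiling(n / 2), floor(n / 2)))
    difficulty <- NULL
  } else {
    p_high <- 1 / (1 + spec$value_ratio)
    condition <- ifelse(stats::runif(n) < p_high, "high", "low")
    difficulty <- if (spec$experiment == 2) {
      ifelse(stats::runif(n) < 0.5, "hard", "easy")
    } else {
      ifelse(condition == "high", "hard", "easy")
    }
  }
  tab <- data.frame(trial = seq_len(n), onset_s = onset, condition = condition,
                    stringsAsFactors = FALSE)
  if (!is.null(difficulty)) tab$difficulty <- difficulty
  tab$rt_s <- NA_real_
  tab$correct <- NA
  tab$responded <- NA
  attr(tab, "paradigm") <- spec
  tab
}

#' Respiration coupling specification
#'
#' Parameters of the generative respiration model: breathing cycles with
#' lognormal durations (mean `cycle_mean_s`, coefficient of variation
#' `cycle_cv`), an asymmetric half-cosine waveform spending
#' `inhale_fraction` of each cycle inhaling, and a von Mises law for the
#' respiratory phase at stimulus onset with preferred phase `mu` and
#' condition-specific concentration `kappa`. `kappa = 0` leaves the phase
#' at onset uniform (no alignment).
#'
#' @param mu preferred phase at onset, radians; defaults to `pi` (peak
#'   inhalation).
#' @param kappa named numeric vector mapping condition labels to von Mises
#'   concentrations (>= 0); an unnamed scalar applies to all conditions.
#' @param cycle_mean_s mean cycle duration, seconds.
#' @param cycle_cv coefficient of variation of cycle durations.
#' @param inhale_fraction fraction of each cycle spent inhaling, in (0, 1).
#' @param amp_jitter lognormal sd of per-cycle amplitude gain.
#' @param noise_sd sd of additive white measurement noise (amplitude units;
#'   the noise-free waveform spans -1..1).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(mu = pi, kappa = 2, cycle_mean_s = 3.8,
                          cycle_cv = 0.12, inhale_fraction = 0.4,
                          amp_jitter = 0.05, noise_sd = 0.02) {
  if (any(kappa < 0)) stop("kappa must be >= 0")
  if (cycle_mean_s <= 0) stop("cycle_mean_s must be positive")
  if (inhale_fraction <= 0 || inhale_fraction >= 1)
    stop("inhale_fraction must lie in (0, 1)")
  structure(list(mu = mu, kappa = kappa, cycle_mean_s = cycle_mean_s,
                 cycle_cv = cycle_cv, inhale_fraction = inhale_fraction,
                 amp_jitter = amp_jitter, noise_sd = noise_sd),
            class = "coupling_spec")
}

kappa_for <- function(coupling, condition) {
  k <- coupling$kappa
  if (is.null(names(k)) || length(k) == 1) return(rep(k[[1]], length(condition)))
  if (!all(condition %in% names(k)))
    stop("coupling kappa does not cover condition(s): ",
         paste(setdiff(unique(condition), names(k)), collapse = ", "))
  unname(k[condition])
}

# Phase -> cycle fraction: inverse of the two-segment linear phase map.
phase_to_frac <- function(theta, f) {
  ifelse(theta < pi, f * theta / pi, f + (1 - f) * (theta - pi) / pi)
}

#' Generate a respiration trace aligned to a trial schedule
#'
#' Builds a continuous respiration trace as a gap-free concatenation of
#' breathing cycles. For each trial, a target phase-at-onset is drawn from
#' von Mises(`mu`, `kappa[condition]`) and the cycle containing that onset
#' is placed so the piecewise-linear phase hits the target exactly; the
#' free-running cycles between trials absorb the required timing
#' adjustment (bounded stretch/shrink, so the cycle-duration distribution
#' stays close to its nominal law). With `kappa = 0` the draws are
#' uniform, i.e. respiration free-runs with no event locking.
#'
#' @param schedule trial table from [gen_schedule()].
#' @param coupling a [coupling_spec()].
#' @param fs sampling rate, Hz (>= 100).
#' @param seed integer seed.
#' @param tail_s recording kept after the last onset.
#' @return a [respiration_trace()] with attribute `truth`: the generating
#'   cycle table (`onset_s`, `peak_s`, `end_s`), the drawn per-trial onset
#'   phases, and a flag for the rare trials where the bounded adjustment
#'   could not realize the drawn phase exactly.
#' @export
gen_respiration <- function(schedule, coupling, fs = 1000, seed = 1,
                            tail_s = 8) {
  stopifnot(inherits(coupling, "coupling_spec"), nrow(schedule) > 0)
  if (fs < 100) stop("fs too low to resolve respiratory cycles (need >= 100 Hz)")
  set.seed(seed)
  cm <- coupling$cycle_mean_s
  f <- coupling$inhale_fraction
  sdlog <- sqrt(log(1 + coupling$cycle_cv^2))
  meanlog <- log(cm) - sdlog^2 / 2
  draw_dur <- function(m) {
    d <- stats::rlnorm(m, meanlog, sdlog)
    pmin(pmax(d, 0.55 * cm), 1.8 * cm)
  }
  onsets <- schedule$onset_s
  kap <- kappa_for(coupling, schedule$condition)
  theta <- numeric(nrow(schedule))
  for (k in sort(unique(kap))) {
    sel <- which(kap == k)
    theta[sel] <- rvonmises(length(sel), coupling$mu, k)
  }

  start <- numeric(0); dur <- numeric(0); holds_onset <- logical(0)
  clamped <- logical(length(onsets))
  t_cur <- 0
  debt <- 0  # cumulative deviation applied to onset-containing durations
  add_cycle <- function(s, d, holds) {
    start <<- c(start, s); dur <<- c(dur, d)
    holds_onset <<- c(holds_onset, holds)
  }
  for (k in seq_along(onsets)) {
    dk <- draw_dur(1)
    uk <- phase_to_frac(theta[k], f)
    on_k <- onsets[k] - uk * dk
    gap <- on_k - t_cur
    if (gap >= 0.45 * cm) {
      # free cycles tile the gap exactly; mild jitter keeps every tiling
      # cycle well above the detectable minimum duration
      m <- max(1L, round(gap / cm))
      w <- exp(stats::rnorm(m, 0, 0.08))
      w <- w / sum(w) * gap
      start <- c(start, t_cur + c(0, cumsum(w[-m])))
      dur <- c(dur, w)
      holds_onset <- c(holds_onset, rep(FALSE, m))
    } else {
      # small or negative gap: absorb it without touching any cycle that
      # holds an earlier onset (its geometry fixes that trial's phase).
      # Candidate absorbers: adjust the previous free cycle; stretch this
      # cycle to start at t_cur (no filler); shrink it and insert a
      # full-length filler. Pick whichever distorts a duration least, so
      # onset-containing cycles stay unbiased around the nominal mean.
      done <- FALSE
      nc <- length(dur)
      if (nc > 0 && !holds_onset[nc]) {
        nd <- dur[nc] + gap
        if (nd >= 0.45 * cm && nd <= 1.9 * cm) {
          dur[nc] <- nd; done <- TRUE
        }
      }
      if (!done && uk > 0.02) {
        L <- onsets[k] - t_cur
        d_solve <- L / uk                       # no filler
        ok_solve <- d_solve >= 0.45 * cm && d_solve <= 1.9 * cm
        d_lo <- max(0.45 * cm, (L - 1.9 * cm) / uk)
        d_hi <- min(1.9 * cm, (L - 0.45 * cm) / uk)
        d_fill <- min(max(dk, d_lo), d_hi)      # with filler >= 0.45 cm
        ok_fill <- d_lo <= d_hi
        # when both absorbers are feasible, pick the one that moves the
        # running sum of applied duration deviations toward zero, so the
        # onset-containing cycles stay unbiased around the nominal mean
        use_solve <- if (ok_solve && ok_fill) {
          abs(debt + d_solve - dk) <= abs(debt + d_fill - dk)
        } else ok_solve
        if (use_solve) {
          debt <- debt + d_solve - dk
          dk <- d_solve; on_k <- t_cur; done <- TRUE
        } else if (ok_fill) {
          debt <- debt + d_fill - dk
          dk <- d_fill
          on_k <- onsets[k] - uk * dk
          add_cycle(t_cur, on_k - t_cur, FALSE)
          done <- TRUE
        }
      }
      if (!done && k > 1 && length(dur) >= 2 &&
          holds_onset[length(dur)] && !holds_onset[length(dur) - 1]) {
        # chained absorber: rescale the previous onset-holding cycle about
        # its own onset (keeping that trial's phase exact) so that it ends
        # at on_k, and let the free cycle before it take up the slack
        nc <- length(dur)
        u_prev <- phase_to_frac(theta[k - 1], f)
        if (u_prev < 1 - 1e-6) {
          d_new <- (on_k - onsets[k - 1]) / (1 - u_prev)
          s_new <- onsets[k - 1] - u_prev * d_new
          nd_free <- s_new - start[nc - 1]
          if (d_new >= 0.45 * cm && d_new <= 1.9 * cm &&
              nd_free >= 0.45 * cm && nd_free <= 1.9 * cm) {
            debt <- debt + d_new - dur[nc]
            dur[nc - 1] <- nd_free
            start[nc] <- s_new
            dur[nc] <- d_new
            done <- TRUE
          }
        }
      }
      if (!done && abs(gap) > 1e-9) {
        # last resort: start this cycle at the current trough (lengthening
        # it if the onset would otherwise fall outside) and record the
        # deviation from the drawn onset phase, rather than emit an
        # unrealistically short cycle
        on_k <- t_cur
        dk <- max(dk, (onsets[k] - t_cur) / 0.98)
        clamped[k] <- TRUE
      }
    }
    add_cycle(on_k, dk, TRUE)
    t_cur <- on_k + dk
  }
  t_end <- onsets[length(onsets)] + tail_s
  while (t_cur < t_end) {
    d <- draw_dur(1)
    start <- c(start, t_cur); dur <- c(dur, d)
    t_cur <- t_cur + d
  }

  cyc_end <- start + dur
  peak <- start + f * dur
  n_samp <- floor(t_cur * fs)
  tg <- (seq_len(n_samp) - 1) / fs
  idx <- findInterval(tg, start)
  idx[idx < 1] <- 1L
  u <- (tg - start[idx]) / dur[idx]
  phi <- ifelse(u < f, pi * u / f, pi + pi * (u - f) / (1 - f))
  # amplitude gain drifts smoothly, anchored at the boundary troughs, so
  # the waveform has no discontinuities at cycle boundaries
  gnode <- exp(stats::rnorm(length(dur) + 1, 0, coupling$amp_jitter))
  gain <- stats::approx(c(start, t_cur), gnode, xout = tg, rule = 2)$y
  x <- -cos(phi) * gain + stats::rnorm(n_samp, 0, coupling$noise_sd)

  trace <- respiration_trace(x, fs = fs, t0 = 0)
  attr(trace, "truth") <- list(
    cycles = data.frame(onset_s = start, peak_s = peak, end_s = cyc_end),
    onset_phase = theta, clamped = clamped)
  trace
}

#' Behavioral outcome specification
#'
#' Shifted-lognormal reaction times per condition (`rt = rt_location_s +
#' lognormal(log(rt_scale), rt_shape)`), Bernoulli accuracy, and a
#' per-condition miss probability (no response).
#'
#' @param conditions condition labels the spec covers.
#' @param rt_location_s shift of the RT distribution, seconds (>= 0);
#'   scalar or one value per condition.
#' @param rt_scale scale (median of the lognormal part), seconds.
#' @param rt_shape lognormal sdlog.
#' @param accuracy_prob probability of a correct response, in `[0, 1]`.
#' @param miss_prob probability of no response, in `[0, 1]`.
#' @return an object of class `behavior_spec`.
#' @export
behavior_spec <- function(conditions, rt_location_s, rt_scale,
                          rt_shape = 0.4, accuracy_prob, miss_prob = 0) {
  rep_cond <- function(x) {
    if (length(x) == 1) x <- rep(x, length(conditions))
    stats::setNames(x, conditions)
  }
  spec <- list(conditions = conditions,
               rt_location_s = rep_cond(rt_location_s),
               rt_scale = rep_cond(rt_scale),
               rt_shape = rep_cond(rt_shape),
               accuracy_prob = rep_cond(accuracy_prob),
               miss_prob = rep_cond(miss_prob))
  if (any(spec$rt_location_s < 0)) stop("rt_location_s must be >= 0")
  if (any(spec$accuracy_prob < 0 | spec$accuracy_prob > 1) ||
      any(spec$miss_prob < 0 | spec$miss_prob > 1))
    stop("probabilities must lie in [0, 1]")
  class(spec) <- "behavior_spec"
  spec
}

#' Default behavioral parameters per experiment
#'
#' Effect sizes chosen to mimic the group-mean reaction times and accuracy
#' of the three paradigms (e.g. mean RT near 0.46 s under the SHORT
#' deadline vs 0.62 s under LONG, with lower accuracy and more misses
#' under SHORT).
#'
#' @param experiment 1, 2 or 3.
#' @return a [behavior_spec()].
#' @export
default_behavior_spec <- function(experiment = 1) {
  lnorm_scale <- function(mean_rt, loc, shape) (mean_rt - loc) / exp(shape^2 / 2)
  if (experiment == 1) {
    behavior_spec(conditions = c("SHORT", "LONG"),
                  rt_location_s = c(0.28, 0.36),
                  rt_scale = c(lnorm_scale(0.461, 0.28, 0.4),
                               lnorm_scale(0.618, 0.36, 0.4)),
                  rt_shape = 0.4,
                  accuracy_prob = c(0.907, 0.968),
                  miss_prob = c(0.10, 0.01))
  } else if (experiment == 2) {
    behavior_spec(conditions = c("high", "low"),
                  rt_location_s = 0.55,
                  rt_scale = c(lnorm_scale(1.254, 0.55, 0.4),
                               lnorm_scale(1.233, 0.55, 0.4)),
                  rt_shape = 0.4,
                  accuracy_prob = c(0.805, 0.800),
                  miss_prob = 0.02)
  } else {
    behavior_spec(conditions = c("high", "low"),
                  rt_location_s = 0.55,
                  rt_scale = c(lnorm_scale(1.158, 0.55, 0.4),
                               lnorm_scale(1.140, 0.55, 0.4)),
                  rt_shape = 0.4,
                  accuracy_prob = c(0.743, 0.757),
                  miss_prob = 0.02)
  }
}

#' Fill behavioral outcomes into a trial schedule
#'
#' @param schedule trial table from [gen_schedule()].
#' @param spec a [behavior_spec()] covering every condition in the schedule.
#' @param seed integer seed.
#' @return the schedule with `rt_s`, `correct` and `responded` filled;
#'   missed trials carry `rt_s = NA` and `correct = NA`.
#' @export
gen_behavior <- function(schedule, spec, seed = 1) {
  stopifnot(inherits(spec, "behavior_spec"))
  unknown <- setdiff(unique(schedule$condition), spec$conditions)
  if (length(unknown) > 0)
    stop("behavior spec does not cover condition(s): ",
         paste(unknown, collapse = ", "))
  set.seed(seed)
  n <- nrow(schedule)
  cond <- schedule$condition
  rt <- spec$rt_location_s[cond] +
    stats::rlnorm(n, log(spec$rt_scale[cond]), spec$rt_shape[cond])
  responded <- stats::runif(n) >= spec$miss_prob[cond]
  correct <- stats::runif(n) < spec$accuracy_prob[cond]
  schedule$rt_s <- ifelse(responded, rt, NA_real_)
  schedule$correct <- ifelse(responded, correct, NA)
  schedule$responded <- responded
  schedule
}

#' Simulate one participant end to end
#'
#' Convenience wrapper fanning a master seed out into independent
#' substreams for the schedule, the respiration trace and the behavior.
#'
#' @param paradigm a [paradigm_spec()].
#' @param coupling a [coupling_spec()].
#' @param behavior a [behavior_spec()].
#' @param fs respiration sampling rate, Hz.
#' @param seed master seed.
#' @return list with `trials` (trial table) and `trace`
#'   (a [respiration_trace()] with generator ground truth attached).
#' @export
simulate_participant <- function(paradigm, coupling, behavior, fs = 1000,
                                 seed = 1) {
  trials <- gen_schedule(paradigm, seed = derive_seed(seed, "schedule"))
  trace <- gen_respiration(trials, coupling, fs = fs,
                           seed = derive_seed(seed, "respiration"))
  trials <- gen_behavior(trials, behavior, seed = derive_seed(seed, "behavior"))
  list(trials = trials, trace = trace)
}
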