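# Phase-locking vector strength, surrogate and cluster-permutation
# inference, plvs slope, paired effect sizes.

#' Phase-locking vector strength over an epoch
#'
#' At each relative time point t, the trial phases are mapped to unit
#' complex numbers and averaged; the modulus of that average is the plvs:
#' 1 when every trial shares the same phase, 0 for uniformly dispersed
#' phases. Invalid cells are excluded with the trial count adjusted; time
#' points with fewer than `min_trials` valid trials are reported as NA
#' (undefined), never as 0.
#'
#' @param epochs an `epoched_phase`.
#' @param min_trials minimum number of valid trials per time point.
#' @return numeric plvs trace in `[0, 1]` with attributes `time_s` and
#'   `n_trials` (valid-trial count per time point).
#' @export
plvs <- function(epochs, min_trials = 10) {
  stopifnot(inherits(epochs, "epoched_phase"))
  Z <- exp(1i * epochs$phase)
  Z[!epochs$valid] <- 0
  n_t <- colSums(epochs$valid)
  v <- Mod(colSums(Z)) / n_t
  v[n_t < min_trials] <- NA_real_
  attr(v, "time_s") <- epochs$time_s
  attr(v, "n_trials") <- n_t
  v
}

#' Extract a plvs value at a given relative time
#'
#' @param trace plvs trace from [plvs()] (with a `time_s` attribute).
#' @param t relative time, seconds.
#' @return the plvs at the grid point nearest to `t`.
#' @export
plvs_at <- function(trace, t) {
  ts <- attr(trace, "time_s")
  as.numeric(trace[which.min(abs(ts - t))])
}

#' Time-shift surrogate null with max-over-time correction
#'
#' Destroys event-locking while preserving each trial's phase content:
#' every iteration circularly shifts each trial's phase epoch by an
#' independent uniform lag within the window, recomputes each
#' participant's plvs trace, averages across participants and records the
#' maximum over time. The corrected significance threshold is the
#' `conf` quantile of these maxima, so any time point where the observed
#' group-mean plvs exceeds it is significant at p < 1 - `conf`, corrected
#' for multiple comparisons over time.
#'
#' @param epoch_list list of `epoched_phase` objects, one per participant.
#' @param n_iter number of surrogate iterations.
#' @param conf confidence level of the corrected threshold.
#' @param min_trials minimum valid trials per time point for a defined plvs.
#' @param seed integer seed.
#' @return list with `threshold`, `max_dist` (surrogate maxima),
#'   `observed` (group-mean plvs trace), `significant` (logical per time
#'   point), `time_s`, `n_iter`, `conf`.
#' @export
surrogate_threshold <- function(epoch_list, n_iter = 4000, conf = 0.99,
                                min_trials = 10, seed = NULL) {
  stopifnot(length(epoch_list) >= 1,
            all(vapply(epoch_list, inherits, TRUE, "epoched_phase")))
  if (n_iter < 100) warning("n_iter < 100: surrogate quantile will be unstable")
  Tn <- length(epoch_list[[1]]$time_s)
  if (!all(vapply(epoch_list, function(e) length(e$time_s), 1L) == Tn))
    stop("all participants must share the same epoch time axis")
  obs <- rowMeans(vapply(epoch_list, function(e) plvs(e, min_trials),
                         numeric(Tn)), na.rm = TRUE)
  obs[is.nan(obs)] <- NA_real_
  # time x trial complex matrices; NaN marks invalid cells
  zmats <- lapply(epoch_list, function(e) {
    Z <- exp(1i * t(e$phase))
    Z[t(!e$valid)] <- complex(real = NaN, imaginary = NaN)
    Z
  })
  if (!is.null(seed)) set.seed(seed)
  mx <- surrogate_max_cpp(zmats, as.integer(n_iter), as.integer(min_trials))
  thr <- stats::quantile(mx, conf, names = FALSE, na.rm = TRUE)
  list(threshold = thr, max_dist = mx, observed = obs,
       significant = !is.na(obs) & obs > thr,
       time_s = epoch_list[[1]]$time_s, n_iter = n_iter, conf = conf)
}

# Supra-threshold runs of consistent sign, at least k_min samples long.
# tvec may contain NA (dropped time points), which break runs.
cluster_runs <- function(tvec, crit, k_min) {
  code <- integer(length(tvec))
  code[!is.na(tvec) & tvec > crit] <- 1L
  code[!is.na(tvec) & tvec < -crit] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= k_min
  data.frame(start = starts[keep], end = ends[keep],
             sum_t = vapply(which(keep),
                            function(j) sum(tvec[starts[j]:ends[j]]), 0))
}

max_cluster_stat <- function(tvec, crit, k_min) {
  cl <- cluster_runs(tvec, crit, k_min)
  if (nrow(cl) == 0) 0 else max(abs(cl$sum_t))
}

#' Cluster-based sign-flip permutation test on paired plvs traces
#'
#' Compares two condition plvs traces within participants. At each time
#' point a paired t statistic of the difference is computed; candidate
#' clusters are maximal runs of contiguous samples whose |t| exceeds the
#' two-sided critical value at `alpha_form` with consistent sign and whose
#' extent is at least `min_cluster_s`. The cluster statistic is the sum of
#' t within the run (max-sum). The null distribution is the maximum
#' absolute cluster sum under independent per-participant sign flips of
#' the condition difference; p = (1 + exceedances) / (1 + n_rand), or the
#' exact proportion over all 2^P sign patterns with `exhaustive = TRUE`.
#' Cohen's D is reported at the time point of largest absolute group-mean
#' difference within each cluster (mean of differences / SD of
#' differences). Time points where any participant lacks a value are
#' dropped (complete-case over time) and break cluster contiguity.
#'
#' @param mat_a,mat_b participants x time matrices of plvs for the two
#'   conditions (paired rows).
#' @param time_s time axis, seconds.
#' @param n_rand number of sign-flip randomizations.
#' @param alpha_form two-sided alpha of the cluster-forming t threshold.
#' @param min_cluster_s minimum cluster extent, seconds.
#' @param seed integer seed.
#' @param exhaustive enumerate all 2^P sign patterns instead of sampling
#'   (P <= 16).
#' @return a `cluster_test` list: `clusters` data frame (`t_start_s`,
#'   `t_end_s`, `n_samples`, `sum_t`, `p`, `cohens_d`), `t_obs`, `crit`,
#'   `null_max`, and the settings used.
#' @export
cluster_permutation <- function(mat_a, mat_b, time_s, n_rand = 4000,
                                alpha_form = 0.05, min_cluster_s = 0.25,
                                seed = NULL, exhaustive = FALSE) {
  stopifnot(is.matrix(mat_a), is.matrix(mat_b),
            all(dim(mat_a) == dim(mat_b)), ncol(mat_a) == length(time_s))
  P <- nrow(mat_a)
  if (P < 2) stop("insufficient data: need >= 2 paired participants")
  D <- mat_a - mat_b
  ok_col <- colSums(is.na(D)) == 0
  D[, !ok_col] <- NA_real_
  dt <- stats::median(diff(time_s))
  k_min <- max(1L, as.integer(round(min_cluster_s / dt)))
  crit <- stats::qt(1 - alpha_form / 2, df = P - 1)

  mean_d <- colMeans(D)
  sd_d <- apply(D, 2, stats::sd)
  t_obs <- mean_d / (sd_d / sqrt(P))
  t_obs[!ok_col | sd_d == 0] <- NA_real_

  obs <- cluster_runs(t_obs, crit, k_min)

  if (exhaustive) {
    if (P > 16) stop("exhaustive enumeration limited to <= 16 participants")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), P)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_rand * P, replace = TRUE), n_rand, P)
  }
  R <- nrow(signs)
  # sign flips leave per-participant squared differences unchanged, so the
  # flipped t statistics follow from the flipped means and colMeans(D^2)
  m2 <- colMeans(D^2)
  mean_null <- signs %*% D / P
  var_null <- sweep(-mean_null^2, 2, m2, "+") * (P / (P - 1))
  var_null[var_null < 0] <- 0
  t_null <- mean_null / sqrt(var_null / P)
  t_null[, !ok_col] <- NA_real_
  null_max <- vapply(seq_len(R),
                     function(r) max_cluster_stat(t_null[r, ], crit, k_min), 0)

  if (nrow(obs) > 0) {
    obs$p <- vapply(obs$sum_t, function(s) {
      if (exhaustive) mean(null_max >= abs(s) - 1e-10)
      else (1 + sum(null_max >= abs(s) - 1e-10)) / (1 + R)
    }, 0)
    obs$cohens_d <- vapply(seq_len(nrow(obs)), function(j) {
      cols <- obs$start[j]:obs$end[j]
      jj <- cols[which.max(abs(mean_d[cols]))]
      mean_d[jj] / sd_d[jj]
    }, 0)
    clusters <- data.frame(t_start_s = time_s[obs$start],
                           t_end_s = time_s[obs$end],
                           n_samples = obs$end - obs$start + 1L,
                           sum_t = obs$sum_t, p = obs$p,
                           cohens_d = obs$cohens_d)
  } else {
    clusters <- data.frame(t_start_s = numeric(0), t_end_s = numeric(0),
                           n_samples = integer(0), sum_t = numeric(0),
                           p = numeric(0), cohens_d = numeric(0))
  }
  structure(list(clusters = clusters, t_obs = t_obs, crit = crit,
                 null_max = null_max, time_s = time_s,
                 n_randomizations = R, alpha_form = alpha_form,
                 min_cluster_s = min_cluster_s, exhaustive = exhaustive),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("cluster-based sign-flip permutation test (%d randomizations%s)\n",
              x$n_randomizations, if (x$exhaustive) ", exhaustive" else ""))
  if (nrow(x$clusters) == 0) cat("no significant clusters\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' plvs slope around stimulus onset
#'
#' Difference between the maximal plvs in the post-onset window and the
#' minimal plvs in the pre-onset window; indexes how sharply respiratory
#' alignment builds toward the event.
#'
#' @param trace plvs trace from [plvs()] or any numeric vector.
#' @param time_s time axis (taken from the trace's `time_s` attribute if
#'   missing).
#' @param pre_window,post_window length-2 windows, seconds, relative to
#'   onset; defaults (-2, -1) and (+1, +2).
#' @return `max(trace[post]) - min(trace[pre])`.
#' @export
plvs_slope <- function(trace, time_s = NULL, pre_window = c(-2, -1),
                       post_window = c(1, 2)) {
  if (is.null(time_s)) time_s <- attr(trace, "time_s")
  if (is.null(time_s)) stop("time_s required")
  if (pre_window[1] < min(time_s) - 1e-9 || post_window[2] > max(time_s) + 1e-9)
    stop("slope windows fall outside the epoch")
  pre <- trace[time_s >= pre_window[1] & time_s <= pre_window[2]]
  post <- trace[time_s >= post_window[1] & time_s <= post_window[2]]
  if (all(is.na(pre)) || all(is.na(post))) return(NA_real_)
  max(post, na.rm = TRUE) - min(pre, na.rm = TRUE)
}

#' Paired t test with Cohen's D
#'
#' Standard paired t test; Cohen's D is the mean of the paired differences
#' divided by their sample standard deviation (n - 1 denominator).
#'
#' @param a,b paired numeric vectors (per participant).
#' @return list with `t`, `p`, `cohens_d`, `df`, `n`, `mean_diff`, and
#'   `degenerate` (TRUE when the differences have zero variance with a
#'   nonzero mean, in which case `t` is NA and `cohens_d` infinite).
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2) stop("insufficient data: need >= 2 pairs")
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, p = 1, cohens_d = 0, df = n - 1, n = n,
                            mean_diff = 0, degenerate = FALSE))
    return(list(t = NA_real_, p = NA_real_, cohens_d = sign(m) * Inf,
                df = n - 1, n = n, mean_diff = m, degenerate = TRUE))
  }
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, cohens_d = m / s,
       df = unname(tt$parameter), n = n, mean_diff = m, degenerate = FALSE)
}
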