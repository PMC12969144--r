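# Cycle segmentation, atypical-cycle flagging, and the piecewise-linear
# respiratory phase.

#' Continuous respiration trace
#'
#' @param samples numeric amplitude values (arbitrary units), uniformly
#'   sampled with no gaps.
#' @param fs sampling rate, Hz (> 0).
#' @param t0 time of the first sample, seconds.
#' @return object of class `respiration_trace`.
#' @export
respiration_trace <- function(samples, fs, t0 = 0) {
  if (fs <= 0) stop("fs must be positive")
  if (anyNA(samples)) stop("trace contains missing samples (gaps)")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "respiration_trace")
}

#' @export
print.respiration_trace <- function(x, ...) {
  cat(sprintf("respiration_trace: %d samples at %g Hz (%.1f s, t0 = %g s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$t0))
  invisible(x)
}

trace_times <- function(trace) trace$t0 + (seq_along(trace$samples) - 1) / trace$fs

# Zero-phase low-pass used only for landmark detection; the raw trace is
# untouched and landmarks are refined on it afterwards.
smooth_for_landmarks <- function(x, fs, cutoff_hz = 2) {
  wc <- cutoff_hz / (fs / 2)
  if (wc >= 1) return(x)
  bf <- signal::butter(4, wc, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Strict local extrema as a trough/peak event sequence.
local_extrema <- function(x) {
  dd <- diff(sign(diff(x)))
  peaks <- which(dd < 0) + 1L
  troughs <- which(dd > 0) + 1L
  ev <- rbind(data.frame(i = peaks, type = 1L), data.frame(i = troughs, type = -1L))
  ev <- ev[order(ev$i), , drop = FALSE]
  ev
}

# Enforce alternation: among adjacent same-type events keep the more extreme.
enforce_alternation <- function(ev, x) {
  if (nrow(ev) < 2) return(ev)
  keep <- rep(TRUE, nrow(ev))
  last <- 1
  for (j in 2:nrow(ev)) {
    if (ev$type[j] == ev$type[last]) {
      better <- if (ev$type[j] == 1L) x[ev$i[j]] > x[ev$i[last]]
                else x[ev$i[j]] < x[ev$i[last]]
      if (better) { keep[last] <- FALSE; last <- j } else keep[j] <- FALSE
    } else last <- j
  }
  ev[keep, , drop = FALSE]
}

# Iteratively delete the weakest adjacent extrema pair until all swings
# clear the prominence floor and trough spacing clears min_cycle.
prune_landmarks <- function(ev, x, fs, min_swing, min_cycle_s) {
  drop_pair <- function(ev, j) ev[-c(j, j + 1L), , drop = FALSE]
  repeat {
    if (nrow(ev) < 3) break
    swing <- abs(diff(x[ev$i]))
    weak <- which(swing < min_swing)
    if (length(weak) > 0) {
      j <- weak[which.min(swing[weak])]
      # deleting an interior adjacent pair preserves alternation; at the
      # edges delete the single outer extremum instead
      if (j == 1) ev <- ev[-1, , drop = FALSE]
      else if (j == nrow(ev) - 1) ev <- ev[-nrow(ev), , drop = FALSE]
      else ev <- drop_pair(ev, j)
      ev <- enforce_alternation(ev, x)
      next
    }
    tr <- which(ev$type == -1L)
    if (length(tr) >= 2) {
      tt <- diff(ev$i[tr]) / fs
      short <- which(tt < min_cycle_s)
      if (length(short) > 0) {
        s <- short[which.min(tt[short])]
        j1 <- tr[s]; j2 <- tr[s + 1]
        # remove the weaker swing inside the short cycle
        sw1 <- abs(x[ev$i[j1 + 1]] - x[ev$i[j1]])
        sw2 <- abs(x[ev$i[j2]] - x[ev$i[j2 - 1]])
        j <- if (sw1 < sw2) j1 else j2 - 1L
        if (j == 1) ev <- ev[-1, , drop = FALSE]
        else if (j == nrow(ev) - 1) ev <- ev[-nrow(ev), , drop = FALSE]
        else ev <- drop_pair(ev, j)
        ev <- enforce_alternation(ev, x)
        next
      }
    }
    break
  }
  ev
}

#' Segment a respiration trace into breathing cycles
#'
#' Detects alternating trough-peak-trough landmarks on a zero-phase
#' low-pass copy of the trace (landmark detection only), rejects swings
#' below a prominence floor and cycles shorter than `min_cycle_s`, then
#' refines each landmark on the raw trace within +/-250 ms. Partial cycles
#' at the recording edges are dropped; consecutive cycles share their
#' boundary trough, so cycles tile the segmented span without overlap.
#'
#' @param trace a [respiration_trace()].
#' @param min_cycle_s minimum trough-to-trough duration, seconds.
#' @param min_prominence_frac minimum swing, as a fraction of the robust
#'   (5th-95th percentile) amplitude range.
#' @param smooth_cutoff_hz low-pass cutoff for landmark detection.
#' @return a `cycle_set` data frame: `onset_s`, `peak_s`, `end_s`,
#'   `distance` (NA until [flag_atypical()]), `atypical`.
#' @export
segment_cycles <- function(trace, min_cycle_s = 1.5, min_prominence_frac = 0.1,
                           smooth_cutoff_hz = 2) {
  stopifnot(inherits(trace, "respiration_trace"))
  x <- trace$samples
  if (length(x) / trace$fs < 3 * min_cycle_s)
    stop("segmentation failure: trace shorter than 3 minimum-length cycles")
  sm <- smooth_for_landmarks(x, trace$fs, smooth_cutoff_hz)
  rng <- diff(stats::quantile(sm, c(0.05, 0.95), names = FALSE))
  if (rng <= 0 || !is.finite(rng))
    stop("segmentation failure: flat trace, no respiratory cycles detectable")
  ev <- local_extrema(sm)
  ev <- enforce_alternation(ev, sm)
  ev <- prune_landmarks(ev, sm, trace$fs, min_prominence_frac * rng, min_cycle_s)
  # refine landmarks within +/-250 ms on a lightly denoised copy of the
  # raw trace (100 ms zero-phase moving average): the band-limited signal
  # used for detection can bias extremum times, while the raw trace is
  # noise-dominated on the flat extrema
  k <- max(1L, round(0.1 * trace$fs))
  xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- x[is.na(xs)]
  half <- round(0.25 * trace$fs)
  n <- length(x)
  idx <- ev$i
  for (j in seq_len(nrow(ev))) {
    lo <- max(1L, idx[j] - half, if (j > 1) idx[j - 1] + 1L else 1L)
    hi <- min(n, idx[j] + half, if (j < nrow(ev)) idx[j + 1] - 1L else n)
    w <- lo:hi
    idx[j] <- w[if (ev$type[j] == 1L) which.max(xs[w]) else which.min(xs[w])]
  }
  ev$i <- idx
  # refine the landmark time on the raw trace by fitting the local shape
  # model: two one-sided quadratics hinged at the extremum (inhale and
  # exhale curvature differ, so a plain parabola vertex is biased, and the
  # raw extremum sample is noise-dominated on the flat top/bottom). The
  # breakpoint is grid-searched at 10 ms resolution and the best-fitting
  # hinge position taken as the landmark time.
  cand <- unique(as.integer(round(seq(-0.2, 0.2, by = 0.01) * trace$fs)))
  frac <- numeric(nrow(ev))
  for (j in seq_len(nrow(ev))) {
    # window scales with the local landmark spacing (long shallow cycles
    # need more data to pin the flat extremum) but never reaches the
    # neighboring landmarks
    gprev <- if (j > 1) idx[j] - idx[j - 1] else Inf
    gnext <- if (j < nrow(ev)) idx[j + 1] - idx[j] else Inf
    gmin <- min(gprev, gnext)
    hv <- max(4L, round(min(0.45 * gmin,
                            max(0.35 * trace$fs, 0.30 * gmin))))
    lo <- max(1L, idx[j] - hv); hi <- min(n, idx[j] + hv)
    tt <- (lo:hi) - idx[j]
    y <- x[lo:hi] - mean(x[lo:hi])
    best <- Inf; vbest <- 0
    for (v in cand) {
      d <- tt - v
      B <- cbind(1, d^2 * (d < 0), d^2 * (d >= 0))
      co <- tryCatch(solve(crossprod(B), crossprod(B, y)),
                     error = function(e) NULL)
      if (is.null(co)) next
      # curvature sign must match the landmark type
      if (ev$type[j] == 1L && any(co[2:3] > 0)) next
      if (ev$type[j] == -1L && any(co[2:3] < 0)) next
      rss <- sum((y - B %*% co)^2)
      if (rss < best) { best <- rss; vbest <- v }
    }
    frac[j] <- vbest
  }
  # complete cycles: trough, peak, trough
  tr <- which(ev$type == -1L)
  if (length(tr) < 4)
    stop("segmentation failure: fewer than 3 complete cycles detected")
  lm_time <- trace_times(trace)[ev$i] + frac / trace$fs
  a <- tr[-length(tr)]; b <- tr[-1]
  good <- (b - a) == 2L & ev$type[a + 1L] == 1L
  cyc <- data.frame(onset_s = lm_time[a[good]],
                    peak_s = lm_time[a[good] + 1L],
                    end_s = lm_time[b[good]])
  if (nrow(cyc) < 3)
    stop("segmentation failure: fewer than 3 complete cycles detected")
  cyc$distance <- NA_real_
  cyc$atypical <- FALSE
  class(cyc) <- c("cycle_set", "data.frame")
  attr(cyc, "fs") <- trace$fs
  cyc
}

#' Flag atypical respiratory cycles
#'
#' Each cycle's waveform (amplitude z-scored over the whole recording) is
#' time-normalized to `n_points` samples; the centroid is the pointwise
#' mean over cycles and a cycle's distance is the mean squared deviation
#' from the centroid. Cycles whose distance exceeds the mean distance by
#' more than `z_thresh` standard deviations are flagged atypical (breath
#' holds, sighs). A degenerate spread (SD = 0, e.g. identical cycles)
#' flags nothing.
#'
#' @param cycles a `cycle_set` from [segment_cycles()].
#' @param trace the [respiration_trace()] the cycles came from.
#' @param n_points number of points in the time-normalized waveform.
#' @param z_thresh atypicality threshold in standard deviations.
#' @return the `cycle_set` with `distance` and `atypical` filled.
#' @export
flag_atypical <- function(cycles, trace, n_points = 100, z_thresh = 3) {
  stopifnot(inherits(cycles, "cycle_set"), inherits(trace, "respiration_trace"))
  if (nrow(cycles) < 10)
    stop("insufficient data: need >= 10 cycles for a stable centroid")
  z <- (trace$samples - mean(trace$samples)) / stats::sd(trace$samples)
  n <- length(z)
  wf <- t(vapply(seq_len(nrow(cycles)), function(i) {
    i0 <- max(1L, floor((cycles$onset_s[i] - trace$t0) * trace$fs) + 1L)
    i1 <- min(n, ceiling((cycles$end_s[i] - trace$t0) * trace$fs) + 1L)
    ts <- seq(cycles$onset_s[i], cycles$end_s[i], length.out = n_points)
    stats::approx(trace$t0 + (i0:i1 - 1) / trace$fs, z[i0:i1], xout = ts,
                  rule = 2)$y
  }, numeric(n_points)))
  centroid <- colMeans(wf)
  d <- rowMeans((wf - rep(centroid, each = nrow(wf)))^2)
  cycles$distance <- d
  sdd <- stats::sd(d)
  cycles$atypical <- if (sdd == 0) rep(FALSE, length(d))
                     else d > mean(d) + z_thresh * sdd
  cycles
}

#' Piecewise-linear respiratory phase at the analysis rate
#'
#' Within each cycle the phase rises linearly from 0 at inspiration onset
#' to pi at peak inhalation and from pi to 2*pi over expiration, wrapping
#' to 0 at the shared boundary trough (cycle membership is half-open:
#' `[onset, end)`). The phase is evaluated directly on the `fs_out` grid
#' anchored at t = 0 of the recording clock; no filtering or interpolation
#' of wrapped values is involved. Samples outside any complete cycle, or
#' inside an atypical one, are marked invalid.
#'
#' @param cycles a `cycle_set`, usually after [flag_atypical()].
#' @param fs_out analysis sampling rate, Hz.
#' @return a `phase_series`: list with `time_s`, `phase_rad` in
#'   `[0, 2*pi)`, logical `valid`, and `fs_out`.
#' @export
compute_phase <- function(cycles, fs_out = 20) {
  stopifnot(inherits(cycles, "cycle_set"))
  k0 <- ceiling(cycles$onset_s[1] * fs_out)
  k1 <- floor(cycles$end_s[nrow(cycles)] * fs_out)
  tg <- (k0:k1) / fs_out
  ph <- phase_at(cycles, tg)
  structure(list(time_s = tg, phase_rad = ph$phase, valid = ph$valid,
                 fs_out = fs_out),
            class = "phase_series")
}

#' Evaluate the piecewise-linear phase of a cycle set at arbitrary times
#'
#' @param cycles a `cycle_set`.
#' @param t times, seconds (recording clock).
#' @return list with `phase` (radians, NA where uncovered), `valid`
#'   (covered by a typical cycle), and `cycle` (row index, NA if none).
#' @export
phase_at <- function(cycles, t) {
  idx <- findInterval(t, cycles$onset_s)
  covered <- idx >= 1 & idx <= nrow(cycles)
  covered[covered] <- t[covered] < cycles$end_s[idx[covered]]
  phase <- rep(NA_real_, length(t))
  i <- idx[covered]
  ti <- t[covered]
  on <- cycles$onset_s[i]; pk <- cycles$peak_s[i]; en <- cycles$end_s[i]
  phase[covered] <- ifelse(ti < pk, pi * (ti - on) / (pk - on),
                           pi + pi * (ti - pk) / (en - pk))
  phase[covered] <- pmin(phase[covered], 2 * pi * (1 - 1e-12))
  valid <- covered
  valid[covered] <- !cycles$atypical[i]
  list(phase = phase, valid = valid, cycle = ifelse(covered, idx, NA_integer_))
}

#' Analytic-signal phase agreement (segmentation sanity check)
#'
#' Computes the instantaneous phase of the band-limited trace via the
#' analytic signal (FFT construction) and returns the mean resultant
#' length of its circular difference from the landmark-based phase: values
#' near 1 mean the two notions of respiratory phase agree up to a constant
#' offset.
#'
#' @param trace a [respiration_trace()].
#' @param cycles the `cycle_set` segmented from it.
#' @return mean resultant length of the phase difference, in `[0, 1]`.
#' @export
hilbert_agreement <- function(trace, cycles) {
  x <- smooth_for_landmarks(trace$samples, trace$fs)
  n <- length(x)
  X <- stats::fft(x - mean(x))
  h <- numeric(n); h[1] <- 1
  if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else h[2:((n + 1) / 2)] <- 2
  z <- stats::fft(X * h, inverse = TRUE) / n
  hphase <- Arg(z) %% (2 * pi)
  lm <- phase_at(cycles, trace_times(trace))
  ok <- lm$valid & !is.na(lm$phase)
  dphi <- lm$phase[ok] - hphase[ok]
  Mod(mean(exp(1i * dphi)))
}
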