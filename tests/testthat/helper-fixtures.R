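# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Epoched phase object from an explicit trials x time phase matrix.
make_epochs <- function(phase, valid = NULL, fs = 20, t_zero_col = NULL,
                        condition = "A") {
  n <- nrow(phase); Tn <- ncol(phase)
  if (is.null(valid)) valid <- matrix(TRUE, n, Tn)
  if (is.null(t_zero_col)) t_zero_col <- (Tn + 1) %/% 2
  structure(list(phase = phase, valid = valid,
                 time_s = ((seq_len(Tn) - t_zero_col)) / fs,
                 onset_s = seq_len(n),
                 condition = rep_len(condition, n), fs_out = fs),
            class = "epoched_phase")
}

# Epochs whose phase at t = 0 is von Mises(mu, kappa); other time points
# carry independent uniform phases (only the t = 0 column matters).
vm_epochs <- function(n, kappa, mu = pi, Tn = 41) {
  ph <- matrix(stats::runif(n * Tn, 0, 2 * pi), n, Tn)
  i0 <- (Tn + 1) %/% 2
  ph[, i0] <- rvonmises(n, mu, kappa)
  make_epochs(ph, t_zero_col = i0)
}

# Free-running respiration-like epochs: wrapped phase ramps with uniform
# random offsets per trial; their plvs traces are smooth and carry no
# event locking (exchangeable null for condition contrasts).
ramp_epochs <- function(n, Tn, fs = 20, f_mean = 0.27, f_sd = 0.03) {
  tt <- (seq_len(Tn) - 1) / fs
  f <- stats::rnorm(n, f_mean, f_sd)
  ph <- (matrix(stats::runif(n, 0, 2 * pi), n, Tn) +
           2 * pi * outer(f, tt)) %% (2 * pi)
  make_epochs(ph)
}

# Cycle set built directly from landmark times (bypasses segmentation).
make_cycle_set <- function(onset, peak, end, atypical = FALSE) {
  cyc <- data.frame(onset_s = onset, peak_s = peak, end_s = end,
                    distance = NA_real_,
                    atypical = rep_len(atypical, length(onset)))
  class(cyc) <- c("cycle_set", "data.frame")
  cyc
}

# Trace made of half-cosine cycles with given durations (and optional
# per-cycle amplitude gains); returns the trace and its true cycle set.
cosine_cycle_trace <- function(durations, gains = 1, fs = 50,
                               inhale_frac = 0.5, noise_sd = 0) {
  gains <- rep_len(gains, length(durations))
  start <- c(0, cumsum(durations))[seq_along(durations)]
  total <- sum(durations)
  tg <- (0:floor(total * fs)) / fs
  idx <- pmin(findInterval(tg, start), length(durations))
  u <- (tg - start[idx]) / durations[idx]
  phi <- ifelse(u < inhale_frac, pi * u / inhale_frac,
                pi + pi * (u - inhale_frac) / (1 - inhale_frac))
  x <- -cos(phi) * gains[idx]
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  list(trace = respiration_trace(x, fs = fs),
       cycles = make_cycle_set(start, start + inhale_frac * durations,
                               start + durations))
}

# Small simulated participant used by several files.
small_participant <- function(seed = 5, n_trials = 60, fs = 250,
                              kappa = c(SHORT = 3, LONG = 1)) {
  simulate_participant(paradigm_spec(1, n_trials = n_trials),
                       coupling_spec(kappa = kappa),
                       default_behavior_spec(1), fs = fs, seed = seed)
}

# Independent brute-force max-cluster statistic used as the oracle for
# the sign-flip permutation test.
oracle_max_cluster <- function(D, crit, k_min) {
  P <- nrow(D)
  tv <- colMeans(D) / (apply(D, 2, stats::sd) / sqrt(P))
  sup <- ifelse(tv > crit, 1L, ifelse(tv < -crit, -1L, 0L))
  r <- rle(sup); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  keep <- r$values != 0L & r$lengths >= k_min
  if (!any(keep)) return(0)
  max(abs(vapply(which(keep), function(j) sum(tv[s[j]:e[j]]), 0)))
}
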