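# Circular phase statistics, angular randomization test, cycle-duration
# contrasts, and behavior-respiration difference correlations.

#' Circular mean and resultant length
#'
#' @param phases angles in radians (non-empty; NAs dropped).
#' @return list with `mean_angle` (radians in `[0, 2*pi)`, NA when
#'   undefined), `resultant` (mean resultant length in `[0, 1]`), `n`, and
#'   `defined` (FALSE when the resultant vanishes, e.g. antipodal phases).
#' @export
circ_mean <- function(phases) {
  phases <- phases[!is.na(phases)]
  if (length(phases) == 0) stop("circ_mean needs at least one phase")
  z <- mean(exp(1i * phases))
  rho <- Mod(z)
  defined <- rho > 1e-9
  list(mean_angle = if (defined) wrap_phase(Arg(z)) else NA_real_,
       resultant = rho, n = length(phases), defined = defined)
}

#' Rayleigh test of circular uniformity
#'
#' @param phases angles in radians.
#' @return list with `r` (resultant length), `z` (n * r^2) and the
#'   finite-n corrected `p` value.
#' @export
rayleigh_test <- function(phases) {
  phases <- phases[!is.na(phases)]
  n <- length(phases)
  if (n < 2) stop("rayleigh_test needs >= 2 phases")
  r <- Mod(mean(exp(1i * phases)))
  z <- n * r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(r = r, z = z, p = min(max(p, 0), 1))
}

#' Per-participant circular phase summary at stimulus onset
#'
#' Computes each participant's trial-averaged respiratory phase (circular
#' mean of the phase at t = 0 over included trials) per condition, and the
#' wrapped angular condition difference.
#'
#' @param epoch_list list of `epoched_phase` objects, one per participant.
#' @param conditions length-2 character, the conditions to contrast.
#' @return list with `summary` (data frame: participant, condition,
#'   mean_angle_rad, resultant, n_trials) and `difference` (per-participant
#'   wrapped angle `conditions[1] - conditions[2]`, in `(-pi, pi]`).
#' @export
circular_summary <- function(epoch_list, conditions) {
  stopifnot(length(conditions) == 2)
  rows <- list(); diffs <- numeric(length(epoch_list))
  for (p in seq_along(epoch_list)) {
    e <- epoch_list[[p]]
    i0 <- which.min(abs(e$time_s))
    ang <- c(NA_real_, NA_real_)
    for (ci in 1:2) {
      sel <- e$condition == conditions[ci] & e$valid[, i0]
      cm <- circ_mean(e$phase[sel, i0])
      ang[ci] <- cm$mean_angle
      rows[[length(rows) + 1]] <- data.frame(
        participant = p, condition = conditions[ci],
        mean_angle_rad = cm$mean_angle, resultant = cm$resultant,
        n_trials = cm$n)
    }
    diffs[p] <- wrap_angle(ang[1] - ang[2])
  }
  list(summary = do.call(rbind, rows), difference = diffs)
}

#' Angular condition-difference randomization test with percentile CI
#'
#' Tests whether the per-participant angular condition differences share a
#' nonzero mean direction. The test statistic is the mean of the wrapped
#' differences (equal to the circular mean direction to first order for
#' small differences); the null distribution flips the sign of each
#' participant's difference independently, and
#' p = (1 + exceedances) / (1 + n_rand). The confidence interval is a
#' percentile bootstrap over participants of the same statistic.
#'
#' @param diffs per-participant wrapped angular differences, radians in
#'   `(-pi, pi]`.
#' @param n_rand number of sign-flip randomizations (and bootstrap
#'   resamples).
#' @param conf CI confidence level.
#' @param seed integer seed.
#' @param exhaustive enumerate all 2^P sign patterns (P <= 20).
#' @return list with `mean_diff` (radians), `ci` (percentile bounds), `p`,
#'   `n`, `n_rand`.
#' @export
angular_difference_test <- function(diffs, n_rand = 4000, conf = 0.95,
                                    seed = NULL, exhaustive = FALSE) {
  diffs <- diffs[!is.na(diffs)]
  P <- length(diffs)
  if (P < 3) stop("insufficient data: need >= 3 participants")
  obs <- mean(diffs)
  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    if (P > 20) stop("exhaustive enumeration limited to <= 20 participants")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), P)))
    null_stat <- abs(signs %*% diffs / P)
    p <- mean(null_stat >= abs(obs) - 1e-12)
  } else {
    signs <- matrix(sample(c(-1, 1), n_rand * P, replace = TRUE), n_rand, P)
    null_stat <- abs(signs %*% diffs / P)
    p <- (1 + sum(null_stat >= abs(obs) - 1e-12)) / (1 + n_rand)
  }
  boot <- vapply(seq_len(n_rand), function(b) {
    mean(diffs[sample.int(P, P, replace = TRUE)])
  }, 0)
  ci <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(mean_diff = obs, ci = ci, p = p, n = P,
       n_rand = if (exhaustive) nrow(signs) else n_rand)
}

#' Group contrast of trial-averaged cycle durations
#'
#' Paired t test (with Cohen's D) of per-participant trial-mean
#' respiratory cycle durations between two conditions.
#'
#' @param dur_a,dur_b per-participant mean cycle durations, seconds.
#' @return as [paired_t()].
#' @export
duration_contrast <- function(dur_a, dur_b) paired_t(dur_a, dur_b)

#' Spearman correlation of condition differences
#'
#' Rank correlation (tie-adjusted) between per-participant condition
#' differences in a respiratory measure and in a behavioral measure, with
#' a two-sided p value.
#'
#' @param x_diff,y_diff paired numeric vectors, one value per participant
#'   (n >= 5).
#' @return list with `r`, `p`, `n`; `r` is NA (flagged) when either
#'   vector is constant.
#' @export
diff_correlation <- function(x_diff, y_diff) {
  ok <- !is.na(x_diff) & !is.na(y_diff)
  x <- x_diff[ok]; y <- y_diff[ok]
  if (length(x) < 5) stop("insufficient data: need >= 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), constant = TRUE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       constant = FALSE)
}
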