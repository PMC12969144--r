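test_that("circular means match hand computations", {
  cm <- circ_mean(rep(pi / 4, 3))
  expect_equal(cm$mean_angle, pi / 4)
  expect_equal(cm$resultant, 1)
  anti <- circ_mean(c(0, pi))
  expect_false(anti$defined)
  expect_true(is.na(anti$mean_angle))
  expect_lt(anti$resultant, 1e-9)
  two <- circ_mean(c(0, pi / 2))
  expect_equal(two$mean_angle, pi / 4)
  expect_equal(two$resultant, sqrt(2) / 2)
})

test_that("the rayleigh test separates uniform from concentrated phases", {
  set.seed(5)
  expect_gt(rayleigh_test(runif(300, 0, 2 * pi))$p, 0.01)
  expect_lt(rayleigh_test(rvonmises(300, 1, 3))$p, 1e-6)
})

test_that("angular difference test matches exhaustive enumeration", {
  # unanimous +pi/2 differences: only the two all-same-sign patterns
  # reach the observed magnitude
  at <- angular_difference_test(rep(pi / 2, 10), exhaustive = TRUE, seed = 2)
  expect_equal(at$p, 2 / 2^10)
  # sampled p respects the never-zero +1 convention and stays near the
  # exhaustive value
  at2 <- angular_difference_test(rep(pi / 2, 10), n_rand = 1000, seed = 2)
  expect_gte(at2$p, 1 / 1001)
  expect_lte(at2$p, 0.02)
  # general fixture against an independent enumeration
  set.seed(9)
  d <- rnorm(10, 0.2, 0.3)
  at3 <- angular_difference_test(d, exhaustive = TRUE)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  p_bf <- mean(abs(signs %*% d / 10) >= abs(mean(d)) - 1e-12)
  expect_equal(at3$p, p_bf)
  # identical conditions: zero difference, p of 1
  at0 <- angular_difference_test(rep(0, 8), n_rand = 500, seed = 1)
  expect_equal(at0$mean_diff, 0)
  expect_equal(at0$p, 1)
  expect_equal(at0$ci, c(0, 0))
  expect_error(angular_difference_test(c(0.1, 0.2)), "insufficient")
})

test_that("angular statistics are rotation-equivariant", {
  set.seed(11)
  Tn <- 21; n <- 40
  mk <- function(mu_a, mu_b, rot = 0) {
    ph <- matrix(runif(n * Tn, 0, 2 * pi), n, Tn)
    i0 <- 11
    ph[1:20, i0] <- rvonmises(20, mu_a, 6)
    ph[21:40, i0] <- rvonmises(20, mu_b, 6)
    make_epochs(wrap_phase(ph + rot), t_zero_col = i0,
                condition = rep(c("A", "B"), each = 20))
  }
  eps0 <- lapply(1:6, function(p) { set.seed(p); mk(2, 2.4) })
  eps1 <- lapply(1:6, function(p) { set.seed(p); mk(2, 2.4, rot = 1.1) })
  s0 <- circular_summary(eps0, c("A", "B"))
  s1 <- circular_summary(eps1, c("A", "B"))
  # means shift by the rotation; paired differences are unchanged
  expect_equal(wrap_angle(s1$summary$mean_angle_rad -
                            s0$summary$mean_angle_rad),
               rep(1.1, 12), tolerance = 1e-9)
  expect_equal(s0$difference, s1$difference, tolerance = 1e-9)
  t0 <- angular_difference_test(s0$difference, n_rand = 400, seed = 3)
  t1 <- angular_difference_test(s1$difference, n_rand = 400, seed = 3)
  expect_equal(t0$p, t1$p)
})

test_that("the bootstrap CI covers a planted angular difference", {
  set.seed(42)
  hits <- 0; nrep <- 100
  for (r in 1:nrep) {
    d <- wrap_angle(rvonmises(24, 0.5, 8))
    ci <- angular_difference_test(d, n_rand = 400)$ci
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hits <- hits + 1
  }
  # nominal 95%; allow 3 binomial SEs at 100 replicates
  expect_gte(hits / nrep, 0.95 - 3 * sqrt(0.95 * 0.05 / nrep))
})

test_that("type-I error of the angular test is nominal under a symmetric null", {
  set.seed(42)
  rej <- 0; nrep <- 500
  for (r in 1:nrep) {
    d <- rnorm(12, 0, 0.3)
    if (angular_difference_test(d, n_rand = 300)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / nrep, 0.03)
  expect_lte(rej / nrep, 0.07)
})

test_that("cycle-duration contrasts detect a planted group difference", {
  # per-participant onset-cycle durations from generator truth, nominal
  # means 3.8 vs 4.0 s
  set.seed(42)
  sig <- 0; nrep <- 8
  for (r in 1:nrep) {
    mk <- function(cm, seed) {
      sch <- gen_schedule(paradigm_spec(1, n_trials = 30), seed = seed)
      tr <- gen_respiration(sch, coupling_spec(kappa = 1, cycle_mean_s = cm),
                            fs = 100, seed = seed + 1)
      cyc <- attr(tr, "truth")$cycles
      out <- cycle_duration_at_onset(sch, make_cycle_set(cyc$onset_s,
                                                         cyc$peak_s,
                                                         cyc$end_s))
      mean(out$cycle_duration_s, na.rm = TRUE)
    }
    base <- r * 1000
    a <- vapply(1:24, function(p) mk(3.8, base + 2 * p), 0)
    b <- vapply(1:24, function(p) mk(4.0, base + 2 * p + 1), 0)
    ct <- duration_contrast(b, a)
    if (ct$p < 0.05 && ct$t > 0) sig <- sig + 1
  }
  expect_gte(sig, 7)
  # a condition contrasted with itself has no effect
  self <- duration_contrast(c(3.8, 3.9, 4.0), c(3.8, 3.9, 4.0))
  expect_equal(self$t, 0)
  expect_equal(self$cohens_d, 0)
})

test_that("spearman difference correlations behave as rank statistics", {
  x <- c(0.3, -0.1, 0.8, 0.2, 0.5, -0.4)
  expect_equal(diff_correlation(x, x)$r, 1)
  expect_equal(diff_correlation(x, -x)$r, -1)
  fix <- diff_correlation(1:5, c(3, 1, 2, 5, 4))
  expect_equal(fix$r, 0.6)
  # invariance under monotone transforms of either variable
  y <- c(2, 0.4, 1, 9, 4, 0.1)
  expect_equal(diff_correlation(x, y)$r,
               diff_correlation(exp(x), y^(1 / 3))$r)
  const <- diff_correlation(rep(1, 6), y)
  expect_true(const$constant)
  expect_true(is.na(const$r))
  expect_error(diff_correlation(1:3, 3:1), "insufficient")
})
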