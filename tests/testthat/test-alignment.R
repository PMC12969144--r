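test_that("plvs matches hand-computed values and handles masking", {
  i0 <- 3
  ep1 <- make_epochs(matrix(1.3, 8, 5))
  expect_equal(as.numeric(plvs(ep1, min_trials = 2)), rep(1, 5))
  ep2 <- make_epochs(matrix(rep(c(0, pi / 2, pi, 3 * pi / 2), 5), 4, 5))
  expect_equal(as.numeric(plvs(ep2, min_trials = 2)), rep(0, 5))
  ep3 <- make_epochs(matrix(rep(c(0, pi / 2), 5), 2, 5))
  expect_equal(as.numeric(plvs(ep3, min_trials = 2)),
               rep(sqrt(2) / 2, 5))
  # below min_trials the plvs is undefined (NA), not zero
  expect_true(all(is.na(plvs(ep3, min_trials = 10))))
  # masked cells are excluded with the count adjusted
  ph <- matrix(c(0, 0, pi), 3, 4)
  vv <- matrix(TRUE, 3, 4); vv[3, 2] <- FALSE
  ep4 <- make_epochs(ph, valid = vv)
  out <- plvs(ep4, min_trials = 2)
  expect_equal(as.numeric(out[2]), 1)          # only the two aligned trials
  expect_equal(as.numeric(out[1]), 1 / 3)      # |2 - 1| / 3
  expect_equal(attr(out, "n_trials"), c(3, 2, 3, 3))
})

test_that("plvs is invariant under global phase rotation", {
  set.seed(2)
  ph <- matrix(runif(40 * 21, 0, 2 * pi), 40, 21)
  a <- plvs(make_epochs(ph), min_trials = 5)
  b <- plvs(make_epochs(wrap_phase(ph + 1.234)), min_trials = 5)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-12)
})

test_that("plvs at t = 0 converges to the Bessel ratio of the generating kappa", {
  set.seed(42)
  n <- 400
  for (kappa in c(0, 1, 2, 4)) {
    # Monte-Carlo SE of the resultant length at this kappa and n, from an
    # independent direct simulation of the phase draws
    reps <- vapply(1:80, function(i)
      Mod(mean(exp(1i * rvonmises(n, pi, kappa)))), 0)
    se <- stats::sd(reps)
    ep <- vm_epochs(n, kappa)
    expect_lt(abs(plvs_at(plvs(ep), 0) - vonmises_resultant(kappa)),
              3 * se + 1e-3)
  }
})

test_that("surrogate thresholds are quantile-monotone and detect locked epochs", {
  set.seed(7)
  eps <- lapply(1:4, function(p) ramp_epochs(30, 81))
  s99 <- surrogate_threshold(eps, n_iter = 200, conf = 0.99, min_trials = 5,
                             seed = 5)
  s95 <- surrogate_threshold(eps, n_iter = 200, conf = 0.95, min_trials = 5,
                             seed = 5)
  expect_gte(s99$threshold, s95$threshold)
  expect_identical(s99$max_dist, s95$max_dist)

  # event-locked fixture: identical phase ramps across trials (plvs = 1
  # everywhere); independent time shifts decohere the trials
  tt <- (0:80) / 20
  locked <- lapply(1:4, function(p) {
    ph <- matrix(wrap_phase(2 * pi * 0.27 * tt), 30, 81, byrow = TRUE)
    make_epochs(wrap_phase(ph + rnorm(1, 0, 0.05)))
  })
  sl <- surrogate_threshold(locked, n_iter = 200, min_trials = 5, seed = 6)
  expect_true(all(sl$observed > 0.999))
  expect_gt(mean(sl$significant), 0.95)
})

test_that("the surrogate kernel reproduces a pure-R reimplementation", {
  set.seed(10)
  eps <- list(make_epochs(matrix(runif(12 * 17, 0, 2 * pi), 12, 17)),
              make_epochs(matrix(runif(9 * 17, 0, 2 * pi), 9, 17)))
  suppressWarnings(
    sur <- surrogate_threshold(eps, n_iter = 40, min_trials = 5, seed = 99))
  Tn <- 17
  set.seed(99)
  oracle <- vapply(1:40, function(it) {
    g <- rowMeans(vapply(eps, function(e) {
      n <- nrow(e$phase)
      Z <- exp(1i * e$phase)
      sh <- floor(runif(n) * Tn)
      S <- t(vapply(seq_len(n), function(j) {
        Z[j, ((seq_len(Tn) - 1 + sh[j]) %% Tn) + 1]
      }, complex(Tn)))
      Mod(colSums(S)) / n
    }, numeric(Tn)))
    max(g)
  }, 0)
  expect_equal(sur$max_dist, oracle, tolerance = 1e-12)
})

test_that("cluster permutation forms, sizes and scores clusters correctly", {
  ts <- seq(-2, 2, by = 0.05)
  Tn <- length(ts)
  set.seed(8)
  base <- matrix(rnorm(10 * Tn, 0.4, 0.02), 10, Tn)
  # identical conditions: no clusters
  expect_equal(nrow(cluster_permutation(base, base, ts, n_rand = 100,
                                        seed = 1)$clusters), 0)
  # a 4-sample effect is below the 250 ms minimum and never reported;
  # a 5-sample effect is reported
  eff4 <- base; eff4[, 30:33] <- eff4[, 30:33] + 0.3
  expect_equal(nrow(cluster_permutation(eff4, base, ts, n_rand = 100,
                                        seed = 1)$clusters), 0)
  eff5 <- base; eff5[, 30:34] <- eff5[, 30:34] + 0.3
  cl <- cluster_permutation(eff5, base, ts, n_rand = 200, seed = 1)$clusters
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_samples, 5L)
  expect_equal(cl$t_start_s, ts[30])
  expect_equal(cl$t_end_s, ts[34])
  expect_gt(cl$cohens_d, 0)
  expect_error(cluster_permutation(base[1, , drop = FALSE],
                                   base[1, , drop = FALSE], ts),
               "insufficient")
})

test_that("exhaustive sign-flip p equals brute-force enumeration", {
  set.seed(4)
  P <- 10; ts <- seq(-1, 0.75, by = 0.05); Tn <- length(ts)
  D <- matrix(rnorm(P * Tn, 0, 0.1), P, Tn)
  D[, 12:22] <- D[, 12:22] + 0.1
  A <- matrix(0.5, P, Tn) + D
  B <- matrix(0.5, P, Tn)
  ct <- cluster_permutation(A, B, ts, exhaustive = TRUE)
  expect_gt(nrow(ct$clusters), 0)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), P)))
  crit <- qt(0.975, P - 1)
  null_max <- apply(signs, 1, function(s)
    oracle_max_cluster(D * s, crit, 5L))
  for (j in seq_len(nrow(ct$clusters))) {
    expect_equal(ct$clusters$p[j],
                 mean(null_max >= abs(ct$clusters$sum_t[j]) - 1e-10))
  }
  # sampled version respects the never-zero p convention
  ct2 <- cluster_permutation(A, B, ts, n_rand = 200, seed = 3)
  expect_true(all(ct2$clusters$p >= 1 / 201))
})

test_that("plvs slope follows its definition and is robust to window shifts", {
  ts <- seq(-4, 4, by = 0.05)
  expect_equal(plvs_slope(rep(0.4, length(ts)), ts), 0)
  tr <- numeric(length(ts))
  tr[ts >= -2 & ts <= -1] <- 0.2
  tr[ts >= 1 & ts <= 2] <- 0.5
  expect_equal(plvs_slope(tr, ts), 0.3)
  # smooth sigmoid ramp: shifting both windows by +0.5 s changes the
  # slope by < 15%
  sm <- 0.3 + 0.3 / (1 + exp(-2 * ts))
  s0 <- plvs_slope(sm, ts)
  s1 <- plvs_slope(sm, ts, pre_window = c(-1.5, -0.5),
                   post_window = c(1.5, 2.5))
  expect_lt(abs(s1 - s0) / s0, 0.15)
  expect_error(plvs_slope(sm, ts, post_window = c(4.5, 5.5)), "outside")
})

test_that("paired t and Cohen's D reproduce closed-form arithmetic", {
  d <- c(0.2, 0.1, 0.3, 0.15, 0.25)
  res <- paired_t(d + 1, rep(1, 5))
  expect_equal(res$t, 5.657, tolerance = 1e-3)
  expect_equal(res$cohens_d, 2.530, tolerance = 1e-3)
  expect_equal(res$p, 2 * pt(-abs(res$t), df = 4))
  eq <- paired_t(1:6, 1:6)
  expect_equal(eq$t, 0)
  expect_equal(eq$cohens_d, 0)
  dg <- paired_t(c(2, 2, 2), c(1, 1, 1))
  expect_true(dg$degenerate)
  expect_identical(dg$cohens_d, Inf)
  expect_true(is.na(dg$t))
})
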