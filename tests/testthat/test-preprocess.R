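test_that("a pure 0.25 Hz sinusoid segments into 4-second cycles", {
  fs <- 200
  tr <- respiration_trace(sin(2 * pi * 0.25 * (0:(120 * fs - 1)) / fs), fs = fs)
  cyc <- segment_cycles(tr)
  expect_true(nrow(cyc) %in% c(29, 30))
  expect_true(all(abs((cyc$end_s - cyc$onset_s) - 4) < 0.05))
  expect_true(all(cyc$onset_s < cyc$peak_s & cyc$peak_s < cyc$end_s))
})

test_that("degenerate traces fail segmentation with a diagnostic", {
  expect_error(segment_cycles(respiration_trace(rep(1, 5000), fs = 100)),
               "segmentation failure")
  expect_error(segment_cycles(respiration_trace(sin(1:200 / 10), fs = 100)),
               "segmentation failure")
  expect_error(respiration_trace(c(1, NA, 3), fs = 10), "missing")
})

test_that("segmentation recovers generator ground truth", {
  sim <- small_participant(seed = 5, n_trials = 60)
  truth <- attr(sim$trace, "truth")$cycles
  cyc <- segment_cycles(sim$trace)
  # interior troughs only: the recording begins exactly at the first one,
  # which no detector can see
  err <- vapply(truth$onset_s[-1],
                function(o) min(abs(cyc$onset_s - o)), 0)
  expect_gte(mean(err <= 0.05), 0.99)
  # circular RMS error of the reconstructed phase against generator truth
  tcyc <- make_cycle_set(truth$onset_s, truth$peak_s, truth$end_s)
  ph <- compute_phase(cyc)
  tru <- phase_at(tcyc, ph$time_s)
  ok <- ph$valid & tru$valid & !is.na(tru$phase)
  rms <- sqrt(mean(wrap_angle(ph$phase_rad[ok] - tru$phase[ok])^2))
  expect_lt(rms, 0.1)
})

test_that("segmentation and phase are invariant to affine amplitude transforms", {
  sim <- small_participant(seed = 8, n_trials = 25)
  tr <- sim$trace
  tr2 <- respiration_trace(3.7 * tr$samples - 5.1, fs = tr$fs)
  c1 <- segment_cycles(tr); c2 <- segment_cycles(tr2)
  expect_equal(nrow(c1), nrow(c2))
  # landmark times agree to well under a sample (numerical round-off in
  # the refinement fit aside)
  expect_equal(c1$onset_s, c2$onset_s, tolerance = 1e-4)
  expect_equal(c1$peak_s, c2$peak_s, tolerance = 1e-4)
  p1 <- compute_phase(c1); p2 <- compute_phase(c2)
  expect_lt(max(abs(wrap_angle(p1$phase_rad[p1$valid] -
                                 p2$phase_rad[p2$valid]))), 0.05)
  # atypicality flags are unchanged on a fixture with a clear outlier
  fix <- cosine_cycle_trace(rep(4, 60), gains = c(rep(1, 30), 3, rep(1, 29)),
                            fs = 50, noise_sd = 0.005)
  g1 <- flag_atypical(fix$cycles, fix$trace)
  tr3 <- respiration_trace(2.5 * fix$trace$samples + 11, fs = 50)
  g2 <- flag_atypical(fix$cycles, tr3)
  expect_equal(g1$distance, g2$distance, tolerance = 1e-9)
  expect_identical(g1$atypical, g2$atypical)
})

test_that("atypicality flags exactly the engineered outlier at 3 SD", {
  # 99 identical cycles plus one with tripled amplitude
  fix <- cosine_cycle_trace(rep(4, 100), gains = c(rep(1, 49), 3, rep(1, 50)),
                            fs = 50, noise_sd = 0.005)
  flagged <- flag_atypical(fix$cycles, fix$trace)
  expect_identical(which(flagged$atypical), 50L)
  # identical cycles: zero spread, nothing flagged
  fix0 <- cosine_cycle_trace(rep(4, 100), fs = 50)
  f0 <- flag_atypical(fix0$cycles, fix0$trace)
  expect_false(any(f0$atypical))
  # default threshold is 3 SDs
  expect_identical(formals(flag_atypical)$z_thresh, 3)
  expect_error(flag_atypical(fix0$cycles[1:5, ], fix0$trace), "insufficient")
})

test_that("the piecewise-linear phase follows the two-segment construction", {
  cyc <- make_cycle_set(0, 1, 4)  # inhale 1 s, exhale 3 s
  expect_equal(phase_at(cyc, 0.5)$phase, pi / 2)
  expect_equal(phase_at(cyc, 1.0)$phase, pi)       # peak inhalation
  expect_equal(phase_at(cyc, 2.5)$phase, 3 * pi / 2)
  expect_equal(phase_at(cyc, 0)$phase, 0)
  # symmetric 4 s cycle at 20 Hz: constant increments of 2*pi/80
  sym <- make_cycle_set(0, 2, 4)
  ps <- compute_phase(sym, fs_out = 20)
  inc <- diff(ps$phase_rad[ps$valid])
  expect_equal(inc, rep(2 * pi / 80, length(inc)), tolerance = 1e-10)
  # half-open membership: the shared trough belongs to the next cycle
  two <- make_cycle_set(c(0, 4), c(2, 6), c(4, 8))
  expect_equal(phase_at(two, 4)$cycle, 2L)
  expect_equal(phase_at(two, 4)$phase, 0)
  # atypical cycles are invalid but still covered
  two$atypical[2] <- TRUE
  pa <- phase_at(two, c(1, 5))
  expect_identical(pa$valid, c(TRUE, FALSE))
  expect_false(is.na(pa$phase[2]))
})

test_that("unwrapped phase is non-decreasing within typical cycles", {
  sim <- small_participant(seed = 13, n_trials = 25)
  cyc <- flag_atypical(segment_cycles(sim$trace), sim$trace)
  ps <- compute_phase(cyc)
  for (i in which(!cyc$atypical)[1:10]) {
    sel <- ps$time_s >= cyc$onset_s[i] & ps$time_s < cyc$end_s[i]
    expect_true(all(diff(ps$phase_rad[sel]) >= -1e-12))
  }
})

test_that("landmark phase agrees with the analytic-signal phase", {
  sim <- small_participant(seed = 4, n_trials = 30)
  cyc <- segment_cycles(sim$trace)
  expect_gt(hilbert_agreement(sim$trace, cyc), 0.9)
})

test_that("traces round-trip through CSV", {
  sim <- small_participant(seed = 2, n_trials = 20, fs = 100)
  f <- tempfile(fileext = ".csv")
  write_respiration_csv(sim$trace, f)
  tr2 <- read_respiration_csv(f)
  expect_equal(tr2$fs, 100, tolerance = 1e-6)
  expect_equal(tr2$samples, sim$trace$samples, tolerance = 1e-6)
  unlink(f)
})
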