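acq <- acquisition_spec()

test_that("acquisition defaults match the dynamic protocol", {
  expect_equal(acq$tr_ms, 3.5)
  expect_equal(acq$te_ms, 1.13)
  expect_equal(acq$vfa_flips_deg, c(4, 8, 15, 25))
  expect_equal(acq$n_frames, 80L)
  expect_equal(acq$frame_interval_s, 3.3)
  expect_equal(acq$n_baseline_frames, 4L)
  expect_equal(acq$b_value_s_per_mm2, 800)
  expect_error(acquisition_spec(n_baseline_frames = 80), "below n_frames")
})

test_that("no tracer exchange leaves the dynamic signal at baseline", {
  truth <- kinetic_truth(0, 0.4, 0)
  sim <- generate_dce_series(truth, acq)
  s <- as.vector(sim$series$frames[1, 1, 1, ])
  expect_equal(s, rep(s[1], acq$n_frames))
  expect_true(all(sim$ct_mM == 0))
})

test_that("signals are linear in M0 and concentrations start at zero", {
  t1 <- kinetic_truth(0.3, 0.3, 0.05, m0 = 1000)
  t2 <- kinetic_truth(0.3, 0.3, 0.05, m0 = 2000)
  s1 <- generate_dce_series(t1, acq)
  s2 <- generate_dce_series(t2, acq)
  expect_equal(2 * s1$series$frames, s2$series$frames, tolerance = 1e-12)
  expect_equal(2 * s1$vfa$signals, s2$vfa$signals, tolerance = 1e-12)
  # pre-bolus frames carry no contrast
  expect_true(all(s1$ct_mM[, , , seq_len(acq$n_baseline_frames)] == 0))
  expect_true(all(s1$series$frames >= 0))
})

test_that("ve = 0 with positive ktrans is rejected", {
  expect_error(kinetic_truth(0.3, 0, 0.05), "ve")
})

test_that("DWI pair follows the mono-exponential closed form and round-trips", {
  dwi <- generate_dwi_pair(1.0e-3, b = 800, s0 = 1000)
  expect_equal(as.vector(dwi$sb), 1000 * exp(-0.8))
  dwi0 <- generate_dwi_pair(1.0e-3, b = 1e-12, s0 = 1000)
  expect_equal(as.vector(dwi0$sb), 1000, tolerance = 1e-9)
  # round trip recovers ADC to machine precision
  adc_true <- array(runif(27, 0.5e-3, 2e-3), c(3, 3, 3))
  pair <- generate_dwi_pair(adc_true, b = 800)
  res <- adc_map(pair$s0, pair$sb, b = 800, roi_mask = array(TRUE, c(3, 3, 3)))
  expect_equal(res$adc_map_mm2_per_s, adc_true, tolerance = 1e-12)
})

test_that("ADC map flags nonpositive and nonphysical voxels instead of dropping them", {
  s0 <- array(1000, c(2, 2, 1)); sb <- array(449.3, c(2, 2, 1))
  sb[1, 1, 1] <- 1000      # no decay: ADC = 0, nonphysical
  sb[2, 1, 1] <- 0         # nonpositive signal: flagged
  res <- adc_map(s0, sb)
  expect_true(res$nonphysical[1, 1, 1])
  expect_true(res$flagged[2, 1, 1])
  expect_true(is.na(res$adc_map_mm2_per_s[2, 1, 1]))
  expect_equal(res$adc_map_mm2_per_s[1, 1, 1], 0)
})

test_that("VFA T1 fit recovers truth, scales M0, and flags nonphysical slopes", {
  flips <- c(4, 8, 15, 25)
  sig <- vapply(flips, function(a) spgr_signal(1000, 1000, a, 3.5), numeric(1))
  fit <- fit_t1_vfa(array(sig, c(1, 1, 1, 4)), flips, 3.5)
  expect_equal(fit$t10_ms[1], 1000, tolerance = 1e-3 * 1000 * 1e-3)  # < 0.1 %
  expect_equal(fit$m0[1], 1000, tolerance = 1e-6)
  # doubling M0 leaves T1 unchanged and doubles the M0 estimate
  fit2 <- fit_t1_vfa(array(2 * sig, c(1, 1, 1, 4)), flips, 3.5)
  expect_equal(fit2$t10_ms[1], fit$t10_ms[1], tolerance = 1e-9)
  expect_equal(fit2$m0[1], 2 * fit$m0[1], tolerance = 1e-9)
  # nonphysical slope (>= 1, T1 undefined) is flagged, not clamped
  bad <- array(c(100, 210, 400, 700), c(1, 1, 1, 4))
  fitb <- fit_t1_vfa(bad, flips, 3.5)
  expect_false(fitb$fittable[1])
  expect_true(is.na(fitb$t10_ms[1]))
  expect_error(fit_t1_vfa(array(sig[1], c(1, 1, 1, 1)), 4, 3.5), "two distinct")
})

test_that("VFA round trip holds across a physiological T1 grid", {
  for (t1_true in c(500, 800, 1200, 1800)) {
    sim <- generate_dce_series(kinetic_truth(0.2, 0.3, 0, t10_ms = t1_true), acq)
    fit <- fit_t1_vfa(sim$vfa$signals, sim$vfa$flips_deg, acq$tr_ms)
    expect_lt(abs(fit$t10_ms[1] - t1_true) / t1_true, 1e-3)
  }
})

test_that("signal-to-concentration inverts the forward model", {
  truth <- kinetic_truth(0.655, 0.4, 0.05)
  sim <- generate_dce_series(truth, acq)
  t1 <- fit_t1_vfa(sim$vfa$signals, sim$vfa$flips_deg, acq$tr_ms)
  conv <- signal_to_concentration(sim$series, t1)
  expect_lt(max(abs(conv$ct_mM - sim$ct_mM)) / max(sim$ct_mM), 0.005)
  expect_equal(conv$n_clipped, 0)
  # frames identical to baseline give zero concentration
  const <- sim$series
  const$frames <- array(const$frames[, , , 1], c(1, 1, 1, acq$n_frames))
  conv0 <- signal_to_concentration(const, t1)
  expect_equal(as.vector(conv0$ct_mM), rep(0, acq$n_frames), tolerance = 1e-9)
  # noise-induced negatives are clipped and counted
  noisy <- generate_dce_series(truth, acq, snr = 15, rng_seed = 2L)
  t1n <- fit_t1_vfa(noisy$vfa$signals, noisy$vfa$flips_deg, acq$tr_ms)
  convn <- signal_to_concentration(noisy$series, t1n)
  expect_gt(convn$n_clipped, 0)
})
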