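test_that("time quotients match hand evaluation", {
  cs <- toy_cycle_set(T_s = 0.010, open_s = 0.008, opening_s = 0.005,
                      closing_s = 0.003)
  q <- compute_time_quotients(cs)
  expect_equal(q$OQ, 0.8)
  expect_equal(q$CQ, 0.3)
  expect_equal(q$SQ, 5 / 3, tolerance = 1e-10)
  expect_equal(q$RQ, 7 / 3, tolerance = 1e-10)
  expect_equal(q$ASQ, 0.625)
  expect_equal(q$SI, 0.25)
  # symmetric pulse
  qs <- compute_time_quotients(toy_cycle_set(T_s = 0.010, open_s = 0.008,
                                             opening_s = 0.004))
  expect_equal(qs$SQ, 1)
  expect_equal(qs$ASQ, 0.5)
  expect_equal(qs$SI, 0)
  # fully open cycle
  qo <- compute_time_quotients(toy_cycle_set(T_s = 0.010, open_s = 0.010))
  expect_equal(qo$OQ, 1)
})

test_that("zero closing durations are excluded with a warning", {
  cs <- toy_cycle_set(T_s = 0.01, open_s = 0.008,
                      opening_s = c(0.004, 0.008),
                      closing_s = c(0.004, 0))
  expect_warning(q <- compute_time_quotients(cs), "zero closing")
  expect_equal(q$SQ, 1)                          # only the valid cycle counts
  cs_all0 <- toy_cycle_set(T_s = 0.01, open_s = 0.008, opening_s = 0.008,
                           closing_s = 0)
  expect_warning(q0 <- compute_time_quotients(cs_all0), "zero closing")
  expect_true(is.na(q0$SQ) && is.na(q0$RQ) && is.na(q0$ASQ) && is.na(q0$SI))
})

test_that("amplitude dynamics match hand differencing", {
  # one cycle of samples [0, 4, 8, 4, 0]: diffs [4, 4, -4, -4]
  g <- new_gaw_record(c(0, 4, 8, 4, 0), fs_fps = 1)
  cs <- toy_cycle_set(T_s = 5, open_s = 5, opening_s = 2, closing_s = 3,
                      dyn_range = 8, peak_area = 8, min_area = 0, fs_fps = 1)
  a <- compute_amplitude_dynamics(g, cs)
  expect_equal(a$MADR, -4)
  expect_equal(a$AMQ, -2)
  expect_equal(a$GGI, 0)                         # min area 0
  expect_true(is.na(a$PA))                       # no halves
  # range endpoints of GGI
  expect_equal(
    compute_amplitude_dynamics(g, toy_cycle_set(T_s = 5, dyn_range = 0,
                                                peak_area = 8, min_area = 8,
                                                fs_fps = 1))$GGI,
    1
  )
})

test_that("identical halves give PA = 0 and an asymmetric generator recovers it", {
  g <- generate_gaw(kinematic_params(n_cycles = 20, phase_asym = 0,
                                     noise_sd = 0, seed = 5))
  cs <- detect_cycles(g, 0.01)
  expect_equal(compute_amplitude_dynamics(g, cs)$PA, 0)
  g2 <- generate_gaw(kinematic_params(n_cycles = 106, phase_asym = -0.02,
                                      noise_sd = 0, seed = 5))
  pa <- compute_amplitude_dynamics(g2, detect_cycles(g2, 0.01))$PA
  expect_lt(abs(pa - (-0.02)), 0.01)
})

test_that("amplitude perturbation measures match hand evaluation", {
  expect_equal(compute_amplitude_perturbation(
    toy_cycle_set(T_s = 0.01, dyn_range = c(10, 8, 10)))$AP, 0.8)
  eq <- compute_amplitude_perturbation(toy_cycle_set(T_s = 0.01,
                                                     dyn_range = rep(7, 6)))
  expect_equal(eq$AP, 1)
  expect_equal(eq$mSH, 0)
  # sd/mean = 0.1  ->  AVI = 20 log10(0.1) = -20 dB
  avi <- compute_amplitude_perturbation(
    toy_cycle_set(T_s = 0.01, dyn_range = c(9, 10, 11)))$AVI
  expect_equal(avi, -20)
  # zero ranges: pairs skipped with warning; all skipped -> NA
  expect_warning(
    p <- compute_amplitude_perturbation(
      toy_cycle_set(T_s = 0.01, dyn_range = c(10, 0, 10))),
    "skipped"
  )
  expect_true(is.na(p$AP))
})

test_that("time perturbation measures match hand arithmetic", {
  eq <- compute_time_perturbation(toy_cycle_set(T_s = rep(0.005, 5)))
  expect_equal(eq$mJT, 0)
  expect_equal(eq$JT, 0)
  tp <- compute_time_perturbation(toy_cycle_set(T_s = c(0.009, 0.011, 0.009)))
  expect_equal(tp$mJT, 2)
  expect_equal(tp$JT, 100 * 2 / (29 / 3), tolerance = 1e-10)   # ~20.7%
})

test_that("spectral helpers satisfy their defining identities", {
  # flat power spectrum: AM = GM -> SPF = 0 dB
  expect_equal(gawsense:::spectral_flatness_db(rep(3.7, 100)), 0)
  expect_lt(gawsense:::spectral_flatness_db(stats::runif(100, 0.1, 10)), 0)
  # harmonic/noise partition is exact
  g <- generate_gaw(kinematic_params(n_cycles = 30, seed = 14))
  ps <- gawsense:::gaw_power_spectrum(g$total_area, 15000)
  harm <- gawsense:::harmonic_bins(ps$freq, 176)
  expect_equal(sum(ps$power[harm]) + sum(ps$power[!harm]), sum(ps$power))
})

test_that("noiseless periodic GAW is nearly all harmonic energy", {
  g <- generate_gaw(quiet_params(seed = 3))
  cs <- detect_cycles(g)
  sn <- compute_spectral_noise(g, cs)
  expect_gte(sn$HI, 99)
  expect_gt(sn$HNR, 20)
  expect_lt(sn$NNE, -20)
  expect_lte(sn$SPF, 0)
})

test_that("white noise scores NNE near 0 dB", {
  set.seed(31)
  vals <- replicate(20, {
    ps <- gawsense:::gaw_power_spectrum(rnorm(4000), 15000)
    gawsense:::nne_db(ps$freq, ps$power, f0 = 176)
  })
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("compute_gaw_parameters populates all twenty fields within range", {
  g <- generate_gaw(kinematic_params(seed = 6))
  p <- compute_gaw_parameters(g)
  expect_true(all(gaw_parameter_names() %in% names(p)))
  expect_true(all(!is.na(p[gaw_parameter_names()])))
  expect_lt(p$AMQ, 0);  expect_lt(p$MADR, 0)
  expect_true(p$ASQ >= 0 && p$ASQ < 1)
  expect_true(p$CQ >= 0 && p$CQ < 1)
  expect_true(p$GGI >= 0 && p$GGI <= 1)
  expect_true(p$OQ >= 0 && p$OQ <= 1)
  expect_true(abs(p$PA) < 1)
  expect_gt(p$RQ, 0);  expect_gte(p$SQ, 0)
  expect_true(abs(p$SI) < 1)
  expect_true(p$AP >= 0 && p$AP <= 1)
  expect_gte(p$mSH, 0)
  expect_true(p$SH >= 0 && p$SH <= 100)
  expect_true(p$JT >= 0 && p$JT <= 100)
  expect_gte(p$mJT, 0)
  expect_true(p$HI >= 0 && p$HI <= 100)
  expect_lte(p$SPF, 0)
  expect_equal(p$fps, 15000)
  expect_equal(p$n_cycles_used, 106)
})

test_that("missing halves yield a PA sentinel, not a failure", {
  g <- generate_gaw(kinematic_params(n_cycles = 12, seed = 7))
  g_total <- new_gaw_record(g$total_area, fs_fps = 15000)
  p <- compute_gaw_parameters(g_total)
  expect_true(is.na(p$PA))
  expect_match(p$undefined, "PA:missing_halves")
  expect_equal(sum(!is.na(p[gaw_parameter_names()])), 19)
})

test_that("constant input propagates sentinels without aborting", {
  g <- new_gaw_record(rep(100, 500), fs_fps = 1000)
  p <- compute_gaw_parameters(g)
  expect_true(all(is.na(p[gaw_parameter_names()])))
  expect_match(p$undefined, "no_oscillation")
})

test_that("SI = 2 ASQ - 1 holds to machine precision on generated data", {
  for (seed in 1:5) {
    g <- generate_gaw(kinematic_params(n_cycles = 30, seed = seed))
    p <- compute_gaw_parameters(g, detect_cycles(g, 0.01))
    expect_equal(p$SI, 2 * p$ASQ - 1, tolerance = 1e-12)
  }
})

test_that("noiseless recovery at 15 kfps hits the stated tolerances", {
  kp <- kinematic_params(noise_sd = 0, seed = 11)   # OQ .9 SQ 1.25 gap .06 PA -.02
  g <- generate_gaw(kp)
  gt <- gaw_ground_truth(g)
  p <- compute_gaw_parameters(g, detect_cycles(g, 0.01))
  expect_lt(abs(p$OQ - gt$oq_total), 0.02)
  expect_lt(abs(p$SQ - gt$sq_total), 0.05)
  expect_lt(abs(p$PA - kp$phase_asym), 0.01)
  expect_lt(abs(p$GGI - kp$gap_fraction), 0.01)
  expect_lt(abs(p$mJT - gt$mJT_ms), 0.05)
  expect_lt(abs(p$mSH - gt$mSH_db), 0.05)
})

test_that("|MADR| shrinks with rate; per-second MADR is stable on divisor rates", {
  g <- generate_gaw(kinematic_params(noise_sd = 0, f0_hz = 150, seed = 5))
  rates <- seq(1000, 15000, 1000)
  madr <- vapply(rates, function(r) {
    d <- decimate_gaw(g, r)
    compute_gaw_parameters(d, detect_cycles(d, 0.01))$MADR
  }, numeric(1))
  expect_true(all(diff(abs(madr)) <= 1e-9))
  # uniform-subsampling rates at >= 20 F0: px/s rescaling is rate-invariant
  div <- rates[15000 %% rates == 0 & rates >= 20 * 150]
  per_s <- abs(madr[match(div, rates)]) * div
  expect_lt((max(per_s) - min(per_s)) / max(per_s), 0.10)
})

test_that("measured jitter on a jitter-free signal stays under one frame", {
  g <- generate_gaw(quiet_params(seed = 2))
  for (r in c(1000, 2000, 4000, 8000, 15000)) {
    d <- decimate_gaw(g, r)
    p <- compute_gaw_parameters(d, detect_cycles(d, 0.01))
    expect_lte(p$mJT, 1000 / r)
  }
})
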