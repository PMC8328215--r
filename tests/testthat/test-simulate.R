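test_that("configuration invariants are enforced", {
  expect_error(simulation_config(delta_freq = 4.5), "below the 4-Hz")
  expect_error(simulation_config(sampling_rate = 10), "oversampling")
  expect_error(simulation_config(noise_exponent = -1), ">= 0")
  expect_error(simulation_config(boundary_pause_s = c(FAST = 2, SLOW = 0.3)),
               "exceeds")
  bad_ev <- list(SLOW = list(sentence_onset = 3, segmentation_point = 2.7,
                             verb_onset = 3.5, sentence_end = 4.5),
                 FAST = list(sentence_onset = 0, segmentation_point = 1.8,
                             verb_onset = 2.3, sentence_end = 3))
  expect_error(simulation_config(event_times = bad_ev), "must satisfy")
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- quick_config(seed = 7)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$participants[[1]]$recording$data,
                   b$participants[[1]]$recording$data)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$participants[[2]]$envelopes,
                   b$participants[[2]]$envelopes)
})

test_that("degenerate configs collapse to the closed-form amplitudes", {
  cfg <- quick_config(coupling_strength = 0, rate_effect = 0, noise_sd = 0,
                      sensor_noise_sd = 0, amp_noise_sd = 0,
                      delta_amplitude = 0, seed = 2)
  gt <- draw_ground_truth(cfg)
  expect_equal(gt$true_evoked_amplitude,
               rep(cfg$baseline_amplitude, nrow(gt)))

  # cosine at the preferred phase adds exactly kappa
  cfg2 <- quick_config(coupling_strength = 5, preferred_phase = 0,
                       amp_noise_sd = 0, seed = 3)
  gt2 <- draw_ground_truth(cfg2)
  expect_equal(gt2$true_evoked_amplitude,
               cfg2$baseline_amplitude +
                 cfg2$rate_effect * (gt2$RATE == "FAST") +
                 5 * cos(gt2$true_phase_at_segpoint),
               tolerance = 1e-12)
})

test_that("mean evoked amplitude matches the analytic expectation at large n", {
  cfg <- simulation_config(n_participants = 1, n_trials_per_condition = 2500,
                           n_channels = 4, sampling_rate = 100, seed = 11)
  gt <- draw_ground_truth(cfg)
  expect_equal(nrow(gt), 10000)
  # E[cos(U - phi0)] = 0 for uniform U, so E[amp] = beta0 + beta_rate * P(FAST)
  expected <- cfg$baseline_amplitude + cfg$rate_effect * mean(gt$RATE == "FAST")
  mc_se <- sqrt(cfg$coupling_strength^2 / 2 + cfg$amp_noise_sd^2) / sqrt(10000)
  expect_lt(abs(mean(gt$true_evoked_amplitude) - expected), 5 * mc_se)
})

test_that("ground-truth phases are uniform and uncoupled when kappa = 0", {
  cfg <- simulation_config(n_participants = 1, n_trials_per_condition = 1250,
                           n_channels = 4, sampling_rate = 100,
                           coupling_strength = 0)
  nonsig <- 0
  n_seeds <- 30
  for (s in seq_len(n_seeds)) {
    gt <- draw_ground_truth(cfg, seed = s)
    if (rayleigh_p(gt$true_phase_at_segpoint) > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, round(0.9 * n_seeds))  # expected ~99%

  cfg0 <- simulation_config(n_participants = 1, n_trials_per_condition = 2500,
                            n_channels = 4, sampling_rate = 100,
                            coupling_strength = 0, seed = 21)
  gt0 <- draw_ground_truth(cfg0)
  r <- circ_lin_corr(gt0$true_phase_at_segpoint, gt0$true_evoked_amplitude)
  expect_lt(r, 0.05)
})

test_that("noiseless delta component has the configured analytic amplitude", {
  cfg <- quick_config(noise_sd = 0, sensor_noise_sd = 0, amp_noise_sd = 0,
                      coupling_strength = 0, rate_effect = 0,
                      baseline_amplitude = 0, neg_amplitude = 0, seed = 4)
  ds <- generate_dataset(cfg)
  rec <- ds$participants[[1]]$recording
  ep <- epoch_data(rec, "segmentation_point", -2, 2)
  n <- dim(ep$data)[3]
  for (ch in c(1, 4)) {
    x <- ar_extend(ep$data[1, ch, ], n)
    env_mid <- Mod(analytic_signal(x))[(n + 100):(2 * n - 100)]
    expect_equal(mean(env_mid),
                 unname(cfg$delta_amplitude * ds$maps$delta[ch]),
                 tolerance = 0.02)
  }
})

test_that("pink noise has the requested spectral slope", {
  expect_error(make_pink_noise(1000, -0.5, 100), ">= 0")
  expect_error(make_pink_noise(1, 1, 100), ">= 2")
  z <- make_pink_noise(2, 1, 100, seed = 1)
  expect_length(z, 2)
  expect_equal(mean(z), 0, tolerance = 1e-12)

  set.seed(10)
  slopes0 <- replicate(25, psd_slope(make_pink_noise(2^13, 0, 100), 100, 1, 25))
  expect_lt(abs(mean(slopes0)), 0.1)
  slopes1 <- replicate(25, psd_slope(make_pink_noise(2^16, 1, 100), 100, 0.5, 25))
  expect_lt(abs(mean(slopes1) + 1), 0.1)
})

test_that("envelopes are positive, compressed for FAST, and carry exact pauses", {
  cfg <- quick_config()
  ev_s <- cfg$event_times$SLOW
  ev_f <- cfg$event_times$FAST
  rate <- 100
  t0 <- cfg$span[1]; t1 <- cfg$span[2]
  ref_dur <- ev_s$sentence_end - ev_s$sentence_onset

  e0 <- make_envelope(ev_s, 0, rate, t0, t1, ref_duration = ref_dur)
  expect_true(all(e0 > 0))

  es <- make_envelope(ev_s, 0.342, rate, t0, t1, ref_duration = ref_dur)
  run <- rle(es == 0)
  zero_run <- max(c(0, run$lengths[run$values]))
  expect_lte(abs(zero_run - 0.342 * rate), 1)

  ef <- make_envelope(ev_f, 0.214, rate, t0, t1, ref_duration = ref_dur)
  runf <- rle(ef == 0)
  expect_lte(abs(max(c(0, runf$lengths[runf$values])) - 0.214 * rate), 1)

  # FAST is the time-compressed SLOW profile
  ef0 <- make_envelope(ev_f, 0, rate, t0, t1, ref_duration = ref_dur)
  factor <- (ev_f$sentence_end - ev_f$sentence_onset) / ref_dur
  tf <- t0 + (seq_along(ef0) - 1) / rate
  probe <- tf[tf > ev_f$sentence_onset + 0.2 & tf < ev_f$sentence_end - 0.2]
  slow_equiv <- approx(t0 + (seq_along(e0) - 1) / rate, e0,
                       xout = ev_s$sentence_onset +
                         (probe - ev_f$sentence_onset) / factor)$y
  fast_vals <- approx(tf, ef0, xout = probe)$y
  expect_equal(fast_vals, slow_equiv, tolerance = 0.02)

  expect_error(make_envelope(ev_s, 2, rate, t0, t1), "pause longer")
})

test_that("trial spans cover every analysis epoch and event ordering holds", {
  cfg <- quick_config(seed = 12)
  ds <- generate_dataset(cfg)
  rec <- ds$participants[[1]]$recording
  # -3..3 s epochs around the segmentation point and -0.5..1.5 s around the
  # verb must both fit
  expect_silent(epoch_data(rec, "segmentation_point", -3, 3))
  expect_silent(epoch_data(rec, "verb_onset", -0.5, 1.5))
  ev <- rec$events
  for (tr in unique(ev$trial)) {
    tt <- ev$time[ev$trial == tr]
    expect_true(all(diff(tt) > 0))
  }
})

test_that("onset phase-reset mode pins the phase at sentence onset", {
  cfg <- quick_config(phase_reset = "onset", preferred_phase = 0.9)
  gt <- draw_ground_truth(cfg)
  f <- cfg$delta_freq
  onset_phase <- gt$psi  # sentence_onset = 0 for both conditions
  expect_lt(max(abs(circ_diff(onset_phase, rep(0.9, nrow(gt))))), 1e-10)
})
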