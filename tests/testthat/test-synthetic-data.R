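test_that("generation is reproducible for a fixed seed and varies across seeds", {
  p <- generator_params(n_sites = 1, n_trials = 18, task = list(block_size = 6))
  a <- generate_session(p, seed = 7)
  b <- generate_session(p, seed = 7)
  expect_identical(a$store$trials, b$store$trials)
  expect_identical(a$store$records$lfp_s01$samples, b$store$records$lfp_s01$samples)
  expect_identical(a$store$spikes[[1]]$spike_times_ms, b$store$spikes[[1]]$spike_times_ms)
  c <- generate_session(p, seed = 8)
  expect_false(identical(a$store$spikes[[1]]$spike_times_ms,
                         c$store$spikes[[1]]$spike_times_ms))
})

test_that("planted band envelopes are recoverable from the simulated LFP", {
  g <- fixture_small_session()
  env_low <- hilbert_envelope(bandpass_beta(
    g$store$records$lfp_s01$samples, "low", 1000))
  expect_gt(stats::cor(env_low, g$truth$sites$s01$env_low), 0.8)
  env_high <- hilbert_envelope(bandpass_beta(
    g$store$records$lfp_s02$samples, "high", 1000))
  expect_gt(stats::cor(env_high, g$truth$sites$s02$env_high), 0.8)
})

test_that("hand simulation plants RTs exactly and keeps micro-movements small", {
  g <- fixture_small_session()
  tr <- g$store$trials
  full <- !is.na(tr$t_go)
  expect_equal(g$truth$trials$true_onset_ms[full], tr$t_go[full] + tr$rt_ms[full])
  # micro-movement speed during delays is far below the reach peak
  kin <- hand_kinematics(g$store$records$hand_x, g$store$records$hand_y)
  hold_idx <- unlist(lapply(which(full), function(i)
    round(tr$t_sel_on[i]):round(tr$t_sc1_on[i])))
  reach_idx <- unlist(lapply(which(full), function(i)
    round(tr$t_move_on[i]) + 0:300))
  ratio <- mean(kin$speed[hold_idx]) / max(kin$speed[reach_idx])
  expect_lt(ratio, 0.05)
})

test_that("spike trains lock to the planted phase with the configured kappa", {
  # controlled phase: pure 16 Hz carrier
  phase <- (2 * pi * 16 * (0:59999) / 1000) %% (2 * pi)
  site <- data.frame(site_id = "t1", ap_coord = 0)
  p1 <- generator_params(spikes = list(kappa = 1, n_units_per_site = 1,
                                       baseline_rate_hz = 10,
                                       preferred_phase = pi / 3))
  sp <- simulate_spikes(p1, phase, site, seed = 4)[[1]]
  expect_gt(length(sp$spike_times_ms), 400)
  ph_at_spk <- phase[floor(sp$spike_times_ms) + 1]
  d <- Arg(exp(1i * (circular_mean(ph_at_spk) - pi / 3)))
  expect_lt(abs(d), 0.2)

  # kappa = 0: no locking (wide tolerance Rayleigh check)
  p0 <- generator_params(spikes = list(kappa = 0, n_units_per_site = 1,
                                       baseline_rate_hz = 10))
  sp0 <- simulate_spikes(p0, phase, site, seed = 4)[[1]]
  rt <- rayleigh_test(phase[floor(sp0$spike_times_ms) + 1])
  expect_gt(rt$p, 0.001)

  # zero baseline -> empty train; negative kappa -> error
  pz <- generator_params(spikes = list(baseline_rate_hz = 0, n_units_per_site = 1))
  expect_length(simulate_spikes(pz, phase, site, seed = 1)[[1]]$spike_times_ms, 0)
  pn <- generator_params(spikes = list(kappa = -1))
  expect_error(simulate_spikes(pn, phase, site, seed = 1), "kappa")
})

test_that("eye simulation honors identity distortion and zero blink rate", {
  p <- generator_params(n_sites = 1, n_trials = 18,
                        task = list(block_size = 6),
                        eye = list(distort_c1 = 0, distort_c2 = 0,
                                   gain_v_per_cm = 1, offset_v = c(0, 0),
                                   noise_v = 0, blink_p_per_delay = 0,
                                   sat_bound_v = 100))
  tr <- generate_trial_sequence(p, seed = 13)
  eye <- simulate_eye(p, tr, seed = 13)
  expect_equal(nrow(eye$blinks), 0)
  # raw equals latent at the camera samples (identity distortion, no noise)
  n_ms <- nrow(eye$latent_cm)
  t_cam <- seq(0, n_ms - 1, by = 1000 / 240)
  lat_x <- stats::approx(seq_len(n_ms) - 1, eye$latent_cm[, 1], xout = t_cam)$y
  expect_equal(eye$eye_x$samples, lat_x, tolerance = 1e-8)
})

test_that("low and high envelopes are uncorrelated when planted independently", {
  flat <- list(low = data.frame(anchor = "touch", offset_ms = 0, level = 1),
               high = data.frame(anchor = "touch", offset_ms = 0, level = 1))
  p <- generator_params(
    n_sites = 1, n_trials = 18, task = list(block_size = 6),
    lfp = list(envelope_template = flat,
               dominance_gradient = function(ap) 0.5),
    coupling = list(hand_to_lowbeta_gain = 0, gaze_to_highbeta_gain = 0,
                    rt_to_lowbeta_gain = 0, time_on_task_slope = 0))
  g <- generate_session(p, seed = 17)
  x <- g$store$records$lfp_s01$samples
  r <- stats::cor(hilbert_envelope(bandpass_beta(x, "low", 1000)),
                  hilbert_envelope(bandpass_beta(x, "high", 1000)))
  expect_lt(abs(r), 0.05)
})
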