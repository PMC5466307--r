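test_that("RR sequence honours mean, SD, bounds and the zero-variance case", {
  # zero HR variance: five beats at 60 bpm are five 1.000 s cycles
  cfg0 <- subject_config(n_beats = 5, mean_hr = 60, sd_hr = 0,
                         ectopic_rate = 0, seed = 1)
  expect_equal(as.numeric(simulate_rr_sequence(cfg0)), rep(1, 5))

  # default population: 128-beat sample mean close to 67 bpm, and the
  # long-run mean/SD (law of large numbers at n = 1e5) match the config
  cfg <- subject_config(n_beats = 128, ectopic_rate = 0, seed = 11)
  hr <- 60 / as.numeric(simulate_rr_sequence(cfg))
  expect_lt(abs(mean(hr) - 67), 3)

  cfg_big <- subject_config(n_beats = 1e5, ectopic_rate = 0, seed = 12)
  hr_big <- attr(simulate_rr_sequence(cfg_big), "hr")
  expect_lt(abs(mean(hr_big) - 67), 3)
  expect_lt(abs(sd(hr_big) - 9.5), 0.5)
  expect_gte(min(hr_big), 44)
  expect_lte(max(hr_big), 114)

  # determinism: same seed, bit-identical; different seed, different draw
  expect_identical(simulate_rr_sequence(cfg), simulate_rr_sequence(cfg))
  cfg2 <- subject_config(n_beats = 128, ectopic_rate = 0, seed = 13)
  expect_false(identical(as.numeric(simulate_rr_sequence(cfg)),
                         as.numeric(simulate_rr_sequence(cfg2))))
})

test_that("ectopic beats violate the 20% screening criteria by construction", {
  # sparse ectopy: each injected beat differs >20% from both the record
  # median and (when the predecessor is normal) the previous cycle
  cfg <- subject_config(n_beats = 80, ectopic_rate = 0.08, seed = 5)
  rr <- simulate_rr_sequence(cfg)
  ect <- attr(rr, "is_ectopic")
  expect_gt(sum(ect), 0)
  med <- median(rr)
  for (i in which(ect)) {
    expect_gt(abs(rr[i] - med), 0.2 * med)
    if (!ect[i - 1]) expect_gt(abs(rr[i] - rr[i - 1]), 0.2 * rr[i - 1])
  }
})

test_that("true end-systole follows the generating line and its noise level", {
  # Weissler-M constants at HR 60: 0.456 - 0.0018*60 = 0.348 s
  cfg <- subject_config(mean_hr = 60, sd_hr = 0, true_slope = -0.0018,
                        true_intercept = 0.456, residual_sd = 0,
                        n_beats = 4, ectopic_rate = 0, seed = 1)
  rr <- simulate_rr_sequence(cfg)
  expect_equal(true_end_systole(cfg, rr), rep(0.348, 4), tolerance = 1e-12)

  # flat model: slope 0 gives the intercept at any heart rate
  cfg_flat <- subject_config(true_slope = 0, true_intercept = 0.3,
                             residual_sd = 0, n_beats = 20,
                             ectopic_rate = 0, seed = 2)
  rr_flat <- simulate_rr_sequence(cfg_flat)
  expect_equal(true_end_systole(cfg_flat, rr_flat), rep(0.3, 20))

  # Monte-Carlo: empirical residual SD at fixed HR recovers 0.014 s
  cfg_mc <- subject_config(mean_hr = 67, sd_hr = 0, residual_sd = 0.014,
                           n_beats = 1e5, ectopic_rate = 0, seed = 3)
  rr_mc <- rep(60 / 67, 1e5)
  s_mc <- true_end_systole(cfg_mc, rr_mc)
  expect_lt(abs(sd(s_mc) - 0.014), 0.001)

  # inconsistent config: noise-free prediction outside the cycle errors
  cfg_bad <- subject_config(true_intercept = 2, true_slope = 0,
                            residual_sd = 0, n_beats = 4, seed = 4)
  expect_error(true_end_systole(cfg_bad, rep(0.9, 4)), "inconsistent")
})

test_that("velocity scene places flow only in vessels with correct timing", {
  sub <- clean_subject()
  scene <- sub$scene
  tr <- scene$truth
  outside <- setdiff(seq_len(nrow(scene$velocity)),
                     c(tr$aorta_pixels, unlist(tr$confounder_pixels)))
  expect_equal(max(abs(scene$velocity[outside, ])), 0)

  # positive velocity at mid-systole in the aorta
  i <- 3
  t_mid <- tr$r_times[i] + 0.5 * tr$end_systole_s[i]
  j_mid <- which.min(abs(scene$times - t_mid))
  expect_gt(scene$velocity[tr$aorta_pixels[1], j_mid], 0)

  # last positive aortic sample within one TR of R + S_i, every beat
  aorta <- scene$velocity[tr$aorta_pixels[1], ]
  for (i in seq_along(tr$rr_durations)) {
    in_cyc <- scene$times >= tr$r_times[i] &
      scene$times < tr$r_times[i] + tr$rr_durations[i]
    pos <- which(in_cyc & aorta > 0)
    expect_lt(abs(scene$times[max(pos)] -
                    (tr$r_times[i] + tr$end_systole_s[i])),
              scene$acq$tr_s + 1e-12)
  }

  # magnitude contrast: vessels bright, air dark
  expect_gt(min(scene$magnitude[tr$aorta_pixels, ]), 0.9)
  expect_lt(max(scene$magnitude[1:10, ]), 0.1)
})

test_that("k-space rendering is deterministic and encodes velocity in phase", {
  sub <- clean_subject()
  ech <- sub$kspace
  expect_length(ech$samples, 2)
  expect_equal(diff(ech$echo_times), rep(0.0066, length(ech$echo_times) - 1),
               tolerance = 1e-12)
  expect_true(all(ech$venc_toggle[-1] * ech$venc_toggle[-length(ech$venc_toggle)] == -1))

  # phase difference convention: v = venc/2 at one pixel -> delta-phase pi/2
  acq <- acq_config(matrix_freq = 16, n_channels = 1)
  v <- matrix(0, 16, 4); v[9, ] <- acq$venc_cm_s / 2
  scene <- structure(list(velocity = v, magnitude = matrix(1, 16, 4),
                          times = (0:3) * acq$tr_s, acq = acq),
                     class = "velocity_scene")
  ech2 <- render_kspace_lines(scene, acq)
  img <- fourier_1d(ech2)$images[[1]]
  dphi <- Arg(img[9, 2] * Conj(img[9, 1]))
  expect_equal(abs(dphi), pi / 2, tolerance = 1e-10)

  expect_identical(render_kspace_lines(sub$scene)$samples, ech$samples)
})

test_that("simulated ECG carries QRS train, MHD bump and detection jitter", {
  cfg <- clean_config(n_beats = 8, seed = 33)
  rr <- simulate_rr_sequence(cfg)
  s <- true_end_systole(cfg, rr)
  ecg <- simulate_ecg(cfg, rr, s)
  # no jitter/noise/MHD: detections equal true R times exactly
  expect_equal(ecg$online_detections, ecg$true_r_times)

  # MHD on: extra deflection inside (R, R + S_i) relative to the clean trace
  cfg_m <- clean_config(n_beats = 8, seed = 33, mhd_amplitude = 0.3)
  ecg_m <- simulate_ecg(cfg_m, rr, s)
  dif <- ecg_m$samples[1, ] - ecg$samples[1, ]
  for (i in seq_along(rr)) {
    win <- ecg$times > ecg$true_r_times[i] + 0.03 &
      ecg$times < ecg$true_r_times[i] + s[i]
    expect_gt(max(dif[win]), 0.2)
    out <- ecg$times > ecg$true_r_times[i] + s[i] + 0.08 &
      ecg$times < ecg$true_r_times[i] + rr[i] - 0.05
    expect_lt(max(abs(dif[out])), 1e-8)
  }

  # jitter: RMS(detections - truth) close to the configured 10 ms
  cfg_j <- clean_config(n_beats = 300, seed = 44, r_jitter_sd = 0.01)
  rr_j <- simulate_rr_sequence(cfg_j)
  s_j <- true_end_systole(cfg_j, rr_j)
  ecg_j <- simulate_ecg(cfg_j, rr_j, s_j)
  rms <- sqrt(mean((ecg_j$online_detections - ecg_j$true_r_times)^2))
  expect_lt(abs(rms - 0.010), 0.002)
})

test_that("whole-subject simulation is bit-reproducible from its seed", {
  cfg <- noisy_config(n_beats = 6, seed = 77)
  a <- simulate_subject(cfg)
  b <- simulate_subject(cfg)
  expect_identical(a$kspace$samples, b$kspace$samples)
  expect_identical(a$ecg$samples, b$ecg$samples)
  expect_identical(a$truth, b$truth)
})
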