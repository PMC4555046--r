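test_that("session layout follows the trial protocol and is seed-deterministic", {
  cfg <- neutral_config(n_channels = 32, trials_per_finger = 3, seed = 5)
  out <- generate_session(cfg)
  ses <- out$session
  expect_equal(nrow(ses$trials), 15)
  expect_equal(unname(table(ses$trials$finger)), rep(3L, 5), ignore_attr = TRUE)
  expect_equal(ncol(ses$data), 15 * 6 * 250)
  expect_equal(nrow(ses$data), 32)
  expect_equal(ses$trials$onset_sample, (0:14) * 1500)

  out2 <- generate_session(cfg)
  expect_identical(ses$data, out2$session$data)
  expect_identical(ses$trials, out2$session$trials)

  out3 <- generate_session(neutral_config(n_channels = 32, trials_per_finger = 3,
                                          seed = 6))
  expect_false(identical(ses$data, out3$session$data))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(neutral_config(trials_per_finger = 0), "trials_per_finger")
  expect_error(neutral_config(sampling_rate_hz = 251), "sampling_rate_hz")
  expect_error(neutral_config(sampling_rate_hz = 120), "sampling_rate_hz")
  expect_error(neutral_config(alpha_peak = c(10, -1, 2)), "alpha_peak")
  expect_error(neutral_config(noise_sd = -1), "noise_sd")
  mon <- default_montage(32)
  bad_erd <- stats::setNames(rep(1.5, 32), mon$label)
  expect_error(synth_config(n_channels = 32, erd_map = bad_erd), "erd_map")
})

test_that("planted ERD attenuation appears as the squared factor in band power", {
  # amplitude attenuation 0.5 on C3 -> 8-12 Hz power ratio ~ 0.25,
  # biased slightly upward by the unattenuated 1/f background in-band
  mon <- default_montage(32)
  erd <- stats::setNames(rep(1, 32), mon$label)
  erd["C3"] <- 0.5
  cfg <- neutral_config(n_channels = 32, trials_per_finger = 8, seed = 7,
                        alpha_peak = c(10, 3, 5), beta_peak = c(20, 2, 0),
                        rhythm_fluctuation_sd = 0, line_noise_amp = 0,
                        noise_sd = 0.01)
  cfg$erd_map <- erd
  out <- generate_session(cfg)
  ses <- out$session
  ch <- which(ses$channel_labels == "C3")
  fs <- 250
  mv <- rs <- numeric(0)
  for (i in seq_len(nrow(ses$trials))) {
    o <- ses$trials$onset_sample[i]
    rs <- c(rs, rect_band_power(ses$data[ch, (o + 626):(o + 875)], 8:12))
    mv <- c(mv, rect_band_power(ses$data[ch, (o + 1126):(o + 1375)], 8:12))
  }
  ratio <- mean(mv) / mean(rs)
  expect_gt(ratio, 0.25 * 0.85)
  expect_lt(ratio, 0.25 * 1.15)
})

test_that("rest spectra of a neutral session match the target background curve", {
  cfg <- neutral_config(n_channels = 32, trials_per_finger = 10, seed = 3,
                        rhythm_fluctuation_sd = 0, line_noise_amp = 0,
                        noise_sd = 0)
  out <- generate_session(cfg)
  ses <- out$session
  ch <- which(ses$channel_labels == "Fp1")
  est <- rowMeans(vapply(seq_len(nrow(ses$trials)), function(i) {
    o <- ses$trials$onset_sample[i]
    x <- ses$data[ch, (o + 626):(o + 875)]
    Mod(stats::fft(x)[2:71])^2 / 250
  }, numeric(70)))
  target <- out$ground_truth$expected_log_psd["rest", "Fp1", ]
  dif <- log(est) - target
  # rectangular periodogram of the tapered block reproduces the planted
  # curve up to a small common offset; every bin within a tolerance band
  expect_lt(max(abs(dif - mean(dif))), 0.5)
  expect_lt(abs(mean(dif)), 0.3)
})

test_that("ground-truth profiles are unit norm with the planted shapes", {
  cfg <- neutral_config(n_channels = 32)
  gt <- ground_truth_profiles(cfg)
  expect_length(gt$broadband_profile, 70)
  expect_length(gt$coupled_profile, 70)
  expect_equal(sqrt(sum(gt$broadband_profile^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(gt$coupled_profile^2)), 1, tolerance = 1e-12)
  # broadband flat by construction
  expect_equal(length(unique(gt$broadband_profile)), 1)
  # coupled profile peaks at the configured alpha center
  expect_equal(which.max(gt$coupled_profile), 10)
  # far from both rhythm bands the coupled profile is near zero
  expect_lt(max(abs(gt$coupled_profile[40:70])), 0.1)
  expect_equal(dim(gt$expected_log_psd), c(6L, 32L, 70L))
})
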