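test_that("generated EEG has the programmed initial band power", {
  cfg <- synth_eeg_config(n_channels = 4, fs = 4, duration_h = 2,
                          power_decay = 0, coherence_decay = 0,
                          cycle_depth = 0, init_power = 2.5, seed = 3)
  eeg <- generate_eeg(cfg)
  bp <- band_power_series(eeg$signals[, 1], eeg$fs, band = cfg$band,
                          window_len = 40)
  expect_lt(abs(mean(bp$power) - 2.5) / 2.5, 0.05)
})

test_that("programmed power decay is recovered by the analysis chain", {
  for (sd in 1:2) {
    cfg <- synth_eeg_config(n_channels = 4, fs = 4, duration_h = 6,
                            power_decay = -1.22, coherence_decay = -0.3,
                            seed = sd)
    eeg <- generate_eeg(cfg)
    slopes <- vapply(1:4, function(ch) {
      bp <- band_power_series(eeg$signals[, ch], eeg$fs, window_len = 40)
      decay_rate(bp$time / 3600, bp$db)$slope
    }, numeric(1))
    # different seeds, different waveforms, same recovered slope
    expect_lt(abs(mean(slopes) + 1.22), 0.25)
  }
})

test_that("zero programmed coherence decay yields a flat coherence series", {
  cfg <- synth_eeg_config(n_channels = 5, fs = 4, duration_h = 6,
                          power_decay = -1, coherence_decay = 0, seed = 9)
  eeg <- generate_eeg(cfg)
  ch <- spatial_coherence_series(eeg$signals, eeg$fs, window_len = 40)
  fit <- decay_rate(ch$time / 3600, rowMeans(ch$db))
  expect_lt(abs(fit$slope), 2.5 * fit$se + 0.05)
})

test_that("coherence rises with the programmed shared fraction", {
  coh_at <- function(c0) {
    cfg <- synth_eeg_config(n_channels = 4, fs = 4, duration_h = 1.5,
                            power_decay = 0, coherence_decay = 0,
                            init_coherence = c0, cycle_depth = 0, seed = 4)
    eeg <- generate_eeg(cfg)
    mean(spatial_coherence_series(eeg$signals, eeg$fs, window_len = 40)$coherence)
  }
  vals <- vapply(c(0.2, 0.5, 0.8), coh_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("infeasible decay programming is rejected", {
  cfg <- synth_eeg_config(init_coherence = 0.9, coherence_decay = +1,
                          duration_h = 2)
  expect_error(generate_eeg(cfg), "infeasible")
})

test_that("paired condition studies feed the permutation test end to end", {
  cfg <- synth_eeg_config(n_channels = 3, fs = 4, duration_h = 5,
                          cycle_depth = 0.3)
  study <- generate_condition_pair(cfg, sham_slope = -1.22,
                                   stim_slope = -0.69, n_subjects = 5,
                                   subject_sd = 0.1, seed = 21)
  fit_one <- function(eeg) {
    bp <- band_power_series(eeg$signals[, 1], eeg$fs, window_len = 40)
    decay_rate(bp$time / 3600, bp$db)$slope
  }
  sham <- vapply(study$sham, fit_one, numeric(1))
  stim <- vapply(study$stim, fit_one, numeric(1))
  expect_equal(length(sham), 5)
  # programmed ordering: stimulation decays less steeply
  expect_gt(mean(stim - sham), 0.2)
  out <- paired_shuffle_test(sham, stim)
  expect_lt(out$p, 0.2)

  # with two subjects and a real difference the smallest attainable
  # two-sided p is 2/4
  s2 <- generate_condition_pair(cfg, -1.22, -0.4, n_subjects = 2,
                                subject_sd = 0, seed = 5)
  p2 <- paired_shuffle_test(vapply(s2$sham, fit_one, numeric(1)),
                            vapply(s2$stim, fit_one, numeric(1)))$p
  expect_equal(p2, 0.5)
})
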