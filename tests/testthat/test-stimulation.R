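test_that("waveform envelopes have the documented shape", {
  sham <- stimulus_waveform("sham")
  expect_equal(waveform_value(sham, c(0, 1, 10)), c(0, 0, 0))

  dc <- stimulus_waveform("dc", schedule = cbind(2, 5))
  expect_equal(waveform_value(dc, c(1, 3, 6)), c(0, 1, 0))

  onoff <- stimulus_waveform("onoff", frequency = 0.75)
  period <- 1 / 0.75
  expect_equal(period, 4 / 3)
  # plateau mid-ON is 1, mid-OFF is 0
  expect_equal(waveform_value(onoff, period / 4), 1)
  expect_equal(waveform_value(onoff, 3 * period / 4), 0)
  expect_true(all(waveform_value(onoff, seq(0, 10, by = 0.001)) >= 0))
  expect_true(all(waveform_value(onoff, seq(0, 10, by = 0.001)) <= 1))

  # trapezoid area over one period: half-period times (1 - ramp_fraction)
  tt <- seq(0, period, length.out = 20001)
  num <- mean(waveform_value(onoff, tt)) * period
  expect_equal(num, (period / 2) * (1 - onoff$ramp_fraction), tolerance = 1e-3)
})

test_that("field coupling calibrates to 0.2 mV per V/m", {
  cal <- calibrate_coupling()
  expect_equal(cal$lambda_mV_per_Vm, 0.2)
  # applying the calibrated current for a 1 V/m field depolarizes by 0.2 mV
  p0 <- neuron_params("excitatory", e_ss = 0)
  rest <- simulate_neuron(p0, 0, 2)$state$v
  dv1 <- simulate_neuron(p0, cal$current_per_Vm, 2)$state$v - rest
  expect_lt(abs(dv1 - 0.2) / 0.2, 0.01)
  # zero field, zero shift; half field, half shift (linearity)
  dv05 <- simulate_neuron(p0, 0.5 * cal$current_per_Vm, 2)$state$v - rest
  expect_lt(abs(dv05 - 0.1) / 0.1, 0.02)
  expect_equal(cal$current_per_Vm, cal$lambda_mV_per_Vm / cal$z_mV_per_current,
               tolerance = 0.05)
})

test_that("field current respects cell type, polarity and arithmetic", {
  cal <- calibrate_coupling()
  prof <- polarity_profile(1, 30)
  w <- stimulus_waveform("onoff", amplitude = 0.31)
  t_on <- (1 / 0.75) / 4  # mid-ON plateau
  expect_equal(field_current(prof, cal, w, t_on, col = 3, is_excitatory = FALSE), 0)
  i_exc <- field_current(prof, cal, w, t_on, col = 3, is_excitatory = TRUE)
  expect_equal(i_exc, 0.31 * cal$current_per_Vm)
  # odd symmetry in the field
  prof_neg <- polarity_profile(0, 30)
  expect_equal(field_current(prof_neg, cal, w, t_on, 3, TRUE), -i_exc)
})

test_that("the field-profile pipeline trims, samples and rescales exactly", {
  # trim correctness on 1000 known-order samples: 31 lost per tail
  s <- 1:1000
  prof <- make_field_profile(s, n_cols = 30, trim_pct = 3.12,
                             target_mean_abs = 0.93)
  expect_length(prof$per_column_field, 30)
  k <- floor(3.12 / 100 * 1000)
  expect_equal(k, 31)
  # brute-force order statistics: 31 smallest and largest excluded, then
  # 30 evenly spaced ranks of the remainder, rescaled to the target mean
  trimmed <- s[32:969]
  expected <- trimmed[floor(seq(1, length(trimmed), length.out = 30))]
  expected <- expected * 0.93 / mean(abs(expected))
  expect_equal(prof$per_column_field, expected)

  # mean |field| is exactly the target
  samples <- synth_field_samples(3000, frac_positive = 0.55, seed = 5)
  prof2 <- make_field_profile(samples)
  expect_equal(mean(abs(prof2$per_column_field)), 0.93, tolerance = 1e-12)

  # sign preservation
  pos <- make_field_profile(abs(samples) + 0.01)
  expect_true(all(pos$per_column_field > 0))
  mixed_signs <- sign(prof2$per_column_field)
  expect_true(any(mixed_signs > 0) && any(mixed_signs < 0))

  # idempotence under re-application
  prof3 <- make_field_profile(prof2$per_column_field, n_cols = 30,
                              trim_pct = 3.12, target_mean_abs = 0.93)
  expect_equal(sort(prof3$per_column_field), sort(prof2$per_column_field),
               tolerance = 1e-9)

  expect_error(make_field_profile(rep(0, 100)), "zero")
})

test_that("synthetic field samples have the programmed polarity mixture", {
  all_pos <- synth_field_samples(500, frac_positive = 1, seed = 1)
  expect_true(all(all_pos > 0))
  s <- synth_field_samples(1e5, frac_positive = 0.5, seed = 2)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(s > 0) - 0.5), 3 * se)
  expect_identical(s, synth_field_samples(1e5, frac_positive = 0.5, seed = 2))
  f <- tempfile()
  write_field_samples(s[1:100], f)
  expect_equal(read_field_samples(f), s[1:100])
  unlink(f)
})

test_that("sham stimulation is bit-identical to no stimulation", {
  net <- tiny_net(seed = 2)
  a <- run_simulation(sim_config(net, duration = 5, seed = 3, subregions = 0))
  b <- run_simulation(sim_config(net, duration = 5, seed = 3, subregions = 0,
                                 waveform = stimulus_waveform("sham"),
                                 field_profile = polarity_profile(1, 10)))
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp_raw, b$lfp_raw)
})
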