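test_that("band power follows Parseval for sinusoids and white noise", {
  fs <- 10
  tt <- seq(0, 400 - 1 / fs, by = 1 / fs)
  A <- 1.7
  x <- A * sin(2 * pi * 0.75 * tt)
  bp <- band_power_series(x, fs, band = c(0.5, 1), window_len = 40)
  expect_equal(nrow(bp), 10)
  expect_lt(abs(median(bp$power) - A^2 / 2) / (A^2 / 2), 0.05)

  # white noise: band power ~ band's share of total variance
  set.seed(1)
  wn <- rnorm(length(tt), sd = 2)
  bq <- band_power_series(wn, fs, band = c(0.5, 4), window_len = 40)
  frac <- (4 - 0.5) / (fs / 2)
  expect_lt(abs(mean(bq$power) - 4 * frac) / (4 * frac), 0.1)

  # zero signal is masked on the dB scale
  b0 <- band_power_series(numeric(800), fs, window_len = 40)
  expect_true(all(b0$power == 0))
  expect_true(all(is.na(b0$db)))
  expect_error(band_power_series(wn, fs, band = c(0.5, 6)))
})

test_that("spatial coherence is 1 for identical channels, small under independence", {
  fs <- 5
  n <- 40 * fs * 6
  set.seed(2)
  base <- rnorm(n)
  x_same <- cbind(base, base, 3 * base)  # amplitude-invariance included
  ch <- spatial_coherence_series(x_same, fs, band = c(0.5, 1))
  expect_true(all(abs(ch$coherence - 1) < 1e-9))

  x_ind <- matrix(rnorm(n * 3), ncol = 3)
  ci <- spatial_coherence_series(x_ind, fs, band = c(0.5, 1))
  expect_lt(mean(ci$coherence), 0.35)
  # longer windows average more sub-segments: null coherence decreases
  ci2 <- spatial_coherence_series(matrix(rnorm(80 * fs * 6 * 2), ncol = 2),
                                  fs, band = c(0.5, 1), window_len = 80)
  expect_lt(mean(ci2$coherence), mean(ci$coherence) + 0.02)
  expect_error(spatial_coherence_series(x_ind[, 1, drop = FALSE], fs))
})

test_that("coherence of a shared source matches the analytic mixing value", {
  # x_i = a s + b n_i with unit-variance white sources: per-bin magnitude
  # squared coherence tends to (a^2/(a^2+b^2))^2
  fs <- 5
  n <- 40 * fs * 30
  set.seed(3)
  s <- rnorm(n)
  a <- sqrt(0.7); b <- sqrt(0.3)
  x <- cbind(a * s + b * rnorm(n), a * s + b * rnorm(n))
  ch <- spatial_coherence_series(x, fs, band = c(0.5, 1))
  expect_lt(abs(mean(ch$coherence) - 0.7^2), 0.08)
})

test_that("robust decay fits recover slopes and resist gross outliers", {
  t_h <- seq(0, 4.5, by = 0.1)
  y <- 3 - 1.22 * t_h
  fit <- decay_rate(t_h, y)
  expect_equal(fit$slope, -1.22, tolerance = 1e-8)

  # 10% gross outliers
  set.seed(4)
  y2 <- y
  bad <- sample(seq_along(y2), round(0.1 * length(y2)))
  y2[bad] <- y2[bad] + 15
  fit2 <- decay_rate(t_h, y2)
  expect_lt(abs(fit2$slope + 1.22), 0.05)

  # constant series: zero slope
  expect_equal(decay_rate(t_h, rep(2, length(t_h)))$slope, 0, tolerance = 1e-9)

  # seconds are converted to per-hour slopes
  fit3 <- decay_rate(t_h * 3600, y, time_unit = "seconds")
  expect_equal(fit3$slope, -1.22, tolerance = 1e-8)

  expect_error(decay_rate(t_h[1:5], y[1:5]), "insufficient")
})

test_that("paired shuffle test matches exhaustive enumeration", {
  # identical vectors: p = 1
  expect_equal(paired_shuffle_test(1:5, 1:5)$p, 1)

  # n = 10, all differences equal and same sign: two-sided p = 2 / 2^10
  sham <- rnorm(10)
  out <- paired_shuffle_test(sham, sham + 1)
  expect_true(out$exact)
  expect_equal(out$p, 2 / 1024)

  # brute-force oracle on arbitrary data
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8, mean = 0.4)
  d <- b - a
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  stats <- abs(as.numeric(signs %*% d) / 8)
  p_brute <- mean(stats >= abs(mean(d)) - 1e-12)
  expect_equal(paired_shuffle_test(a, b)$p, p_brute)

  # sampling path applies the add-one correction
  set.seed(6)
  big <- paired_shuffle_test(rnorm(20), rnorm(20, 2), n_perm = 999)
  expect_false(big$exact)
  expect_equal(big$p, 1 / 1000)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  # single p-value unchanged
  expect_equal(fdr_bh(0.03)$adjusted, 0.03)
  # classic step-up case: all rejected at q = 0.05
  out <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(out$rejected))
  # hand-computed adjusted values: min over j>=i of p_(j) * m / j
  p <- c(0.005, 0.04, 0.03, 0.9)
  hand <- p.adjust(p, "BH")
  srt <- sort(p)
  manual <- rev(cummin(rev(srt * 4 / seq_len(4))))[rank(p)]
  expect_equal(hand, pmin(1, manual))
  expect_equal(fdr_bh(p)$adjusted, hand)
  # all ones: nothing rejected
  expect_false(any(fdr_bh(rep(1, 5))$rejected))
})

test_that("phase locking is 1 for a locked oscillation and small under the null", {
  fs <- 50
  dur <- 120
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  wf <- stimulus_waveform("onoff", frequency = 0.75)
  x <- sin(2 * pi * 0.75 * tt + 0.7)
  pl <- phase_locking(x, fs, wf, band = c(0.5, 1), duration = dur)
  expect_gt(pl$plv, 0.98)
  expect_equal(pl$n_cycles, length(pl$phases))

  # uniform random phases: PLV on the 1/sqrt(n) scale
  set.seed(7)
  null_plv <- replicate(20, {
    ph <- runif(100, -pi, pi)
    Mod(mean(exp(1i * ph)))
  })
  expect_lt(mean(null_plv), 2 / sqrt(100))

  expect_error(phase_locking(x[1:100], fs, wf, duration = 2), "cycles")
})
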