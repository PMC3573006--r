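# EEG/LFP spectral analysis: windowed band power, spatial coherence,
# robust decay-rate fits, paired permutation statistics, FDR, entrainment.

#' Band power in consecutive windows
#'
#' For each non-overlapping window the periodogram is computed
#' (mean-detrended, rectangular taper) and the one-sided power is summed
#' over the frequency bins falling inside `band`. With this convention a
#' pure sinusoid of amplitude `A` whose frequency lies in the band yields a
#' band power of `A^2/2` (its variance), and for white noise the band power
#' approximates the band's share of the total variance.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz); must exceed twice the band's upper edge.
#' @param band `c(f_lo, f_hi)` in Hz (slow-wave oscillation band
#'   `c(0.5, 1)` by default; slow-wave activity is `c(0.5, 4)`).
#' @param window_len window length (s, default 40 as in overnight EEG
#'   analyses).
#' @param t0 time of the first sample (s).
#' @return data.frame of class `spectral_series` with `time` (window
#'   centers, s), `power` (linear) and `db` (`10*log10(power)`; zero power
#'   is masked to `NA`).
#' @export
band_power_series <- function(x, fs, band = c(0.5, 1), window_len = 40,
                              t0 = 0) {
  stopifnot(length(band) == 2, band[2] > band[1], fs > 2 * band[2])
  nw <- floor(window_len * fs)
  stopifnot(length(x) >= nw)
  k <- floor(length(x) / nw)
  freqs <- (seq_len(nw) - 1) * fs / nw
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  out <- data.frame(time = numeric(k), power = numeric(k))
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * nw + 1):(i * nw)]
    seg <- seg - mean(seg)
    p <- 2 * Mod(fft(seg))^2 / nw^2  # one-sided variance contribution
    out$power[i] <- sum(p[sel])
    out$time[i] <- t0 + (i - 0.5) * nw / fs
  }
  out$db <- ifelse(out$power > 0, 10 * log10(out$power), NA_real_)
  attr(out, "band") <- band
  attr(out, "window_len") <- window_len
  class(out) <- c("spectral_series", "data.frame")
  out
}

#' Windowed spatial coherence between channels
#'
#' Within each analysis window, every channel is cut into `seg_len`-second
#' sub-segments which are standardized to zero mean and unit energy (so the
#' measure is normalized by power and invariant to per-channel amplitude
#' rescaling). For each channel pair the magnitude-squared coherence is
#' computed from sub-segment-averaged cross- and auto-spectra and averaged
#' over the frequency bins inside `band`; each channel's coherence is the
#' mean over all pairs involving it.
#'
#' @param x numeric matrix, one channel per column (at least 2).
#' @param fs sampling rate (Hz).
#' @param band `c(f_lo, f_hi)` in Hz.
#' @param window_len analysis window (s, default 40).
#' @param seg_len sub-segment length (s, default 5); `window_len/seg_len`
#'   sub-segments enter each estimate, bounding the positive bias of the
#'   estimator under independence at roughly `seg_len/window_len`.
#' @param t0 time of the first sample (s).
#' @return list of class `coherence_series`: `time` (window centers),
#'   `coherence` (windows x channels matrix, values in `[0, 1]`), `db`,
#'   `band`.
#' @export
spatial_coherence_series <- function(x, fs, band = c(0.5, 1),
                                     window_len = 40, seg_len = 5, t0 = 0) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 channels for spatial coherence")
  nw <- floor(window_len * fs)
  ns <- floor(seg_len * fs)
  n_seg <- floor(nw / ns)
  stopifnot(n_seg >= 2, nrow(x) >= nw)
  k <- floor(nrow(x) / nw)
  nc <- ncol(x)
  freqs <- (seq_len(ns) - 1) * fs / ns
  sel <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  if (length(sel) == 0) stop("no frequency bins inside the band")

  coh <- matrix(NA_real_, k, nc)
  times <- numeric(k)
  for (i in seq_len(k)) {
    win <- x[((i - 1) * nw + 1):(i * nw), , drop = FALSE]
    # spectra of standardized sub-segments: [bins x seg x chan]
    X <- array(0i, dim = c(length(sel), n_seg, nc))
    for (s in seq_len(n_seg)) {
      seg <- win[((s - 1) * ns + 1):(s * ns), , drop = FALSE]
      seg <- sweep(seg, 2, colMeans(seg))
      en <- sqrt(colSums(seg^2))
      en[en == 0] <- 1
      seg <- sweep(seg, 2, en, "/")
      sp <- stats::mvfft(seg)
      X[, s, ] <- sp[sel, , drop = FALSE]
    }
    pair_sum <- matrix(0, nc, nc)
    auto <- matrix(0, length(sel), nc)
    for (ch in seq_len(nc)) {
      auto[, ch] <- rowMeans(Mod(X[, , ch, drop = FALSE])^2)
    }
    for (p in seq_len(nc - 1)) {
      for (q in (p + 1):nc) {
        cross <- rowMeans(X[, , p] * Conj(X[, , q]))
        msc <- Mod(cross)^2 / (auto[, p] * auto[, q])
        pair_sum[p, q] <- pair_sum[q, p] <- mean(msc)
      }
    }
    coh[i, ] <- rowSums(pair_sum) / (nc - 1)
    times[i] <- t0 + (i - 0.5) * nw / fs
  }
  structure(
    list(time = times, coherence = coh,
         db = ifelse(coh > 0, 10 * log10(coh), NA_real_), band = band,
         window_len = window_len, seg_len = seg_len),
    class = "coherence_series"
  )
}

#' Robust decay-rate fit in dB per hour
#'
#' Iteratively reweighted least squares (bisquare weights, tuning constant
#' 4.685) line fit of a dB series against time in hours; the slope is the
#' decay rate. Exponential decay of power in time is linear on the dB scale.
#'
#' @param time times of the series values, in hours (or seconds, see
#'   `time_unit`).
#' @param db series in dB.
#' @param fit_window optional `c(t_start, t_end)` (same unit as `time`)
#'   restricting the fit.
#' @param time_unit `"hours"` or `"seconds"`; seconds are converted so the
#'   slope is always per hour.
#' @param min_windows minimum number of points required (default 10).
#' @return list of class `decay_fit` with `slope` (dB/hour), `intercept`,
#'   `se`, `n_windows`, `residual_scale`, `method`, `fit_window`.
#' @export
decay_rate <- function(time, db, fit_window = NULL, time_unit = c("hours", "seconds"),
                       min_windows = 10) {
  time_unit <- match.arg(time_unit)
  if (inherits(time, "spectral_series")) {
    db <- time$db
    time <- time$time
    time_unit <- "seconds"
  }
  if (time_unit == "seconds") time <- time / 3600
  keep <- is.finite(db) & is.finite(time)
  if (!is.null(fit_window)) {
    fw <- fit_window
    if (time_unit == "seconds") fw <- fw / 3600
    keep <- keep & time >= fw[1] & time <= fw[2]
  } else {
    fw <- range(time[keep])
  }
  t_fit <- time[keep]
  y <- db[keep]
  if (length(y) < min_windows) {
    stop("insufficient windows inside the fit window (", length(y), " < ",
         min_windows, ")")
  }
  fit <- tryCatch(
    MASS::rlm(y ~ t_fit, psi = MASS::psi.bisquare, c = 4.685, maxit = 100),
    error = function(e) lm(y ~ t_fit)
  )
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit)))[2], error = function(e) NA_real_)
  structure(
    list(slope = unname(cf[2]), intercept = unname(cf[1]), se = unname(se),
         n_windows = length(y),
         residual_scale = mad(residuals(fit), center = 0),
         method = "IRLS-bisquare(4.685)",
         fit_window = fw),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> slope %.3f dB/hour (se %.3f, n = %d, %s)\n",
              x$slope, x$se, x$n_windows, x$method))
  invisible(x)
}

#' Paired two-sided permutation test
#'
#' Tests whether paired condition slopes differ by randomizing the condition
#' labels within pairs. The statistic is the mean paired difference; the
#' two-sided p-value is the fraction of sign assignments whose |statistic|
#' is at least the observed one. All `2^n` assignments are enumerated when
#' `2^n <= n_perm`; otherwise `n_perm` random assignments are drawn and the
#' add-one-corrected `p = (b + 1)/(n_perm + 1)` is returned.
#'
#' @param sham,stim numeric vectors of per-subject values, paired by
#'   position (length at least 2).
#' @param n_perm permutation budget (default 10000).
#' @param seed seed for the sampled case.
#' @return list with `p`, `statistic` (mean difference stim - sham), `n`,
#'   `exact`.
#' @export
paired_shuffle_test <- function(sham, stim, n_perm = 10000, seed = 1) {
  stopifnot(length(sham) == length(stim), length(sham) >= 2)
  d <- stim - sham
  n <- length(d)
  obs <- mean(d)
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- as.numeric(signs %*% d) / n
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    exact <- TRUE
  } else {
    b <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(mean(d * sample(c(-1, 1), n, replace = TRUE))) >= abs(obs) - 1e-12
      }, logical(1)))
    })
    p <- (b + 1) / (n_perm + 1)
    exact <- FALSE
  }
  list(p = p, statistic = obs, n = n, exact = exact)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR-adjusted p-values (monotone).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q rejection level for the returned rejection set (default 0.05).
#' @return list with `adjusted` and logical `rejected`.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- p.adjust(pvalues, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Phase locking of an oscillation to a periodic stimulus
#'
#' The signal is band-pass filtered, its instantaneous phase extracted via
#' the analytic signal, and sampled once per stimulus cycle at the ON-ramp
#' onset (the stimulus phase-zero landmark). The phase-locking value is the
#' resultant length of the unit phase vectors (1 = perfect locking) and the
#' Rayleigh test provides a p-value against uniform phase.
#'
#' @param x signal (e.g. LFP).
#' @param fs sampling rate (Hz).
#' @param waveform a [stimulus_waveform()] of kind `"onoff"` (its frequency
#'   and schedule define the cycle landmarks), or a numeric vector of
#'   landmark times (s).
#' @param band band-pass edges (Hz).
#' @param t0 time of the first sample.
#' @param duration total signal duration (s); inferred from `x` and `fs`.
#' @return list with `plv`, `mean_phase` (cycles in `[-0.5, 0.5)`),
#'   `rayleigh_p`, `n_cycles`, and the per-cycle `phases` (cycles).
#' @export
phase_locking <- function(x, fs, waveform, band = c(0.5, 1), t0 = 0,
                          duration = NULL) {
  duration <- duration %||% (t0 + length(x) / fs)
  if (inherits(waveform, "stimulus_waveform")) {
    period <- 1 / waveform$frequency
    sched <- waveform$schedule
    if (is.null(sched)) sched <- matrix(c(0, duration), 1)
    landmarks <- unlist(lapply(seq_len(nrow(sched)), function(k) {
      seq(sched[k, 1], sched[k, 2] - period / 2, by = period)
    }))
  } else {
    landmarks <- waveform
  }
  landmarks <- landmarks[landmarks >= t0 + 2 / band[1] &
                           landmarks <= duration - 2 / band[1]]
  if (length(landmarks) < 10) stop("need at least 10 stimulus cycles")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x - mean(x))
  # analytic signal via FFT
  n <- length(xb)
  X <- fft(xb)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  xa <- fft(X * h, inverse = TRUE) / n
  phase <- Arg(xa)
  idx <- pmin(n, pmax(1, round((landmarks - t0) * fs) + 1))
  ph <- phase[idx]
  mv <- mean(exp(1i * ph))
  plv <- Mod(mv)
  n_c <- length(ph)
  # Rayleigh approximation
  Z <- n_c * plv^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n_c) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n_c^2))
  list(plv = plv, mean_phase = Arg(mv) / (2 * pi), rayleigh_p = min(1, max(0, p)),
       n_cycles = n_c, phases = ph / (2 * pi))
}

#' Read a multi-channel delimited signal file
#'
#' Tab-separated channels with a header line `# fs=<Hz>` followed by a
#' column-name row.
#'
#' @param file path.
#' @return list with `signals` (matrix) and `fs`.
#' @export
read_signal_text <- function(file) {
  first <- readLines(file, n = 1)
  if (!grepl("^#\\s*fs=", first)) stop("missing '# fs=<Hz>' header line")
  fs <- as.numeric(sub("^#\\s*fs=", "", first))
  x <- as.matrix(read.table(file, header = TRUE, skip = 1, sep = "\t"))
  list(signals = x, fs = fs)
}

#' @rdname read_signal_text
#' @param signals matrix, one channel per column.
#' @param fs sampling rate (Hz).
#' @export
write_signal_text <- function(signals, fs, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", fs), con)
  sig <- as.data.frame(signals)
  names(sig) <- colnames(signals) %||% paste0("ch", seq_len(ncol(sig)))
  write.table(sig, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
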