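# Simulation driver around the compiled lattice engine.

.swostim_cache <- new.env(parent = emptyenv())

default_coupling <- function(lambda = 0.2) {
  key <- sprintf("cal_%g", lambda)
  if (is.null(.swostim_cache[[key]])) {
    .swostim_cache[[key]] <- calibrate_coupling(lambda = lambda)
  }
  .swostim_cache[[key]]
}

#' Simulation configuration
#'
#' @param network a [build_lattice()] network (typically after
#'   [sample_parameters()]).
#' @param duration simulated time (s).
#' @param dt_ms integration step (ms, default 0.5; the voltage equation is
#'   advanced in two half-steps).
#' @param seed integer seed for the simulation noise stream. Runs are
#'   bit-reproducible given `(config, seed)`; sham stimulation is
#'   bit-identical to no stimulation.
#' @param waveform a [stimulus_waveform()].
#' @param field_profile a `field_profile` (per-column field in V/m), or
#'   `NULL` for no field.
#' @param coupling a [calibrate_coupling()] result; computed once and cached
#'   when `NULL` and a field is applied.
#' @param plasticity a [homeostasis_config()] or `NULL` (disabled).
#' @param noise_sd per-neuron membrane-noise current (model units): the
#'   per-step SD when white, the stationary SD when `noise_tau > 0`.
#' @param noise_tau correlation time (s) of the membrane noise; 0 gives
#'   white noise, positive values an Ornstein-Uhlenbeck process. Slow
#'   fluctuations of background drive jitter the timing of DOWN-to-UP
#'   transitions and set the oscillation's coherence time.
#' @param noise_global_sd stationary SD of an additional network-wide
#'   (shared) drive fluctuation with the same correlation time, emulating
#'   global arousal/neuromodulatory drift; the main determinant of
#'   cycle-to-cycle period jitter and hence of the coherence time.
#' @param lfp_cutoff LFP low-pass cutoff (Hz, default 2.5).
#' @param record_every LFP recording cadence in steps (default 10, i.e.
#'   200 Hz at `dt_ms = 0.5`).
#' @param series_dt cadence of the scalar series (s): mean homeostatic
#'   factor, mean rates, population rate.
#' @param time_compression simulated-seconds-to-night-hours factor: 60 means
#'   1 simulated minute corresponds to 1 hour of night EEG. Used when
#'   expressing decay slopes in dB per night-equivalent hour.
#' @param subregions number of 11x11 recording blocks (0, 1 or 4).
#' @param transient initial period (s) excluded from summary analyses.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(network, duration = 60, dt_ms = 0.5, seed = 1,
                       waveform = stimulus_waveform("sham"),
                       field_profile = NULL, coupling = NULL,
                       plasticity = NULL, noise_sd = 2, noise_tau = 4,
                       noise_global_sd = 0.9,
                       lfp_cutoff = 2.5, record_every = 10,
                       series_dt = 0.1, time_compression = 60,
                       subregions = 4, transient = 5) {
  stopifnot(inherits(network, "lattice_network"), duration > 0,
            dt_ms > 0, dt_ms <= 1, lfp_cutoff > 0)
  structure(
    list(network = network, duration = duration, dt_ms = dt_ms, seed = seed,
         waveform = waveform, field_profile = field_profile,
         coupling = coupling, plasticity = plasticity, noise_sd = noise_sd,
         noise_tau = noise_tau, noise_global_sd = noise_global_sd,
         lfp_cutoff = lfp_cutoff, record_every = record_every,
         series_dt = series_dt, time_compression = time_compression,
         subregions = subregions, transient = transient),
    class = "sim_config"
  )
}

#' Run a lattice simulation
#'
#' Integrates all neurons with synaptic, excitability, field and (optionally)
#' homeostatic updates at each step and returns spikes, local field
#' potentials (global and per 11x11 subregion, defined as the average
#' postsynaptic current low-pass filtered at the configured cutoff) and the
#' scalar time series needed by the experiment drivers.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_result`.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  net <- cfg$network
  n_steps <- round(cfg$duration / (cfg$dt_ms / 1000))

  # CSR edge lists by presynaptic neuron
  pre <- c(net$exc_edges$pre, net$inh_edges$pre)
  post <- c(net$exc_edges$post, net$inh_edges$post)
  w <- c(net$w_exc, net$w_inh)
  o <- order(pre)
  out_ptr <- c(0L, cumsum(tabulate(pre, nbins = net$n)))

  # per-neuron stimulation current amplitude (signed, model units)
  stim_amp <- numeric(net$n)
  stim_env <- 0
  wf <- cfg$waveform
  if (!is.null(cfg$field_profile) && wf$kind != "sham") {
    stopifnot(length(cfg$field_profile$per_column_field) == net$n_cols)
    cal <- cfg$coupling %||% default_coupling()
    stim_amp <- ifelse(
      net$is_exc,
      cfg$field_profile$per_column_field[net$col] * wf$amplitude *
        cal$current_per_Vm,
      0
    )
    tt <- (seq_len(n_steps) - 1) * cfg$dt_ms / 1000
    stim_env <- waveform_value(wf, tt)
  }

  sub_id <- rep(-1L, net$n)
  n_sub <- 0L
  if (cfg$subregions > 0 && min(net$n_rows, net$n_cols) >= 22) {
    subs <- subregion_indices(net, k = cfg$subregions, size = 11)
    for (k in seq_along(subs)) sub_id[subs[[k]]] <- k - 1L
    n_sub <- length(subs)
  } else if (cfg$subregions == 1) {
    sub_id[] <- 0L
    n_sub <- 1L
  }

  pl <- cfg$plasticity
  plast_enabled <- !is.null(pl) && isTRUE(pl$enabled)
  if (plast_enabled && length(pl$w_hom) != net$n) {
    pl$w_hom <- rep(pl$w_hom[1], net$n)
  }

  series_every <- max(1L, round(cfg$series_dt / (cfg$dt_ms / 1000)))

  raw <- .sim_core(
    n = net$n, is_exc = as.integer(net$is_exc),
    a = net$params$a, b = net$params$b, c = net$params$c, d = net$params$d,
    e_ss = net$params$e_ss,
    out_ptr = out_ptr, out_post = as.integer(post[o] - 1L), out_w = w[o],
    kin = net$kinetics, k_e = net$k_e, tau_r = net$tau_r,
    dt_ms = cfg$dt_ms, n_steps = as.integer(n_steps),
    stim_amp = stim_amp, stim_env = stim_env,
    noise_sd = cfg$noise_sd, noise_tau = cfg$noise_tau %||% 0,
    noise_global_sd = cfg$noise_global_sd %||% 0,
    seed = cfg$seed,
    plast_enabled = plast_enabled,
    r0 = if (plast_enabled) pl$r0 else 1,
    tau_h = if (plast_enabled) pl$tau_h else 1,
    stale_s = if (plast_enabled) pl$staleness else 1,
    w_hom0 = if (plast_enabled) pl$w_hom else rep(1, net$n),
    record_every = as.integer(cfg$record_every), sub_id = sub_id,
    n_sub = n_sub, series_every = as.integer(series_every),
    v0 = rep(-70, net$n), u0 = rep(-70 * 0.2, net$n)
  )

  fs_lfp <- 1000 / cfg$dt_ms / cfg$record_every
  lfp_filtered <- compute_lfp(raw$lfp_raw, fs_lfp, cfg$lfp_cutoff)

  res <- list(
    spikes = data.frame(neuron = raw$spike_neuron, time = raw$spike_time),
    t_lfp = raw$t_lfp, fs_lfp = fs_lfp,
    lfp_raw = raw$lfp_raw[, 1],
    lfp_global = lfp_filtered[, 1],
    lfp_subregions = if (n_sub > 0) lfp_filtered[, -1, drop = FALSE] else NULL,
    series = data.frame(
      t = raw$t_series, w_hom_mean = raw$w_hom_mean,
      r_inst_mean = raw$r_inst_mean, r_mean = raw$r_mean,
      rate_exc = raw$rate_exc, rate_all = raw$rate_all
    ),
    final = list(v = raw$v, u = raw$u, r = raw$r, w_hom = raw$w_hom),
    config = cfg
  )
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %.1f s, %d neurons, %d spikes (%.2f Hz mean rate)\n",
    x$config$duration, x$config$network$n, nrow(x$spikes),
    nrow(x$spikes) / x$config$duration / x$config$network$n
  ))
  invisible(x)
}

#' Low-pass filtered average postsynaptic current (model LFP)
#'
#' Zero-phase 4th-order Butterworth low-pass at `cutoff` Hz applied forwards
#' and backwards.
#'
#' @param x numeric vector or matrix (columns filtered independently).
#' @param fs sampling rate (Hz).
#' @param cutoff cutoff frequency (Hz, default 2.5).
#' @return filtered series, same shape as `x`.
#' @export
compute_lfp <- function(x, fs, cutoff = 2.5) {
  stopifnot(cutoff > 0, fs > 2 * cutoff)
  bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
  f1 <- function(v) signal::filtfilt(bf, v)
  if (is.matrix(x)) apply(x, 2, f1) else f1(x)
}

#' Population firing rate series
#'
#' @param res a `sim_result`.
#' @param bin bin width (s).
#' @param which `"exc"`, `"inh"` or `"all"`.
#' @return data.frame with `t` (bin centers) and `rate` (Hz per neuron).
#' @export
population_rate <- function(res, bin = 0.005, which = c("exc", "all", "inh")) {
  which <- match.arg(which)
  net <- res$config$network
  keep <- switch(which,
    exc = net$is_exc[res$spikes$neuron],
    inh = !net$is_exc[res$spikes$neuron],
    all = rep(TRUE, nrow(res$spikes))
  )
  n_cells <- switch(which, exc = sum(net$is_exc), inh = sum(!net$is_exc),
                    all = net$n)
  n_bins <- floor(res$config$duration / bin)
  idx <- floor(res$spikes$time[keep] / bin) + 1
  counts <- tabulate(idx[idx <= n_bins], nbins = n_bins)
  data.frame(t = (seq_len(n_bins) - 0.5) * bin, rate = counts / bin / n_cells)
}

#' Detect UP and DOWN states by hysteresis thresholding
#'
#' The population rate is smoothed with a 50 ms moving average; an UP state
#' starts when the rate exceeds `on_frac` of its 90th percentile and ends
#' when it falls below `off_frac` of the same reference.
#'
#' @param rate numeric rate series (Hz) or a data.frame from
#'   [population_rate()].
#' @param fs sampling rate of the series (Hz); inferred from a
#'   `population_rate` data.frame.
#' @param smooth_s smoothing window (s).
#' @param on_frac,off_frac hysteresis thresholds as fractions of the 90th
#'   percentile of the smoothed rate.
#' @return data.frame of alternating intervals with columns `state`
#'   (`"UP"`/`"DOWN"`), `start`, `end`, `duration` (s). Empty (with a
#'   warning) if no transitions are found.
#' @export
detect_updown <- function(rate, fs = NULL, smooth_s = 0.05, on_frac = 0.3,
                          off_frac = 0.1) {
  if (is.data.frame(rate)) {
    fs <- 1 / diff(rate$t[1:2])
    t0 <- rate$t[1]
    rate <- rate$rate
  } else {
    stopifnot(!is.null(fs))
    t0 <- 1 / fs / 2
  }
  sm <- smooth_ma(rate, round(smooth_s * fs))
  ref <- quantile(sm, 0.9, names = FALSE)
  thr_on <- on_frac * ref
  thr_off <- off_frac * ref
  if (ref <= 0) {
    warning("no activity; no UP states found")
    return(data.frame(state = character(0), start = numeric(0),
                      end = numeric(0), duration = numeric(0)))
  }
  up <- logical(length(sm))
  cur <- sm[1] > thr_on
  for (i in seq_along(sm)) {
    if (!cur && sm[i] > thr_on) cur <- TRUE
    if (cur && sm[i] < thr_off) cur <- FALSE
    up[i] <- cur
  }
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- c(1, ends[-length(ends)] + 1)
  tt <- t0 + (seq_along(sm) - 1) / fs
  out <- data.frame(
    state = ifelse(r$values, "UP", "DOWN"),
    start = tt[starts],
    end = tt[ends] + 1 / fs
  )
  out$duration <- out$end - out$start
  if (all(out$state == out$state[1])) {
    warning("no UP/DOWN transitions found")
  }
  out
}

#' Mean excitatory firing rate within detected UP states
#'
#' @param res a `sim_result`.
#' @param transient initial period to discard (s); defaults to the config
#'   value.
#' @return list with `rate_up` (Hz per excitatory neuron), `intervals`, and
#'   the fraction of time spent in UP states.
#' @export
up_state_rate <- function(res, transient = NULL) {
  transient <- transient %||% res$config$transient
  pr <- population_rate(res, which = "exc")
  pr <- pr[pr$t >= transient, ]
  iv <- detect_updown(pr)
  up <- iv[iv$state == "UP", ]
  if (nrow(up) == 0) {
    return(list(rate_up = NA_real_, intervals = iv, up_fraction = 0))
  }
  net <- res$config$network
  sp <- res$spikes
  sp <- sp[net$is_exc[sp$neuron] & sp$time >= transient, ]
  n_in_up <- sum(vapply(
    seq_len(nrow(up)),
    function(k) sum(sp$time >= up$start[k] & sp$time < up$end[k]),
    numeric(1)
  ))
  t_up <- sum(up$duration)
  list(
    rate_up = n_in_up / t_up / sum(net$is_exc),
    intervals = iv,
    up_fraction = t_up / (max(pr$t) - transient)
  )
}

#' Dominant frequency of a signal below a maximum frequency
#'
#' Welch-averaged periodogram (20 s segments, mean-detrended, rectangular
#' taper); returns the frequency of the largest power between `fmin` and
#' `fmax`.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param fmin,fmax search band (Hz).
#' @param seg_len segment length (s).
#' @return frequency in Hz.
#' @export
dominant_frequency <- function(x, fs, fmin = 0.2, fmax = 4, seg_len = 20) {
  nseg <- floor(seg_len * fs)
  stopifnot(length(x) >= nseg)
  k <- floor(length(x) / nseg)
  psd <- 0
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)]
    seg <- seg - mean(seg)
    psd <- psd + Mod(fft(seg))^2
  }
  freqs <- (seq_len(nseg) - 1) * fs / nseg
  sel <- freqs >= fmin & freqs <= fmax
  freqs[sel][which.max(psd[sel])]
}

#' Coherence time of an oscillation, in cycles
#'
#' Computes the autocorrelation of the (mean-removed) signal, extracts its
#' local maxima at positive lags (one per oscillation cycle, the envelope of
#' the decaying oscillatory autocorrelation) and finds the lag at which this
#' envelope first falls below `1/e`, interpolating linearly between
#' neighboring peaks. The coherence time is that lag expressed in units of
#' the dominant oscillation period: an irregular oscillation loses memory of
#' its phase within a few cycles.
#'
#' @param x numeric series (e.g. a low-pass filtered LFP).
#' @param fs sampling rate (Hz).
#' @param max_lag_cycles how many oscillation periods of lag to consider.
#' @return list with `cycles` (coherence time), `tau_s` (same in seconds),
#'   `freq` (dominant frequency, Hz) and the envelope peaks.
#' @export
coherence_time <- function(x, fs, max_lag_cycles = 15) {
  f0 <- dominant_frequency(x, fs)
  period <- 1 / f0
  max_lag <- round(max_lag_cycles * period * fs)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags <- (seq_along(ac) - 1) / fs
  # envelope: zero-lag point plus local maxima at least half a period out
  is_peak <- c(FALSE, diff(sign(diff(ac))) < 0, FALSE)
  sel <- which(is_peak & lags > 0.5 * period & ac > 0)
  env_lag <- c(0, lags[sel])
  env_val <- c(1, ac[sel])
  thr <- exp(-1)
  below <- which(env_val < thr)
  if (length(below) == 0) {
    # envelope never crosses 1/e within the window considered
    tau_s <- max(env_lag)
  } else {
    i2 <- below[1]
    i1 <- i2 - 1
    tau_s <- env_lag[i1] + (env_val[i1] - thr) /
      (env_val[i1] - env_val[i2]) * (env_lag[i2] - env_lag[i1])
  }
  list(
    cycles = tau_s / period, tau_s = tau_s, freq = f0,
    peaks = data.frame(lag = env_lag, value = env_val)
  )
}
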