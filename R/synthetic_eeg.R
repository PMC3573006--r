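# Multi-channel sleep-EEG-like signal generator with programmed decay of
# slow-wave band power and spatial coherence, used to validate the analysis
# chain end to end (the human overnight recordings are not packaged).

#' Synthetic sleep-EEG configuration
#'
#' @param n_channels number of channels (default 11, as in a reduced
#'   sleep-EEG montage).
#' @param fs sampling rate (Hz); must exceed four times `swo_freq`.
#' @param duration_h recording length (hours).
#' @param power_decay programmed slow-wave band power decay (dB/hour,
#'   negative for decline); scalar or per-channel vector.
#' @param coherence_decay programmed decay of inter-channel band coherence
#'   (dB/hour).
#' @param swo_freq center of the slow-oscillation band (Hz).
#' @param band band of the programmed decays (Hz).
#' @param init_power initial band power (linear units).
#' @param init_coherence initial pairwise band coherence in (0, 1].
#' @param cycle_period_min period of the non-REM/REM modulation envelope
#'   (minutes).
#' @param cycle_depth relative depth of the envelope (0 = none, 0.5 halves
#'   the amplitude at the trough).
#' @param noise_floor relative amplitude of broadband white noise.
#' @param align_offset_h offset of the decay clock relative to the first
#'   sample (hours), mirroring alignment of recordings to stable sleep.
#' @param seed integer seed.
#' @return list of class `synth_eeg_config`.
#' @export
synth_eeg_config <- function(n_channels = 11, fs = 5, duration_h = 7,
                             power_decay = -1.22, coherence_decay = -0.70,
                             swo_freq = 0.75, band = c(0.5, 1),
                             init_power = 1, init_coherence = 0.6,
                             cycle_period_min = 90, cycle_depth = 0.5,
                             noise_floor = 0.05, align_offset_h = 0,
                             seed = 1) {
  stopifnot(n_channels >= 2, fs > 4 * swo_freq, duration_h > 0,
            init_coherence > 0, init_coherence <= 1,
            cycle_depth >= 0, cycle_depth < 1)
  structure(
    list(n_channels = n_channels, fs = fs, duration_h = duration_h,
         power_decay = power_decay, coherence_decay = coherence_decay,
         swo_freq = swo_freq, band = band, init_power = init_power,
         init_coherence = init_coherence,
         cycle_period_min = cycle_period_min, cycle_depth = cycle_depth,
         noise_floor = noise_floor, align_offset_h = align_offset_h,
         seed = seed),
    class = "synth_eeg_config"
  )
}

# Band-limited unit-band-power noise source.
narrowband_source <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  # normalize so the analysis-convention band power is 1
  x <- x - mean(x)
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  bp <- sum(2 * (Mod(fft(x))^2)[sel] / n^2)
  x / sqrt(bp)
}

#' Generate a synthetic multi-channel sleep-EEG-like recording
#'
#' Each channel mixes a shared narrowband (slow-oscillation band) source
#' with an independent per-channel narrowband source. The shared-variance
#' fraction `phi(t)` is scheduled so that the pairwise band coherence
#' (approximately `phi(t)^2` for this estimator) decays at
#' `coherence_decay` dB/hour, while the total band amplitude is scheduled so
#' that band power decays at `power_decay` dB/hour. A multiplicative
#' non-REM/REM envelope, identical across channels, modulates amplitudes on
#' the sleep-cycle time scale, and white broadband noise is added at
#' `noise_floor` relative amplitude.
#'
#' @param cfg a [synth_eeg_config()].
#' @return list of class `synth_eeg` with `signals` (samples x channels),
#'   `fs`, and `truth` (programmed slopes, schedules, seed).
#' @export
generate_eeg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_eeg_config"))
  n <- round(cfg$duration_h * 3600 * cfg$fs)
  t_h <- (seq_len(n) - 1) / cfg$fs / 3600 + cfg$align_offset_h
  pd <- rep(cfg$power_decay, length.out = cfg$n_channels)

  # the programmed coherence refers to what the windowed magnitude-squared
  # coherence estimator measures; that estimator has a positive bias of
  # about (1 - C)/K for K averaged sub-segments, so the generated shared
  # fraction is pre-compensated for it (K = 8 matches the default 40 s
  # windows with 5 s sub-segments)
  # E[estimate] = C + (1 - C)^2 / K for true coherence C; invert the
  # quadratic so the measured series decays at the programmed rate
  K <- 8
  m_t <- cfg$init_coherence * 10^(cfg$coherence_decay * t_h / 10)
  if (min(m_t) < 1 / K || max(m_t) > 1) {
    stop("infeasible decay combination: required shared fraction is ",
         "outside [0, 1] for this duration")
  }
  b <- 1 - 2 / K
  phi2 <- (-b + sqrt(b^2 - 4 * (1 / K) * (1 / K - m_t))) / (2 / K)
  phi2 <- pmin(1, pmax(0, phi2))
  phi <- sqrt(phi2)

  # the non-REM/REM envelope is snapped to an integer number of cycles over
  # the recording so the periodic modulation cannot leak into the fitted
  # decay trend
  n_cyc <- max(1, round(cfg$duration_h * 60 / cfg$cycle_period_min))
  cyc <- 1 - cfg$cycle_depth / 2 +
    (cfg$cycle_depth / 2) * cos(2 * pi * t_h * n_cyc / cfg$duration_h)

  with_seed(cfg$seed, {
    shared <- narrowband_source(n, cfg$fs, cfg$band)
    signals <- matrix(0, n, cfg$n_channels)
    for (ch in seq_len(cfg$n_channels)) {
      own <- narrowband_source(n, cfg$fs, cfg$band)
      amp <- sqrt(cfg$init_power * 10^(pd[ch] * t_h / 10))
      x <- amp * cyc * (sqrt(phi) * shared + sqrt(1 - phi) * own)
      signals[, ch] <- x + cfg$noise_floor * rnorm(n)
    }
    colnames(signals) <- paste0("ch", seq_len(cfg$n_channels))
    structure(
      list(signals = signals, fs = cfg$fs,
           truth = list(power_decay = pd,
                        coherence_decay = cfg$coherence_decay,
                        init_power = cfg$init_power,
                        init_coherence = cfg$init_coherence,
                        seed = cfg$seed)),
      class = "synth_eeg"
    )
  })
}

#' Generate a paired sham/stimulation synthetic study
#'
#' Produces `n_subjects` paired recordings whose programmed power decays are
#' the given condition slopes plus a subject-level random offset shared
#' within the pair, for end-to-end rehearsal of the paired permutation
#' statistics.
#'
#' @param cfg a [synth_eeg_config()] template.
#' @param sham_slope,stim_slope condition power-decay slopes (dB/hour).
#' @param n_subjects number of subjects (at least 2).
#' @param subject_sd SD of the subject-level slope offset (dB/hour).
#' @param seed integer seed.
#' @return list with `sham` and `stim` (lists of `synth_eeg`) and `truth`
#'   (per-subject programmed slopes).
#' @export
generate_condition_pair <- function(cfg, sham_slope, stim_slope,
                                    n_subjects = 10, subject_sd = 0.3,
                                    seed = 1) {
  stopifnot(n_subjects >= 2)
  offs <- with_seed(seed, rnorm(n_subjects, 0, subject_sd))
  sham <- vector("list", n_subjects)
  stim <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    cs <- cfg
    cs$power_decay <- sham_slope + offs[s]
    cs$seed <- seed + 1000L + s
    sham[[s]] <- generate_eeg(cs)
    ct <- cfg
    ct$power_decay <- stim_slope + offs[s]
    ct$seed <- seed + 2000L + s
    stim[[s]] <- generate_eeg(ct)
  }
  list(sham = sham, stim = stim,
       truth = data.frame(subject = seq_len(n_subjects),
                          sham_slope = sham_slope + offs,
                          stim_slope = stim_slope + offs))
}
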