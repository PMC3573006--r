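#' Stimulation waveform
#'
#' Time course of the applied field envelope. `"sham"` is zero everywhere,
#' `"dc"` is constant 1 inside the active schedule, and `"onoff"` is a
#' 0.75 Hz (by default) trapezoid: the field ramps up, holds, and ramps down
#' within the ON half-period and is zero during the OFF half-period.
#'
#' @param kind `"sham"`, `"dc"` or `"onoff"`.
#' @param frequency ON/OFF cycle frequency in Hz (default 0.75).
#' @param amplitude field amplitude in V/m multiplying the spatial profile.
#' @param ramp_fraction fraction of the ON half-period spent on each ramp
#'   (default 0.1).
#' @param schedule optional two-column matrix/data.frame of active epochs
#'   `(start, end)` in seconds; `NULL` means always active.
#' @return list of class `stimulus_waveform`.
#' @export
stimulus_waveform <- function(kind = c("sham", "dc", "onoff"),
                              frequency = 0.75, amplitude = 1,
                              ramp_fraction = 0.1, schedule = NULL) {
  kind <- match.arg(kind)
  stopifnot(frequency > 0, ramp_fraction >= 0, ramp_fraction <= 0.5)
  if (!is.null(schedule)) {
    schedule <- as.matrix(schedule)
    stopifnot(ncol(schedule) == 2, all(schedule[, 2] > schedule[, 1]))
  }
  structure(
    list(kind = kind, frequency = frequency, amplitude = amplitude,
         ramp_fraction = ramp_fraction, schedule = schedule),
    class = "stimulus_waveform"
  )
}

#' Evaluate the stimulation envelope
#'
#' @param w a [stimulus_waveform()].
#' @param t time or vector of times (s).
#' @return envelope values in `[0, 1]` (amplitude is applied elsewhere).
#'   For `"onoff"`, phase 0 is the ON-ramp onset, measured from the start of
#'   the enclosing schedule epoch.
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "stimulus_waveform"))
  if (w$kind == "sham") return(rep(0, length(t)))
  if (is.null(w$schedule)) {
    active <- rep(TRUE, length(t))
    t_rel <- t
  } else {
    active <- rep(FALSE, length(t))
    t_rel <- t
    for (k in seq_len(nrow(w$schedule))) {
      in_k <- t >= w$schedule[k, 1] & t < w$schedule[k, 2]
      active[in_k] <- TRUE
      t_rel[in_k] <- t[in_k] - w$schedule[k, 1]
    }
  }
  if (w$kind == "dc") return(as.numeric(active))
  period <- 1 / w$frequency
  half <- period / 2
  ramp <- w$ramp_fraction * half
  ph <- t_rel %% period
  env <- numeric(length(t))
  if (ramp > 0) {
    up <- ph < ramp
    env[up] <- ph[up] / ramp
    plateau <- ph >= ramp & ph < half - ramp
    env[plateau] <- 1
    down <- ph >= half - ramp & ph < half
    env[down] <- (half - ph[down]) / ramp
  } else {
    env[ph < half] <- 1
  }
  env * as.numeric(active)
}

#' Calibrate the field-to-current coupling
#'
#' A weak electric field polarizes the soma of a pyramidal neuron in
#' proportion to the field: `lambda` mV per V/m (default 0.2, the value
#' measured for rat hippocampal pyramidal cells). The field is modelled as a
#' somatic current injection; this routine measures the neuron's
#' subthreshold input resistance `z` (mV per current unit) by integrating the
#' quiescent neuron under a small probe current to steady state, then sets
#' `current_per_Vm = lambda / z` and refines it so that a sustained 1 V/m
#' field produces exactly `lambda` mV of depolarization (subthreshold
#' response is weakly nonlinear; the refinement removes the residual error).
#'
#' Calibration uses an isolated neuron with no excitability bias (the bias is
#' a network-state variable, not part of the resting cell).
#'
#' @param params a [neuron_params()] (excitatory by default).
#' @param lambda somatic sensitivity in mV per V/m.
#' @param probe_current probe amplitude (model current units).
#' @param settle integration time to steady state (s).
#' @return list of class `coupling_calibration` with `lambda_mV_per_Vm`,
#'   `z_mV_per_current`, `current_per_Vm`, `v_rest`.
#' @export
calibrate_coupling <- function(params = neuron_params("excitatory"),
                               lambda = 0.2, probe_current = 0.05,
                               settle = 2) {
  p0 <- params
  p0$e_ss <- 0  # quiescent: no excitability bias during calibration
  rest <- simulate_neuron(p0, 0, settle)
  if (length(rest$spike_times) > 0) {
    stop("neuron spikes at rest; cannot calibrate coupling")
  }
  v_rest <- rest$state$v
  measure <- function(I) {
    out <- simulate_neuron(p0, I, settle)
    if (length(out$spike_times) > 0) {
      stop("neuron spikes during calibration; use a smaller probe current")
    }
    out$state$v - v_rest
  }
  z <- measure(probe_current) / probe_current
  cpv <- lambda / z
  # fixed-point refinement at the working current (per 1 V/m)
  for (k in 1:4) {
    dv <- measure(cpv)
    if (abs(dv - lambda) < 1e-3 * lambda) break
    cpv <- cpv * lambda / dv
  }
  structure(
    list(lambda_mV_per_Vm = lambda, z_mV_per_current = z,
         current_per_Vm = cpv, v_rest = v_rest),
    class = "coupling_calibration"
  )
}

#' Stimulation current for one neuron
#'
#' Excitatory neurons receive `field[col] * envelope(t) * current_per_Vm`;
#' inhibitory somata are symmetric and receive no field-induced current.
#'
#' @param profile a [make_field_profile()] (per-column field, V/m).
#' @param cal a [calibrate_coupling()].
#' @param w a [stimulus_waveform()].
#' @param t time (s).
#' @param col lattice column of the neuron.
#' @param is_excitatory logical.
#' @return current in model units.
#' @export
field_current <- function(profile, cal, w, t, col, is_excitatory) {
  if (!is_excitatory) return(0)
  profile$per_column_field[col] * w$amplitude * waveform_value(w, t) *
    cal$current_per_Vm
}

#' Map sampled cortical radial fields onto lattice columns
#'
#' Mirrors the published field-profile workflow: the signed radial-field
#' samples are sorted, the top and bottom `trim_pct` percent are excluded
#' (`floor(trim_pct/100 * n)` samples per tail), `n_cols` values are taken at
#' evenly spaced ranks of the trimmed list, and amplitudes are rescaled so
#' that the mean absolute field equals `target_mean_abs` (default
#' 0.93 V/m). Signs are preserved, so mixed-polarity profiles stay mixed.
#'
#' @param samples numeric vector of signed radial fields (V/m).
#' @param n_cols number of lattice columns (default 30).
#' @param trim_pct percentile excluded per tail (default 3.12).
#' @param target_mean_abs target mean absolute field (V/m, default 0.93).
#' @return list of class `field_profile` with `per_column_field` and
#'   `source_meta`.
#' @export
make_field_profile <- function(samples, n_cols = 30, trim_pct = 3.12,
                               target_mean_abs = 0.93) {
  stopifnot(length(samples) >= n_cols, trim_pct >= 0, trim_pct < 50)
  s <- sort(samples)
  k <- floor(trim_pct / 100 * length(s))
  if (k > 0) s <- s[(k + 1):(length(s) - k)]
  idx <- floor(seq(1, length(s), length.out = n_cols))
  prof <- s[idx]
  m <- mean(abs(prof))
  if (m == 0) stop("all sampled fields are zero; cannot rescale profile")
  prof <- prof * target_mean_abs / m
  structure(
    list(per_column_field = prof,
         source_meta = list(n_samples = length(samples),
                            trim_pct = trim_pct,
                            target_mean_abs = target_mean_abs)),
    class = "field_profile"
  )
}

#' Uniform or split-polarity field profile
#'
#' Utility for intensity sweeps: the first `ceiling(frac_depolarized *
#' n_cols)` columns get field `+1` V/m and the remainder `-1` V/m (scaled by
#' the waveform amplitude at run time).
#'
#' @param frac_depolarized fraction of columns with depolarizing (positive)
#'   field.
#' @param n_cols number of lattice columns.
#' @return a `field_profile`.
#' @export
polarity_profile <- function(frac_depolarized = 1, n_cols = 30) {
  stopifnot(frac_depolarized >= 0, frac_depolarized <= 1)
  n_pos <- ceiling(frac_depolarized * n_cols)
  f <- c(rep(1, n_pos), rep(-1, n_cols - n_pos))
  structure(
    list(per_column_field = f,
         source_meta = list(frac_depolarized = frac_depolarized)),
    class = "field_profile"
  )
}

#' Synthetic mixed-polarity field samples
#'
#' Surrogate for the anatomical current-flow model: draws signed radial-field
#' values from a two-lobe distribution (folded-normal magnitudes with
#' positive or negative sign) so that profiles show the mixed polarities
#' observed on folded cortex.
#'
#' @param n number of samples (at least 100).
#' @param frac_positive probability of the depolarizing lobe.
#' @param scale magnitude scale (V/m).
#' @param seed integer seed.
#' @return numeric vector of signed field values.
#' @export
synth_field_samples <- function(n, frac_positive = 0.55, scale = 1,
                                seed = 1) {
  stopifnot(n >= 100, frac_positive >= 0, frac_positive <= 1)
  with_seed(seed, {
    pos <- runif(n) < frac_positive
    mag <- abs(rnorm(n, mean = scale, sd = 0.5 * scale))
    ifelse(pos, mag, -mag)
  })
}

#' Read / write field samples as single-column delimited text
#'
#' @param file path; the file has a one-line header.
#' @param samples numeric vector for writing.
#' @return `read_field_samples` returns a numeric vector.
#' @export
read_field_samples <- function(file) {
  read.table(file, header = TRUE)[[1]]
}

#' @rdname read_field_samples
#' @export
write_field_samples <- function(samples, file) {
  write.table(data.frame(field_Vm = samples), file, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(file)
}
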