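# In-silico experiment drivers: intensity/polarity sweeps, compressed-night
# runs with homeostatic plasticity, electrode matching, connectivity sweeps.

#' Mean excitatory firing rate of a run after the transient
#'
#' @param res a `sim_result`.
#' @param transient discard period (s).
#' @return Hz per excitatory neuron.
#' @export
mean_exc_rate <- function(res, transient = NULL) {
  transient <- transient %||% res$config$transient
  net <- res$config$network
  sp <- res$spikes
  keep <- net$is_exc[sp$neuron] & sp$time >= transient
  sum(keep) / (res$config$duration - transient) / sum(net$is_exc)
}

#' Stimulation-intensity / polarity-fraction sweep
#'
#' For each grid cell, a fraction of lattice columns receives a depolarizing
#' field and the rest a hyperpolarizing field of the same magnitude; the
#' change in mean excitatory firing rate relative to a sham run with the
#' same network and noise stream is reported. For ON/OFF stimulation the
#' phase of the network oscillation relative to the stimulus (phase-locking
#' value and circular mean at the ON-ramp onset) is also measured.
#'
#' @param intensities field magnitudes (V/m).
#' @param fractions fractions of columns depolarized, in `[0, 1]`.
#' @param mode `"dc"` or `"onoff"`.
#' @param reps independent network/noise replicates per cell.
#' @param duration run length per cell (s).
#' @param seed base seed.
#' @param network_args extra arguments to [build_lattice()].
#' @return data.frame with one row per (intensity, fraction, rep):
#'   `rate`, `sham_rate`, `d_rate`, and for ON/OFF `plv`, `phase` (cycles).
#'   The attribute `sham_se` carries the standard error of the sham rates.
#' @export
sweep_stimulation <- function(intensities, fractions,
                              mode = c("onoff", "dc"), reps = 3,
                              duration = 20, seed = 1,
                              network_args = list()) {
  mode <- match.arg(mode)
  grid <- expand.grid(intensity = intensities, fraction = fractions,
                      rep = seq_len(reps))
  grid$rate <- NA_real_
  grid$sham_rate <- NA_real_
  if (mode == "onoff") {
    grid$plv <- NA_real_
    grid$phase <- NA_real_
  }
  sham_rates <- numeric(reps)
  nets <- vector("list", reps)
  for (r in seq_len(reps)) {
    net <- do.call(build_lattice, c(list(seed = seed + r), network_args))
    net <- sample_parameters(net, seed = seed + 100 + r)
    nets[[r]] <- net
    sham <- run_simulation(sim_config(net, duration = duration,
                                      seed = seed + 200 + r,
                                      subregions = 0))
    sham_rates[r] <- mean_exc_rate(sham)
  }
  for (i in seq_len(nrow(grid))) {
    r <- grid$rep[i]
    net <- nets[[r]]
    prof <- polarity_profile(grid$fraction[i], net$n_cols)
    wf <- stimulus_waveform(mode, amplitude = grid$intensity[i])
    res <- run_simulation(sim_config(net, duration = duration,
                                     seed = seed + 200 + r,
                                     waveform = wf, field_profile = prof,
                                     subregions = 0))
    grid$rate[i] <- mean_exc_rate(res)
    grid$sham_rate[i] <- sham_rates[r]
    if (mode == "onoff") {
      tr <- res$config$transient
      i0 <- which(res$t_lfp >= tr)[1]
      pl <- tryCatch(
        phase_locking(res$lfp_global[i0:length(res$lfp_global)],
                      res$fs_lfp, wf, t0 = res$t_lfp[i0],
                      duration = duration),
        error = function(e) list(plv = NA_real_, mean_phase = NA_real_)
      )
      grid$plv[i] <- pl$plv
      grid$phase[i] <- pl$mean_phase
    }
  }
  grid$d_rate <- grid$rate - grid$sham_rate
  attr(grid, "sham_se") <- sd(sham_rates) / sqrt(reps)
  grid
}

#' Default compressed-night stimulation protocol
#'
#' Five stimulation blocks separated by four gaps, scaled from the human
#' protocol (5 x 5 min blocks with 1 min gaps) by the time-compression
#' factor: with the default compression of 60 (one simulated minute per
#' night hour), blocks last 5 s and gaps 1 s.
#'
#' @param start onset of the first block (s of simulated time).
#' @param compression time-compression factor.
#' @return two-column matrix of `(start, end)` epochs (s).
#' @export
night_protocol <- function(start, compression = 60) {
  block <- 300 / compression
  gap <- 60 / compression
  starts <- start + (0:4) * (block + gap)
  unname(cbind(starts, starts + block))
}

#' A compressed-night simulation with homeostatic plasticity
#'
#' Runs a pre-stimulation baseline, the stimulation epoch (sham or 0.75 Hz
#' ON/OFF at `stim_field` V/m) and a post-stimulation period in one
#' continuous simulation with homeostatic scaling enabled, then fits the
#' post-stimulation decay of slow-wave band power (global LFP) and spatial
#' coherence (four 11x11 subregion LFPs), expressed in dB per
#' night-equivalent hour.
#'
#' @param condition `"sham"` or `"stim"`.
#' @param net_seed seed for the network and parameter randomization.
#' @param noise_seed seed for the simulation noise stream (shared between
#'   paired sham/stim runs).
#' @param stim_field field magnitude (V/m, default 0.31).
#' @param profile spatial profile; default uniform depolarizing.
#' @param pre,post baseline and post-stimulation durations (s).
#' @param r0,tau_h,staleness homeostasis parameters (see
#'   [homeostasis_config()]); `tau_h` is in simulated seconds, i.e. already
#'   compressed.
#' @param w_init initial homeostatic factor; values above 1 represent
#'   synapses potentiated by prior wakefulness.
#' @param compression time-compression factor (simulated seconds to night
#'   hours: one night hour is `3600/compression` simulated seconds).
#' @param power_window,coh_window analysis window lengths (s of simulated
#'   time) for the power and coherence series.
#' @param network_args extra arguments to [build_lattice()].
#' @param noise_sd membrane noise (model units).
#' @return list of class `night_run` with the decay fits, series, mean
#'   homeostatic-factor trajectory and the full `sim_result`.
#' @export
night_run <- function(condition = c("sham", "stim"), net_seed = 1,
                      noise_seed = 1, stim_field = 0.31, profile = NULL,
                      pre = 30, post = 270, r0 = 0.2, tau_h = 120000,
                      w_init = 1.3, staleness = 5, compression = 60,
                      power_window = 15, coh_window = 15,
                      network_args = list(), noise_sd = 2) {
  condition <- match.arg(condition)
  net <- do.call(build_lattice, c(list(seed = net_seed), network_args))
  net <- sample_parameters(net, seed = net_seed + 5000L)
  sched <- night_protocol(pre, compression)
  stim_len <- max(sched) - pre
  duration <- pre + stim_len + post
  wf <- if (condition == "stim") {
    stimulus_waveform("onoff", amplitude = stim_field, schedule = sched)
  } else {
    stimulus_waveform("sham")
  }
  profile <- profile %||% polarity_profile(1, net$n_cols)
  pl <- homeostasis_config(n = net$n, r0 = r0, tau_h = tau_h,
                           staleness = staleness, w_init = w_init)
  cfg <- sim_config(net, duration = duration, seed = noise_seed,
                    waveform = wf,
                    field_profile = if (condition == "stim") profile else NULL,
                    plasticity = pl, noise_sd = noise_sd,
                    time_compression = compression)
  res <- run_simulation(cfg)

  t_end_stim <- max(sched)
  i_post <- which(res$t_lfp >= t_end_stim)
  to_hours <- compression / 3600
  pw <- band_power_series(res$lfp_global[i_post], res$fs_lfp,
                          window_len = power_window,
                          t0 = res$t_lfp[i_post[1]])
  power_fit <- decay_rate(pw$time * to_hours, pw$db)
  # as with multi-electrode EEG, fit each subregion LFP and average the
  # slopes; the averaged slope is much less sensitive to single-window noise
  if (!is.null(res$lfp_subregions)) {
    sub_slopes <- apply(res$lfp_subregions[i_post, , drop = FALSE], 2,
                        function(ch) {
      bp <- band_power_series(ch, res$fs_lfp, window_len = power_window,
                              t0 = res$t_lfp[i_post[1]])
      decay_rate(bp$time * to_hours, bp$db)$slope
    })
    power_fit$slope_global <- power_fit$slope
    power_fit$sub_slopes <- sub_slopes
    power_fit$slope <- mean(c(power_fit$slope_global, sub_slopes))
  }
  coh_fit <- NULL
  ch <- NULL
  if (!is.null(res$lfp_subregions)) {
    ch <- spatial_coherence_series(res$lfp_subregions[i_post, , drop = FALSE],
                                   res$fs_lfp, window_len = coh_window,
                                   seg_len = 5,
                                   t0 = res$t_lfp[i_post[1]])
    mean_db <- rowMeans(ch$db)
    coh_fit <- tryCatch(decay_rate(ch$time * to_hours, mean_db),
                        error = function(e) NULL)
  }
  # mean homeostatic factor at start and end of the stimulation epoch
  w_at <- function(t) {
    i <- which.min(abs(res$series$t - t))
    res$series$w_hom_mean[i]
  }
  structure(
    list(condition = condition, power_fit = power_fit, coh_fit = coh_fit,
         power_series = pw, coherence_series = ch,
         w_hom = res$series[, c("t", "w_hom_mean")],
         w_drop_stim = w_at(pre) - w_at(t_end_stim),
         schedule = sched, compression = compression,
         net_seed = net_seed, noise_seed = noise_seed,
         result = res),
    class = "night_run"
  )
}

#' @export
print.night_run <- function(x, ...) {
  cat(sprintf(
    "<night_run> %s: power decay %.3f dB/h, coherence decay %s dB/h\n",
    x$condition, x$power_fit$slope,
    if (is.null(x$coh_fit)) "NA" else sprintf("%.3f", x$coh_fit$slope)
  ))
  invisible(x)
}

#' Paired sham/stimulation compressed nights
#'
#' Runs `n_pairs` paired compressed nights (identical network and noise
#' seeds within a pair) and summarizes the after-stimulation decay ordering
#' and the homeostatic-factor drop during the stimulation epoch.
#'
#' @param n_pairs number of pairs (default 10).
#' @param seed base seed.
#' @param ... forwarded to [night_run()].
#' @return list with the per-pair table, the sign-test p-value for reduced
#'   post-stimulation decay magnitude under stimulation, and the count of
#'   pairs with faster homeostatic decline during stimulation.
#' @export
night_experiment <- function(n_pairs = 10, seed = 1, ...) {
  rows <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    sham <- night_run("sham", net_seed = seed + k, noise_seed = seed + 50 + k,
                      ...)
    stim <- night_run("stim", net_seed = seed + k, noise_seed = seed + 50 + k,
                      ...)
    rows[[k]] <- data.frame(
      pair = k,
      sham_power = sham$power_fit$slope, stim_power = stim$power_fit$slope,
      sham_coh = if (is.null(sham$coh_fit)) NA else sham$coh_fit$slope,
      stim_coh = if (is.null(stim$coh_fit)) NA else stim$coh_fit$slope,
      sham_wdrop = sham$w_drop_stim, stim_wdrop = stim$w_drop_stim
    )
  }
  tab <- do.call(rbind, rows)
  reduced <- abs(tab$stim_power) < abs(tab$sham_power)
  p_sign <- stats::binom.test(sum(reduced), n_pairs,
                              alternative = "greater")$p.value
  list(pairs = tab, n_reduced = sum(reduced), sign_p = p_sign,
       n_faster_wdrop = sum(tab$stim_wdrop > tab$sham_wdrop))
}

#' Match model networks to per-location target decay rates
#'
#' For each location (EEG electrode), random network-weight seeds are tried
#' until a sham compressed night matches the location's target decay rate
#' within `tol` dB/hour; the matched network is then stimulated using the
#' location's field profile (mean absolute field `target_mean_abs` V/m) and
#' the change in decay rate is reported.
#'
#' @param target_decays per-location sham power-decay targets (dB/hour).
#' @param field_samples list of per-location signed radial-field sample
#'   vectors (from a current-flow model or [synth_field_samples()]).
#' @param tol matching tolerance (dB/hour, default 0.15).
#' @param budget maximum seeds tried per location (default 200).
#' @param seed base seed.
#' @param target_mean_abs profile scaling (V/m, default 0.93).
#' @param reference_effects optional per-location reference effect sizes to
#'   correlate with the model's (stim - sham) effects.
#' @param ... forwarded to [night_run()].
#' @return list with the per-location table (`target`, `matched_seed`,
#'   `sham_decay`, `stim_decay`, `effect`, `matched`), and, when reference
#'   effects are supplied, their Pearson and Spearman correlations with the
#'   model effects.
#' @export
electrode_match <- function(target_decays, field_samples, tol = 0.15,
                            budget = 200, seed = 1, target_mean_abs = 0.93,
                            reference_effects = NULL, ...) {
  n_loc <- length(target_decays)
  stopifnot(n_loc >= 2, length(field_samples) == n_loc)
  rows <- vector("list", n_loc)
  for (loc in seq_len(n_loc)) {
    matched_seed <- NA_integer_
    sham_slope <- NA_real_
    tried <- 0L
    for (s in seq_len(budget)) {
      tried <- tried + 1L
      cand <- night_run("sham", net_seed = seed + 997L * loc + s,
                        noise_seed = seed + 31L * loc + s, ...)
      if (abs(cand$power_fit$slope - target_decays[loc]) <= tol) {
        matched_seed <- seed + 997L * loc + s
        sham_slope <- cand$power_fit$slope
        break
      }
    }
    stim_slope <- NA_real_
    if (!is.na(matched_seed)) {
      n_cols <- tryCatch(list(...)$network_args$n_cols, error = function(e) NULL)
      prof <- make_field_profile(field_samples[[loc]],
                                 n_cols = n_cols %||% 30,
                                 target_mean_abs = target_mean_abs)
      stim <- night_run("stim", net_seed = matched_seed,
                        noise_seed = seed + 31L * loc + (matched_seed - seed - 997L * loc),
                        profile = prof, ...)
      stim_slope <- stim$power_fit$slope
    }
    rows[[loc]] <- data.frame(
      location = loc, target = target_decays[loc],
      matched_seed = matched_seed, seeds_tried = tried,
      sham_decay = sham_slope, stim_decay = stim_slope,
      effect = stim_slope - sham_slope, matched = !is.na(matched_seed)
    )
  }
  tab <- do.call(rbind, rows)
  out <- list(locations = tab)
  if (!is.null(reference_effects)) {
    ok <- tab$matched
    out$pearson <- stats::cor(tab$effect[ok], reference_effects[ok])
    out$spearman <- stats::cor(tab$effect[ok], reference_effects[ok],
                               method = "spearman")
  }
  out
}

#' Field-effect dependence on network size and synaptic in-degree
#'
#' Measures the normalized change in mean excitatory firing rate under a
#' uniform depolarizing DC field while varying (a) the lattice size at fixed
#' neighborhood and (b) the excitatory neighborhood size (in-degree) at
#' fixed lattice, optionally rescaling per-synapse weights so that the total
#' excitatory input is held constant.
#'
#' @param sizes lattice edge lengths to test.
#' @param nbhds excitatory neighborhood sizes to test (odd).
#' @param field DC field magnitude (V/m).
#' @param hold_total_input rescale `w_exc_mean` by `(ref_nbhd^2 - 1) /
#'   (nbhd^2 - 1)` so total input is fixed while in-degree varies.
#' @param duration run length (s).
#' @param seed base seed.
#' @param reps replicates per condition.
#' @return data.frame with `varied` (`"size"`/`"degree"`), the varied value,
#'   the mean in-degree, and the normalized rate change
#'   `(rate - sham)/sham`.
#' @export
connectivity_sweep <- function(sizes = c(20, 30), nbhds = c(3, 5, 7),
                               field = 1, hold_total_input = FALSE,
                               duration = 20, seed = 1, reps = 2) {
  run_one <- function(n_side, nbhd, w_scale, s) {
    kin <- synapse_kinetics()
    kin$w_exc_mean <- kin$w_exc_mean * w_scale
    net <- build_lattice(n_side, n_side, seed = s, exc_nbhd = nbhd,
                         kinetics = kin)
    net <- sample_parameters(net, seed = s + 100)
    sham <- run_simulation(sim_config(net, duration = duration, seed = s,
                                      subregions = 0))
    prof <- polarity_profile(1, net$n_cols)
    wf <- stimulus_waveform("dc", amplitude = field)
    stim <- run_simulation(sim_config(net, duration = duration, seed = s,
                                      waveform = wf, field_profile = prof,
                                      subregions = 0))
    r0 <- mean_exc_rate(sham)
    c(norm_d_rate = (mean_exc_rate(stim) - r0) / r0,
      in_degree = 0.8 * (nbhd^2 - 1))
  }
  rows <- list()
  ref_nbhd <- 5
  for (ns in sizes) {
    for (r in seq_len(reps)) {
      v <- run_one(ns, ref_nbhd, 1, seed + 10 * ns + r)
      rows[[length(rows) + 1]] <- data.frame(
        varied = "size", value = ns, in_degree = v["in_degree"],
        rep = r, norm_d_rate = v["norm_d_rate"]
      )
    }
  }
  for (nb in nbhds) {
    w_scale <- if (hold_total_input) (ref_nbhd^2 - 1) / (nb^2 - 1) else 1
    for (r in seq_len(reps)) {
      v <- run_one(max(sizes), nb, w_scale, seed + 1000 + 10 * nb + r)
      rows[[length(rows) + 1]] <- data.frame(
        varied = "degree", value = nb, in_degree = v["in_degree"],
        rep = r, norm_d_rate = v["norm_d_rate"]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled entrainment measurement for weak ON/OFF stimulation
#'
#' Weak-field entrainment of the slow oscillation is a small per-cycle phase
#' bias, so it is measured by pooling per-cycle network phases (sampled at
#' the stimulus ON-ramp onsets) across several independent simulations per
#' condition: purely depolarizing ("anodal"), purely hyperpolarizing
#' ("cathodal") and sham. The pooled phase-locking value of each condition is
#' compared with the 95th percentile of PLVs obtained by resampling the
#' pooled sham phases, and the circular separation between anodal and
#' cathodal mean phases is reported (opposite polarities entrain in
#' antiphase).
#'
#' @param field field magnitude (V/m, default 0.31).
#' @param n_seeds independent networks per condition.
#' @param duration run length per simulation (s).
#' @param seed base seed.
#' @param n_boot resamples for the sham percentile.
#' @param network_args extra arguments to [build_lattice()].
#' @return list with pooled `plv` per condition, `sham_p95`, circular mean
#'   phases (cycles), `separation` (cycles, in `[0, 0.5]`), and cycle counts.
#' @export
entrainment_experiment <- function(field = 0.31, n_seeds = 5,
                                   duration = 120, seed = 1, n_boot = 500,
                                   network_args = list()) {
  wf <- stimulus_waveform("onoff", amplitude = field)
  get_phases <- function(res) {
    i0 <- which(res$t_lfp >= res$config$transient)[1]
    phase_locking(res$lfp_global[i0:length(res$lfp_global)], res$fs_lfp, wf,
                  t0 = res$t_lfp[i0], duration = duration)$phases
  }
  pools <- list(anodal = c(), cathodal = c(), sham = c())
  for (sd in seq_len(n_seeds)) {
    net <- do.call(build_lattice, c(list(seed = seed + sd), network_args))
    net <- sample_parameters(net, seed = seed + 100 + sd)
    mk <- function(wave = stimulus_waveform("sham"), prof = NULL)
      sim_config(net, duration = duration, seed = seed + 200 + sd,
                 waveform = wave, field_profile = prof, subregions = 0)
    pools$anodal <- c(pools$anodal,
                      get_phases(run_simulation(mk(wf, polarity_profile(1, net$n_cols)))))
    pools$cathodal <- c(pools$cathodal,
                        get_phases(run_simulation(mk(wf, polarity_profile(0, net$n_cols)))))
    pools$sham <- c(pools$sham, get_phases(run_simulation(mk())))
  }
  plv_of <- function(ph) Mod(mean(exp(2i * pi * ph)))
  mean_ph <- function(ph) Arg(mean(exp(2i * pi * ph))) / (2 * pi)
  n <- length(pools$anodal)
  boot <- with_seed(seed + 999, {
    vapply(seq_len(n_boot), function(b) {
      plv_of(sample(pools$sham, n, replace = TRUE))
    }, numeric(1))
  })
  sep <- abs(mean_ph(pools$anodal) - mean_ph(pools$cathodal))
  if (sep > 0.5) sep <- 1 - sep
  list(
    plv = vapply(pools, plv_of, numeric(1)),
    sham_p95 = quantile(boot, 0.95, names = FALSE),
    mean_phase = vapply(pools, mean_ph, numeric(1)),
    separation = sep,
    n_cycles = vapply(pools, length, numeric(1)),
    field = field
  )
}
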