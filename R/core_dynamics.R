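#' Izhikevich neuron parameters
#'
#' Parameter set for a single-compartment Izhikevich neuron augmented with an
#' activity-dependent excitability bias. Defaults follow the standard
#' regular-spiking (excitatory) and fast-spiking (inhibitory) parameter sets;
#' the excitability bias `e` enters the voltage equation as an additive drive
#' and is slaved to the neuron's own low-pass filtered firing rate `r` as
#' `e = e_ss - k_e * r`, which exhausts active (UP) periods and recovers
#' during quiescent (DOWN) periods.
#'
#' @param type `"excitatory"` (regular spiking) or `"inhibitory"`
#'   (fast spiking).
#' @param a,b,c,d Izhikevich recovery/reset constants; defaults depend on
#'   `type`.
#' @param e_ss steady-state excitability bias (model current units). The
#'   defaults place the emergent network oscillation in the 0.5--1 Hz slow
#'   wave band (see the package vignette for the calibration).
#' @param k_e excitability feedback gain (dimensionless, default 6).
#' @param tau_r time constant of the low-pass rate estimate (s, default 0.9).
#' @return A list of class `neuron_params`.
#' @export
neuron_params <- function(type = c("excitatory", "inhibitory"),
                          a = NULL, b = NULL, c = NULL, d = NULL,
                          e_ss = NULL, k_e = 6, tau_r = 0.9) {
  type <- match.arg(type)
  def <- if (type == "excitatory") {
    list(a = 0.02, b = 0.2, c = -65, d = 8, e_ss = 9)
  } else {
    list(a = 0.1, b = 0.2, c = -65, d = 2, e_ss = 2)
  }
  p <- list(
    a = a %||% def$a, b = b %||% def$b, c = c %||% def$c, d = d %||% def$d,
    is_excitatory = (type == "excitatory"),
    e_ss = e_ss %||% def$e_ss, k_e = k_e, tau_r = tau_r
  )
  stopifnot(
    is.finite(p$a), is.finite(p$b), is.finite(p$c), is.finite(p$d),
    p$tau_r > 0, p$k_e >= 0
  )
  class(p) <- "neuron_params"
  p
}

#' Synaptic kinetics and reversal potentials
#'
#' First-order conductance kinetics for AMPA, NMDA, GABA-A and GABA-B
#' channels. Each presynaptic spike increments the matching postsynaptic
#' conductance by the synapse weight (NMDA and GABA-B scaled by
#' `nmda_ratio` / `gabab_ratio`); conductances then decay exponentially.
#'
#' @param tau_ampa,tau_nmda,tau_gabaa,tau_gabab decay time constants (ms).
#' @param E_exc,E_gabaa,E_gabab reversal potentials (mV).
#' @param w_exc_mean,w_inh_mean mean conductance increment per presynaptic
#'   spike for excitatory and inhibitory synapses.
#' @param nmda_ratio,gabab_ratio increment of the slow conductance relative
#'   to the fast one of the same synapse class.
#' @param g_nmda_max,g_gabab_max saturation ceilings for the accumulated
#'   slow conductances (finite receptor pools); `Inf` disables saturation.
#' @param tau_gabab_rise rise time of the GABA-B conductance (ms):
#'   presynaptic increments feed a pool that activates the conductance with
#'   this time constant. 0 gives instantaneous activation.
#' @return A list of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(tau_ampa = 5, tau_nmda = 150, tau_gabaa = 6,
                             tau_gabab = 500, E_exc = 0, E_gabaa = -70,
                             E_gabab = -90, w_exc_mean = 0.042,
                             w_inh_mean = 0.85, nmda_ratio = 3,
                             gabab_ratio = 3.3, g_nmda_max = 3,
                             g_gabab_max = 2, tau_gabab_rise = 100) {
  stopifnot(
    tau_ampa > 0, tau_nmda > 0, tau_gabaa > 0, tau_gabab > 0,
    w_exc_mean > 0, w_inh_mean > 0, nmda_ratio >= 0, gabab_ratio >= 0
  )
  structure(
    list(
      tau_ampa = tau_ampa, tau_nmda = tau_nmda, tau_gabaa = tau_gabaa,
      tau_gabab = tau_gabab, E_exc = E_exc, E_gabaa = E_gabaa,
      E_gabab = E_gabab, w_exc_mean = w_exc_mean, w_inh_mean = w_inh_mean,
      nmda_ratio = nmda_ratio, gabab_ratio = gabab_ratio,
      g_nmda_max = g_nmda_max, g_gabab_max = g_gabab_max,
      tau_gabab_rise = tau_gabab_rise
    ),
    class = "synapse_kinetics"
  )
}

#' Initial dynamical state of a neuron
#'
#' @param params a [neuron_params()] object.
#' @param v initial membrane potential (mV).
#' @return A list of class `neuron_state` holding `v`, `u`, the low-pass
#'   rate `r`, the excitability bias `e`, the four synaptic conductances and
#'   spike-time bookkeeping.
#' @export
neuron_state <- function(params, v = -70) {
  s <- list(
    v = v, u = params$b * v, r = 0, e = params$e_ss,
    g_ampa = 0, g_nmda = 0, g_gabaa = 0, g_gabab = 0,
    last_spike_time = -Inf, last_isi = NA_real_
  )
  class(s) <- "neuron_state"
  s
}

# NMDA voltage dependence (magnesium block relief)
nmda_gate <- function(v) {
  x2 <- ((v + 80) / 60)^2
  x2 / (1 + x2)
}

#' Advance the Izhikevich voltage/recovery equations by one step
#'
#' One forward-Euler step (two half-steps for the voltage equation) of
#' `dv/dt = 0.04 v^2 + 5 v + 140 - u + I` and `du/dt = a (b v - u)`, where
#' the total drive `I` is `I_total` plus the neuron's excitability bias `e`.
#' On crossing +30 mV a spike is emitted and `v -> c`, `u -> u + d`.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param I_total external + synaptic current (model units), excluding the
#'   excitability bias which `state$e` carries.
#' @param dt time step in seconds, at most 1 ms.
#' @param t current time (s), used for spike bookkeeping.
#' @return `list(state = <neuron_state>, spiked = <logical>)`.
#' @export
izhikevich_step <- function(state, params, I_total, dt, t = 0) {
  stopifnot(dt > 0, dt <= 1e-3, is.finite(I_total))
  dt_ms <- dt * 1000
  I <- I_total + state$e
  v <- state$v
  u <- state$u
  # -100 mV floor: numerical guard against Euler overshoot under strong
  # hyperpolarizing drive (inert in normal regimes)
  v <- v + 0.5 * dt_ms * (0.04 * v^2 + 5 * v + 140 - u + I)
  if (v < -100) v <- -100
  if (v < 30) {
    v <- v + 0.5 * dt_ms * (0.04 * v^2 + 5 * v + 140 - u + I)
    if (v < -100) v <- -100
  }
  u <- u + dt_ms * params$a * (params$b * min(v, 30) - u)
  if (!is.finite(v)) {
    stop(sprintf("numerical blow-up in neuron at t = %.4f s", t))
  }
  spiked <- v >= 30
  if (spiked) {
    v <- params$c
    u <- u + params$d
    if (is.finite(state$last_spike_time)) {
      state$last_isi <- t - state$last_spike_time
    }
    state$last_spike_time <- t
  }
  state$v <- v
  state$u <- u
  list(state = state, spiked = spiked)
}

#' Total synaptic current of a neuron
#'
#' `I_syn = w_hom * (g_ampa + g_nmda * B(v)) * (E_exc - v) +
#'  g_gabaa * (E_gabaa - v) + g_gabab * (E_gabab - v)`, where `B(v)` is the
#' NMDA voltage dependence and the homeostatic factor `w_hom` scales the
#' excitatory conductances only.
#'
#' @param state a [neuron_state()].
#' @param kin a [synapse_kinetics()].
#' @param w_hom multiplicative homeostatic factor on excitatory inputs.
#' @return Current in model units.
#' @export
synaptic_current <- function(state, kin, w_hom = 1) {
  stopifnot(w_hom >= 0)
  v <- state$v
  w_hom * (state$g_ampa + state$g_nmda * nmda_gate(v)) * (kin$E_exc - v) +
    state$g_gabaa * (kin$E_gabaa - v) + state$g_gabab * (kin$E_gabab - v)
}

#' Exponential decay of synaptic conductances over one step
#'
#' Exact solution of first-order kinetics over `dt`, then addition of any
#' presynaptic increments (conductance per spike; NMDA/GABA-B increments
#' already scaled by the caller).
#'
#' @param state a [neuron_state()].
#' @param kin a [synapse_kinetics()].
#' @param dt step in ms.
#' @param inc optional named list of increments to add after decay
#'   (`g_ampa`, `g_nmda`, `g_gabaa`, `g_gabab`).
#' @return Updated `neuron_state`.
#' @export
decay_conductances <- function(state, kin, dt, inc = NULL) {
  stopifnot(dt > 0)
  state$g_ampa <- state$g_ampa * exp(-dt / kin$tau_ampa)
  state$g_nmda <- state$g_nmda * exp(-dt / kin$tau_nmda)
  state$g_gabaa <- state$g_gabaa * exp(-dt / kin$tau_gabaa)
  state$g_gabab <- state$g_gabab * exp(-dt / kin$tau_gabab)
  if (!is.null(inc)) {
    for (nm in names(inc)) state[[nm]] <- state[[nm]] + inc[[nm]]
  }
  state
}

#' Activity-dependent excitability feedback
#'
#' The low-pass rate `r` is a leaky integrator of the spike train with time
#' constant `tau_r`; each spike adds `1/tau_r` so that `r` estimates the
#' firing rate in Hz. The excitability bias is the algebraic negative
#' feedback `e = e_ss - k_e * r`.
#'
#' @param state a [neuron_state()].
#' @param params a [neuron_params()].
#' @param dt step in seconds.
#' @param spiked did the neuron spike in this step?
#' @return Updated `neuron_state`.
#' @export
excitability_update <- function(state, params, dt, spiked = FALSE) {
  stopifnot(dt > 0)
  state$r <- state$r * exp(-dt / params$tau_r) + if (spiked) 1 / params$tau_r else 0
  state$e <- params$e_ss - params$k_e * state$r
  state
}

#' Integrate a single neuron (reference path)
#'
#' Plain-R integration of one neuron under a prescribed input current, used
#' for calibration and as an independent check of the compiled network
#' engine. Synaptic conductances stay at zero; the drive is
#' `I(t) + e(t)` with the excitability feedback active unless `k_e = 0`.
#'
#' @param params a [neuron_params()].
#' @param I a constant, a vector of per-step currents, or a function of time.
#' @param duration total time (s).
#' @param dt step (s), default 0.5 ms.
#' @param v0 initial membrane potential.
#' @return list with `t`, `v`, `spike_times`, `state` (final).
#' @export
simulate_neuron <- function(params, I, duration, dt = 5e-4, v0 = -70) {
  n_steps <- round(duration / dt)
  tt <- (seq_len(n_steps) - 1) * dt
  Iv <- if (is.function(I)) {
    vapply(tt, I, numeric(1))
  } else if (length(I) == 1) {
    rep(I, n_steps)
  } else {
    stopifnot(length(I) == n_steps)
    I
  }
  st <- neuron_state(params, v = v0)
  v_trace <- numeric(n_steps)
  spikes <- numeric(0)
  for (k in seq_len(n_steps)) {
    out <- izhikevich_step(st, params, Iv[k], dt, t = tt[k])
    st <- out$state
    st <- excitability_update(st, params, dt, out$spiked)
    if (out$spiked) spikes <- c(spikes, tt[k])
    v_trace[k] <- st$v
  }
  list(t = tt, v = v_trace, spike_times = spikes, state = st)
}
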