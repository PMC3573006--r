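#' Firing-rate homeostasis configuration and state
#'
#' Multiplicative homeostatic scaling of excitatory synapses driven by the
#' postsynaptic firing rate: `tau_h * dw/dt = (r0 - r_inst) / r0`, where
#' `r_inst` is the instantaneous rate computed as the inverse of the last
#' inter-spike interval. Inputs to neurons firing above the target rate `r0`
#' weaken; inputs to neurons firing below it strengthen. `w_hom` multiplies
#' the AMPA and NMDA conductances of the postsynaptic neuron's inputs only
#' and is clipped at zero.
#'
#' Defaults: `r0` is 0.8 times the mean instantaneous rate measured in a
#' baseline run of the default network, and `tau_h` is set so that a
#' compressed simulated night reproduces an overnight slow-wave power decline
#' on the dB-per-hour scale seen in sleep EEG (see the vignette).
#'
#' @param n number of neurons tracked.
#' @param r0 target firing rate (Hz).
#' @param tau_h homeostatic time constant (s of simulated time).
#' @param staleness if a neuron stays silent this long (s), its `r_inst`
#'   resets to 0 so it registers as below target.
#' @param enabled logical.
#' @param w_init initial factor (default 1).
#' @return list of class `homeostasis_state`.
#' @export
homeostasis_config <- function(n = 1, r0 = 0.2, tau_h = 120000, staleness = 5,
                               enabled = TRUE, w_init = 1) {
  stopifnot(r0 > 0, tau_h > 0, staleness > 0, w_init >= 0)
  structure(
    list(w_hom = rep(w_init, n), r_inst = rep(0, n),
         last_spike = rep(-Inf, n), r0 = r0, tau_h = tau_h,
         staleness = staleness, enabled = enabled),
    class = "homeostasis_state"
  )
}

#' Update the instantaneous (1/ISI) rate on a spike
#'
#' @param h a [homeostasis_config()] state.
#' @param neuron neuron index.
#' @param spike_time current spike time (s).
#' @param last_spike_time previous spike time (s); if `-Inf` (no prior
#'   spike) the ISI is undefined and `r_inst` is left unchanged.
#' @return updated state.
#' @export
isi_rate_update <- function(h, neuron, spike_time, last_spike_time) {
  stopifnot(spike_time > last_spike_time)
  if (is.finite(last_spike_time)) {
    h$r_inst[neuron] <- 1 / (spike_time - last_spike_time)
  }
  h$last_spike[neuron] <- spike_time
  h
}

#' Advance the homeostatic factors by one step
#'
#' Applies the staleness rule, then
#' `w_hom <- max(0, w_hom + dt/tau_h * (r0 - r_inst)/r0)`.
#'
#' @param h a [homeostasis_config()] state.
#' @param dt step (s).
#' @param t current time (s), used for the staleness rule.
#' @return updated state.
#' @export
homeostatic_step <- function(h, dt, t = NULL) {
  stopifnot(dt > 0)
  if (!h$enabled) return(h)
  if (!is.null(t)) {
    stale <- (t - h$last_spike) > h$staleness
    h$r_inst[stale] <- 0
  }
  h$w_hom <- pmax(0, h$w_hom + (dt / h$tau_h) * (h$r0 - h$r_inst) / h$r0)
  h
}
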