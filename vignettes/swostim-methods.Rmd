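---
title: "Modeling slow-wave oscillations under weak electric-field stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling slow-wave oscillations under weak electric-field stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`swostim` simulates the slow-wave oscillation (SWO, 0.5–1 Hz) of non-REM
sleep in a 30×30 lattice of 900 Izhikevich neurons (80% regular-spiking
excitatory, 20% fast-spiking inhibitory, placed at random). Every neuron
receives one synapse from each excitatory neuron in its 5×5 neighborhood
and from each inhibitory neuron in its 3×3 neighborhood, with periodic
boundaries and no self-connections. Izhikevich parameters and synaptic
weights are drawn per run from normal distributions with a 5% coefficient
of variation.

Membrane dynamics follow the standard Izhikevich equations,

  dv/dt = 0.04 v² + 5 v + 140 − u + I,   du/dt = a (b v − u),

with a reset to `c` and `u + d` on crossing +30 mV. The total drive `I`
combines synaptic currents, membrane noise, the applied-field current, and
an activity-dependent *excitability bias* `e` that generates UP/DOWN
transitions: each neuron low-pass filters its own spike train
(`tau_r = 0.9 s`, each spike contributing `1/tau_r`, so `r` estimates the
firing rate in Hz) and sets

  e = e_ss − k_e · r,   with k_e = 6.

Sustained firing therefore exhausts excitability and terminates the active
(UP) state; during quiescence `r` decays and excitability recovers until
the next network-wide event ignites and propagates through the lattice like
an avalanche. The printed form of this feedback and the population values
of `e_ss` are not constrained by any published equation available to us;
the algebraic form above is the minimal implementation of a rate-driven
negative feedback with the stated time constant, and `e_ss` (9 for
excitatory, 2 for inhibitory neurons) was calibrated once so that the
emergent rhythm meets the physiological targets listed below.

## Synapses

Four conductance classes with first-order kinetics: AMPA (5 ms), NMDA
(150 ms, with the voltage gate `B(v) = ((v+80)/60)² / (1 + ((v+80)/60)²)`),
GABA-A (6 ms) and GABA-B (500 ms decay, 100 ms rise). A presynaptic spike
increments the fast conductance of its class by the synapse weight and the
slow one by the weight times `nmda_ratio` (3) or `gabab_ratio` (3.3). Two
features deserve explanation because they are load-bearing:

- **Slow-receptor saturation.** The accumulated NMDA and GABA-B
  conductances are capped (`g_nmda_max = 3`, `g_gabab_max = 2`),
  representing finite receptor pools. Without the caps the lattice has a
  second, seizure-like attractor: once the per-Hz gain of the slow
  excitatory conductance exceeds the excitability-feedback gain `k_e`, the
  network locks into refractory-limited firing. The caps remove this
  attractor *structurally* — above saturation the NMDA current is
  rate-independent while the excitability feedback keeps growing, so the
  feedback always wins.
- **GABA-B as the DOWN-state pacemaker.** The slow inhibitory conductance
  (rise 100 ms, decay 500 ms) builds up during each population event and
  then holds the network down; the oscillation period is set jointly by
  this suppression and by the excitability recovery. The rise time matters:
  it lets the event complete before suppression peaks, which preserves
  UP-state firing rates. With the companion-style 150 ms decay the rhythm
  sits near 1.4 Hz; 500 ms places it at ~0.75 Hz. GABA-B decay constants of
  several hundred milliseconds are within the physiological range for this
  K⁺-channel-coupled receptor.

## Membrane noise

Each neuron receives an Ornstein–Uhlenbeck current (SD 2.0, correlation
time 4 s) plus a small network-wide shared component (SD 0.9). The slow
per-neuron drift reshuffles which neurons participate in each event on a
~3-cycle timescale, which is what limits the coherence time of the rhythm;
the shared component adds a little cycle-to-cycle period jitter. The split
matters: decoherence carried by *per-neuron* fluctuations averages out of
the collective event timing, leaving weak uniform fields able to bias that
timing, whereas a large shared-noise component would both mask applied
fields and sustain noise-driven synchrony that no longer depends on
synaptic strength (breaking the link between homeostatic downscaling and
slow-wave power). We learned both failure modes by measurement during
calibration.

## Calibration targets

The free constants (`e_ss`, weights, conductance ratios, noise) were tuned
once, jointly, against the physiological targets the model is meant to
reproduce — dominant LFP frequency within 0.5–1 Hz, mean excitatory UP-state
rate near 5 Hz (the in-vitro 2–10 Hz range), coherence time near 3 cycles,
and slow-wave power and coherence time increasing with excitatory coupling
— and then frozen, with the measurement protocols fixed at the scales the
summaries use (120 s runs for frequency and UP-state rate, 300 s for
coherence time; the coherence-time estimator reads low on shorter
records). Across five seeds the defaults give a median dominant frequency
of 0.75 Hz, a median UP-state rate of ≈ 4–5 Hz and a median coherence time
of ≈ 3.7 cycles.

# Electric-field coupling

A uniform field `E` polarizes pyramidal somata by `lambda = 0.2 mV` per
V/m (the value reported for rat hippocampal pyramidal cells); inhibitory
somata, being symmetric, are unaffected. The field is modelled as a somatic
current injection to each excitatory neuron. `calibrate_coupling()` probes
the quiescent neuron's subthreshold input resistance, derives the current
per V/m, and refines it by fixed-point iteration so that a sustained 1 V/m
field depolarizes the soma by exactly 0.2 mV (the subthreshold
current–voltage relation of the Izhikevich neuron is weakly nonlinear, so a
single-probe estimate would be ~1% off).

Waveforms: DC, or 0.75 Hz ON/OFF with a trapezoid envelope (ramps of 10% of
the ON half-period; the exact ramp sharpness is not documented anywhere we
know of and is configurable). Spatial profiles map one signed field value
(V/m) to each lattice column. `make_field_profile()` reproduces the
published field-profile workflow: sort the sampled radial fields, exclude
the top and bottom 3.12 percentiles (`floor(0.0312 n)` samples per tail,
read as per-tail), take 30 evenly spaced ranks, and rescale so the mean
absolute field is 0.93 V/m, preserving signs. `synth_field_samples()` is a
synthetic stand-in for an anatomical current-flow solver: it draws
mixed-polarity samples from a two-lobe folded-normal distribution. It
emulates only the *statistics* of cortical field distributions (mixed
polarity, heavy right tail), not their spatial correlation structure.

# Homeostatic plasticity

Excitatory synapses onto each neuron are scaled by a factor `w_hom`
(clipped at 0) driven by the postsynaptic instantaneous rate
`r_inst = 1/ISI` (held between spikes, reset to 0 after 5 s of silence):

  tau_h · dw/dt = (r0 − r_inst) / r0.

The relative-error form makes the drive dimensionless; an absolute-error
variant would only rescale `tau_h`. Defaults: `r0 = 0.2 Hz`,
`tau_h = 1.2e5 s`, initial factor `w_init = 1.3` in night runs
(wake-potentiated synapses). Because the SWO regime is event-like (roughly
one spike per neuron per cycle, occasionally a doublet), the 1/ISI
estimator is strongly bimodal — doublets register as >100 Hz — and the
homeostatic drive is dominated by pruning doublet-prone neurons. `r0` is
set *below* the one-spike-per-cycle floor (~0.75 Hz) so that the bulk of
the population also downscales steadily through the night rather than
equilibrating; `tau_h` is large because the drive is normalized by the
small `r0`. These two constants were chosen so that a compressed sham
night shows a steady decline of slow-wave power through the analysis
window; the magnitude of that decline (about −0.3 dB per night-equivalent
hour) falls short of the −1.2 dB/h scale of overnight human EEG, a known
limitation discussed below.

## Compressed nights

Real nights last hours; `night_run()` compresses time by a factor
(default 60: one simulated minute per night-equivalent hour) applied to the
plasticity clock and the protocol durations, while the SWO dynamics run at
their natural speed. The stimulation epoch mirrors the human protocol
shape — five blocks with four gaps, scaled to 5 s + 1 s — and the
post-stimulation analysis covers 4.5 night-equivalent hours (270 s
simulated). Decay rates are reported in dB per night-equivalent hour; power
slopes are fitted per subregion LFP and averaged, as multi-electrode EEG
analyses average across electrodes.

# Signal analysis

All analyses treat simulated LFPs (average postsynaptic current, zero-phase
low-pass at 2.5 Hz; four 11×11 subregions serve as "electrodes") and
EEG-like signals identically:

- **Band power**: per non-overlapping 40 s window, one-sided periodogram
  power (rectangular taper) summed over the bins inside the band, so a
  sinusoid of amplitude A in-band yields A²/2. dB is `10 log10`.
- **Spatial coherence**: within each window, 5 s sub-segments are
  standardized to zero mean and unit energy (power normalization), and the
  magnitude-squared coherence is computed from sub-segment-averaged cross-
  and auto-spectra, averaged over in-band bins and over all pairs involving
  each channel. Identical channels give exactly 1; independent channels
  give a positive bias of roughly one over the sub-segment count, which
  shrinks as windows lengthen. Pair values are averaged on the linear
  scale before conversion to dB.
- **Decay rates**: robust IRLS line fit (bisquare, tuning constant 4.685)
  of dB against time in hours.
- **Paired statistics**: within-pair label permutation of the mean
  difference, exhaustively enumerated when `2^n` fits the budget, with the
  add-one correction otherwise; Benjamini–Hochberg FDR for per-channel
  tests.
- **Entrainment**: the SWO-band LFP phase (analytic signal) is sampled at
  each stimulus ON-ramp onset; the phase-locking value is the resultant
  length. For weak fields `entrainment_experiment()` pools per-cycle phases
  across independent simulations and compares the pooled PLV with a
  resampled sham 95th percentile.

The synthetic sleep-EEG generator mixes a shared narrowband (0.5–1 Hz)
source with per-channel independent sources, schedules the shared-variance
fraction and total band amplitude so coherence and power decay at
programmed dB/hour rates, multiplies by a ~90 min non-REM/REM envelope and
adds a broadband noise floor. Two calibration details make the programmed
decays identifiable: the envelope period is snapped to an integer number of
cycles over the recording (so the periodic modulation cannot leak into the
fitted trend), and the scheduled shared fraction is pre-compensated for the
known positive bias of the windowed coherence estimator,
`E[estimate] = C + (1 - C)^2/K` for `K` averaged sub-segments, so that the
*measured* coherence decays at the programmed rate. It validates the analysis chain end to end;
it does not emulate spindles, artifacts, or sleep-stage transitions, so
recovery there shows estimator correctness, not robustness to real-world
EEG contamination.

# Worked example

```{r}
library(swostim)

net <- build_lattice(seed = 1)
net <- sample_parameters(net, seed = 2)
res <- run_simulation(sim_config(net, duration = 60, seed = 3))

x <- res$lfp_global[res$t_lfp > 5]
dominant_frequency(x, res$fs_lfp)     # ~0.7 Hz
up_state_rate(res)$rate_up            # a few Hz within UP states
coherence_time(x, res$fs_lfp)$cycles  # ~3 cycles

# a compressed sham night with homeostatic downscaling
nr <- night_run("sham", net_seed = 1, noise_seed = 2)
nr$power_fit
```

# Numerical choices

Forward Euler with `dt = 0.5 ms`, the voltage equation advanced in two
0.25 ms half-steps with the spike threshold tested between them, and a
−100 mV voltage floor. Both guards are inert in normal regimes (reversal
potentials keep trajectories above −90 mV) but prevent the quadratic
voltage term from running away under synchronized volleys or strong
transient hyperpolarization. Conductances decay by exact exponentials.
The correlated membrane noise is refreshed on a 4 ms cadence (held in
between), which is indistinguishable dynamically for a 4 s correlation
time. Simulations are bit-reproducible given the configuration and seed,
and a sham run is bit-identical to an unstimulated run because the noise
stream does not depend on the stimulus.

Problem sizes used by the tests and the acceptance script (chosen once as
reasonable desk-scale statistics): five 120 s baselines for frequency and
UP-rate summaries, five 300 s baselines for coherence time, an 8×8
intensity-by-fraction grid with 3 replicates and 12 s runs for the
rectification maps, five 120 s runs per polarity for pooled entrainment,
ten paired compressed nights, and 100 synthetic-EEG replicates for
parameter recovery.

# Known limitations

- The overnight power decline of the model (~−0.3 dB per night-equivalent
  hour) is weaker than the human −1.22 dB/h scale: per-neuron homeostatic
  scaling spends most of its drive on doublet-prone neurons whose extra
  spikes carry little band power. The *direction* of all homeostatic
  effects is reproduced; their magnitude is not calibrated to the human
  data.
- At the 0.31 V/m amplitude used for the weak-field experiments, the
  field's current (0.05 model units, equivalent to a 0.06 mV polarization)
  is far below every dynamical scale that controls event timing, and the
  finite coherence time fixes a phase-diffusion floor. Entrainment is
  therefore a small statistical bias at 0.31 V/m (detectable only by
  pooling; its anodal/cathodal antiphase structure emerges cleanly at
  ≥1 V/m), and rate and night-decay effects at 0.31 V/m are below
  single-experiment detectability.
- Hyperpolarizing DC reduces firing far less than depolarizing DC raises
  it (the DOWN state is already quiescent — a floor effect), and because
  ON/OFF rectification is an entrainment phenomenon, mostly-cathodal
  ON/OFF stimulation in this implementation still reduces rates somewhat
  (like a half-duty DC field) rather than being fully rectified.
- Neighborhood connectivity, single-compartment somata (no dendritic field
  effects), and the absence of thalamocortical circuitry and sleep-stage
  architecture are inherited simplifications of the modelled system.
- The dependence of the field effect on synaptic in-degree is inverted
  relative to densely connected cortex-scale arguments: because the field
  effect here is carried by intrinsic excitability margins rather than
  recurrent amplification, increasing the neighborhood dilutes rather than
  amplifies the normalized rate change.
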