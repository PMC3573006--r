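# swostim

Simulation and analysis of cortical **slow-wave oscillations (SWO,
0.5–1 Hz)** under weak transcranial electric-field stimulation, with
firing-rate homeostatic plasticity and a sleep-EEG-style spectral analysis
toolbox.

## Who this is for

Computational neuroscientists and sleep/stimulation researchers who want a
desk-scale spiking model that links three levels:

1. **Cellular** — single-compartment Izhikevich neurons whose excitability
   is depressed by their own recent firing (`e = e_ss − k_e·r`, with `r` a
   0.9 s low-pass of the spike train and `k_e = 6`), producing alternating
   network-wide UP (active) and DOWN (quiescent) states;
2. **Field coupling** — a uniform field `E` polarizes pyramidal somata by
   0.2 mV per V/m and is modelled as a calibrated somatic current to
   excitatory neurons only, with DC or 0.75 Hz ON/OFF trapezoid waveforms
   and mixed-polarity spatial profiles mapped onto lattice columns (the
   folded-cortex situation);
3. **Plasticity and EEG statistics** — multiplicative homeostatic scaling
   of excitatory synapses driven by the postsynaptic 1/ISI rate
   (`tau_h·dw/dt = (r0 − r_inst)/r0`), and the analysis chain used for
   overnight sleep EEG: 40 s windowed band power, power-normalized spatial
   coherence, robust (IRLS) decay-rate fits in dB/hour, paired permutation
   tests, FDR, and phase-locking (entrainment) measures.

The network is a 30×30 lattice (900 neurons, 20% fast-spiking inhibitory)
with excitatory input from each neuron's 5×5 neighborhood and inhibitory
input from its 3×3 neighborhood, periodic boundaries, and 5% parameter
heterogeneity. The model LFP is the average postsynaptic current, low-pass
filtered at 2.5 Hz; four 11×11 subregions serve as "electrodes".

## Worked example

```r
library(swostim)

net <- build_lattice(seed = 1)              # 900 neurons, 5x5/3x3 wiring
net <- sample_parameters(net, seed = 2)     # 5% parameter heterogeneity
res <- run_simulation(sim_config(net, duration = 60, seed = 3))

x <- res$lfp_global[res$t_lfp > 5]
dominant_frequency(x, res$fs_lfp)
#> [1] 0.8
up_state_rate(res)$rate_up
#> [1] 3.73
coherence_time(x, res$fs_lfp)$cycles
#> [1] 3.74
```

The network oscillates at 0.8 Hz (inside the human SWO band), excitatory
neurons fire at ≈ 4 Hz during detected UP states (the in-vitro range is
2–10 Hz), and the oscillation loses phase memory after ≈ 3–4 cycles — the
irregular slow-wave pattern typical of human sleep EEG rather than the
metronomic rhythm of strongly coupled slice preparations.

Weak-field experiments follow the same pattern:

```r
# a 0.75 Hz ON/OFF field, uniformly depolarizing, 0.31 V/m
prof <- polarity_profile(1, 30)
wf   <- stimulus_waveform("onoff", amplitude = 0.31)
stim <- run_simulation(sim_config(net, duration = 60, seed = 3,
                                  waveform = wf, field_profile = prof))

# paired compressed nights with homeostatic downscaling
ex <- night_experiment(n_pairs = 10, seed = 100)

# mixed-polarity cortical field profile from synthetic field samples
profile <- make_field_profile(synth_field_samples(3000, seed = 1))
mean(abs(profile$per_column_field))
#> [1] 0.93
```

A thin command-line wrapper is installed under `inst/cli/swostim`
(`simulate`, `fieldprofile`, `analyze`, `show-config`).

See the vignette (`vignettes/swostim-methods.Rmd`) for the model's
assumptions, the calibration of every free constant, and known
limitations — including which stimulation effects are too small to detect
at the 0.31 V/m amplitude.

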