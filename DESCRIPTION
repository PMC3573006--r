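Package: swostim
Title: Spiking-Network Model of Slow-Wave Oscillations Under Weak Electric
    Field Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates cortical slow-wave oscillations (SWO, 0.5-1 Hz) in a
    2D lattice of Izhikevich excitatory and inhibitory neurons with an
    activity-dependent excitability feedback that generates UP/DOWN state
    transitions. Weak transcranial electrical stimulation is modelled as a
    calibrated somatic current injection to excitatory neurons, with support
    for DC and slow-oscillating ON/OFF (0.75 Hz) trapezoid waveforms and for
    mixed-polarity cortical field profiles mapped onto lattice columns.
    Firing-rate homeostatic scaling of excitatory synapses reproduces the
    overnight downscaling of slow-wave power, and an EEG-style analysis
    toolbox provides windowed band power, spatial coherence, robust decay-rate
    fits in dB per hour, paired permutation statistics, FDR correction and
    phase-locking (entrainment) measures, together with a synthetic
    multi-channel sleep-EEG generator with programmed decay rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
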