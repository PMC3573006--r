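# Small reusable fixtures; everything is generated in code.

tiny_net <- function(seed = 1, ...) {
  sample_parameters(build_lattice(10, 10, seed = seed, ...), seed = seed + 100)
}

# memoized default-parameter baseline runs shared by the acceptance blocks
.accept_cache <- new.env(parent = emptyenv())

baseline_runs <- function(n_seeds = 5, duration = 120) {
  key <- sprintf("base_%d_%d", n_seeds, duration)
  if (is.null(.accept_cache[[key]])) {
    .accept_cache[[key]] <- lapply(seq_len(n_seeds), function(sd) {
      net <- sample_parameters(build_lattice(seed = sd), seed = sd + 10)
      run_simulation(sim_config(net, duration = duration, seed = sd,
                                subregions = 0))
    })
  }
  .accept_cache[[key]]
}
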