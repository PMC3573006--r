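test_that("a quiescent neuron stays silent and relaxes to rest", {
  p <- neuron_params("excitatory", e_ss = 2)  # below rheobase (~4)
  out <- simulate_neuron(p, I = 0, duration = 1)
  expect_length(out$spike_times, 0)
  # with no bias, v relaxes to the resting fixed point near -70 mV
  p0 <- neuron_params("excitatory", e_ss = 0)
  out0 <- simulate_neuron(p0, I = 0, duration = 1, v0 = -60)
  expect_length(out0$spike_times, 0)
  expect_lt(abs(out0$state$v - (-70)), 0.5)
})

test_that("spiking agrees with a tenfold-finer reference integration", {
  p <- neuron_params("excitatory", e_ss = 0, k_e = 0)
  for (I in c(6, 10)) {
    coarse <- simulate_neuron(p, I = I, duration = 1, dt = 5e-4)
    fine <- simulate_neuron(p, I = I, duration = 1, dt = 5e-5)
    expect_gt(length(coarse$spike_times), 3)
    expect_lte(abs(length(coarse$spike_times) - length(fine$spike_times)), 1)
  }
})

test_that("subthreshold response to constant current is linear", {
  p <- neuron_params("excitatory", e_ss = 0, k_e = 0)
  rest <- simulate_neuron(p, 0, 2)$state$v
  dv <- vapply(c(0.05, 0.1), function(I) {
    simulate_neuron(p, I, 2)$state$v - rest
  }, numeric(1))
  z <- dv / c(0.05, 0.1)
  expect_lt(abs(z[1] / z[2] - 1), 0.02)
})

test_that("synaptic current matches hand arithmetic and reversal rules", {
  kin <- synapse_kinetics()
  st <- neuron_state(neuron_params("excitatory"))

  # all conductances zero
  expect_equal(synaptic_current(st, kin), 0)

  # at the excitatory reversal potential the excitatory terms vanish
  st$v <- kin$E_exc
  st$g_ampa <- 0.5
  st$g_nmda <- 0.3
  expect_equal(synaptic_current(st, kin), 0)

  # fixed instance, hand-computed
  st$v <- -65
  st$g_ampa <- 0.3; st$g_nmda <- 0.2; st$g_gabaa <- 0.1; st$g_gabab <- 0.05
  B <- ((-65 + 80) / 60)^2 / (1 + ((-65 + 80) / 60)^2)
  by_hand <- 0.9 * (0.3 + 0.2 * B) * (0 - (-65)) +
    0.1 * (-70 - (-65)) + 0.05 * (-90 - (-65))
  expect_equal(synaptic_current(st, kin, w_hom = 0.9), by_hand)
})

test_that("conductances decay exponentially, superpose, and match an ODE oracle", {
  kin <- synapse_kinetics()
  st <- neuron_state(neuron_params("excitatory"))
  st$g_ampa <- 1
  st <- decay_conductances(st, kin, dt = kin$tau_ampa)
  expect_equal(st$g_ampa, exp(-1))

  # linear superposition: two increments then decay
  s1 <- neuron_state(neuron_params("excitatory"))
  s1$g_gabaa <- 0.4
  s1 <- decay_conductances(s1, kin, dt = 3, inc = list(g_gabaa = 0.6))
  expect_equal(s1$g_gabaa, 0.4 * exp(-3 / kin$tau_gabaa) + 0.6)

  # arbitrary schedule of increments vs brute-force Euler at dt/100
  set.seed(7)
  times <- sort(sample(1:200, 12))  # ms grid
  incs <- runif(12, 0.05, 0.3)
  st2 <- neuron_state(neuron_params("excitatory"))
  for (k in seq_len(200)) {
    hit <- which(times == k)
    st2 <- decay_conductances(st2, kin, dt = 1,
                              inc = if (length(hit)) list(g_nmda = sum(incs[hit])) else NULL)
  }
  # oracle: explicit Euler of dg/dt = -g/tau at dt = 0.01 ms
  g <- 0
  dt_o <- 0.01
  for (k in seq_len(200 / dt_o)) {
    g <- g - dt_o * g / kin$tau_nmda
    t_ms <- k * dt_o
    hit <- which(abs(times - t_ms) < dt_o / 2)
    if (length(hit)) g <- g + sum(incs[hit])
  }
  expect_lt(abs(st2$g_nmda - g) / g, 0.01)
})

test_that("excitability feedback tracks the firing rate", {
  p <- neuron_params("excitatory")
  st <- neuron_state(p)

  # no spikes: r stays 0 and e stays at e_ss
  for (k in 1:100) st <- excitability_update(st, p, dt = 0.01, spiked = FALSE)
  expect_equal(st$r, 0)
  expect_equal(st$e, p$e_ss)

  # periodic spiking at f: stationary mean of the leaky estimator is f
  f <- 8
  dt <- 1e-3
  st <- neuron_state(p)
  rs <- c()
  for (k in seq_len(30 / dt)) {
    spiked <- (k %% round(1 / f / dt)) == 0
    st <- excitability_update(st, p, dt = dt, spiked = spiked)
    if (k > 20 / dt) rs <- c(rs, st$r)
  }
  expect_lt(abs(mean(rs) - f) / f, 0.05)

  # e = e_ss - k_e * r is algebraic
  p2 <- neuron_params("excitatory", e_ss = 10, k_e = 6)
  st2 <- neuron_state(p2)
  st2$r <- 1 / (1 - exp(-1e-9 / p2$tau_r))  # contrive r ~ 1 after decay
  st2$r <- 1
  st2 <- excitability_update(st2, p2, dt = 1e-9, spiked = FALSE)
  expect_equal(st2$e, 10 - 6 * st2$r, tolerance = 1e-9)
  expect_lt(abs(st2$e - 4), 1e-6)
})

test_that("the compiled engine reproduces the plain-R neuron trajectory", {
  # 5x5 lattice with (effectively) severed synapses and no noise: every
  # neuron is an independent copy of the single-neuron reference
  net <- build_lattice(5, 5, seed = 1)
  net$w_exc[] <- 1e-12
  net$w_inh[] <- 1e-12
  net$params$a <- rep(0.02, net$n); net$params$b <- rep(0.2, net$n)
  net$params$c <- rep(-65, net$n); net$params$d <- rep(8, net$n)
  net$params$e_ss <- rep(20, net$n)
  res <- run_simulation(sim_config(net, duration = 5, seed = 1, noise_sd = 0,
                                   noise_global_sd = 0, subregions = 0))
  eng <- sort(res$spikes$time[res$spikes$neuron == 1])
  p <- neuron_params("excitatory", e_ss = 20)
  ref <- simulate_neuron(p, 0, 5)$spike_times
  expect_equal(length(eng), length(ref))
  expect_lt(max(abs(eng - ref)), 1e-9)
})
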