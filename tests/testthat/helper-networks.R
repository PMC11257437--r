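# Shared small fixtures built in code.

# Single LIF neuron at the origin with unit resistance and rest == reset,
# so the closed-form inter-spike interval applies.
one_lif <- function(tau_m = 10, refractory_ms = 2) {
  neuron_population(matrix(0, 1, 3), tau_m = tau_m, v_rest = -70,
                    v_thresh = -50, v_reset = -70, R = 1,
                    refractory_ms = refractory_ms)
}

# Run a population under constant current, returning spike times.
run_constant_current <- function(pop, current, duration_ms, dt) {
  times <- c()
  t <- 0
  n_steps <- round(duration_ms / dt)
  for (k in seq_len(n_steps)) {
    s <- step_neurons(pop, current, dt)
    pop <- s$pop
    t <- t + dt
    if (length(s$spikes)) times <- c(times, rep(t, length(s$spikes)))
  }
  list(pop = pop, times = times)
}

# Small bursty E/I disc simulation used by LFP comparison tests.
small_ei_sim <- function(duration_ms = 800, seed = 42, dt = 0.2) {
  net <- make_ei_disc(n_e = 100, n_i = 25, diameter_um = 500, seed = seed)
  sim <- simulation(dt = dt, seed = seed + 1)
  add_population(sim, net$exc)
  add_population(sim, net$inh)
  for (s in net$synapses) add_synapses(sim, s)
  run(sim, duration_ms)
  sim
}

# Fraction of spectral power above a cutoff frequency (Hz) for a trace
# sampled at dt_ms.
high_freq_power_fraction <- function(x, dt_ms, cutoff_hz = 100) {
  x <- x - mean(x)
  n <- length(x)
  p <- Mod(fft(x))^2
  freqs <- (seq_len(n) - 1) / (n * dt_ms / 1000)
  half <- seq_len(floor(n / 2))
  sum(p[half][freqs[half] > cutoff_hz]) / sum(p[half])
}
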