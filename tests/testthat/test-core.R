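test_that("a resting LIF neuron with no input is a fixed point", {
  for (dt in c(0.01, 0.1, 1, 5)) {
    pop <- one_lif()
    s <- step_neurons(pop, 0, dt)
    expect_equal(s$pop$v, -70)
    expect_equal(length(s$spikes), 0)
  }
})

test_that("LIF inter-spike interval matches the closed form within 1%", {
  tau_m <- 10
  dt <- 0.01 * tau_m
  for (current in c(25, 30, 60)) {
    pop <- one_lif(tau_m = tau_m, refractory_ms = 2)
    res <- run_constant_current(pop, current, 600, dt)
    isi <- diff(res$times)
    closed <- tau_m * log(current / (current - 20)) + 2
    expect_lt(abs(mean(isi) - closed) / closed, 0.01)
  }
})

test_that("AdEx adaptation increments by b at each spike", {
  pop <- neuron_population(matrix(0, 1, 3), model = "adex", tau_m = 10,
                           v_rest = -70, v_thresh = -40, v_reset = -60,
                           R = 1, refractory_ms = 0, delta_T = 2,
                           v_T = -50, a = 0, b = 3, tau_w = 1e9)
  w_before <- pop$w
  n_spikes <- 0
  for (k in 1:5000) {
    s <- step_neurons(pop, 40, 0.05)
    pop <- s$pop
    n_spikes <- n_spikes + length(s$spikes)
  }
  expect_gt(n_spikes, 0)
  # tau_w huge and a = 0: w only changes via the per-spike reset rule
  expect_equal(pop$w, w_before + n_spikes * 3, tolerance = 1e-6)
})

test_that("non-finite inputs fail with the offending neuron named", {
  pop <- one_lif()
  expect_error(step_neurons(pop, NaN, 0.1), "neuron 1")
})

test_that("neurons stay clamped at reset during the refractory period", {
  pop <- one_lif(tau_m = 10, refractory_ms = 5)
  dt <- 0.1
  res <- run_constant_current(pop, 100, 50, dt)
  isi <- diff(res$times)
  expect_true(all(isi >= 5))
})

test_that("injection precomputes per-neuron geometry of the right shape", {
  sim <- simulation(dt = 0.1)
  pop <- make_unconnected_box(25, seed = 3)
  add_population(sim, pop)
  fib <- light_device(optic_fiber(tip = c(75, 75, -10)), label = "fib")
  inject(sim, fib, "box")
  expect_length(sim$devices$fib$pops$box$unit_irr, 25)
  probe <- spike_probe(linear_probe(c(10, 10, 0), n_contacts = 4),
                       label = "pr")
  inject(sim, probe, "box")
  d <- sim$devices$pr$pops$box$distances
  expect_equal(dim(d), c(4, 25))
  expect_true(all(d > 0))
})

test_that("one stimulator injected into two populations takes one update", {
  sim <- simulation(dt = 0.1, seed = 12)
  a <- make_unconnected_box(3, seed = 1, bias = 0, noise_sd = 0)
  a$name <- "a"
  b <- make_unconnected_box(3, seed = 2, bias = 0, noise_sd = 0)
  b$name <- "b"
  add_population(sim, a)
  add_population(sim, b)
  light <- light_device(uniform_light(470), label = "shared")
  ops <- opsin_device(simple_opsin(100), NULL, 1, label = "ops")
  for (pn in c("a", "b")) {
    inject(sim, light, pn)
    inject(sim, ops, pn)
  }
  io <- io_processor(1, function(meas, t) {
    if (t == 5) list(shared = 1) else NULL
  })
  run(sim, 30, io)
  # both populations depolarize and fire after the single shared update
  expect_gt(nrow(get_spikes(sim, "a")), 0)
  expect_gt(nrow(get_spikes(sim, "b")), 0)
  expect_true(all(get_spikes(sim, "a")$time_ms > 5))
})

test_that("devices cannot be injected after the run starts", {
  sim <- simulation(dt = 0.1)
  add_population(sim, make_unconnected_box(2, seed = 1))
  run(sim, 1)
  expect_error(inject(sim, light_device(uniform_light(470), label = "l"),
                      "box"), "after the run")
})

test_that("a 10 ms run at 1 ms sampling pushes exactly 10 measurements", {
  sim <- simulation(dt = 0.1, seed = 4)
  add_population(sim, make_unconnected_box(5, seed = 5))
  seen <- c()
  io <- io_processor(1, function(meas, t) {
    seen <<- c(seen, t)
    NULL
  })
  run(sim, 10, io)
  expect_equal(seen, 1:10)
})

test_that("a sampling period off the step grid is rejected at configuration", {
  sim <- simulation(dt = 0.3)
  add_population(sim, make_unconnected_box(2, seed = 1))
  io <- io_processor(1, function(meas, t) NULL)
  expect_error(run(sim, 9, io), "multiple of dt")
})

test_that("an always-zero controller leaves the trajectory untouched", {
  make_sim <- function() {
    sim <- simulation(dt = 0.1, seed = 31)
    add_population(sim, make_unconnected_box(30, seed = 6, bias = 19,
                                             noise_sd = 3))
    light <- light_device(uniform_light(470), label = "l")
    ops <- opsin_device(simple_opsin(10), NULL, 1, label = "o")
    inject(sim, light, "box")
    inject(sim, ops, "box")
    sim
  }
  s1 <- make_sim()
  run(s1, 100, io_processor(1, function(meas, t) list(l = 0)))
  s2 <- make_sim()
  run(s2, 100)
  expect_identical(get_spikes(s1, "box"), get_spikes(s2, "box"))
})

test_that("recording devices do not perturb the network trajectory", {
  base <- simulation(dt = 0.1, seed = 32)
  add_population(base, make_unconnected_box(30, seed = 7, bias = 19,
                                            noise_sd = 3))
  run(base, 100)
  rec <- simulation(dt = 0.1, seed = 32)
  add_population(rec, make_unconnected_box(30, seed = 7, bias = 19,
                                           noise_sd = 3))
  inject(rec, spike_probe(linear_probe(c(75, 75, 0), n_contacts = 8),
                          label = "pr"), "box")
  inject(rec, tklfp_recorder(electrode_array(c(75, 75, -50)),
                             label = "lfp"), "box")
  run(rec, 100)
  expect_identical(get_spikes(base, "box"), get_spikes(rec, "box"))
})

test_that("identical seeds and configs give bit-identical outputs", {
  go <- function() {
    net <- make_ei_disc(n_e = 40, n_i = 10, diameter_um = 400, seed = 8)
    sim <- simulation(dt = 0.2, seed = 9)
    add_population(sim, net$exc)
    add_population(sim, net$inh)
    for (s in net$synapses) add_synapses(sim, s)
    run(sim, 300)
    list(e = get_spikes(sim, "exc"), i = get_spikes(sim, "inh"))
  }
  expect_identical(go(), go())
})

test_that("a stimulator update delivered mid-run applies from its delivery time", {
  sim <- simulation(dt = 0.1, seed = 33)
  add_population(sim, make_unconnected_box(1, seed = 10, bias = 0,
                                           noise_sd = 0))
  light <- light_device(uniform_light(470), label = "l")
  ops <- opsin_device(simple_opsin(1000), NULL, 1, label = "o")
  inject(sim, light, "box")
  inject(sim, ops, "box")
  io <- io_processor(1, function(meas, t) {
    if (t == 20) list(l = 1) else NULL
  }, latency_model(3))
  run(sim, 40, io)
  sp <- get_spikes(sim, "box")
  # sampled at 20 ms + 3 ms latency: light turns on at 23 ms, never before
  expect_gt(nrow(sp), 0)
  expect_true(all(sp$time_ms > 23))
  expect_lt(min(sp$time_ms), 24)
})
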