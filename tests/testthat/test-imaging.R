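test_that("ROI selection follows the sphere cross-section geometry", {
  scope <- microscope(center = c(0, 0, 100), fov_width_um = 200,
                      soma_radius_um = 10, snr_cutoff = 0)
  ip <- indicator_params("GCaMP6f")
  dz <- c(0, 10, 10 / sqrt(2), 5, 50)
  pop <- neuron_population(cbind(0, 0, 100 + dz))
  rois <- select_rois(scope, pop, 1, ip)
  # on-plane: N = 1 and SNR = indicator SNR; |dz| = R excluded; R/sqrt(2)
  # gives exactly half the cross section
  expect_true(all(c(1, 3, 4) %in% rois$neuron))
  expect_false(2 %in% rois$neuron)  # dz = R: no cross section
  expect_false(5 %in% rois$neuron)  # far outside
  expect_equal(rois$N[rois$neuron == 1], 1)
  expect_equal(rois$snr[rois$neuron == 1], ip$dFF_1AP / ip$sigma_noise)
  expect_equal(rois$N[rois$neuron == 3], 0.5)
  expect_equal(rois$snr[rois$neuron == 3],
               0.5 * ip$dFF_1AP / ip$sigma_noise)
})

test_that("ROIs outside the field of view or below the SNR cutoff are dropped", {
  ip <- indicator_params("GCaMP6f")
  scope <- microscope(center = c(0, 0, 100), fov_width_um = 100,
                      soma_radius_um = 10, snr_cutoff = 1)
  pop <- neuron_population(rbind(c(0, 0, 100), c(200, 0, 100),
                                 c(0, 0, 109.9)))
  rois <- select_rois(scope, pop, 1, ip)
  expect_true(1 %in% rois$neuron)
  expect_false(2 %in% rois$neuron)   # laterally outside
  expect_false(3 %in% rois$neuron)   # sliver of cross-section, SNR < 1
  # low expression can also push an on-plane cell below the cutoff
  rois_lowrho <- select_rois(scope, pop, rho_rel = c(0.05, 1, 1), ip)
  expect_false(1 %in% rois_lowrho$neuron)
})

test_that("calcium rests at the fixed point and jumps by the buffered increment", {
  ip <- indicator_params("GCaMP6f")
  st <- calcium_state(2, ip)
  st2 <- ca_step(st, c(0, 0), ip, dt = 1)
  expect_equal(st2$ca, st$ca)
  st3 <- ca_step(st, c(1, 0), ip, dt = 1)
  kb <- looplab:::kappa_b(ip$Ca_rest_uM, ip)
  jump <- ip$dCa_T_uM / (1 + ip$kappa_S + kb)
  expect_equal(st3$ca[1], ip$Ca_rest_uM + jump, tolerance = 1e-12)
  expect_equal(st3$ca[2], ip$Ca_rest_uM)
})

test_that("calcium relaxes monotonically at the buffered clearance rate", {
  ip <- indicator_params("GCaMP6f")
  st <- calcium_state(1, ip)
  st <- ca_step(st, 1, ip, dt = 1)
  trace <- numeric(400)
  for (k in seq_along(trace)) {
    st <- ca_step(st, 0, ip, dt = 1)
    trace[k] <- st$ca
  }
  expect_true(all(diff(trace) < 0))
  expect_true(all(trace > ip$Ca_rest_uM))
  # reference: fine-step forward-Euler integration of the same nonlinear ODE
  ca_ref <- ip$Ca_rest_uM +
    ip$dCa_T_uM / (1 + ip$kappa_S + looplab:::kappa_b(ip$Ca_rest_uM, ip))
  dt_fine <- 0.01
  for (k in seq_len(400 / dt_fine)) {
    kb <- looplab:::kappa_b(ca_ref, ip)
    ca_ref <- ca_ref - dt_fine * ip$gamma_per_s / 1000 *
      (ca_ref - ip$Ca_rest_uM) / (1 + ip$kappa_S + kb)
  }
  expect_equal(trace[400], ca_ref, tolerance = 1e-3)
})

test_that("the convolution stage reproduces the double-exponential kernel", {
  ip <- indicator_params("GCaMP6f")
  dt <- 0.5
  st <- calcium_state(1, ip)
  # constant input at rest stays at rest
  for (k in 1:50) st <- kernel_step(st, ip, dt)
  expect_equal(st$cab_active, ip$Ca_rest_uM)
  # unit impulse deviation: response proportional to h(t)
  n <- 4000
  st <- calcium_state(1, ip)
  st$ca <- ip$Ca_rest_uM + 1 / dt  # area-1 impulse over one step
  st <- kernel_step(st, ip, dt)
  st$ca <- ip$Ca_rest_uM
  resp <- numeric(n)
  resp[1] <- st$cab_active - ip$Ca_rest_uM
  for (k in 2:n) {
    st <- kernel_step(st, ip, dt)
    resp[k] <- st$cab_active - ip$Ca_rest_uM
  }
  t_grid <- (seq_len(n)) * dt
  tau_s <- 1 / (1 / ip$tau_on_ms + 1 / ip$tau_off_ms)
  A <- 1 / (ip$tau_off_ms - tau_s)
  h <- A * (1 - exp(-t_grid / ip$tau_on_ms)) * exp(-t_grid / ip$tau_off_ms)
  expect_equal(max(resp), max(h), tolerance = 0.01)
  expect_lt(max(abs(resp - h)), 0.01 * max(h))
})

test_that("convolution stage is linear in its input", {
  ip <- indicator_params("GCaMP6f")
  drive <- c(rep(0.2, 30), rep(0, 70))
  respond <- function(scale) {
    st <- calcium_state(1, ip)
    out <- numeric(100)
    for (k in 1:100) {
      st$ca <- ip$Ca_rest_uM + scale * drive[k]
      st <- kernel_step(st, ip, 1)
      out[k] <- st$cab_active - ip$Ca_rest_uM
    }
    out
  }
  expect_equal(respond(2), 2 * respond(1), tolerance = 1e-12)
})

test_that("the Hill readout is zero at rest, increasing, and saturating", {
  for (ind in c("GCaMP6f", "jGCaMP7", "OGB-1")) {
    ip <- indicator_params(ind)
    expect_equal(dff(ip$Ca_rest_uM, ip), 0)
    x <- seq(0.001, 20, length.out = 500)
    y <- dff(x, ip)
    expect_true(all(diff(y) > 0))
    sat <- ip$dFF_max *
      (1 - 1 / (1 + (ip$Kd_uM / ip$Ca_rest_uM)^ip$nH))
    expect_equal(dff(1e9, ip), sat, tolerance = 1e-4)
  }
})

test_that("readout noise scales inversely with the visible fraction", {
  ip <- indicator_params("GCaMP6f")
  ip0 <- indicator_params("GCaMP6f", sigma_noise = 0)
  expect_equal(frame_readout(0.3, N = 1, rho_rel = 0.7, ip0), 0.21)
  set.seed(41)
  n <- 1e5
  s_full <- sd(frame_readout(rep(0.3, n), N = 1, rho_rel = 1, ip))
  s_half <- sd(frame_readout(rep(0.3, n), N = 0.5, rho_rel = 1, ip))
  se_rel <- 1 / sqrt(2 * n)  # relative SE of a Gaussian SD estimate
  expect_lt(abs(s_full / ip$sigma_noise - 1), 4 * se_rel)
  expect_lt(abs(s_half / (ip$sigma_noise / 0.5) - 1), 4 * se_rel)
})

test_that("a 100 Hz pulse train yields a rising, saturating transient", {
  ip <- indicator_params("GCaMP6f")
  spike_times <- seq(100, by = 10, length.out = 10)
  tr <- simulate_calcium(spike_times, 2500, dt = 1, ip)
  expect_true(all(tr$dff[tr$time_ms < 100] == 0))
  # rising during the train: dff at successive spike times increases
  at_spikes <- tr$dff[match(spike_times + 5, tr$time_ms)]
  expect_true(all(diff(at_spikes) > 0))
  # the transient crests after the last pulse (indicator kinetics outlast
  # the train) and then decays back toward baseline
  t_peak <- tr$time_ms[which.max(tr$dff)]
  expect_gt(t_peak, max(spike_times))
  expect_lt(t_peak, max(spike_times) + 1000)
  after_peak <- tr$dff[tr$time_ms >= t_peak]
  expect_true(all(diff(after_peak) <= 0))
  expect_lt(tr$dff[nrow(tr)], 0.5 * max(tr$dff))
})

test_that("expression level scales the single-spike transient linearly", {
  ip <- indicator_params("GCaMP6f", sigma_noise = 0)
  tr <- simulate_calcium(50, 600, dt = 1, ip)
  peak <- max(tr$dff)
  # readout with rho_rel scales the trace exactly (no noise)
  expect_equal(frame_readout(peak, 1, 0.5, ip), 0.5 * peak)
  expect_equal(frame_readout(peak, 1, 2, ip), 2 * peak)
})

test_that("targeted neurons respond more strongly than off-target neighbors", {
  # two neurons 30 um apart laterally; laser focused on the first
  coords <- rbind(c(0, 0, 100), c(30, 0, 100))
  pop <- neuron_population(coords, bias = 0, noise_sd = 0, name = "pair")
  lt <- laser_targets(c(0, 0, 100), sigma_lateral = 8, sigma_axial = 24,
                      d_soma_um = 20)
  sim <- simulation(dt = 0.1, seed = 55)
  add_population(sim, pop)
  laser <- light_device(lt, label = "laser")
  ops <- opsin_device(simple_opsin(0.02), NULL, 1, label = "ops")
  scope <- microscope(center = c(0, 0, 100), fov_width_um = 150,
                      soma_radius_um = 10, frame_period_ms = 10,
                      snr_cutoff = 0)
  img <- imaging_device(scope, indicator_params("GCaMP6f"), 1,
                        label = "img")
  inject(sim, laser, "pair")
  inject(sim, ops, "pair")
  inject(sim, img, "pair")
  # 10 pulses of 2 ms at 100 Hz via the I/O processor
  io <- io_processor(1, function(meas, t) {
    on <- t >= 100 & t < 200 & (t %% 10) < 2
    list(laser = if (on) 5 else 0)
  })
  run(sim, 600, io)
  out <- device_output(sim, "img")
  frames <- out$frames
  peak_target <- max(frames[, 2])
  peak_off <- max(frames[, 3])
  sp <- get_spikes(sim, "pair")
  expect_gt(sum(sp$neuron == 1), sum(sp$neuron == 2))
  expect_gt(peak_target, peak_off)
  expect_gt(peak_target, 0)
})
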