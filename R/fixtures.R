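#' Uniform light field
#'
#' Whole-field illumination (e.g., an LED bathing a culture dish): every
#' neuron receives the commanded irradiance directly, with no spatial
#' falloff. Useful for in vitro-style experiments where light is not focal.
#'
#' @param wavelength_nm Wavelength (nm).
#' @param irr0 Commanded irradiance (mW/mm^2).
#' @return Object of classes `uniform_light`, `light_source`.
#' @export
uniform_light <- function(wavelength_nm, irr0 = 0) {
  stopifnot(irr0 >= 0)
  structure(list(wavelength_nm = wavelength_nm, irr0 = irr0),
            class = c("uniform_light", "light_source"))
}

#' Multi-electrode array grid
#'
#' Planar grid of contacts (z = 0 plane by default), optionally dropping the
#' four corners — the classic 60-channel 8 x 8 culture MEA layout with 200 um
#' pitch.
#'
#' @param rows,cols Grid dimensions.
#' @param pitch_um Contact spacing (um).
#' @param center Grid center (x, y, z) in um.
#' @param drop_corners Drop the four corner contacts.
#' @return An [electrode_array()].
#' @export
mea_grid <- function(rows = 8, cols = 8, pitch_um = 200,
                     center = c(0, 0, 0), drop_corners = TRUE) {
  xs <- (seq_len(cols) - (cols + 1) / 2) * pitch_um + center[1]
  ys <- (seq_len(rows) - (rows + 1) / 2) * pitch_um + center[2]
  g <- expand.grid(x = xs, y = ys)
  if (drop_corners) {
    corner <- (g$x %in% range(xs)) & (g$y %in% range(ys))
    g <- g[!corner, ]
  }
  electrode_array(cbind(g$x, g$y, center[3]))
}

#' Unconnected population in a box
#'
#' n neurons at uniform random coordinates in a rectangular volume, no
#' synapses — the standard fixture for single-cell all-optical experiments
#' (default: 100 LIF neurons in 150 x 150 x 100 um).
#'
#' @param n Number of neurons.
#' @param box_um Box dimensions (x, y, z extents in um).
#' @param origin_um Box corner (um); the box spans `origin + [0, box]`.
#' @param seed Optional seed for reproducible coordinates.
#' @param ... Passed to [neuron_population()].
#' @return A [neuron_population()].
#' @export
make_unconnected_box <- function(n = 100, box_um = c(150, 150, 100),
                                 origin_um = c(0, 0, 0), seed = NULL, ...) {
  stopifnot(n > 0, length(box_um) == 3, all(box_um > 0))
  if (!is.null(seed)) set.seed(seed)
  coords <- cbind(runif(n, 0, box_um[1]), runif(n, 0, box_um[2]),
                  runif(n, 0, box_um[3]))
  coords <- sweep(coords, 2, origin_um, "+")
  neuron_population(coords, name = "box", ...)
}

#' Excitatory/inhibitory LIF disc network
#'
#' E and I cells at uniform random positions in a flat disc (z = 0), with
#' sparse random connectivity. The inhibitory weight is set to
#' `g_rel * g_balanced` times the unit inhibitory weight, where `g_balanced`
#' satisfies `sum(w_e) = g_balanced * sum(w_i)` over all connections, so
#' `g_rel = 1` balances total excitation and inhibition and the default
#' `g_rel = 1.875` makes inhibition overpower excitation, producing
#' network-wide bursting when combined with a noisy subthreshold drive.
#'
#' Unlisted constants (LIF parameters, connection probability, weight scale,
#' background drive) are fixture choices recorded here: tau_m 20 ms, rest -70,
#' threshold -50, reset -70 mV, 2 ms refractory, p_conn 0.1, unit weight 2
#' (current units, R = 1), synaptic tau 5 ms (AMPA) / 8 ms (GABA), bias 19
#' with noise SD 3 — chosen once to give burst-dominated baseline activity of
#' a few Hz.
#'
#' @param n_e,n_i Population sizes.
#' @param diameter_um Disc diameter (um).
#' @param g_rel Inhibitory dominance relative to the balanced point.
#' @param p_conn Connection probability (all pairs, self-connections
#'   excluded within a population).
#' @param w_e Unit excitatory weight (current units).
#' @param bias,noise_sd Background drive (see [neuron_population()]).
#' @param seed Optional seed.
#' @return List with `exc`, `inh` (populations named `"exc"`, `"inh"`) and
#'   `synapses` (list of four [synapse_group()]s), plus the realized
#'   `g_balanced` and inhibitory weight.
#' @export
make_ei_disc <- function(n_e = 800, n_i = 200, diameter_um = 2000,
                         g_rel = 1.875, p_conn = 0.1, w_e = 2,
                         bias = 19, noise_sd = 3, seed = NULL) {
  stopifnot(n_e > 0, n_i > 0, diameter_um > 0, g_rel > 0,
            p_conn > 0, p_conn <= 1)
  if (!is.null(seed)) set.seed(seed)
  rad <- diameter_um / 2
  disc_coords <- function(n) {
    r <- rad * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(r * cos(th), r * sin(th), 0)
  }
  exc <- neuron_population(disc_coords(n_e), "excitatory", "lif",
                           bias = bias, noise_sd = noise_sd, name = "exc")
  inh <- neuron_population(disc_coords(n_i), "inhibitory", "lif",
                           bias = bias, noise_sd = noise_sd, name = "inh")
  connect <- function(ns, nt, self = FALSE) {
    m <- matrix(runif(ns * nt) < p_conn, ns, nt)
    if (!self && ns == nt) diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)
    list(pre = idx[, 1], post = idx[, 2])
  }
  ee <- connect(n_e, n_e)
  ei <- connect(n_e, n_i)
  ie <- connect(n_i, n_e)
  ii <- connect(n_i, n_i)
  n_exc_conn <- length(ee$pre) + length(ei$pre)
  n_inh_conn <- length(ie$pre) + length(ii$pre)
  # sum(w_e) = g_balanced * sum(w_i_unit), unit inhibitory weight = w_e
  g_balanced <- (n_exc_conn * w_e) / (n_inh_conn * w_e)
  w_i <- -g_rel * g_balanced * w_e
  synapses <- list(
    synapse_group("exc", "exc", ee$pre, ee$post, w_e, receptor = "AMPA",
                  tau_syn_ms = 5),
    synapse_group("exc", "inh", ei$pre, ei$post, w_e, receptor = "AMPA",
                  tau_syn_ms = 5),
    synapse_group("inh", "exc", ie$pre, ie$post, w_i, receptor = "GABA",
                  tau_syn_ms = 8),
    synapse_group("inh", "inh", ii$pre, ii$post, w_i, receptor = "GABA",
                  tau_syn_ms = 8))
  list(exc = exc, inh = inh, synapses = synapses,
       g_balanced = g_balanced, w_i = w_i)
}

# Assemble a simulation around an E/I disc network with bidirectional
# whole-field optogenetics and an MEA probe; shared by the optoclamp demo and
# the config-driven CLI.
optoclamp_setup <- function(net, dt = 0.2, seed = NULL,
                            k_blue = 50, k_amber = -50,
                            expression = expression_model(1, "lognormal",
                                                          0, 0.5),
                            probe_mode = "mua") {
  sim <- simulation(dt = dt, seed = seed)
  add_population(sim, net$exc)
  add_population(sim, net$inh)
  for (s in net$synapses) add_synapses(sim, s)
  blue <- light_device(uniform_light(465), label = "blue")
  amber <- light_device(uniform_light(590), label = "amber")
  exc_opsin <- opsin_device(simple_opsin(k_blue, "chr2-like"),
                            action_spectrum("ChR2-H134R"),
                            expression, label = "exc_opsin")
  inh_opsin <- opsin_device(simple_opsin(k_amber, "halo-like"),
                            action_spectrum("eNpHR3.0"),
                            expression, label = "inh_opsin")
  probe <- spike_probe(mea_grid(), mode = probe_mode, label = "mea")
  for (pn in c("exc", "inh")) {
    inject(sim, blue, pn)
    inject(sim, amber, pn)
    inject(sim, exc_opsin, pn)
    inject(sim, inh_opsin, pn)
  }
  inject(sim, probe, "exc")
  sim
}

#' Closed-loop firing-rate clamp demo (optoclamp)
#'
#' End-to-end demonstration: the E/I disc network is recorded with a
#' 60-channel MEA, firing rate is estimated from multi-unit activity with an
#' exponential filter, and a PI controller sets the intensities of two
#' opposing whole-field light sources (465 nm driving a depolarizing opsin,
#' 590 nm driving a hyperpolarizing one, with action-spectrum crosstalk
#' between the channels) to clamp the rate to multiples of the measured
#' baseline.
#'
#' @param targets_rel Target rates as multiples of the measured baseline.
#' @param baseline_ms Duration of the open-loop baseline phase (ms).
#' @param clamp_ms Duration of each closed-loop phase (ms).
#' @param seed Seed for the whole experiment.
#' @param dt Simulation step (ms).
#' @param sample_ms Sampling period (ms).
#' @param delay_ms Control loop latency (ms).
#' @param kp,ki PI gains (mW/mm^2 per Hz; mW/mm^2 per spike).
#' @param tau_est_ms Rate-estimator time constant (ms).
#' @param u_max Light intensity bound per channel (mW/mm^2).
#' @param n_e,n_i Network size.
#' @return List with `baseline_hz`, `targets_hz`, and per-target data frames
#'   (`time_ms`, `rate_hz`, `u_blue`, `u_amber`) in `$traces`, plus
#'   `steady_rate_hz`, the mean measured rate over the final quarter of each
#'   clamp phase.
#' @export
demo_optoclamp <- function(targets_rel = c(2, 3), baseline_ms = 2000,
                           clamp_ms = 15000, seed = 1, dt = 0.5,
                           sample_ms = 1, delay_ms = 3, kp = 0.005,
                           ki = 0.003, tau_est_ms = 1000, u_max = 20,
                           n_e = 800, n_i = 200) {
  rate_tracker <- function() {
    env <- new.env()
    env$rate <- 0
    env
  }
  mua_rate_hz <- function(meas, est, n_ch) {
    count <- if (is.null(meas$mea)) 0 else nrow(meas$mea)
    est$rate <- exp_rate_update(est$rate, count / n_ch, sample_ms,
                                tau_est_ms)
    est$rate
  }

  # baseline phase: record without stimulation
  net <- make_ei_disc(n_e = n_e, n_i = n_i, seed = seed)
  sim <- optoclamp_setup(net, dt = dt, seed = seed + 1)
  est <- rate_tracker()
  n_ch <- 60
  base_rates <- c()
  io_base <- io_processor(sample_ms, function(meas, t_ms) {
    r <- mua_rate_hz(meas, est, n_ch)
    base_rates[[length(base_rates) + 1]] <<- r
    NULL
  }, latency_model(delay_ms))
  run(sim, baseline_ms, io_base)
  base_rates <- unlist(base_rates)
  baseline_hz <- mean(base_rates[seq(length(base_rates) %/% 2,
                                     length(base_rates))])

  targets_hz <- targets_rel * baseline_hz
  traces <- list()
  steady <- numeric(length(targets_hz))
  for (j in seq_along(targets_hz)) {
    target <- targets_hz[j]
    net <- make_ei_disc(n_e = n_e, n_i = n_i, seed = seed)
    sim <- simulation_with_clamp <- optoclamp_setup(net, dt = dt,
                                                    seed = seed + 1)
    est <- rate_tracker()
    ctl <- pi_controller(kp, ki, bounds = c(-u_max, u_max))
    log <- list()
    io <- io_processor(sample_ms, function(meas, t_ms) {
      r <- mua_rate_hz(meas, est, n_ch)
      u <- pi_update(ctl, target, r, sample_ms)
      ub <- max(u, 0)
      ua <- max(-u, 0)
      log[[length(log) + 1]] <<- c(t_ms, r, ub, ua)
      list(blue = ub, amber = ua)
    }, latency_model(delay_ms))
    run(sim, clamp_ms, io)
    m <- do.call(rbind, log)
    tr <- data.frame(time_ms = m[, 1], rate_hz = m[, 2],
                     u_blue = m[, 3], u_amber = m[, 4])
    traces[[j]] <- tr
    tail_idx <- tr$time_ms > 0.75 * clamp_ms
    steady[j] <- mean(tr$rate_hz[tail_idx])
  }
  list(baseline_hz = baseline_hz, targets_rel = targets_rel,
       targets_hz = targets_hz, traces = traces, steady_rate_hz = steady)
}
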