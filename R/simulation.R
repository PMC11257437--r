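#' Create a simulation
#'
#' The simulation object owns populations, synapses, injected devices, and
#' the clock. Time is in ms; the clock advances in fixed steps of `dt`.
#' Sampling and delivery times are snapped to the step grid. All randomness
#' draws from R's global stream, seeded from `seed` at the start of [run()]
#' for reproducibility.
#'
#' @param dt Simulation step (ms), `> 0`.
#' @param seed Optional integer seed applied at the start of each [run()].
#' @return An environment of class `simulation`.
#' @export
simulation <- function(dt = 0.1, seed = NULL) {
  stopifnot(dt > 0)
  sim <- new.env(parent = emptyenv())
  sim$dt <- dt
  sim$t <- 0
  sim$seed <- seed
  sim$started <- FALSE
  sim$populations <- list()
  sim$synapses <- list()
  sim$devices <- list()
  sim$spike_log <- list()
  class(sim) <- "simulation"
  sim
}

#' Register a population with a simulation
#'
#' @param sim A [simulation()].
#' @param pop A [neuron_population()]; its `name` field is the registry key.
#' @return The population name, invisibly.
#' @export
add_population <- function(sim, pop) {
  stopifnot(inherits(sim, "simulation"), inherits(pop, "neuron_population"))
  if (sim$started) stop("cannot add populations after the run has started")
  sim$populations[[pop$name]] <- pop
  sim$spike_log[[pop$name]] <- list(t = list(), i = list())
  invisible(pop$name)
}

#' Register a synapse group with a simulation
#'
#' @param sim A [simulation()].
#' @param syn A [synapse_group()] whose `source`/`target` name registered
#'   populations.
#' @return Invisibly, the index of the group.
#' @export
add_synapses <- function(sim, syn) {
  stopifnot(inherits(sim, "simulation"), inherits(syn, "synapse_group"))
  if (sim$started) stop("cannot add synapses after the run has started")
  for (nm in c(syn$source, syn$target)) {
    if (is.null(sim$populations[[nm]]))
      stop("unknown population '", nm, "'")
  }
  stopifnot(max(syn$i_pre) <= length(sim$populations[[syn$source]]$ids),
            max(syn$j_post) <= length(sim$populations[[syn$target]]$ids))
  sim$synapses[[length(sim$synapses) + 1]] <- syn
  invisible(length(sim$synapses))
}

#' Inject a device into a population
#'
#' Registers a recording or stimulation device and precomputes its per-neuron
#' geometric quantities (distances, transmittance, PSF weights, ROI
#' visibility) for that population. A device may be injected into several
#' populations; devices must be injected before the run begins.
#'
#' @param sim A [simulation()].
#' @param device A device: [light_device()], [opsin_device()],
#'   [spike_probe()], [imaging_device()], [tklfp_recorder()], or
#'   [rwslfp_recorder()].
#' @param pop_name Name of a registered population.
#' @return The device label, invisibly.
#' @export
inject <- function(sim, device, pop_name) {
  stopifnot(inherits(sim, "simulation"))
  if (sim$started) stop("cannot inject devices after the run has started")
  pop <- sim$populations[[pop_name]]
  if (is.null(pop)) stop("unknown population '", pop_name, "'")
  if (is.null(pop$coords)) stop("population has no coordinates")
  label <- device$label
  entry <- sim$devices[[label]]
  if (is.null(entry)) entry <- list(device = device, pops = list())
  entry$pops[[pop_name]] <- device_init(device, pop, sim)
  sim$devices[[label]] <- entry
  invisible(label)
}

# Per-(device, population) precomputation; returns the per-population state.
device_init <- function(device, pop, sim) UseMethod("device_init")

#' Light source device
#'
#' Wraps an [optic_fiber()] or [laser_targets()] as an injectable stimulator.
#' Injection precomputes each neuron's irradiance per unit commanded
#' intensity (tip irradiance in mW/mm^2 for fibers; per-target power in mW
#' for laser target sets). Control messages address the device by `label`
#' and set the commanded intensity.
#'
#' @param source An [optic_fiber()] or [laser_targets()].
#' @param label Unique device label.
#' @param value Initial commanded intensity.
#' @return Object of class `light_device`.
#' @export
light_device <- function(source, label, value = 0) {
  stopifnot(inherits(source, "light_source"), value >= 0)
  structure(list(source = source, label = label, value = value,
                 wavelength_nm = source$wavelength_nm),
            class = c("light_device", "device"))
}

#' @export
device_init.light_device <- function(device, pop, sim) {
  unit_irr <- if (inherits(device$source, "optic_fiber")) {
    fiber_transmittance(device$source, pop$coords)
  } else if (inherits(device$source, "uniform_light")) {
    rep(1, nrow(pop$coords))
  } else {
    laser_irradiance(device$source, pop$coords,
                     power_mW = rep(1, nrow(device$source$targets)))
  }
  list(unit_irr = unit_irr)
}

#' Opsin device
#'
#' Attaches an opsin (Markov or proportional) to a population. Each step the
#' device sums irradiance over all injected light sources, weighting each
#' wavelength by the opsin's action spectrum (effective irradiance), and
#' converts it to per-neuron photocurrent scaled by expression level.
#'
#' @param model A [markov_opsin()] or [simple_opsin()].
#' @param spectrum An [action_spectrum()]; `NULL` restricts sensitivity to
#'   light sources whose wavelength equals the opsin's peak.
#' @param expression An [expression_model()] (sampled per population at
#'   injection) or a numeric vector of `rho_rel` recycled to the population.
#' @param label Unique device label.
#' @return Object of class `opsin_device`.
#' @export
opsin_device <- function(model, spectrum = NULL,
                         expression = expression_model(), label) {
  stopifnot(inherits(model, "markov_opsin") || inherits(model,
                                                        "simple_opsin"))
  structure(list(model = model, spectrum = spectrum,
                 expression = expression, label = label),
            class = c("opsin_device", "device"))
}

#' @export
device_init.opsin_device <- function(device, pop, sim) {
  n <- length(pop$ids)
  rho <- if (inherits(device$expression, "expression_model")) {
    sample_expression(n, device$expression)
  } else {
    rep_len(device$expression, n)
  }
  st <- if (inherits(device$model, "markov_opsin")) markov_state(n) else NULL
  list(rho = rho, state = st)
}

#' Extracellular spike-recording probe
#'
#' Injection precomputes the contacts-by-neurons distance matrix. When the
#' run has an I/O processor attached, detection runs causally on each sample
#' window and the sampled events form the measurement payload; the
#' accumulated events are also the device output. Without an I/O processor,
#' the output is computed once over the whole run.
#'
#' @param electrodes An [electrode_array()].
#' @param cfg A [spike_detector_config()].
#' @param mode `"mua"` or `"sorted"`.
#' @param label Unique device label.
#' @param noise_events,collisions Passed to the detection pipeline.
#' @return Object of class `spike_probe`.
#' @export
spike_probe <- function(electrodes, cfg = spike_detector_config(),
                        mode = c("mua", "sorted"), label = "probe",
                        noise_events = TRUE, collisions = TRUE) {
  mode <- match.arg(mode)
  structure(list(electrodes = electrodes, cfg = cfg, mode = mode,
                 label = label, noise_events = noise_events,
                 collisions = collisions),
            class = c("spike_probe", "device"))
}

#' @export
device_init.spike_probe <- function(device, pop, sim) {
  d <- distance_matrix(device$electrodes$coords, pop$coords)
  list(distances = d, sampled = list())
}

# c x n Euclidean distance matrix between contact and neuron coordinates.
distance_matrix <- function(contacts, coords) {
  c_n <- nrow(contacts)
  n <- nrow(coords)
  out <- matrix(0, c_n, n)
  for (k in 1:3) {
    out <- out + outer(contacts[, k], coords[, k], "-")^2
  }
  sqrt(out)
}

#' Two-photon imaging device
#'
#' Injection selects ROIs ([select_rois()]) and initializes per-ROI calcium
#' state. During the run the indicator dynamics advance every step from that
#' population's spikes and a noisy frame is read out every frame period.
#'
#' @param scope A [microscope()].
#' @param indicator An [indicator_params()].
#' @param expression An [expression_model()] or numeric `rho_rel` vector.
#' @param label Unique device label.
#' @return Object of class `imaging_device`.
#' @export
imaging_device <- function(scope, indicator = indicator_params(),
                           expression = expression_model(),
                           label = "scope") {
  structure(list(scope = scope, indicator = indicator,
                 expression = expression, label = label),
            class = c("imaging_device", "device"))
}

#' @export
device_init.imaging_device <- function(device, pop, sim) {
  n <- length(pop$ids)
  rho <- if (inherits(device$expression, "expression_model")) {
    sample_expression(n, device$expression)
  } else {
    rep_len(device$expression, n)
  }
  rois <- select_rois(device$scope, pop, rho, device$indicator)
  frame_every <- round(device$scope$frame_period_ms / sim$dt)
  if (abs(frame_every * sim$dt - device$scope$frame_period_ms) > 1e-9)
    stop("frame period must be a multiple of the simulation step")
  list(rois = rois, ca = calcium_state(nrow(rois), device$indicator),
       frame_every = frame_every, frames = list())
}

#' Kernel LFP recorder (offline proxy)
#'
#' Registers electrodes for the per-spike kernel proxy; the trace is computed
#' from the run's recorded spikes when [device_output()] is called.
#'
#' @param electrodes An [electrode_array()].
#' @param params A [tklfp_params()].
#' @param out_dt_ms Output trace step (ms).
#' @param label Unique device label.
#' @return Object of class `tklfp_recorder`.
#' @export
tklfp_recorder <- function(electrodes, params = tklfp_params(),
                           out_dt_ms = 1, label = "tklfp") {
  structure(list(electrodes = electrodes, params = params,
                 out_dt_ms = out_dt_ms, label = label),
            class = c("tklfp_recorder", "device"))
}

#' @export
device_init.tklfp_recorder <- function(device, pop, sim) list()

#' Reference-weighted synaptic-current LFP recorder (offline proxy)
#'
#' Registers electrodes for the reference-weighted sum of synaptic currents.
#' At output time, per-neuron AMPA and GABA currents onto the target
#' (pyramidal) population are synthesized from the recorded presynaptic
#' spikes with a biexponential kernel, using the receptor labels of the
#' registered synapse groups (an error if a group targeting the population
#' lacks an AMPA/GABA label).
#'
#' @param electrodes An [electrode_array()].
#' @param params An [rwslfp_params()].
#' @param synth A list with biexponential constants `tau_r`, `tau_d` (ms).
#' @param out_dt_ms Output trace step (ms).
#' @param variant Spatial profile variant, see [rwslfp_amplitude()].
#' @param label Unique device label.
#' @return Object of class `rwslfp_recorder`.
#' @export
rwslfp_recorder <- function(electrodes, params = rwslfp_params(),
                            synth = list(tau_r = 0.5, tau_d = 2),
                            out_dt_ms = 1, variant = "per_neuron",
                            label = "rwslfp") {
  structure(list(electrodes = electrodes, params = params, synth = synth,
                 out_dt_ms = out_dt_ms, variant = variant, label = label),
            class = c("rwslfp_recorder", "device"))
}

#' @export
device_init.rwslfp_recorder <- function(device, pop, sim) list()

#' Retrieve recorded ground-truth spikes
#'
#' @param sim A [simulation()] after [run()].
#' @param pop_name Population name.
#' @return Data frame with `time_ms` and `neuron`.
#' @export
get_spikes <- function(sim, pop_name) {
  log <- sim$spike_log[[pop_name]]
  if (is.null(log)) stop("unknown population '", pop_name, "'")
  t <- unlist(log$t)
  i <- unlist(log$i)
  data.frame(time_ms = if (is.null(t)) numeric(0) else t,
             neuron = if (is.null(i)) integer(0) else as.integer(i))
}

#' Collect a device's recorded output
#'
#' @param sim A [simulation()] after [run()].
#' @param label Device label.
#' @return Device-specific output: detected spikes for a [spike_probe()],
#'   ROI traces (`time_ms` x ROI matrix plus manifest) for an
#'   [imaging_device()], LFP traces for the LFP recorders.
#' @export
device_output <- function(sim, label) {
  entry <- sim$devices[[label]]
  if (is.null(entry)) stop("unknown device '", label, "'")
  device <- entry$device
  pops <- names(entry$pops)
  if (inherits(device, "spike_probe")) {
    st <- entry$pops[[pops[1]]]
    if (length(st$sampled) > 0) {
      out <- do.call(rbind, st$sampled)
      rownames(out) <- NULL
      return(out)
    }
    spikes <- get_spikes(sim, pops[1])
    return(record_spikes(spikes, st$distances, device$cfg,
                         duration_ms = sim$t, mode = device$mode,
                         noise_events = device$noise_events,
                         collisions = device$collisions))
  }
  if (inherits(device, "imaging_device")) {
    st <- entry$pops[[pops[1]]]
    frames <- do.call(rbind, st$frames)
    return(list(rois = st$rois, frames = frames))
  }
  if (inherits(device, "tklfp_recorder")) {
    t_grid <- seq(0, sim$t, by = device$out_dt_ms)
    out <- 0
    for (pn in pops) {
      out <- out + tklfp_signal(get_spikes(sim, pn), sim$populations[[pn]],
                                device$electrodes, t_grid, device$params)
    }
    return(list(time_ms = t_grid, lfp = out))
  }
  if (inherits(device, "rwslfp_recorder")) {
    return(rwslfp_output(sim, device, pops[1]))
  }
  entry$pops
}

# Synthesize per-neuron AMPA/GABA currents from presynaptic spikes and weight
# them into the RWSLFP trace.
rwslfp_output <- function(sim, device, pop_name) {
  pop <- sim$populations[[pop_name]]
  n <- length(pop$ids)
  t_grid <- seq(0, sim$t, by = device$out_dt_ms)
  ampa <- matrix(0, length(t_grid), n)
  gaba <- matrix(0, length(t_grid), n)
  any_syn <- FALSE
  for (syn in sim$synapses) {
    if (syn$target != pop_name) next
    any_syn <- TRUE
    rec <- toupper(syn$receptor)
    if (!all(rec %in% c("AMPA", "GABA")))
      stop("synapse group onto '", pop_name,
           "' lacks AMPA/GABA receptor labels")
    pre_spikes <- get_spikes(sim, syn$source)
    for (m in seq_along(syn$i_pre)) {
      ts <- pre_spikes$time_ms[pre_spikes$neuron == syn$i_pre[m]] +
        syn$delay_ms[m]
      if (length(ts) == 0) next
      cur <- synthesize_currents(ts, t_grid, device$synth$tau_r,
                                 device$synth$tau_d,
                                 weight = abs(syn$weight[m]))
      j <- syn$j_post[m]
      if (rec[m] == "AMPA") {
        ampa[, j] <- ampa[, j] + cur
      } else {
        gaba[, j] <- gaba[, j] + cur
      }
    }
  }
  if (!any_syn)
    stop("reference-weighted LFP requires synapse groups onto '",
         pop_name, "'")
  lfp <- rwslfp_signal(ampa, gaba, pop$coords, device$electrodes,
                       device$out_dt_ms, device$params, device$variant)
  list(time_ms = t_grid, lfp = lfp)
}

#' Run the simulation
#'
#' Per step: apply control messages due at the step start to stimulators,
#' integrate each population under background, synaptic, and photocurrents,
#' log spikes, advance indicator dynamics, and at the end of each sampling
#' period push a measurement to the I/O processor, whose reply enters the
#' delivery buffer with the modeled latency. Recorders never perturb the
#' network state.
#'
#' @param sim A [simulation()].
#' @param duration_ms Duration (ms); must be a multiple of `dt`.
#' @param io Optional [io_processor()]; its sampling period must be a
#'   multiple of `dt`.
#' @return The simulation, invisibly (clock advanced; outputs via
#'   [get_spikes()] and [device_output()]).
#' @export
run <- function(sim, duration_ms, io = NULL) {
  stopifnot(inherits(sim, "simulation"), duration_ms > 0)
  dt <- sim$dt
  n_steps <- round(duration_ms / dt)
  if (abs(n_steps * dt - duration_ms) > 1e-9)
    stop("duration must be a multiple of dt")
  sample_every <- NA
  if (!is.null(io)) {
    stopifnot(inherits(io, "io_processor"))
    sample_every <- round(io$sample_period_ms / dt)
    if (sample_every < 1 ||
        abs(sample_every * dt - io$sample_period_ms) > 1e-9)
      stop("sampling period must be a positive multiple of dt")
  }
  if (!sim$started && !is.null(sim$seed)) set.seed(sim$seed)
  sim$started <- TRUE
  t0 <- sim$t

  pop_names <- names(sim$populations)
  n_pop <- vapply(sim$populations, function(p) length(p$ids), integer(1))

  # synaptic machinery: per-group exponential current + delay ring buffer
  syn_state <- lapply(sim$synapses, function(s) {
    numeric(n_pop[[s$target]])
  })
  syn_setup <- lapply(sim$synapses, function(s) {
    dsteps <- as.integer(round(s$delay_ms / dt))
    by_d <- split(seq_along(s$i_pre), dsteps)
    mats <- lapply(by_d, function(idx) {
      synapse_weight_matrix(
        synapse_group(s$source, s$target, s$i_pre[idx], s$j_post[idx],
                      s$weight[idx], receptor = s$receptor[idx],
                      tau_syn_ms = s$tau_syn_ms),
        n_pop[[s$source]], n_pop[[s$target]])
    })
    max_d <- max(as.integer(names(by_d)))
    list(delay_steps = as.integer(names(by_d)), mats = mats,
         ring = matrix(0, nrow = max_d + 1, ncol = n_pop[[s$target]]),
         decay = exp(-dt / s$tau_syn_ms))
  })

  light_labels <- names(sim$devices)[vapply(sim$devices, function(d)
    inherits(d$device, "light_device"), logical(1))]

  spk_t <- lapply(pop_names, function(x) vector("list", n_steps))
  spk_i <- lapply(pop_names, function(x) vector("list", n_steps))
  names(spk_t) <- names(spk_i) <- pop_names

  window_spikes <- lapply(pop_names, function(x) list())
  names(window_spikes) <- pop_names

  for (k in seq_len(n_steps)) {
    t_start <- t0 + (k - 1) * dt
    t_end <- t0 + k * dt

    if (!is.null(io)) {
      for (msg in buffer_pop(io$buffer, t_start + 1e-9)) {
        upd <- msg$payload
        for (nm in names(upd)) {
          if (!nm %in% light_labels)
            stop("control message names unknown stimulator '", nm, "'")
          sim$devices[[nm]]$device$value <- max(upd[[nm]], 0)
        }
      }
    }

    spikes_this_step <- list()
    for (pn in pop_names) {
      pop <- sim$populations[[pn]]
      n <- n_pop[[pn]]
      input <- pop$bias
      if (pop$noise_sd > 0)
        input <- input + pop$noise_sd * rnorm(n) / sqrt(dt)
      for (g in seq_along(sim$synapses)) {
        if (sim$synapses[[g]]$target == pn) input <- input + syn_state[[g]]
      }
      # photocurrents: per opsin device on this population
      any_light_on <- any(vapply(light_labels, function(ll)
        sim$devices[[ll]]$device$value > 0, logical(1)))
      for (lab in names(sim$devices)) {
        entry <- sim$devices[[lab]]
        if (!inherits(entry$device, "opsin_device")) next
        st <- entry$pops[[pn]]
        if (is.null(st)) next
        if (!any_light_on && inherits(entry$device$model, "simple_opsin"))
          next
        irr_eff <- numeric(n)
        for (ll in light_labels) {
          lentry <- sim$devices[[ll]]
          lst <- lentry$pops[[pn]]
          if (is.null(lst) || lentry$device$value == 0) next
          irr <- lentry$device$value * lst$unit_irr
          eps <- if (is.null(entry$device$spectrum)) {
            peak <- if (inherits(entry$device$model, "markov_opsin"))
              entry$device$model$wavelength_nm else NA
            if (is.na(peak) ||
                lentry$device$wavelength_nm == peak) 1 else 0
          } else {
            epsilon_at(entry$device$spectrum, lentry$device$wavelength_nm)
          }
          irr_eff <- irr_eff + eps * irr
        }
        if (inherits(entry$device$model, "simple_opsin")) {
          input <- input + simple_current(entry$device$model, irr_eff,
                                          st$rho)
        } else {
          ms <- markov_step(st$state, irr_eff, pop$v, entry$device$model,
                            dt, st$rho)
          sim$devices[[lab]]$pops[[pn]]$state <- ms$state
          input <- input + ms$i_opto
        }
      }
      stepped <- step_neurons(pop, input, dt)
      sim$populations[[pn]] <- stepped$pop
      spikes_this_step[[pn]] <- stepped$spikes
      if (length(stepped$spikes)) {
        spk_t[[pn]][[k]] <- rep(t_end, length(stepped$spikes))
        spk_i[[pn]][[k]] <- stepped$spikes
        window_spikes[[pn]][[length(window_spikes[[pn]]) + 1]] <-
          cbind(t_end, stepped$spikes)
      }
    }

    # synaptic propagation and decay
    for (g in seq_along(sim$synapses)) {
      s <- sim$synapses[[g]]
      setup <- syn_setup[[g]]
      spk <- spikes_this_step[[s$source]]
      if (length(spk)) {
        sv <- numeric(n_pop[[s$source]])
        sv[spk] <- 1
        for (di in seq_along(setup$delay_steps)) {
          row <- (k + setup$delay_steps[di]) %% nrow(setup$ring) + 1
          setup$ring[row, ] <- setup$ring[row, ] +
            as.numeric(setup$mats[[di]] %*% sv)
        }
      }
      row_now <- k %% nrow(setup$ring) + 1
      syn_state[[g]] <- syn_state[[g]] * setup$decay + setup$ring[row_now, ]
      setup$ring[row_now, ] <- 0
      syn_setup[[g]] <- setup
    }

    # imaging devices: indicator dynamics each step, frames on schedule
    for (lab in names(sim$devices)) {
      entry <- sim$devices[[lab]]
      if (!inherits(entry$device, "imaging_device")) next
      for (pn in names(entry$pops)) {
        st <- entry$pops[[pn]]
        if (nrow(st$rois) == 0) next
        counts <- integer(nrow(st$rois))
        spk <- spikes_this_step[[pn]]
        if (length(spk)) counts <- as.integer(st$rois$neuron %in% spk)
        st$ca <- ca_step(st$ca, counts, entry$device$indicator, dt)
        st$ca <- kernel_step(st$ca, entry$device$indicator, dt)
        if (k %% st$frame_every == 0) {
          vals <- dff(st$ca$cab_active, entry$device$indicator)
          noisy <- vapply(seq_len(nrow(st$rois)), function(r) {
            frame_readout(vals[r], st$rois$N[r], st$rois$rho_rel[r],
                          entry$device$indicator)
          }, numeric(1))
          st$frames[[length(st$frames) + 1]] <- c(time_ms = t_end, noisy)
        }
        sim$devices[[lab]]$pops[[pn]] <- st
      }
    }

    # sampling: measurement push and control reply into the buffer
    if (!is.null(io) && k %% sample_every == 0) {
      meas <- list(time_ms = t_end)
      for (lab in names(sim$devices)) {
        entry <- sim$devices[[lab]]
        if (!inherits(entry$device, "spike_probe")) next
        pn <- names(entry$pops)[1]
        st <- entry$pops[[pn]]
        ws <- window_spikes[[pn]]
        spikes <- if (length(ws)) {
          m <- do.call(rbind, ws)
          data.frame(time_ms = m[, 1], neuron = as.integer(m[, 2]))
        } else {
          data.frame(time_ms = numeric(0), neuron = integer(0))
        }
        det <- record_spikes(spikes, st$distances, entry$device$cfg,
                             duration_ms = io$sample_period_ms,
                             mode = entry$device$mode,
                             noise_events = entry$device$noise_events,
                             collisions = entry$device$collisions)
        st$sampled[[length(st$sampled) + 1]] <- det
        sim$devices[[lab]]$pops[[pn]] <- st
        meas[[lab]] <- det
      }
      for (pn in pop_names) window_spikes[[pn]] <- list()
      upd <- io$process(meas, t_end)
      if (!is.null(upd) && length(upd))
        buffer_put(io$buffer, upd, t_end, draw_delay(io$latency))
    }
  }

  for (pn in pop_names) {
    sim$spike_log[[pn]]$t <- c(sim$spike_log[[pn]]$t, spk_t[[pn]])
    sim$spike_log[[pn]]$i <- c(sim$spike_log[[pn]]$i, spk_i[[pn]])
  }
  sim$t <- t0 + n_steps * dt
  invisible(sim)
}
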