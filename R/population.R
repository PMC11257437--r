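#' Spatial point-neuron population
#'
#' A group of LIF or AdEx point neurons with 3D coordinates (um; z increases
#' with depth into tissue), cell-type labels, and membrane state. Integrator
#' constants use ms/mV conventions; the membrane resistance `R` converts
#' input current (model units) to voltage drive.
#'
#' LIF: `tau_m * dv/dt = -(v - v_rest) + R*I`; threshold crossing emits a
#' spike, resets `v` to `v_reset`, and clamps `v` there for the refractory
#' period. AdEx adds the exponential spike-initiation term and an adaptation
#' current `w`:
#' `tau_m * dv/dt = -(v - v_rest) + delta_T*exp((v - v_T)/delta_T) + R*(I - w)`,
#' `tau_w * dw/dt = a*(v - v_rest) - w`, with `w <- w + b` at each spike.
#'
#' @param coords n x 3 matrix of (x, y, z) in um.
#' @param cell_type Per-neuron label (`"excitatory"`, `"inhibitory"`, or
#'   other), recycled.
#' @param model `"lif"` or `"adex"`.
#' @param tau_m Membrane time constant (ms).
#' @param v_rest,v_thresh,v_reset Rest, spike threshold (cutoff), and reset
#'   potentials (mV or model units).
#' @param R Membrane resistance (voltage unit per current unit).
#' @param refractory_ms Absolute refractory period (ms).
#' @param delta_T,v_T,a,b,tau_w AdEx sharpness (mV), exponential threshold
#'   (mV), subthreshold adaptation coupling, spike-triggered adaptation
#'   increment, and adaptation time constant (ms).
#' @param bias Constant background current per neuron (model units),
#'   recycled.
#' @param noise_sd Standard deviation of white background current noise
#'   (model units * sqrt(ms)); per step the contribution is
#'   `noise_sd * rnorm(n) / sqrt(dt)`.
#' @param name Population label.
#' @return Object of class `neuron_population`.
#' @export
neuron_population <- function(coords, cell_type = "excitatory",
                              model = c("lif", "adex"),
                              tau_m = 20, v_rest = -70, v_thresh = -50,
                              v_reset = -70, R = 1, refractory_ms = 2,
                              delta_T = 2, v_T = -55, a = 0, b = 0,
                              tau_w = 100, bias = 0, noise_sd = 0,
                              name = "pop") {
  model <- match.arg(model)
  coords <- rbind_points(coords)
  n <- nrow(coords)
  cell_type <- rep_len(cell_type, n)
  stopifnot(tau_m > 0, refractory_ms >= 0, R != 0,
            v_thresh > v_reset)
  structure(
    list(ids = seq_len(n), coords = coords, cell_type = cell_type,
         model = model, name = name,
         params = list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                       v_reset = v_reset, R = R,
                       refractory_ms = refractory_ms, delta_T = delta_T,
                       v_T = v_T, a = a, b = b, tau_w = tau_w),
         bias = rep_len(bias, n), noise_sd = noise_sd,
         v = rep(v_rest, n), w = numeric(n), refr_left = numeric(n)),
    class = "neuron_population"
  )
}

#' @export
print.neuron_population <- function(x, ...) {
  cat(sprintf("<neuron_population '%s': %d %s neurons (%s)>\n", x$name,
              length(x$ids), x$model,
              paste(names(table(x$cell_type)), table(x$cell_type),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Advance a neuron population one step
#'
#' Exponential-Euler update of the leak/input dynamics for LIF (exact for
#' piecewise-constant input); forward Euler for the AdEx exponential and
#' adaptation terms. Neurons crossing `v_thresh` emit a spike, reset to
#' `v_reset`, and are clamped there for the refractory period (adaptation
#' keeps integrating).
#'
#' @param pop A [neuron_population()].
#' @param input_current Per-neuron input current (model units), scalar
#'   recycled; must be finite.
#' @param dt Step (ms), `> 0`.
#' @return List with `pop` (updated state) and `spikes` (indices of neurons
#'   that fired this step).
#' @export
step_neurons <- function(pop, input_current = 0, dt) {
  stopifnot(dt > 0)
  n <- length(pop$ids)
  input_current <- rep_len(input_current, n)
  if (!all(is.finite(input_current)))
    stop("non-finite input current for neuron ",
         which(!is.finite(input_current))[1])
  p <- pop$params
  v <- pop$v
  active <- pop$refr_left <= 0
  if (pop$model == "lif") {
    v_inf <- p$v_rest + p$R * input_current
    decay <- exp(-dt / p$tau_m)
    v[active] <- v_inf[active] + (v[active] - v_inf[active]) * decay
  } else {
    expo <- p$delta_T * exp(pmin((v - p$v_T) / p$delta_T, 20))
    dv <- (-(v - p$v_rest) + expo + p$R * (input_current - pop$w)) / p$tau_m
    v[active] <- v[active] + dt * dv[active]
    pop$w <- pop$w + dt * (p$a * (v - p$v_rest) - pop$w) / p$tau_w
  }
  if (!all(is.finite(v)))
    stop("non-finite membrane potential for neuron ",
         which(!is.finite(v))[1])
  spikes <- which(active & v >= p$v_thresh)
  if (length(spikes)) {
    v[spikes] <- p$v_reset
    pop$refr_left[spikes] <- p$refractory_ms
    if (pop$model == "adex") pop$w[spikes] <- pop$w[spikes] + p$b
  }
  refr <- pop$refr_left > 0
  pop$refr_left[refr] <- pop$refr_left[refr] - dt
  v[refr & !seq_len(n) %in% spikes] <- p$v_reset  # clamp during refractory
  pop$v <- v
  list(pop = pop, spikes = spikes)
}

#' Synapse group between two populations
#'
#' Connection list with weights in model current units, conduction delays,
#' and a receptor label (`"AMPA"`, `"GABA"`, or other). In the simulation
#' loop each presynaptic spike increments an exponentially decaying
#' postsynaptic current (`tau_syn_ms`) on the target after the delay
#' (snapped to the step grid, round-half-up).
#'
#' @param source,target Population names (as registered in a
#'   [simulation()]).
#' @param i_pre,j_post Presynaptic (source) and postsynaptic (target) neuron
#'   indices, equal length.
#' @param weight Per-connection weight (current units), recycled; negative
#'   for inhibition.
#' @param delay_ms Conduction delay, `>= 0`, recycled.
#' @param receptor Receptor label per connection, recycled. Required
#'   (AMPA/GABA) when a reference-weighted LFP proxy is attached.
#' @param tau_syn_ms Postsynaptic current decay constant (ms).
#' @return Object of class `synapse_group`.
#' @export
synapse_group <- function(source, target, i_pre, j_post, weight = 1,
                          delay_ms = 0, receptor = "AMPA", tau_syn_ms = 5) {
  stopifnot(length(i_pre) == length(j_post), all(i_pre >= 1),
            all(j_post >= 1), all(delay_ms >= 0), tau_syn_ms > 0)
  m <- length(i_pre)
  structure(
    list(source = source, target = target,
         i_pre = as.integer(i_pre), j_post = as.integer(j_post),
         weight = rep_len(weight, m), delay_ms = rep_len(delay_ms, m),
         receptor = rep_len(receptor, m), tau_syn_ms = tau_syn_ms),
    class = "synapse_group"
  )
}

# Sparse weight matrix (n_target x n_source) of a synapse group.
synapse_weight_matrix <- function(syn, n_source, n_target) {
  Matrix::sparseMatrix(i = syn$j_post, j = syn$i_pre, x = syn$weight,
                       dims = c(n_target, n_source))
}
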