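#' Fixed-schedule sample times
#'
#' Samples fall at `period, 2*period, ...` up to and including `duration`
#' (the first sample after one full period).
#'
#' @param period_ms Sampling period (ms), `> 0`.
#' @param duration_ms Total duration (ms).
#' @return Numeric vector of sample times (ms).
#' @export
schedule_samples <- function(period_ms, duration_ms) {
  stopifnot(period_ms > 0, duration_ms >= 0)
  n <- floor(duration_ms / period_ms + 1e-9)
  period_ms * seq_len(n)
}

#' Latency-aware delivery buffer
#'
#' Holds control messages together with the time they become deliverable,
#' modeling real-time compute latency: a sample processed at time t with
#' delay d is delivered at t + d (e.g., a sample at 20 ms with a 3 ms delay
#' delivers at 23 ms). In `"parallel"` mode each sample's delay is independent
#' of the others; in `"serial"` mode processing of a sample cannot begin until
#' the previous message has been delivered, so delivery times follow the
#' queueing recurrence `d_k = max(t_k, d_{k-1}) + delay_k`.
#'
#' @param mode `"parallel"` or `"serial"`.
#' @return An environment of class `delivery_buffer`.
#' @export
delivery_buffer <- function(mode = c("parallel", "serial")) {
  mode <- match.arg(mode)
  buf <- new.env(parent = emptyenv())
  buf$mode <- mode
  buf$messages <- list()
  buf$delivery_times <- numeric(0)
  buf$last_delivery <- -Inf
  class(buf) <- "delivery_buffer"
  buf
}

#' Put a control message into the delivery buffer
#'
#' @param buf A [delivery_buffer()].
#' @param msg Arbitrary payload (typically a named list of stimulator
#'   updates).
#' @param sample_t_ms Time the sample was taken (ms).
#' @param delay_ms Processing delay (ms), `>= 0`.
#' @return The delivery time (ms), invisibly.
#' @export
buffer_put <- function(buf, msg, sample_t_ms, delay_ms) {
  stopifnot(inherits(buf, "delivery_buffer"), delay_ms >= 0)
  delivery <- if (buf$mode == "serial") {
    max(sample_t_ms, buf$last_delivery) + delay_ms
  } else {
    sample_t_ms + delay_ms
  }
  if (buf$mode == "serial") buf$last_delivery <- delivery
  ord <- order(c(buf$delivery_times, delivery))
  buf$messages <- c(buf$messages,
                    list(list(computed_at = sample_t_ms,
                              delivery_time = delivery, payload = msg)))[ord]
  buf$delivery_times <- c(buf$delivery_times, delivery)[ord]
  invisible(delivery)
}

#' Pop all due messages from the delivery buffer
#'
#' Returns (and removes) every message with delivery time `<= now`
#' (inclusive at equality), ordered by delivery time.
#'
#' @param buf A [delivery_buffer()].
#' @param now_ms Current simulation time (ms).
#' @return List of messages, each with `computed_at`, `delivery_time`,
#'   `payload`; empty list if none due.
#' @export
buffer_pop <- function(buf, now_ms) {
  stopifnot(inherits(buf, "delivery_buffer"))
  due <- buf$delivery_times <= now_ms
  out <- buf$messages[due]
  buf$messages <- buf$messages[!due]
  buf$delivery_times <- buf$delivery_times[!due]
  out
}

#' Exponential firing-rate estimator update
#'
#' Discrete exponential smoothing of the instantaneous rate: with spike count
#' `c` over sample period `delta`,
#' `rate <- rate * exp(-delta/tau) + (c/delta) * (1 - exp(-delta/tau))`.
#' The fixed point under a constant input rate is that rate.
#'
#' @param rate_hz Current estimate (Hz).
#' @param count Spike count in the sample period.
#' @param delta_ms Sample period (ms), `> 0`.
#' @param tau_ms Filter time constant (ms), `> 0`; 1000 ms is a typical
#'   choice for firing-rate clamping.
#' @return Updated rate estimate (Hz).
#' @export
exp_rate_update <- function(rate_hz, count, delta_ms, tau_ms = 1000) {
  stopifnot(delta_ms > 0, tau_ms > 0)
  a <- exp(-delta_ms / tau_ms)
  inst_hz <- count / (delta_ms / 1000)
  rate_hz * a + inst_hz * (1 - a)
}

#' Proportional-integral controller
#'
#' Maps firing-rate error to a stimulation intensity (e.g., fiber-tip
#' irradiance in mW/mm^2). The integral accumulates `error * delta`;
#' anti-windup by conditional integration: while the output is saturated at a
#' bound, the integral is frozen.
#'
#' @param kp Proportional gain (mW/mm^2 per Hz).
#' @param ki Integral gain (mW/mm^2 per spike, i.e. per Hz*s).
#' @param bounds Output bounds, default `c(0, Inf)` since light intensity
#'   cannot be negative.
#' @return An environment of class `pi_controller` with fields `kp`, `ki`,
#'   `integral` (Hz*s), `bounds`.
#' @export
pi_controller <- function(kp = 0.005, ki = 0.003, bounds = c(0, Inf)) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  ctl <- new.env(parent = emptyenv())
  ctl$kp <- kp
  ctl$ki <- ki
  ctl$integral <- 0
  ctl$bounds <- bounds
  class(ctl) <- "pi_controller"
  ctl
}

#' PI controller update
#'
#' `e = target - measured`; `u = clamp(kp*e + ki*integral, bounds)`. The
#' integral (in Hz*s) only accumulates when the unclamped output is within
#' bounds or the error drives it back toward them.
#'
#' @param ctl A [pi_controller()].
#' @param target_hz Reference rate (Hz).
#' @param measured_hz Measured/estimated rate (Hz).
#' @param delta_ms Time since the previous update (ms), `> 0`.
#' @return Control value within bounds (same units as the gains' numerator).
#' @export
pi_update <- function(ctl, target_hz, measured_hz, delta_ms) {
  stopifnot(inherits(ctl, "pi_controller"), delta_ms > 0)
  e <- target_hz - measured_hz
  cand <- ctl$integral + e * delta_ms / 1000
  u_raw <- ctl$kp * e + ctl$ki * cand
  u <- min(max(u_raw, ctl$bounds[1]), ctl$bounds[2])
  saturated <- u_raw != u
  # conditional integration: freeze while saturated and pushing outward
  if (!saturated || sign(e) != sign(u_raw - u)) ctl$integral <- cand
  u
}

#' Latency model
#'
#' Per-sample processing delay: a constant, or a draw function called once
#' per sample (for probabilistic round-trip times).
#'
#' @param delay_ms Constant delay (ms) or a function `function()` returning
#'   one delay draw.
#' @param mode Processing mode, `"parallel"` (delays independent across
#'   samples) or `"serial"` (one sample at a time).
#' @return Object of class `latency_model`.
#' @export
latency_model <- function(delay_ms = 0, mode = c("parallel", "serial")) {
  mode <- match.arg(mode)
  if (!is.function(delay_ms)) stopifnot(delay_ms >= 0)
  structure(list(delay_ms = delay_ms, mode = mode), class = "latency_model")
}

draw_delay <- function(latency) {
  if (is.function(latency$delay_ms)) latency$delay_ms() else latency$delay_ms
}

#' I/O processor: sampling, processing callback, and latency
#'
#' The simulation pushes a measurement to the processor at each scheduled
#' sample time; `process(measurement, t_ms)` returns a named list of
#' stimulator updates (names matching stimulator labels in the simulation),
#' which is stored in the delivery buffer and applied to the stimulators at
#' the first step at or after `t + delay`.
#'
#' @param sample_period_ms Sampling period (ms); must be a multiple of the
#'   simulation step.
#' @param process Callback `function(measurement, t_ms)` returning a named
#'   list of stimulator updates (or NULL for no update).
#' @param latency A [latency_model()].
#' @return An environment of class `io_processor`.
#' @export
io_processor <- function(sample_period_ms, process,
                         latency = latency_model(0)) {
  stopifnot(sample_period_ms > 0, is.function(process))
  io <- new.env(parent = emptyenv())
  io$sample_period_ms <- sample_period_ms
  io$process <- process
  io$latency <- latency
  io$buffer <- delivery_buffer(latency$mode)
  class(io) <- "io_processor"
  io
}
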