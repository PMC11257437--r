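#' Two-photon microscope configuration
#'
#' Selects neurons with a soma cross-section in the imaging plane: a neuron at
#' axial offset `dz` from the focal plane is visible when `|dz| < soma radius`
#' and its soma center lies laterally within the square field of view. The
#' visible-pixel fraction is the normalized sphere cross-section area
#' `N = 1 - (dz/R_soma)^2`.
#'
#' @param center Field-of-view center `(x, y)` and focal-plane depth `z`
#'   (um; z increases with depth).
#' @param fov_width_um Width of the square field of view (um).
#' @param soma_radius_um Soma radius R_soma (um).
#' @param frame_period_ms Imaging frame period (ms); must be at least the
#'   simulation step when attached to a simulation.
#' @param snr_cutoff Minimum ROI SNR for inclusion (non-strict, `>=`).
#' @return Object of class `microscope`.
#' @export
microscope <- function(center = c(0, 0, 100), fov_width_um = 150,
                       soma_radius_um = 10, frame_period_ms = 33,
                       snr_cutoff = 1) {
  stopifnot(length(center) == 3, fov_width_um > 0, soma_radius_um > 0,
            frame_period_ms > 0, snr_cutoff >= 0)
  structure(list(center = as.numeric(center), fov_width_um = fov_width_um,
                 soma_radius_um = soma_radius_um,
                 frame_period_ms = frame_period_ms, snr_cutoff = snr_cutoff),
            class = "microscope")
}

#' Load packaged calcium-indicator parameters
#'
#' Biophysical calcium-handling constants plus indicator-specific response
#' parameters. The packaged sets (OGB-1, GCaMP6f, jGCaMP7) are approximate
#' transcriptions of published indicator simulation tables, intended as
#' realistic defaults; each field can be overridden.
#'
#' @param indicator `"GCaMP6f"`, `"jGCaMP7"`, or `"OGB-1"`.
#' @param ... Named overrides of any parameter column.
#' @return Object of class `indicator_params` with fields `Ca_rest_uM`
#'   (resting free calcium), `gamma_per_s` (clearance rate), `kappa_S`
#'   (endogenous binding ratio), `dCa_T_uM` (total calcium increase per
#'   spike), `B_total_uM` (total indicator concentration), `Kd_uM`
#'   (dissociation constant), `dFF_max`, `nH` (Hill coefficient), `dFF_1AP`
#'   (single-spike peak), `sigma_noise`, and convolution-kernel constants
#'   `tau_on_ms`, `tau_off_ms` (with `tau_off > tau_on`).
#' @export
indicator_params <- function(indicator = "GCaMP6f", ...) {
  tab <- read.csv(system.file("extdata", "indicator_params.csv",
                              package = "looplab"))
  row <- tab[tab$indicator == indicator, ]
  if (nrow(row) != 1)
    stop("no packaged parameters for indicator '", indicator, "'")
  p <- as.list(row)
  over <- list(...)
  stopifnot(all(names(over) %in% names(p)))
  p[names(over)] <- over
  stopifnot(p$Ca_rest_uM > 0, p$gamma_per_s > 0, p$kappa_S > 0,
            p$dCa_T_uM > 0, p$B_total_uM > 0, p$Kd_uM > 0,
            p$tau_off_ms > p$tau_on_ms, p$tau_on_ms > 0,
            p$sigma_noise >= 0, p$nH > 0)
  structure(p, class = "indicator_params")
}

# Indicator (exogenous buffer) binding ratio at free calcium ca (uM):
# kappa_B = B_T * Kd / (ca + Kd)^2, evaluated pointwise.
kappa_b <- function(ca, params) {
  params$B_total_uM * params$Kd_uM / (ca + params$Kd_uM)^2
}

#' Initialize calcium state for n neurons
#'
#' Free calcium starts at rest; the two linear states implementing the
#' response-kinetics convolution start at zero, so `CaBactive = Ca_rest`.
#'
#' @param n Number of neurons.
#' @param params An [indicator_params()].
#' @return Object of class `calcium_state` with fields `ca` (free calcium,
#'   uM), `x1`, `x2` (convolution states), `cab_active` (uM).
#' @export
calcium_state <- function(n, params) {
  structure(list(ca = rep(params$Ca_rest_uM, n), x1 = numeric(n),
                 x2 = numeric(n),
                 cab_active = rep(params$Ca_rest_uM, n)),
            class = "calcium_state")
}

#' Advance free-calcium dynamics one step
#'
#' Continuous clearance toward rest at instantaneous rate
#' `gamma / (1 + kappa_S + kappa_B)` (exponential-Euler update with
#' `kappa_B` evaluated at the current concentration), then per spike an
#' increment `dCa_T / (1 + kappa_S + kappa_B)` with `kappa_B` at the
#' pre-spike concentration. Negative concentrations (impossible under these
#' updates, but guarded) are clamped to 0.
#'
#' @param state A [calcium_state()].
#' @param spike_counts Spikes per neuron this step (integer vector, scalar
#'   recycled).
#' @param params An [indicator_params()].
#' @param dt Step (ms).
#' @return The updated state (only `ca` changes; see [kernel_step()]).
#' @export
ca_step <- function(state, spike_counts, params, dt) {
  stopifnot(dt > 0)
  n <- length(state$ca)
  spike_counts <- rep_len(spike_counts, n)
  kb <- kappa_b(state$ca, params)
  rate <- params$gamma_per_s / 1000 / (1 + params$kappa_S + kb)  # 1/ms
  rest <- params$Ca_rest_uM
  ca <- rest + (state$ca - rest) * exp(-rate * dt)
  spk <- spike_counts > 0
  if (any(spk)) {
    kb_pre <- kappa_b(ca[spk], params)
    ca[spk] <- ca[spk] + spike_counts[spk] * params$dCa_T_uM /
      (1 + params$kappa_S + kb_pre)
  }
  neg <- ca < 0
  if (any(neg)) {
    ca[neg] <- 0
    message("ca_step: negative calcium clamped to 0")
  }
  state$ca <- ca
  state
}

#' Advance the response-kinetics convolution one step
#'
#' The deviation `Ca - Ca_rest` is convolved with the double-exponential
#' kernel `h(t) = A * (1 - exp(-t/tau_on)) * exp(-t/tau_off)` by integrating
#' the equivalent two-state linear system (`h` is a difference of two
#' exponentials with time constants `tau_off` and
#' `tau_s = 1/(1/tau_on + 1/tau_off)`). `A` normalizes `h` to unit area so a
#' sustained deviation passes through unchanged. Returns the state with
#' updated `cab_active = Ca_rest + (Ca - Ca_rest) convolved with h`.
#'
#' @param state A [calcium_state()] (after [ca_step()]).
#' @param params An [indicator_params()].
#' @param dt Step (ms).
#' @return Updated state.
#' @export
kernel_step <- function(state, params, dt) {
  tau1 <- params$tau_off_ms
  tau_s <- 1 / (1 / params$tau_on_ms + 1 / params$tau_off_ms)
  A <- 1 / (tau1 - tau_s)  # unit-area normalization
  u <- state$ca - params$Ca_rest_uM
  e1 <- exp(-dt / tau1)
  e2 <- exp(-dt / tau_s)
  state$x1 <- state$x1 * e1 + u * tau1 * (1 - e1)
  state$x2 <- state$x2 * e2 + u * tau_s * (1 - e2)
  state$cab_active <- params$Ca_rest_uM + A * (state$x1 - state$x2)
  state
}

#' Fluorescence change from active indicator-bound calcium
#'
#' Hill-equation nonlinearity with the baseline subtracted so that
#' `dFF = 0` exactly when `cab_active = Ca_rest`:
#' \deqn{\Delta F/F_0 = \Delta F/F_{0,max}\left[
#'   \frac{1}{1 + (K_d/CaB_{active})^{n_H}} -
#'   \frac{1}{1 + (K_d/Ca_{rest})^{n_H}}\right]}
#'
#' @param cab_active Active concentration(s), uM, `>= 0`.
#' @param params An [indicator_params()].
#' @return Fractional fluorescence change, strictly increasing in
#'   `cab_active` and saturating at
#'   `dFF_max * (1 - 1/(1 + (Kd/Ca_rest)^nH))`.
#' @export
dff <- function(cab_active, params) {
  stopifnot(all(cab_active >= 0))
  hill <- function(x) 1 / (1 + (params$Kd_uM / x)^params$nH)
  base <- hill(params$Ca_rest_uM)
  val <- ifelse(cab_active == 0, 0, hill(cab_active))
  params$dFF_max * (val - base)
}

#' Select imaging ROIs from a population
#'
#' Candidates are neurons whose soma cross-sections the focal plane: axial
#' offset `|dz| < R_soma` and soma center laterally within the field of view.
#' Visible-pixel fraction `N = 1 - (dz/R_soma)^2`; per-ROI signal-to-noise is
#' `SNR = (dFF_1AP / sigma_noise) * rho_rel * N` and ROIs with
#' `SNR >= snr_cutoff` are retained.
#'
#' @param scope A [microscope()].
#' @param pop A [neuron_population()].
#' @param rho_rel Per-neuron indicator expression level (default 1).
#' @param params An [indicator_params()].
#' @return Data frame with columns `neuron`, `N`, `rho_rel`, `snr`.
#' @export
select_rois <- function(scope, pop, rho_rel = 1,
                        params = indicator_params()) {
  stopifnot(inherits(scope, "microscope"))
  coords <- pop$coords
  n <- nrow(coords)
  rho_rel <- rep_len(rho_rel, n)
  dz <- coords[, 3] - scope$center[3]
  half <- scope$fov_width_um / 2
  in_fov <- abs(coords[, 1] - scope$center[1]) <= half &
    abs(coords[, 2] - scope$center[2]) <= half
  vis <- abs(dz) < scope$soma_radius_um & in_fov
  N <- pmax(1 - (dz / scope$soma_radius_um)^2, 0)
  snr_ind <- params$dFF_1AP / params$sigma_noise
  snr_roi <- snr_ind * rho_rel * N
  keep <- vis & snr_roi >= scope$snr_cutoff
  out <- data.frame(neuron = which(keep), N = N[keep],
                    rho_rel = rho_rel[keep], snr = snr_roi[keep])
  rownames(out) <- NULL
  out
}

#' Noisy frame readout of an ROI
#'
#' One sample per frame: `rho_rel * dFF + Normal(0, (sigma_noise / N)^2)` —
#' signal scales with expression, and noise grows as the visible cross
#' section shrinks. Uses R's global RNG.
#'
#' @param dff_value Noise-free dFF value(s) for the frame(s).
#' @param N Visible-pixel fraction of the ROI.
#' @param rho_rel Expression level of the ROI.
#' @param params An [indicator_params()].
#' @return Noisy sample(s).
#' @export
frame_readout <- function(dff_value, N, rho_rel = 1,
                          params = indicator_params()) {
  stopifnot(N > 0)
  rho_rel * dff_value + rnorm(length(dff_value), 0, params$sigma_noise / N)
}

#' Simulate a single neuron's fluorescence response to a spike train
#'
#' Convenience wrapper running [ca_step()], [kernel_step()], and [dff()] on a
#' regular grid, without readout noise.
#'
#' @param spike_times Spike times (ms).
#' @param duration_ms Total duration (ms).
#' @param dt Step (ms).
#' @param params An [indicator_params()].
#' @return Data frame with `time_ms`, `ca_uM`, `cab_active_uM`, `dff`.
#' @export
simulate_calcium <- function(spike_times, duration_ms, dt = 1,
                             params = indicator_params()) {
  t_grid <- seq(dt, duration_ms, by = dt)
  # count spikes falling in (t - dt, t]
  counts <- vapply(seq_along(t_grid), function(i) {
    sum(spike_times > t_grid[i] - dt & spike_times <= t_grid[i])
  }, integer(1))
  st <- calcium_state(1, params)
  out <- data.frame(time_ms = t_grid, ca_uM = NA_real_,
                    cab_active_uM = NA_real_, dff = NA_real_)
  for (i in seq_along(t_grid)) {
    st <- ca_step(st, counts[i], params, dt)
    st <- kernel_step(st, params, dt)
    out$ca_uM[i] <- st$ca
    out$cab_active_uM[i] <- st$cab_active
    out$dff[i] <- dff(st$cab_active, params)
  }
  out
}

#' Export an ROI manifest to CSV
#'
#' Columns `roi_id`, `neuron_id`, `N`, `rho_rel`, `snr`.
#'
#' @param rois Output of [select_rois()].
#' @param path File path.
#' @export
write_roi_manifest_csv <- function(rois, path) {
  out <- data.frame(roi_id = seq_len(nrow(rois)), neuron_id = rois$neuron,
                    N = rois$N, rho_rel = rois$rho_rel, snr = rois$snr)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
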