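#' Per-spike kernel LFP proxy parameters (TKLFP)
#'
#' The kernel proxy approximates each spike's contribution to the LFP as a
#' delayed Gaussian whose peak amplitude and delay depend on the neuron's
#' position relative to the electrode and on its cell type. Peak amplitudes
#' `A0(depth)` come from cubic interpolation of a tabulated depth profile
#' (packaged in `extdata/tklfp_profile.csv`, an approximate transcription of
#' reference uLFP measurements) and are forced to exactly 0 at 600 um below
#' and 1000 um above the soma; laterally the amplitude decays exponentially.
#' The spike-to-peak delay has a base term plus a lateral-distance term set by
#' a horizontal propagation velocity.
#'
#' Depth convention: `depth_rel_soma > 0` means the electrode is above
#' (superficial to) the soma; z itself increases with depth into tissue.
#'
#' @param sigma_t_ms Temporal Gaussian width (ms); shared by both cell types.
#' @param delay0_ms Base spike-to-peak delay (ms).
#' @param velocity_um_ms Horizontal propagation velocity (um/ms; 200 um/ms =
#'   0.2 m/s).
#' @param lateral_lambda_um Exponential lateral space constant (um).
#' @param profile Depth-profile table with columns `cell_type`,
#'   `depth_rel_soma_um`, `amplitude_uV`; defaults to the packaged table.
#' @return Object of class `tklfp_params`.
#' @export
tklfp_params <- function(sigma_t_ms = 2.1, delay0_ms = 10.4,
                         velocity_um_ms = 200, lateral_lambda_um = 200,
                         profile = NULL) {
  if (is.null(profile))
    profile <- read.csv(system.file("extdata", "tklfp_profile.csv",
                                    package = "looplab"))
  stopifnot(sigma_t_ms > 0, delay0_ms >= 0, velocity_um_ms > 0,
            lateral_lambda_um > 0,
            all(c("cell_type", "depth_rel_soma_um", "amplitude_uV") %in%
                  names(profile)))
  splines <- lapply(split(profile, profile$cell_type), function(p) {
    p <- p[order(p$depth_rel_soma_um), ]
    list(fun = splinefun(p$depth_rel_soma_um, p$amplitude_uV,
                         method = "natural"),
         lo = min(p$depth_rel_soma_um), hi = max(p$depth_rel_soma_um))
  })
  structure(list(sigma_t_ms = sigma_t_ms, delay0_ms = delay0_ms,
                 velocity_um_ms = velocity_um_ms,
                 lateral_lambda_um = lateral_lambda_um,
                 splines = splines),
            class = "tklfp_params")
}

#' Kernel LFP peak amplitude at a recording offset
#'
#' Cubic interpolation of the depth profile times exponential lateral
#' attenuation; exactly 0 outside the depth support (600 um below to 1000 um
#' above the soma).
#'
#' @param depth_rel_soma Electrode depth relative to the soma (um, positive
#'   above the soma).
#' @param lateral Lateral (horizontal) distance (um).
#' @param cell_type `"excitatory"` or `"inhibitory"` (recycled).
#' @param params A [tklfp_params()].
#' @return Peak amplitude (uV), vectorized.
#' @export
tklfp_amplitude <- function(depth_rel_soma, lateral = 0,
                            cell_type = "excitatory",
                            params = tklfp_params()) {
  n <- max(length(depth_rel_soma), length(lateral), length(cell_type))
  depth_rel_soma <- rep_len(depth_rel_soma, n)
  lateral <- rep_len(lateral, n)
  cell_type <- rep_len(cell_type, n)
  out <- numeric(n)
  for (ct in unique(cell_type)) {
    sp <- params$splines[[ct]]
    if (is.null(sp)) stop("no kernel profile for cell type '", ct, "'")
    i <- which(cell_type == ct)
    d <- depth_rel_soma[i]
    a <- ifelse(d < sp$lo | d > sp$hi, 0, sp$fun(d))
    out[i] <- a * exp(-abs(lateral[i]) / params$lateral_lambda_um)
  }
  out
}

#' Kernel LFP proxy signal from spikes
#'
#' Strict linear superposition of per-spike delayed Gaussians:
#' `sum A0 * exp(-(t - t_spike - d)^2 / (2*sigma_t^2))` with
#' `d = delay0 + lateral / velocity`.
#'
#' @param spikes Data frame with columns `time_ms` and `neuron`.
#' @param pop A [neuron_population()] supplying coordinates and cell types.
#' @param electrodes An [electrode_array()].
#' @param t_grid Uniform time grid (ms).
#' @param params A [tklfp_params()].
#' @return Matrix (length(t_grid) x contacts) of LFP (uV).
#' @export
tklfp_signal <- function(spikes, pop, electrodes, t_grid,
                         params = tklfp_params()) {
  stopifnot(inherits(electrodes, "electrode_array"))
  n_e <- nrow(electrodes$coords)
  out <- matrix(0, nrow = length(t_grid), ncol = n_e,
                dimnames = list(NULL, electrodes$ids))
  if (nrow(spikes) == 0) return(out)
  coords <- pop$coords
  for (e in seq_len(n_e)) {
    ec <- electrodes$coords[e, ]
    dz <- coords[spikes$neuron, 3] - ec[3]          # + if electrode above soma
    lat <- sqrt((coords[spikes$neuron, 1] - ec[1])^2 +
                  (coords[spikes$neuron, 2] - ec[2])^2)
    a0 <- tklfp_amplitude(dz, lat, pop$cell_type[spikes$neuron], params)
    delay <- params$delay0_ms + lat / params$velocity_um_ms
    live <- which(a0 != 0)
    for (s in live) {
      out[, e] <- out[, e] + a0[s] *
        exp(-(t_grid - spikes$time_ms[s] - delay[s])^2 /
              (2 * params$sigma_t_ms^2))
    }
  }
  out
}

#' Synthesize synaptic currents from a spike train
#'
#' Convolves spikes with a biexponential kernel
#' `(exp(-t/tau_d) - exp(-t/tau_r)) / norm` for `t >= 0`, 0 before, with the
#' kernel normalized to unit peak so synapse weights carry the amplitude. The
#' peak occurs at `t_peak = tau_r*tau_d/(tau_d - tau_r) * log(tau_d/tau_r)`.
#'
#' @param spike_times Spike times (ms).
#' @param t_grid Uniform time grid (ms).
#' @param tau_r,tau_d Rise and decay time constants (ms), `tau_d > tau_r > 0`.
#' @param weight Synaptic weight multiplying the unit-peak kernel.
#' @return Current trace on `t_grid`.
#' @export
synthesize_currents <- function(spike_times, t_grid, tau_r = 0.5, tau_d = 2,
                                weight = 1) {
  if (tau_r == tau_d)
    stop("tau_r == tau_d; use distinct time constants ",
         "(the alpha-function limit is not implemented)")
  stopifnot(tau_d > tau_r, tau_r > 0)
  t_peak <- tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)
  norm <- exp(-t_peak / tau_d) - exp(-t_peak / tau_r)
  out <- numeric(length(t_grid))
  for (ts in spike_times) {
    dt <- t_grid - ts
    on <- dt >= 0
    out[on] <- out[on] +
      weight * (exp(-dt[on] / tau_d) - exp(-dt[on] / tau_r)) / norm
  }
  out
}

#' Reference-weighted sum of synaptic currents LFP parameters (RWSLFP)
#'
#' Sums AMPA and GABA currents onto pyramidal cells, the GABA term with weight
#' `alpha = -1.65` and the AMPA term delayed by `tau_ampa` (6 ms), i.e.
#' `LFP(t) proportional to sum w * (AMPA(t - tau_ampa) - alpha * GABA(t))`.
#' The spatial weight over (axial, lateral) recording offsets is stored as a
#' scaled beta-distribution kernel fit at each tabulated lateral distance with
#' linear interpolation between them (packaged table is an approximate
#' transcription of the reference population profile; support ends at the
#' outermost tabulated radius and outside the axial range).
#'
#' Three amplitude variants are provided: `"population"` (the profile as
#' tabulated, appropriate when all pyramidal cells share one reference
#' position), `"per_neuron"` (the same shape rescaled so that contributions
#' summed over a 250 um-radius population cylinder approximate the population
#' profile), and `"closed_form"` (a scaled dipole-like per-neuron analytic
#' contribution).
#'
#' @param alpha GABA weight (default -1.65).
#' @param tau_ampa_ms AMPA delay (ms, default 6).
#' @param profile Profile table (see `extdata/rwslfp_profile.csv`).
#' @param n_cylinder Nominal pyramidal-cell count in the 250 um reference
#'   cylinder used to calibrate the per-neuron variants.
#' @return Object of class `rwslfp_params`.
#' @export
rwslfp_params <- function(alpha = -1.65, tau_ampa_ms = 6, profile = NULL,
                          n_cylinder = 1000) {
  if (is.null(profile))
    profile <- read.csv(system.file("extdata", "rwslfp_profile.csv",
                                    package = "looplab"))
  stopifnot(is.finite(alpha), is.finite(tau_ampa_ms),
            all(diff(profile$lateral_um) > 0))
  p <- structure(list(alpha = alpha, tau_ampa_ms = tau_ampa_ms,
                      profile = profile, n_cylinder = n_cylinder,
                      per_neuron_scale = NA_real_,
                      closed_form_scale = NA_real_),
                 class = "rwslfp_params")
  p$per_neuron_scale <- calibrate_rwslfp_scale(p, variant = "per_neuron")
  p$closed_form_scale <- calibrate_rwslfp_scale(p, variant = "closed_form")
  p
}

# Population profile: beta kernel over axial offset at each tabulated lateral
# distance, peak-normalized to the tabulated amplitude, linearly interpolated
# between lateral distances; 0 outside support.
rwslfp_population_weight <- function(axial, lateral, profile) {
  n <- max(length(axial), length(lateral))
  axial <- rep_len(axial, n)
  lateral <- rep_len(abs(lateral), n)
  radii <- profile$lateral_um
  kern <- function(ax, row) {
    x <- (ax - row$axial_lo_um) / (row$axial_hi_um - row$axial_lo_um)
    mode <- (row$shape1 - 1) / (row$shape1 + row$shape2 - 2)
    val <- ifelse(x <= 0 | x >= 1, 0,
                  dbeta(x, row$shape1, row$shape2) /
                    dbeta(mode, row$shape1, row$shape2))
    row$amplitude * val
  }
  vals <- vapply(seq_len(nrow(profile)),
                 function(i) kern(axial, profile[i, ]), numeric(n))
  vals <- matrix(vals, nrow = n)
  out <- numeric(n)
  inside <- lateral <= max(radii)
  for (i in which(inside)) {
    out[i] <- approx(radii, vals[i, ], xout = lateral[i])$y
  }
  out
}

# Dipole-like closed-form per-neuron contribution (unscaled):
# w = h / (h^2 + rho^2 + eps^2)^(3/2), h the axial offset of the electrode
# relative to the dipole midpoint (placed 200 um above the soma), eps a 50 um
# softening scale that bounds the self-contribution.
rwslfp_closed_form_raw <- function(axial, lateral) {
  h <- axial - 200
  eps <- 50
  h / (h^2 + lateral^2 + eps^2)^1.5
}

# Least-squares scale making per-neuron contributions, summed over a 250 um
# cylinder of n_cylinder cells, match the population profile on an evaluation
# grid. Deterministic sunflower layout for the cell positions.
calibrate_rwslfp_scale <- function(params, variant) {
  n <- params$n_cylinder
  k <- seq_len(n)
  rr <- 250 * sqrt((k - 0.5) / n)
  th <- k * pi * (3 - sqrt(5))
  cx <- rr * cos(th)
  cy <- rr * sin(th)
  ax_eval <- seq(-300, 700, by = 100)
  lat_eval <- c(0, 100, 200)
  target <- c()
  summed <- c()
  for (le in lat_eval) {
    for (ae in ax_eval) {
      target <- c(target,
                  rwslfp_population_weight(ae, le, params$profile))
      lat_n <- sqrt((cx - le)^2 + cy^2)
      contrib <- if (variant == "closed_form") {
        rwslfp_closed_form_raw(rep(ae, n), lat_n)
      } else {
        rwslfp_population_weight(rep(ae, n), lat_n, params$profile)
      }
      summed <- c(summed, sum(contrib))
    }
  }
  sum(summed * target) / sum(summed^2)
}

#' RWSLFP spatial weight at a recording offset
#'
#' @param axial Axial offset of the electrode relative to the pyramidal soma
#'   (um, positive above).
#' @param lateral Lateral distance (um).
#' @param params An [rwslfp_params()].
#' @param variant `"population"`, `"per_neuron"`, or `"closed_form"`.
#' @return Spatial weight (dimensionless), 0 outside the profile support.
#' @export
rwslfp_amplitude <- function(axial, lateral = 0, params = rwslfp_params(),
                             variant = c("population", "per_neuron",
                                         "closed_form")) {
  variant <- match.arg(variant)
  switch(variant,
    population = rwslfp_population_weight(axial, lateral, params$profile),
    per_neuron = params$per_neuron_scale *
      rwslfp_population_weight(axial, lateral, params$profile),
    closed_form = params$closed_form_scale *
      rwslfp_closed_form_raw(axial, rep_len(abs(lateral),
                                            max(length(axial),
                                                length(lateral)))))
}

#' RWSLFP proxy signal from per-neuron synaptic currents
#'
#' Per electrode: `sum_n w_n * (AMPA_n(t - tau_ampa) - alpha * GABA_n(t))`
#' with `alpha = -1.65` by default (so GABA adds with weight +1.65). The AMPA
#' delay is applied by shifting on the uniform grid (snapped to the nearest
#' step). The output is proportional (normalized units).
#'
#' @param ampa,gaba Matrices (time x neurons) of synaptic currents onto each
#'   pyramidal cell; see [synthesize_currents()].
#' @param pyr_coords Pyramidal soma coordinates (n x 3, um).
#' @param electrodes An [electrode_array()].
#' @param dt_ms Grid step of the current traces (ms).
#' @param params An [rwslfp_params()].
#' @param variant Spatial weight variant, see [rwslfp_amplitude()].
#' @return Matrix (time x contacts), normalized units.
#' @export
rwslfp_signal <- function(ampa, gaba, pyr_coords, electrodes, dt_ms,
                          params = rwslfp_params(),
                          variant = "population") {
  ampa <- as.matrix(ampa); gaba <- as.matrix(gaba)
  stopifnot(all(dim(ampa) == dim(gaba)), dt_ms > 0)
  pyr_coords <- rbind_points(pyr_coords)
  stopifnot(nrow(pyr_coords) == ncol(ampa))
  shift <- round(params$tau_ampa_ms / dt_ms)
  nt <- nrow(ampa)
  ampa_del <- rbind(matrix(0, nrow = min(shift, nt), ncol = ncol(ampa)),
                    ampa[seq_len(max(nt - shift, 0)), , drop = FALSE])
  n_e <- nrow(electrodes$coords)
  out <- matrix(0, nrow = nt, ncol = n_e,
                dimnames = list(NULL, electrodes$ids))
  for (e in seq_len(n_e)) {
    ec <- electrodes$coords[e, ]
    axial <- pyr_coords[, 3] - ec[3]   # + if electrode above soma
    lateral <- sqrt((pyr_coords[, 1] - ec[1])^2 + (pyr_coords[, 2] - ec[2])^2)
    w <- rwslfp_amplitude(axial, lateral, params, variant)
    out[, e] <- (ampa_del - params$alpha * gaba) %*% w
  }
  out
}

#' Export LFP (or any multichannel) traces to CSV
#'
#' Columns: `time_ms` plus one column per channel/ROI.
#'
#' @param t_grid Time grid (ms).
#' @param traces Matrix (time x channels).
#' @param path File path.
#' @export
write_traces_csv <- function(t_grid, traces, path) {
  traces <- as.matrix(traces)
  stopifnot(length(t_grid) == nrow(traces))
  cn <- colnames(traces)
  if (is.null(cn)) cn <- paste0("ch", seq_len(ncol(traces)))
  out <- data.frame(time_ms = t_grid, traces)
  names(out) <- c("time_ms", cn)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
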