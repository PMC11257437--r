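#' Extracellular electrode array
#'
#' @param coords Contact coordinates (um): matrix with columns x, y, z or a
#'   length-3 vector for a single contact.
#' @param ids Contact ids (default 1..c).
#' @return Object of class `electrode_array`.
#' @export
electrode_array <- function(coords, ids = NULL) {
  coords <- rbind_points(coords)
  if (is.null(ids)) ids <- seq_len(nrow(coords))
  stopifnot(length(ids) == nrow(coords), !anyDuplicated(ids))
  structure(list(coords = coords, ids = ids), class = "electrode_array")
}

#' Linear electrode probe
#'
#' Convenience constructor for an n-channel linear array (e.g., a 32-channel
#' laminar probe) along a given direction.
#'
#' @param start Coordinate of the first contact (um).
#' @param direction Direction along the shank; normalized internally.
#' @param n_contacts Number of contacts.
#' @param pitch_um Contact spacing (um).
#' @return An [electrode_array()].
#' @export
linear_probe <- function(start = c(0, 0, 0), direction = c(0, 0, 1),
                         n_contacts = 32, pitch_um = 25) {
  direction <- as.numeric(direction) / sqrt(sum(direction^2))
  offs <- (seq_len(n_contacts) - 1) * pitch_um
  electrode_array(t(vapply(offs, function(d) start + d * direction,
                           numeric(3))))
}

#' Probabilistic spike-detector configuration
#'
#' Point-neuron spike detection without extracellular waveforms: the expected
#' spike amplitude on a channel, in units of the background-noise standard
#' deviation (sigma_b), decays with distance as `(r_noise_floor / r)^p`, so
#' `r_noise_floor` is the distance at which SNR = 1. Measured amplitudes vary
#' stochastically (background noise plus proportional intrinsic amplitude
#' variability `cv`); measurements above the threshold `theta` are candidate
#' events, which are then thinned by collision sampling. Pure-noise threshold
#' crossings arrive as a Poisson stream at the effective sampling rate times
#' the Gaussian upper-tail probability of the threshold.
#'
#' @param r_noise_floor Distance at which SNR = 1 (um, default 80).
#' @param threshold Detection threshold theta (sigma_b units, default 4).
#' @param sort_threshold SNR needed for a unit to be sortable (default 6).
#' @param decay_exponent Amplitude decay exponent p (default 2, i.e. 1/r^2).
#' @param cv Coefficient of variation of intrinsic spike amplitude
#'   (default 0.05).
#' @param collision_window_ms Window tau_c within which same-channel events
#'   can mask each other (ms, default 1).
#' @param sample_rate_khz Effective event-sampling rate for noise events
#'   (kHz, default 30).
#' @param r_min Minimum distance events are clipped to (um, default 1),
#'   guarding against coincident neuron/contact positions.
#' @return Object of class `spike_detector_config`.
#' @export
spike_detector_config <- function(r_noise_floor = 80, threshold = 4,
                                  sort_threshold = 6, decay_exponent = 2,
                                  cv = 0.05, collision_window_ms = 1,
                                  sample_rate_khz = 30, r_min = 1) {
  stopifnot(r_noise_floor > 0, threshold > 0,
            sort_threshold >= threshold, decay_exponent > 0, cv >= 0,
            collision_window_ms >= 0, sample_rate_khz > 0, r_min > 0)
  structure(list(r_noise_floor = r_noise_floor, threshold = threshold,
                 sort_threshold = sort_threshold,
                 decay_exponent = decay_exponent, cv = cv,
                 collision_window_ms = collision_window_ms,
                 sample_rate_khz = sample_rate_khz, r_min = r_min),
            class = "spike_detector_config")
}

#' Distance-dependent spike signal-to-noise ratio
#'
#' `SNR(r) = (r_noise_floor / r)^p`; equals 1 at `r = r_noise_floor` and is
#' also the expected measured amplitude in sigma_b units. Distances below
#' `r_min` are clipped.
#'
#' @param r Electrode-neuron distances (um).
#' @param cfg A [spike_detector_config()].
#' @return SNR (dimensionless), same shape as `r`.
#' @export
snr <- function(r, cfg = spike_detector_config()) {
  r <- pmax(r, cfg$r_min)
  (cfg$r_noise_floor / r)^cfg$decay_exponent
}

#' Stochastic threshold crossings from ground-truth spikes
#'
#' Each true spike is measured on each channel with amplitude
#' `Normal(a(r), sigma_tot^2)` where `a(r) = SNR(r)` and
#' `sigma_tot = sqrt(1 + (cv*a)^2)` combines unit background noise with
#' proportional intrinsic variability in quadrature; measurements above the
#' threshold become candidate events. Independently, each channel receives
#' pure-noise candidates as a Poisson stream with rate
#' `f_s * Q(theta)` (Q the standard normal upper tail) and amplitudes drawn
#' from the Normal(0, 1) tail above the threshold. Uses R's global RNG.
#'
#' @param spikes Data frame of ground-truth spikes with columns `time_ms` and
#'   `neuron` (index into the columns of `distances`).
#' @param distances c x n matrix of channel-to-neuron distances (um).
#' @param cfg A [spike_detector_config()].
#' @param duration_ms Recording duration, needed for noise events; `NULL`
#'   (the span of the spike times) or a scalar.
#' @param noise_events If FALSE, suppress the pure-noise stream.
#' @return Data frame of candidate events: `time_ms`, `channel`, `neuron`
#'   (NA for noise events), `amplitude` (sigma_b units, all > threshold),
#'   sorted by channel then time.
#' @export
detect_crossings <- function(spikes, distances, cfg = spike_detector_config(),
                             duration_ms = NULL, noise_events = TRUE) {
  stopifnot(is.matrix(distances))
  n_chan <- nrow(distances)
  n_spk <- nrow(spikes)
  out <- list()
  if (n_spk > 0) {
    a <- snr(distances[, spikes$neuron, drop = FALSE], cfg)  # c x n_spk
    sigma_tot <- sqrt(1 + (cfg$cv * a)^2)
    amp <- matrix(rnorm(n_chan * n_spk, mean = a, sd = sigma_tot),
                  nrow = n_chan)
    keep <- amp > cfg$threshold
    if (any(keep)) {
      idx <- which(keep, arr.ind = TRUE)
      out$true <- data.frame(time_ms = spikes$time_ms[idx[, 2]],
                             channel = idx[, 1],
                             neuron = spikes$neuron[idx[, 2]],
                             amplitude = amp[keep])
    }
  }
  if (noise_events) {
    if (is.null(duration_ms))
      duration_ms <- if (n_spk > 0) max(spikes$time_ms) else 0
    p_tail <- pnorm(cfg$threshold, lower.tail = FALSE)
    rate_per_ms <- cfg$sample_rate_khz * p_tail  # kHz * prob = events/ms
    n_noise <- rpois(n_chan, rate_per_ms * duration_ms)
    tot <- sum(n_noise)
    if (tot > 0) {
      # amplitude ~ N(0,1) conditioned on exceeding the threshold
      u <- runif(tot)
      out$noise <- data.frame(
        time_ms = runif(tot, 0, duration_ms),
        channel = rep(seq_len(n_chan), n_noise),
        neuron = NA_integer_,
        amplitude = qnorm(1 - u * p_tail))
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(time_ms = numeric(0), channel = integer(0),
               neuron = integer(0), amplitude = numeric(0))
  ev <- ev[order(ev$channel, ev$time_ms), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Collision sampling of closely timed events
#'
#' Sweeping each channel's events in time order, whenever two events fall
#' within the collision window `tau_c` the smaller-amplitude one is removed
#' with probability `1 - |dt| / tau_c` (certain masking at identical times,
#' none at or beyond the window). Never increases the event count; with
#' `tau_c = 0` the input is returned unchanged.
#'
#' @param events Candidate events as returned by [detect_crossings()].
#' @param cfg A [spike_detector_config()].
#' @return The surviving subset of `events`.
#' @export
sample_collisions <- function(events, cfg = spike_detector_config()) {
  tau <- cfg$collision_window_ms
  if (tau <= 0 || nrow(events) < 2) return(events)
  keep <- rep(TRUE, nrow(events))
  for (ch in unique(events$channel)) {
    idx <- which(events$channel == ch)
    idx <- idx[order(events$time_ms[idx])]
    last <- 0L  # index (into events) of previous surviving event
    for (i in idx) {
      if (last == 0L) { last <- i; next }
      dt <- events$time_ms[i] - events$time_ms[last]
      if (dt < tau && runif(1) < 1 - dt / tau) {
        # remove the smaller-amplitude member of the pair
        if (events$amplitude[i] < events$amplitude[last]) {
          keep[i] <- FALSE
        } else {
          keep[last] <- FALSE
          last <- i
        }
      } else {
        last <- i
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit detected spikes as MUA or sorted output
#'
#' Multi-unit activity (`"mua"`) reports every surviving event with its
#' channel id, noise events included, with no unit identity. Sorted output
#' (`"sorted"`) reports only events from neurons whose best-channel SNR meets
#' the sortable-unit threshold, labeled by ground-truth unit id and
#' deduplicated across channels (one row per unit and spike time); noise
#' events are excluded.
#'
#' @param events Surviving events (after [sample_collisions()]).
#' @param distances c x n channel-to-neuron distance matrix (um), required for
#'   sorted output.
#' @param cfg A [spike_detector_config()].
#' @param mode `"mua"` or `"sorted"`.
#' @return Data frame with `time_ms`, `channel`, `amplitude`, and `unit`
#'   (NA in MUA mode).
#' @export
emit_spikes <- function(events, distances = NULL,
                        cfg = spike_detector_config(),
                        mode = c("mua", "sorted")) {
  mode <- match.arg(mode)
  if (mode == "mua") {
    out <- data.frame(time_ms = events$time_ms, channel = events$channel,
                      amplitude = events$amplitude,
                      unit = rep(NA_integer_, nrow(events)))
    return(out[order(out$time_ms, out$channel), , drop = FALSE])
  }
  stopifnot(!is.null(distances))
  best_snr <- apply(snr(distances, cfg), 2, max)
  sortable <- which(best_snr >= cfg$sort_threshold)
  ev <- events[!is.na(events$neuron) & events$neuron %in% sortable, ,
               drop = FALSE]
  if (nrow(ev) == 0)
    return(data.frame(time_ms = numeric(0), channel = integer(0),
                      amplitude = numeric(0), unit = integer(0)))
  # deduplicate across channels: keep the largest-amplitude detection of each
  # (unit, spike time)
  key <- paste(ev$neuron, ev$time_ms)
  ev <- ev[order(key, -ev$amplitude), , drop = FALSE]
  ev <- ev[!duplicated(paste(ev$neuron, ev$time_ms)), , drop = FALSE]
  out <- data.frame(time_ms = ev$time_ms, channel = ev$channel,
                    amplitude = ev$amplitude, unit = ev$neuron)
  out <- out[order(out$time_ms, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full spike-recording pipeline
#'
#' Runs detection, collision sampling, and emission in sequence.
#'
#' @inheritParams detect_crossings
#' @inheritParams emit_spikes
#' @param collisions If FALSE, skip collision sampling.
#' @return As [emit_spikes()].
#' @export
record_spikes <- function(spikes, distances, cfg = spike_detector_config(),
                          duration_ms = NULL, mode = c("mua", "sorted"),
                          noise_events = TRUE, collisions = TRUE) {
  ev <- detect_crossings(spikes, distances, cfg, duration_ms, noise_events)
  if (collisions) ev <- sample_collisions(ev, cfg)
  emit_spikes(ev, distances, cfg, mode)
}

#' Export detected spikes to CSV
#'
#' Columns `time_ms`, `channel`, `unit`, `amplitude_sigma`.
#'
#' @param spikes Output of [emit_spikes()].
#' @param path File path.
#' @export
write_spikes_csv <- function(spikes, path) {
  out <- data.frame(time_ms = spikes$time_ms, channel = spikes$channel,
                    unit = spikes$unit, amplitude_sigma = spikes$amplitude)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
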