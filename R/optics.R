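#' Optic fiber light source
#'
#' Describes a fiber-coupled light source and the optical properties of the
#' surrounding tissue. Light spread is modeled by combining a Gaussian radial
#' beam profile within the divergence cone set by `NA_/n`, geometric (inverse
#' square-like) spreading, and Kubelka-Munk attenuation with distance, which
#' assumes an optically homogeneous medium with scatterers larger than the
#' wavelength.
#'
#' Default absorbance, scattering, and refraction values describe brain tissue
#' for 473 nm blue light and are stored (editable) in
#' `extdata/light_medium_params.csv`.
#'
#' @param tip Numeric length-3, fiber tip position (um).
#' @param direction Numeric length-3 axis pointing out of the fiber into the
#'   tissue; normalized internally. Default points down the z axis (deeper).
#' @param radius Fiber core radius R (um).
#' @param NA_ Numerical aperture (dimensionless); must satisfy `0 < NA_ < n`.
#' @param wavelength_nm Light wavelength (nm); used to match opsin action
#'   spectra.
#' @param K Absorbance coefficient (1/mm), `K >= 0`.
#' @param S Scattering coefficient (1/mm), `S > 0`.
#' @param n Tissue refractive index.
#' @param irr0 Commanded intensity: irradiance at the fiber tip (mW/mm^2).
#'
#' @return An object of class `optic_fiber`.
#' @seealso [fiber_transmittance()], [light_medium_params()]
#' @export
optic_fiber <- function(tip = c(0, 0, 0), direction = c(0, 0, 1),
                        radius = 100, NA_ = 0.37, wavelength_nm = 473,
                        K = NULL, S = NULL, n = NULL, irr0 = 0) {
  med <- light_medium_params(wavelength_nm)
  if (is.null(K)) K <- med$K
  if (is.null(S)) S <- med$S
  if (is.null(n)) n <- med$n
  stopifnot(length(tip) == 3, all(is.finite(tip)),
            length(direction) == 3, sum(direction^2) > 0,
            radius > 0, NA_ > 0, NA_ < n, K >= 0, S > 0, irr0 >= 0)
  structure(
    list(tip = as.numeric(tip),
         direction = as.numeric(direction) / sqrt(sum(direction^2)),
         radius = radius, NA_ = NA_, wavelength_nm = wavelength_nm,
         K = K, S = S, n = n, irr0 = irr0),
    class = c("optic_fiber", "light_source")
  )
}

#' Default tissue optics parameters by wavelength
#'
#' Reads the packaged medium-parameter table (absorbance K, scattering S,
#' refractive index n per wavelength) and returns the row whose wavelength is
#' nearest the request. The table ships with a 473 nm entry; users may edit the
#' CSV or pass explicit values to [optic_fiber()].
#'
#' @param wavelength_nm Requested wavelength (nm).
#' @return A list with elements `K` (1/mm), `S` (1/mm), `n`.
#' @export
light_medium_params <- function(wavelength_nm = 473) {
  tab <- read.csv(system.file("extdata", "light_medium_params.csv",
                              package = "looplab"))
  i <- which.min(abs(tab$wavelength_nm - wavelength_nm))
  list(K = tab$K_per_mm[i], S = tab$S_per_mm[i], n = tab$n[i])
}

# Kubelka-Munk attenuation factor over path length x (mm).
# M(x) = b / (a*sinh(b*S*x) + b*cosh(b*S*x)), a = 1 + K/S, b = sqrt(a^2 - 1).
# As K -> 0, b -> 0 and M -> 1/(S*x + 1) (analytic limit, used when b is
# numerically tiny to avoid 0/0).
kubelka_munk <- function(x_mm, K, S) {
  a <- 1 + K / S
  b <- sqrt(a^2 - 1)
  if (b < 1e-7) return(1 / (S * x_mm + 1))
  b / (a * sinh(b * S * x_mm) + b * cosh(b * S * x_mm))
}

#' Fiber light transmittance at points in space
#'
#' Fraction `T` in `[0, 1]` of the fiber-tip irradiance reaching each point:
#' `T = G(r, z) * C(z) * M(dist)` where `G` is a Gaussian radial profile with
#' 1/e^2 half-width `R + z*tan(asin(NA_/n))`, `C = rho^2 / (rho + z)^2` the
#' geometric spreading factor with `rho = R*sqrt((n/NA_)^2 - 1)`, and `M` the
#' Kubelka-Munk attenuation over the Euclidean distance from the tip. Points
#' behind the fiber tip (negative axial coordinate) receive 0.
#'
#' @param fiber An [optic_fiber()].
#' @param points Numeric matrix with columns x, y, z (um), one row per point,
#'   or a length-3 vector for a single point.
#' @return Numeric vector of transmittance values in `[0, 1]`.
#' @export
fiber_transmittance <- function(fiber, points) {
  stopifnot(inherits(fiber, "optic_fiber"))
  points <- rbind_points(points)
  rel <- sweep(points, 2, fiber$tip)
  z <- as.numeric(rel %*% fiber$direction)          # axial distance, um
  r <- sqrt(pmax(rowSums(rel^2) - z^2, 0))          # radial distance, um
  theta_div <- asin(fiber$NA_ / fiber$n)
  w <- fiber$radius + z * tan(theta_div)            # beam half-width at z
  G <- exp(-2 * (r / w)^2)
  rho <- fiber$radius * sqrt((fiber$n / fiber$NA_)^2 - 1)
  C <- rho^2 / (rho + z)^2
  dist_mm <- sqrt(r^2 + z^2) / 1000
  M <- vapply(dist_mm, kubelka_munk, numeric(1), K = fiber$K, S = fiber$S)
  tr <- G * C * M
  tr[z < 0] <- 0
  pmin(pmax(tr, 0), 1)
}

#' Per-neuron irradiance from a fiber
#'
#' @param fiber An [optic_fiber()].
#' @param points Coordinates (um) as in [fiber_transmittance()].
#' @param irr0 Optional override of the fiber's commanded tip irradiance
#'   (mW/mm^2).
#' @return Irradiance at each point (mW/mm^2).
#' @export
fiber_irradiance <- function(fiber, points, irr0 = fiber$irr0) {
  irr0 * fiber_transmittance(fiber, points)
}

#' Load a packaged opsin action spectrum
#'
#' Action spectra are shipped as CSV files (`wavelength_nm`, `epsilon`) with
#' `epsilon = 1` at the opsin's peak wavelength. Values are transcriptions of
#' published normalized response curves at coarse wavelength resolution;
#' between tabulated wavelengths the package interpolates linearly.
#'
#' @param opsin Opsin name, e.g. `"ChR2"`, `"ChR2-H134R"`, `"Chrimson"`,
#'   `"Vf-Chrimson"`, `"GtACR2"`, `"eNpHR3.0"`.
#' @return A data.frame of class `action_spectrum` with columns
#'   `wavelength_nm` (strictly increasing) and `epsilon` in `[0, 1]`.
#' @export
action_spectrum <- function(opsin) {
  path <- system.file("extdata", "action_spectra.csv", package = "looplab")
  tab <- read.csv(path)
  tab <- tab[tab$opsin == opsin, c("wavelength_nm", "epsilon")]
  if (nrow(tab) == 0)
    stop("no packaged action spectrum for opsin '", opsin, "'")
  tab <- tab[order(tab$wavelength_nm), ]
  as_action_spectrum(tab$wavelength_nm, tab$epsilon)
}

#' Build an action spectrum from wavelength/sensitivity pairs
#'
#' @param wavelength_nm Strictly increasing wavelengths (nm).
#' @param epsilon Normalized sensitivities in `[0, 1]`, with maximum 1 at the
#'   peak wavelength.
#' @return A data.frame of class `action_spectrum`.
#' @export
as_action_spectrum <- function(wavelength_nm, epsilon) {
  stopifnot(length(wavelength_nm) == length(epsilon),
            !is.unsorted(wavelength_nm, strictly = TRUE),
            all(epsilon >= 0), all(epsilon <= 1))
  structure(data.frame(wavelength_nm = wavelength_nm, epsilon = epsilon),
            class = c("action_spectrum", "data.frame"))
}

#' Evaluate an action spectrum at arbitrary wavelengths
#'
#' Linear interpolation between tabulated wavelengths; wavelengths outside the
#' tabulated support return 0 with a warning (the opsin is treated as
#' insensitive there).
#'
#' @param spectrum An [action_spectrum()].
#' @param wavelength_nm Wavelengths to evaluate (nm).
#' @return Sensitivities `epsilon` in `[0, 1]`.
#' @export
epsilon_at <- function(spectrum, wavelength_nm) {
  stopifnot(inherits(spectrum, "action_spectrum"))
  out <- approx(spectrum$wavelength_nm, spectrum$epsilon,
                xout = wavelength_nm, rule = 1)$y
  if (anyNA(out)) {
    warning("wavelength outside action-spectrum support; using epsilon = 0")
    out[is.na(out)] <- 0
  }
  out
}

#' Effective irradiance across wavelengths
#'
#' Combines irradiance from multiple light sources into the single effective
#' irradiance an opsin responds to, `Irr_eff = sum eps(lambda) * Irr(lambda)`,
#' with `eps = 1` at the opsin's peak wavelength. The linear combination
#' embodies the simplifying assumption that the opsin's response to
#' photostimulation is linear in irradiance.
#'
#' @param irr_by_wavelength Named numeric vector (names = wavelength in nm) or
#'   list mapping wavelength to irradiance (mW/mm^2). Each irradiance may be a
#'   scalar or per-neuron vector.
#' @param spectrum An [action_spectrum()].
#' @return Effective irradiance (mW/mm^2), scalar or per-neuron.
#' @export
effective_irradiance <- function(irr_by_wavelength, spectrum) {
  if (!is.list(irr_by_wavelength))
    irr_by_wavelength <- as.list(irr_by_wavelength)
  stopifnot(length(irr_by_wavelength) > 0,
            !is.null(names(irr_by_wavelength)))
  lambdas <- as.numeric(names(irr_by_wavelength))
  eps <- epsilon_at(spectrum, lambdas)
  out <- 0
  for (i in seq_along(lambdas)) {
    irr <- irr_by_wavelength[[i]]
    stopifnot(all(irr >= 0))
    out <- out + eps[i] * irr
  }
  out
}

#' Two-photon laser target set
#'
#' Focal points of a scanned/holographic two-photon stimulation laser, each
#' with its own power. Off-target excitation follows a Gaussian ellipsoid
#' point spread function with `sigma_axial > sigma_lateral`; the optical axis
#' defaults to the z axis (light entering from above the tissue).
#'
#' @param targets Matrix (n x 3) of focal points (um) or length-3 vector.
#' @param power_mW Per-target laser power (mW), recycled to the number of
#'   targets.
#' @param sigma_lateral,sigma_axial Gaussian PSF widths (um),
#'   `sigma_axial > sigma_lateral > 0`.
#' @param wavelength_nm Laser wavelength (nm).
#' @param d_soma_um Soma diameter used to convert power to irradiance (um).
#' @param axis Optical axis direction (normalized internally).
#' @return Object of class `laser_targets`.
#' @export
laser_targets <- function(targets, power_mW = 0, sigma_lateral = 8,
                          sigma_axial = 24, wavelength_nm = 1060,
                          d_soma_um = 20, axis = c(0, 0, 1)) {
  targets <- rbind_points(targets)
  stopifnot(sigma_lateral > 0, sigma_axial > sigma_lateral,
            all(power_mW >= 0), d_soma_um > 0)
  structure(
    list(targets = targets,
         power_mW = rep_len(power_mW, nrow(targets)),
         sigma_lateral = sigma_lateral, sigma_axial = sigma_axial,
         wavelength_nm = wavelength_nm, d_soma_um = d_soma_um,
         axis = as.numeric(axis) / sqrt(sum(axis^2))),
    class = c("laser_targets", "light_source")
  )
}

#' Gaussian-ellipsoid PSF scale at a point
#'
#' `scale = exp(-d_lat^2 / (2*sigma_lateral^2) - d_ax^2 / (2*sigma_axial^2))`
#' relative to each laser target, where the axial component is taken along the
#' optical axis.
#'
#' @param lasers A [laser_targets()] object.
#' @param point Length-3 coordinate (um).
#' @return Numeric vector, one scale in `(0, 1]` per target.
#' @export
psf_scale <- function(lasers, point) {
  stopifnot(inherits(lasers, "laser_targets"), length(point) == 3)
  rel <- sweep(lasers$targets, 2, as.numeric(point), FUN = function(a, b) b - a)
  d_ax <- as.numeric(rel %*% lasers$axis)
  d_lat2 <- pmax(rowSums(rel^2) - d_ax^2, 0)
  exp(-d_lat2 / (2 * lasers$sigma_lateral^2) -
        d_ax^2 / (2 * lasers$sigma_axial^2))
}

#' Convert laser power to irradiance over a soma
#'
#' Divides power by the soma cross-sectional area: `Irr = P / (pi*(d/2)^2)`
#' with the diameter converted from um to mm, so 5 mW over a 20 um soma gives
#' about 1.59e4 mW/mm^2.
#'
#' @param power_mW Laser power (mW), `>= 0`.
#' @param d_soma_um Soma diameter (um), `> 0`.
#' @return Irradiance (mW/mm^2).
#' @export
power_to_irradiance <- function(power_mW, d_soma_um = 20) {
  if (any(d_soma_um <= 0)) stop("d_soma_um must be > 0")
  stopifnot(all(power_mW >= 0))
  d_mm <- d_soma_um / 1000
  power_mW / (pi * (d_mm / 2)^2)
}

#' Per-neuron irradiance from a two-photon laser target set
#'
#' Total irradiance at each point is the sum over targets of the PSF scale
#' times the target's power converted to irradiance over a soma.
#'
#' @param lasers A [laser_targets()] object.
#' @param points Coordinates (um), matrix or length-3 vector.
#' @param power_mW Optional per-target power override (mW).
#' @return Irradiance at each point (mW/mm^2).
#' @export
laser_irradiance <- function(lasers, points, power_mW = lasers$power_mW) {
  points <- rbind_points(points)
  power_mW <- rep_len(power_mW, nrow(lasers$targets))
  irr_per_target <- power_to_irradiance(power_mW, lasers$d_soma_um)
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    out[i] <- sum(psf_scale(lasers, points[i, ]) * irr_per_target)
  }
  out
}

# Coerce a length-3 vector or n x 3 matrix/data.frame to an n x 3 matrix.
rbind_points <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) {
    stopifnot(length(points) == 3)
    points <- matrix(points, nrow = 1)
  }
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  storage.mode(points) <- "double"
  points
}
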