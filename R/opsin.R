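#' Four-state Markov opsin parameters
#'
#' Kinetic scheme with two closed (C1, C2) and two open (O1, O2) states:
#' light drives C1 -> O1 (rate `Ga1`) and C2 -> O2 (`Ga2`), open states decay
#' in the dark (O1 -> C1 at `Gd1`, O2 -> C2 at `Gd2`), the open states
#' interconvert (O1 -> O2 at `Gf`, O2 -> O1 at `Gb`, both light-modulated),
#' and C2 recovers to the dark-adapted C1 at `Gr0`. Light enters through the
#' photon flux `phi` (photons/mm^2/s, converted from irradiance at the
#' configured wavelength):
#'
#' \deqn{Ga1 = k1 \phi^p / (\phi^p + \phi_m^p), \quad
#'       Ga2 = k2 \phi^p / (\phi^p + \phi_m^p)}
#' \deqn{Gf = Gf0 + kf \phi^q / (\phi^q + \phi_m^q), \quad
#'       Gb = Gb0 + kb \phi^q / (\phi^q + \phi_m^q)}
#'
#' The photocurrent is conductance-based, reproducing its dependence on
#' membrane potential including rectification:
#' `Iopto = rho_rel * g0 * (O1 + gamma*O2) * v1 * (1 - exp(-(v-E)/v0))`,
#' reported with depolarizing current positive (so it is positive for
#' `v < E`, zero at `v = E`).
#'
#' Packaged parameter sets (`opsin_markov_params()`) name six opsins; the
#' ChR2 entry follows the published four-state channelrhodopsin fit, and the
#' remaining entries are approximate transcriptions intended as realistic
#' starting points — users fitting quantitative experiments should register
#' their own values with this constructor.
#'
#' @param g0_nS Maximal conductance (nS).
#' @param gamma Conductance ratio of O2 relative to O1.
#' @param phim Half-saturation photon flux (photons/mm^2/s).
#' @param k1,k2 Maximal light-activation rates (1/ms).
#' @param p,q Hill exponents of the flux dependence.
#' @param Gf0,kf,Gb0,kb Inter-open-state base rates and light-scaling (1/ms).
#' @param Gd1,Gd2 Dark decay rates of O1, O2 (1/ms).
#' @param Gr0 C2 -> C1 recovery rate (1/ms).
#' @param E_mV Reversal potential (mV).
#' @param v0_mV,v1_mV Voltage-rectification parameters (mV).
#' @param wavelength_nm Peak wavelength used for irradiance-to-flux
#'   conversion (nm).
#' @param name Label for the parameter set.
#' @return Object of class `markov_opsin`.
#' @export
markov_opsin <- function(g0_nS, gamma, phim, k1, k2, p, q, Gf0, kf, Gb0, kb,
                         Gd1, Gd2, Gr0, E_mV, v0_mV, v1_mV,
                         wavelength_nm = 470, name = "custom") {
  rates <- c(k1 = k1, k2 = k2, Gf0 = Gf0, kf = kf, Gb0 = Gb0, kb = kb,
             Gd1 = Gd1, Gd2 = Gd2, Gr0 = Gr0)
  stopifnot(all(rates >= 0), g0_nS > 0, gamma >= 0, phim > 0,
            p > 0, q > 0, v0_mV != 0)
  structure(
    list(g0_nS = g0_nS, gamma = gamma, phim = phim, k1 = k1, k2 = k2,
         p = p, q = q, Gf0 = Gf0, kf = kf, Gb0 = Gb0, kb = kb,
         Gd1 = Gd1, Gd2 = Gd2, Gr0 = Gr0, E_mV = E_mV,
         v0_mV = v0_mV, v1_mV = v1_mV,
         wavelength_nm = wavelength_nm, name = name),
    class = "markov_opsin"
  )
}

#' Load a packaged four-state opsin parameter set
#'
#' @param opsin One of `"ChR2"`, `"ChR2-H134R"`, `"Chrimson"`,
#'   `"Vf-Chrimson"`, `"GtACR2"`, `"eNpHR3.0"`.
#' @param wavelength_nm Peak wavelength for flux conversion; defaults to the
#'   peak of the packaged action spectrum of the same opsin.
#' @return A [markov_opsin()] object.
#' @export
opsin_markov_params <- function(opsin, wavelength_nm = NULL) {
  tab <- read.csv(system.file("extdata", "markov_opsin_params.csv",
                              package = "looplab"))
  row <- tab[tab$opsin == opsin, ]
  if (nrow(row) != 1)
    stop("no packaged Markov parameter set for opsin '", opsin, "'")
  if (is.null(wavelength_nm)) {
    spec <- action_spectrum(opsin)
    wavelength_nm <- spec$wavelength_nm[which.max(spec$epsilon)]
  }
  markov_opsin(row$g0_nS, row$gamma, row$phim, row$k1, row$k2, row$p, row$q,
               row$Gf0, row$kf, row$Gb0, row$kb, row$Gd1, row$Gd2, row$Gr0,
               row$E_mV, row$v0_mV, row$v1_mV,
               wavelength_nm = wavelength_nm, name = opsin)
}

#' Dark-adapted Markov opsin state for n neurons
#'
#' All occupancy in C1. Rows are neurons, columns the states
#' (C1, O1, O2, C2); each row sums to 1 and is kept at 1 (to 1e-9) by
#' [markov_step()].
#'
#' @param n Number of neurons.
#' @return n x 4 occupancy matrix of class `markov_state`.
#' @export
markov_state <- function(n) {
  s <- matrix(0, nrow = n, ncol = 4,
              dimnames = list(NULL, c("C1", "O1", "O2", "C2")))
  s[, "C1"] <- 1
  structure(s, class = c("markov_state", "matrix"))
}

# Photon flux (photons/mm^2/s) from irradiance (mW/mm^2) at wavelength (nm).
irradiance_to_flux <- function(irr, wavelength_nm) {
  h <- 6.62607015e-34  # J s
  c_ <- 2.99792458e8   # m/s
  e_photon <- h * c_ / (wavelength_nm * 1e-9)
  irr * 1e-3 / e_photon
}

# Light-dependent transition rates (1/ms) at effective irradiance irr_eff.
markov_rates <- function(params, irr_eff) {
  phi <- irradiance_to_flux(irr_eff, params$wavelength_nm)
  hp <- phi^params$p / (phi^params$p + params$phim^params$p)
  hq <- phi^params$q / (phi^params$q + params$phim^params$q)
  hp[phi == 0] <- 0
  hq[phi == 0] <- 0
  list(Ga1 = params$k1 * hp, Ga2 = params$k2 * hp,
       Gf = params$Gf0 + params$kf * hq, Gb = params$Gb0 + params$kb * hq)
}

#' Validate an integration step against the fastest opsin rate
#'
#' Forward-Euler integration of the master equation requires
#' `dt * max_rate < 0.1`; the maximal rate is evaluated at the largest
#' irradiance the experiment will command.
#'
#' @param params A [markov_opsin()].
#' @param dt Step (ms).
#' @param max_irr Largest expected effective irradiance (mW/mm^2).
#' @return Invisibly TRUE, or an error naming the offending rate.
#' @export
markov_check_dt <- function(params, dt, max_irr = 100) {
  r <- markov_rates(params, max_irr)
  rates <- c(Ga1 = r$Ga1, Ga2 = r$Ga2, Gf = r$Gf, Gb = r$Gb,
             Gd1 = params$Gd1, Gd2 = params$Gd2, Gr0 = params$Gr0)
  worst <- which.max(rates)
  if (dt * rates[worst] >= 0.1)
    stop("dt = ", dt, " ms too large for opsin rate ", names(rates)[worst],
         " = ", signif(rates[worst], 3), " /ms; need dt*rate < 0.1")
  invisible(TRUE)
}

#' Advance a four-state opsin one step and report photocurrent
#'
#' Forward-Euler update of the four-state master equation, with per-row
#' occupancy conservation enforced (drift beyond 1e-9 is renormalized and
#' noted). Photocurrent per neuron:
#' `Iopto = rho_rel * g0 * (O1 + gamma*O2) * v1 * (1 - exp(-(v - E)/v0))`
#' (depolarizing positive, exactly 0 at `v = E`).
#'
#' @param state [markov_state()] occupancies (n x 4).
#' @param irr_eff Effective irradiance per neuron (mW/mm^2), scalar recycled.
#' @param v Membrane potential per neuron (mV).
#' @param params A [markov_opsin()].
#' @param dt Step (ms); see [markov_check_dt()].
#' @param rho_rel Relative expression per neuron (default 1).
#' @return List with `state` (advanced occupancies) and `i_opto` (per-neuron
#'   current, nS*mV).
#' @export
markov_step <- function(state, irr_eff, v, params, dt, rho_rel = 1) {
  n <- nrow(state)
  irr_eff <- rep_len(irr_eff, n)
  v <- rep_len(v, n)
  rho_rel <- rep_len(rho_rel, n)
  r <- markov_rates(params, irr_eff)
  C1 <- as.numeric(state[, 1L]); O1 <- as.numeric(state[, 2L])
  O2 <- as.numeric(state[, 3L]); C2 <- as.numeric(state[, 4L])
  dC1 <- -r$Ga1 * C1 + params$Gd1 * O1 + params$Gr0 * C2
  dO1 <- r$Ga1 * C1 - (params$Gd1 + r$Gf) * O1 + r$Gb * O2
  dO2 <- r$Gf * O1 - (params$Gd2 + r$Gb) * O2 + r$Ga2 * C2
  dC2 <- params$Gd2 * O2 - (r$Ga2 + params$Gr0) * C2
  new <- cbind(C1 = C1 + dt * dC1, O1 = O1 + dt * dO1,
               O2 = O2 + dt * dO2, C2 = C2 + dt * dC2)
  tot <- rowSums(new)
  if (any(abs(tot - 1) > 1e-9)) {
    new <- new / tot
    message("markov_step: occupancy drift renormalized")
  }
  i_opto <- markov_current(new, v, params, rho_rel)
  list(state = structure(new, class = c("markov_state", "matrix")),
       i_opto = i_opto)
}

#' Photocurrent from a Markov opsin state
#'
#' @inheritParams markov_step
#' @param state Occupancy matrix (n x 4).
#' @return Per-neuron photocurrent (depolarizing positive).
#' @export
markov_current <- function(state, v, params, rho_rel = 1) {
  drive <- params$v1_mV * (1 - exp(-(v - params$E_mV) / params$v0_mV))
  o1 <- as.numeric(state[, 2L])
  o2 <- as.numeric(state[, 3L])
  -rho_rel * params$g0_nS * (o1 + params$gamma * o2) * drive
}

#' Integrate a Markov opsin over an irradiance trace
#'
#' Tight-loop forward-Euler integration for a single neuron (or a common
#' state shared by identical neurons), used for long-horizon kinetics such as
#' light ramps. Occupancies are renormalized whenever drift exceeds 1e-9.
#'
#' @param params A [markov_opsin()].
#' @param irr_trace Effective irradiance at each step (mW/mm^2).
#' @param v Membrane potential (mV), scalar or per-step vector.
#' @param dt Step (ms).
#' @param state0 Length-4 initial occupancy (default dark-adapted).
#' @param rho_rel Relative expression level.
#' @param renormalize Renormalize occupancies when drift exceeds 1e-9
#'   (default); set FALSE to measure the integrator's raw conservation
#'   drift.
#' @return List with `i_opto` (photocurrent trace), `state` (final
#'   occupancies), and `conservation_err` (max |sum - 1| seen before any
#'   renormalization).
#' @export
markov_run <- function(params, irr_trace, v, dt, state0 = c(1, 0, 0, 0),
                       rho_rel = 1, renormalize = TRUE) {
  markov_check_dt(params, dt, max_irr = max(irr_trace))
  nt <- length(irr_trace)
  v <- rep_len(v, nt)
  r <- markov_rates(params, irr_trace)
  Ga1 <- r$Ga1; Ga2 <- r$Ga2; Gf <- r$Gf; Gb <- r$Gb
  Gd1 <- params$Gd1; Gd2 <- params$Gd2; Gr0 <- params$Gr0
  C1 <- state0[1]; O1 <- state0[2]; O2 <- state0[3]; C2 <- state0[4]
  drive <- params$v1_mV * (1 - exp(-(v - params$E_mV) / params$v0_mV))
  gain <- -rho_rel * params$g0_nS
  i_opto <- numeric(nt)
  cons_err <- 0
  for (k in seq_len(nt)) {
    nC1 <- C1 + dt * (-Ga1[k] * C1 + Gd1 * O1 + Gr0 * C2)
    nO1 <- O1 + dt * (Ga1[k] * C1 - (Gd1 + Gf[k]) * O1 + Gb[k] * O2)
    nO2 <- O2 + dt * (Gf[k] * O1 - (Gd2 + Gb[k]) * O2 + Ga2[k] * C2)
    nC2 <- C2 + dt * (Gd2 * O2 - (Ga2[k] + Gr0) * C2)
    tot <- nC1 + nO1 + nO2 + nC2
    err <- abs(tot - 1)
    if (err > cons_err) cons_err <- err
    if (renormalize && err > 1e-9) {
      nC1 <- nC1 / tot; nO1 <- nO1 / tot; nO2 <- nO2 / tot; nC2 <- nC2 / tot
    }
    C1 <- nC1; O1 <- nO1; O2 <- nO2; C2 <- nC2
    i_opto[k] <- gain * (O1 + params$gamma * O2) * drive[k]
  }
  list(i_opto = i_opto, state = c(C1 = C1, O1 = O1, O2 = O2, C2 = C2),
       conservation_err = cons_err)
}

#' Proportional ("simple") opsin model
#'
#' For network models whose membrane potentials are not in biophysical units,
#' the photocurrent is taken directly proportional to light intensity:
#' `Iopto = k * Irr * rho_rel`, where `k` is an arbitrary gain in
#' (current unit)*mm^2/mW that adapts the model to whatever current scale the
#' neurons use.
#'
#' @param k Gain; sign sets whether the opsin depolarizes (k > 0) or
#'   hyperpolarizes (k < 0).
#' @param name Label.
#' @return Object of class `simple_opsin`.
#' @export
simple_opsin <- function(k, name = "simple") {
  stopifnot(is.finite(k))
  structure(list(k = k, name = name), class = "simple_opsin")
}

#' Photocurrent of the proportional opsin model
#'
#' @param k Gain ((current unit)*mm^2/mW) or a [simple_opsin()].
#' @param irr_eff Effective irradiance (mW/mm^2), `>= 0`.
#' @param rho_rel Relative expression level, `>= 0` (0 for non-expressing
#'   cells).
#' @return `k * irr_eff * rho_rel`, elementwise.
#' @export
simple_current <- function(k, irr_eff, rho_rel = 1) {
  if (inherits(k, "simple_opsin")) k <- k$k
  stopifnot(all(irr_eff >= 0), all(rho_rel >= 0))
  k * irr_eff * rho_rel
}

#' Heterogeneous opsin/indicator expression model
#'
#' Cells express with probability `p_expr`; expressing cells receive a
#' relative expression level `rho_rel` that is either the constant 1 (the
#' standard model fit) or drawn from a lognormal distribution.
#'
#' @param p_expr Expression probability in `[0, 1]`.
#' @param distribution `"constant"` or `"lognormal"`.
#' @param meanlog,sdlog Lognormal parameters (log scale); defaults give a
#'   median of 1.
#' @return Object of class `expression_model`.
#' @export
expression_model <- function(p_expr = 1, distribution = c("constant",
                                                          "lognormal"),
                             meanlog = 0, sdlog = 0.5) {
  distribution <- match.arg(distribution)
  stopifnot(p_expr >= 0, p_expr <= 1, is.finite(meanlog), sdlog >= 0)
  structure(list(p_expr = p_expr, distribution = distribution,
                 meanlog = meanlog, sdlog = sdlog),
            class = "expression_model")
}

#' Sample per-cell expression levels
#'
#' Uses R's global random number stream (set a seed for reproducibility).
#' Non-expressing cells get `rho_rel = 0`.
#'
#' @param n Number of cells, `> 0`.
#' @param model An [expression_model()].
#' @return Numeric vector of `rho_rel >= 0`, length n.
#' @export
sample_expression <- function(n, model = expression_model()) {
  stopifnot(n > 0, inherits(model, "expression_model"))
  expresses <- runif(n) < model$p_expr
  rho <- numeric(n)
  k <- sum(expresses)
  if (k > 0) {
    rho[expresses] <- switch(model$distribution,
      constant = 1,
      lognormal = rlnorm(k, model$meanlog, model$sdlog))
  }
  rho
}
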