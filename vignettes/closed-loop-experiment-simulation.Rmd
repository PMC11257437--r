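---
title: "Simulating closed-loop electrophysiology and optophysiology experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating closed-loop electrophysiology and optophysiology experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looplab)
```

# What looplab models

Systems-neuroscience experiments increasingly combine optogenetic
stimulation, electrode recording, two-photon imaging, and real-time feedback
control. looplab wraps a spatial point-neuron network model with virtual
versions of this apparatus so that whole experiments — including the
imperfections of measurement, stimulation, and control latency — can be
prototyped in simulation. Every neuron carries (x, y, z) coordinates in
micrometers (z grows with depth into tissue); devices are "injected" into
populations, precompute their per-neuron geometry, and either perturb the
network (light sources plus opsins) or observe it (spike probes, LFP proxies,
a two-photon microscope). A simulated I/O processor samples measurements on a
fixed schedule and returns stimulator updates through a latency buffer,
closing the loop.

Units throughout: time ms, coordinates um, irradiance mW/mm^2, rates Hz.

# Neurons and the simulation loop

Populations integrate standard leaky integrate-and-fire (LIF) or adaptive
exponential (AdEx) dynamics. The leak/input part uses exponential-Euler
updates (exact for piecewise-constant input); the AdEx exponential and
adaptation terms use forward Euler. After a spike the membrane is clamped at
the reset potential for the refractory period. With `v_reset = v_rest`, the
LIF inter-spike interval under constant current has the closed form
`tau_m * log(I / (I - (v_thresh - v_rest)/R)) + t_ref`, which the test suite
verifies to within 1% at `dt = 0.01 * tau_m`.

Synapses are connection lists with weights in model current units, conduction
delays snapped to the step grid (round-half-up), and receptor labels
(AMPA/GABA — required when the synaptic-current LFP proxy is attached). Each
presynaptic spike increments an exponentially decaying postsynaptic current.

Sampling and delivery times are snapped to the simulation step grid; a
sampling period that is not a multiple of `dt` is rejected at configuration
time rather than rounded silently. A stimulator update whose delivery time is
t applies starting with the first step at or after t. This choice (rather
than end-of-step application) makes the worked latency example exact: a
sample taken at 20 ms with a 3 ms processing delay changes the light command
at 23 ms.

# Light propagation

Optic fibers use Kubelka-Munk propagation, valid for optically homogeneous
media with scatterers larger than the wavelength. Transmittance factors into
a Gaussian radial beam profile (1/e^2 half-width `R + z*tan(asin(NA/n))`), a
geometric spreading term `rho^2/(rho+z)^2` with
`rho = R*sqrt((n/NA)^2 - 1)`, and Kubelka-Munk attenuation
`M(x) = b/(a*sinh(b*S*x) + b*cosh(b*S*x))`, `a = 1 + K/S`,
`b = sqrt(a^2 - 1)`, over the Euclidean distance from the tip. When `K = 0`,
`M` is evaluated by its analytic limit `1/(S*x + 1)` instead of risking
0/0. Default medium constants for 473 nm light (`K = 0.125` /mm,
`S = 7.37` /mm, `n = 1.36`) ship as an editable CSV.

Two-photon stimulation is focal: per-target laser power is converted to
irradiance by dividing by the soma cross-section (20 um diameter by default;
5 mW is about 1.6e4 mW/mm^2), and off-target excitation follows a Gaussian
ellipsoid point spread function with `sigma_axial > sigma_lateral`.

Multi-wavelength crosstalk uses action spectra: an opsin driven by several
sources responds to the effective irradiance
`Irr_eff = sum eps(lambda) * Irr(lambda)` with `eps = 1` at its peak. This is
deliberately linear — the simplifying assumption that photocurrent responds
linearly to irradiance — and epsilon is linearly interpolated between
tabulated wavelengths, zero outside the tabulated support (with a warning).
The packaged spectra are coarse transcriptions of published normalized
response curves; quantitative work on a specific opsin should replace them
via `as_action_spectrum()`.

# Opsins

Two photocurrent models are provided. The four-state Markov scheme (closed
states C1, C2, open states O1, O2) reproduces rise, peak, plateau, and fall
kinetics and, because it defines a conductance, the photocurrent's dependence
on membrane potential including rectification:
`I = rho_rel * g0 * (O1 + gamma*O2) * v1 * (1 - exp(-(v - E)/v0))`
(reported with depolarizing current positive; exactly zero at `v = E`). Light
enters through photon flux with Hill-type saturation at `phi_m`. Integration
is forward Euler with a configuration-time validity check
(`dt * max_rate < 0.1`); occupancy conservation is monitored and drift beyond
1e-9 renormalized. The machinery treats parameter sets as opaque, so three-
or six-state schemes can reuse it. The packaged ChR2 entry follows the
published four-state fit; the other five named entries are approximate
placeholders to be replaced for quantitative work, and are documented as
such.

Because the Markov model needs biophysical membrane potentials, networks with
normalized units should use the proportional model `I = k * Irr * rho_rel`,
whose gain `k` is explicitly arbitrary and absorbs the unit conversion.
Heterogeneous expression is modeled by an expression probability and a
per-cell level `rho_rel` (constant 1 by default, optionally lognormal).

# Electrode recording

Spike detection is probabilistic and waveform-free, designed for point
neurons. Expected spike amplitude on a channel, in background-noise SD units,
is `a(r) = (r_noise_floor / r)^2` by default, so `r_noise_floor` (80 um) is
the distance where SNR = 1. Measured amplitudes are Gaussian around `a(r)`
with SD `sqrt(1 + (cv*a)^2)` — background noise plus proportional intrinsic
amplitude variability in quadrature (`cv = 0.05` by default; the reference
behavior constrains the spread qualitatively, not numerically). Crossings of
the threshold (4 SD) are candidates; pure-noise candidates arrive as a
Poisson stream at the effective sampling rate (30 kHz) times the Gaussian
upper-tail probability of the threshold, which at defaults is about 0.95
events per channel-second. Within the 1 ms collision window, the
smaller-amplitude of two close events is removed with probability
`1 - |dt|/tau_c` — a piecewise-linear stand-in for the masking curves, exact
at coincidence and vanishing at the window edge. Multi-unit output reports
every surviving event per channel; sorted output is idealized, reporting
ground-truth unit identities for neurons whose best-channel SNR reaches 6 SD,
deduplicated across channels.

# LFP proxies

Two proxies approximate cortical LFP without biophysical forward modeling.

The kernel proxy adds, per spike, a delayed Gaussian whose peak amplitude
depends on electrode depth relative to the soma (cubic interpolation of a
tabulated profile, forced to zero 600 um below and 1000 um above the soma)
and cell type, with exponential lateral attenuation; the delay is a base
10.4 ms plus lateral distance over a 0.2 m/s horizontal velocity, and the
temporal width is 2.1 ms for both cell types (the reference leaves the
inhibitory width unstated; we share it). The packaged depth profile is an
approximate transcription — the reference reports amplitudes at only four
depths — and is stored as editable CSV.

The reference-weighted proxy sums AMPA and GABA currents onto pyramidal
cells: `LFP(t) ~ sum w * (AMPA(t - 6 ms) - alpha*GABA(t))` with
`alpha = -1.65`, so GABA contributes with weight +1.65. Spatial weights are
scaled beta-distribution kernels over axial offset, fit per lateral distance
and interpolated linearly between radii. Because the reference profile was
measured by summing a 250 um-radius population, a per-neuron variant rescales
the profile (least squares against the population profile over a
deterministic sunflower layout of 1000 cells) so summed single-cell
contributions recover it; a scaled dipole-like closed form is also provided.
For spike-only network models, synaptic currents are synthesized by
convolving presynaptic spikes with a biexponential kernel normalized to unit
peak — normalization to peak (not area) keeps synaptic weights interpretable
as amplitudes, so `alpha` retains its meaning independent of kinetics.

The two proxies differ most visibly in bandwidth: the test suite verifies on
a bursty E/I fixture that the current-based proxy carries relatively more
power above 100 Hz than the spike-kernel proxy.

# Two-photon imaging

The microscope selects neurons whose soma intersects the focal plane inside
a square field of view. The visible fraction is the normalized sphere
cross-section `N = 1 - (dz/R_soma)^2` (a continuous idealization of relative
pixel counts), ROI SNR is `(dFF_1AP/sigma_noise) * rho_rel * N`, and ROIs at
or above the cutoff are kept (the inclusive inequality is our choice; the
boundary case is measure-zero).

Intracellular calcium follows buffered single-compartment dynamics:
clearance at rate `gamma/(1 + kappa_S + kappa_B)` toward rest, per-spike
increments `dCa_T/(1 + kappa_S + kappa_B)`, with the indicator binding ratio
`kappa_B = B_T*Kd/(Ca + Kd)^2` re-evaluated pointwise each step (the spike
increment uses the pre-spike concentration). Response kinetics not captured
by binding affinity are modeled by convolving the calcium deviation with
`h(t) = A*(1 - exp(-t/tau_on))*exp(-t/tau_off)`, implemented exactly as a
two-state linear system (h is a difference of exponentials with constants
`tau_off` and `1/(1/tau_on + 1/tau_off)`); `A` normalizes h to unit area so
a sustained deviation passes through unchanged. Fluorescence uses a Hill
nonlinearity with the baseline subtracted, so dFF is exactly zero at rest
and saturates at `dFF_max * (1 - 1/(1 + (Kd/Ca_rest)^nH))`. Frame readout
adds Gaussian noise with SD `sigma_noise/N`. Indicator tables (OGB-1,
GCaMP6f, jGCaMP7) are approximate transcriptions of published simulator
values; the GCaMP6f buffer concentration was set so the emergent single-spike
response is near the nominal `dFF_1AP` used for SNR. Per-neuron soma-size
variation is not supported.

# The I/O processor

Measurements are sampled at `period, 2*period, ...` (first sample after one
full period). Each processed sample enters a delivery buffer with its
delivery time; the simulation pops all messages with delivery time `<= now`
at each step (inclusive at equality). Parallel mode treats per-sample
processing as independent; serial mode starts a sample only after the
previous delivery, giving the queueing recurrence
`d_k = max(t_k, d_{k-1}) + delay_k`, which the tests verify exactly.
Firing-rate estimation uses discrete exponential smoothing,
`rate <- rate*exp(-dt/tau) + (count/dt)*(1 - exp(-dt/tau))` — the cited
controller descriptions differ in discretization detail, so ours is stated
and the constant exposed. The PI controller clamps its output to bounds
(light cannot be negative) with anti-windup by conditional integration:
without it, the nonnegativity clamp produces overshoot unrelated to the
models under study.

# Fixtures and the optoclamp demo

All test data are generated in code. `make_unconnected_box()` gives the
100-neuron 150 x 150 x 100 um population used for single-cell all-optical
experiments. `make_ei_disc()` builds the 800E/200I LIF network in a 2 mm
disc with the inhibitory weight multiplier set to `1.875 * g_balanced`, where
`g_balanced` equates total excitatory and inhibitory weight. Constants the
study conditions leave open were fixed once and recorded in the
documentation: 10% connectivity, unit weight 2 with R = 1, synaptic decay
5 ms (AMPA) / 8 ms (GABA), subthreshold bias 19 with noise SD 3 — chosen to
produce inhibition-gated network-wide bursting at a baseline of a few Hz.

`demo_optoclamp()` closes the loop: a 60-channel MEA records multi-unit
activity, an exponential filter (tau = 1 s) estimates rate, and a PI
controller (Kp = 0.005 mW/mm^2/Hz, Ki = 0.003 mW/mm^2/spikes) drives two
opposing whole-field light channels (465 nm exciting a depolarizing opsin,
590 nm a hyperpolarizing one) whose action spectra overlap, so each light
leaks into the other opsin. The proportional opsin model is used for both
channels because the fixture's LIF units carry non-biophysical current
units — exactly the situation that model exists for; its gains
(k = +/-50 current units mm^2/mW) were calibrated once so the
literature-scale controller gains settle the loop within the simulated
phases, mirroring how such stimulation strengths are titrated in practice. With a 2 s baseline
phase and 15 s clamp phases at `dt = 0.5` ms (sizes chosen to keep a
single-CPU run in a few minutes), the measured rate settles within 20% of
targets at 2x and 5x baseline, rising from below with the initial
overshoot/settling transient in the control signal.

```{r, eval = FALSE}
res <- demo_optoclamp(targets_rel = c(2, 5), seed = 1)
res$baseline_hz
res$steady_rate_hz / res$targets_hz
```

# Numerical choices and degenerate inputs

- Electrode-neuron distances are clipped below at 1 um so coincident
  placement cannot produce infinite SNR.
- `tau_r = tau_d` in biexponential synthesis is an error (the alpha-function
  limit is deliberately not silently substituted).
- Occupancy drift, negative calcium, and out-of-spectrum wavelengths are
  renormalized/clamped/zeroed with a message or warning rather than
  propagated.
- All stochastic stages draw from R's global RNG; a `simulation(seed = )`
  re-seeds at run start, making whole experiments bit-reproducible.

# What passing tests do and do not show

The fixtures emulate geometry, connectivity balance, bursting statistics,
and actuator/sensor physics at the level the models define — they do not
emulate adaptation, homeostasis, realistic synaptic kinetics, EAP waveforms,
imaging pixel noise structure, or brain motion. Quantities transcribed from
reference tables (action spectra, non-ChR2 opsin kinetics, LFP spatial
profiles, indicator constants) are approximate; tests verify the structural
properties of the models (fixed points, symmetries, linearity, conservation,
closed forms, scaling laws) and the end-to-end behavior of the loop, not
agreement with any specific biological dataset.
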