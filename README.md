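# looplab

Systems-neuroscience experiments now routinely mix optogenetics, electrode
recording, two-photon calcium imaging, and closed-loop control. Designing
such experiments by intuition alone is expensive and error-prone: device
geometry, opsin kinetics, detection noise, and control latency all interact.
looplab is an R package that injects virtual versions of this apparatus into
spatial point-neuron network models (neurons with x, y, z coordinates in
um), so a whole experiment — stimulation, measurement, and the real-time
processing loop — can be simulated and iterated on before touching a rig.
It is aimed at computational and experimental neuroscientists prototyping
experiment designs, control algorithms, or recording configurations on
mesoscale spiking models.

## Models at its core

- **Light**: optic-fiber propagation as
  `T(r, z) = G(r, z) · ρ²/(ρ+z)² · M(d)`, with a Gaussian radial profile
  `G`, geometric spreading (`ρ = R√((n/NA)² − 1)`), and Kubelka–Munk
  attenuation `M(x) = b/(a·sinh(bSx) + b·cosh(bSx))`, `a = 1 + K/S`,
  `b = √(a² − 1)`; two-photon targets as Gaussian ellipsoid PSFs
  (σ_axial > σ_lateral) with power converted to irradiance over the soma
  cross-section. Multi-wavelength crosstalk via action spectra:
  `Irr_eff = Σ ε(λ)·Irr(λ)`.
- **Opsins**: a four-state Markov scheme (C1, O1, O2, C2) with
  conductance-based, rectified photocurrent
  `I = ρ_rel·g0·(O1 + γO2)·v1·(1 − e^{−(v−E)/v0})`, and a proportional model
  `I = k·Irr·ρ_rel` for networks in normalized units; heterogeneous
  expression (Bernoulli × lognormal ρ_rel).
- **Spikes**: probabilistic, waveform-free detection with amplitude
  `a(r) = (r_floor/r)²` in noise-SD units (SNR = 1 at r_floor = 80 um),
  Gaussian measurement noise, Poisson noise events at the Gaussian tail
  rate, linear collision masking within 1 ms, and MUA or idealized sorted
  output (sortable above 6 SD).
- **LFP**: a per-spike delayed-Gaussian kernel proxy (depth profile zero
  600 um below / 1000 um above the soma) and a reference-weighted sum of
  synaptic currents, `LFP ∝ Σ w·(AMPA(t − 6 ms) + 1.65·GABA(t))`, with
  biexponential current synthesis from spikes.
- **Imaging**: soma cross-section ROI selection (`N = 1 − (Δz/R)²`),
  buffered calcium dynamics with per-spike increments, double-exponential
  response kinetics, Hill-equation ΔF/F0 (exactly 0 at rest), and Gaussian
  readout noise scaling as σ/N.
- **Control**: fixed-schedule sampling, a latency buffer (sample at 20 ms +
  3 ms delay → delivery at 23 ms; parallel or serial queueing), exponential
  rate estimation, and bounded PI control with anti-windup.

## Worked example

```r
library(looplab)

# light through tissue: 10 mW/mm2 commanded at the fiber tip
fib <- optic_fiber(tip = c(0, 0, 0), irr0 = 10)
fiber_irradiance(fib, rbind(c(0, 0, 100), c(0, 0, 400), c(0, 0, 800)))
#> [1] 3.451 0.512 0.105        # mW/mm2 at 100/400/800 um depth

# extracellular SNR under default detector settings
snr(c(40, 80, 160))
#> [1] 4.00 1.00 0.25           # SNR = 1 at the 80 um noise floor

# record a noisy population with an 8-contact probe for one second
sim <- simulation(dt = 0.1, seed = 1)
pop <- make_unconnected_box(100, seed = 1, bias = 19, noise_sd = 3)
add_population(sim, pop)
inject(sim, spike_probe(linear_probe(c(75, 75, 0), n_contacts = 8,
                                     pitch_um = 15), label = "probe"),
       "box")
run(sim, 1000)
nrow(get_spikes(sim, "box")); nrow(device_output(sim, "probe"))
#> [1] 252                      # ground-truth spikes
#> [1] 301                      # detected MUA events (multi-channel + noise)

# indicator response to a 3-spike burst
tr <- simulate_calcium(c(100, 110, 120), 800, params = indicator_params("GCaMP6f"))
max(tr$dff)
#> [1] 0.586                    # peak dF/F0
```

The detected-event count exceeds the ground-truth count because nearby
contacts each detect loud spikes (MUA carries no unit identity) and noise
crossings are included; `mode = "sorted"` deduplicates per unit instead.

The full closed-loop demonstration —
`demo_optoclamp(targets_rel = c(2, 5), seed = 1)` — records an 800E/200I
bursting disc network with a 60-channel MEA and clamps its multi-unit rate
at 2x and 5x baseline with a PI controller driving two spectrally
overlapping light channels. It runs in a few minutes on one CPU and settles
within 20% of both targets.

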