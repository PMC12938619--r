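---
title: "Harmonic-ratio tissue characterization: model, synthesis and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonic-ratio tissue characterization: model, synthesis and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsharmonics)
```

## The forward model

A superparamagnetic tracer ensemble in a spatially uniform sinusoidal drive
field $B(t) = A \sin(2\pi f_0 t)$ magnetizes, at thermodynamic equilibrium,
as

$$M(t) = m\,c\,L(\xi(t)), \qquad L(\xi)=\coth\xi - 1/\xi, \qquad
\xi(t) = \frac{m\,B(t)}{k_B T},$$

with per-particle moment $m$ (A m²), number concentration $c$ (m⁻³) and
temperature $T$. The field is parameterized directly as a flux density so
that the conventional "9 mT drive" is usable without converting through
$\mu_0 H$ — this removes a recurring unit ambiguity in the MPS literature.
Because $L$ is odd and saturating, $M(t)$ obeys
$M(t + 1/2f_0) = -M(t)$ and its spectrum contains only odd multiples of
$f_0$. The receive coil sees the Faraday voltage
$u(t) = -\mu_0\,p\,V\,g\,\mathrm{d}M/\mathrm{d}t$ (sensitivity $p$, sample
volume $V$, amplifier gain $g$), so a magnetization harmonic of amplitude
$a_k$ appears in the voltage with amplitude $\propto k\,2\pi f_0\,a_k$.

`langevin()` switches to the Taylor series
$\xi/3 - \xi^3/45 + 2\xi^5/945$ below $|\xi| < 10^{-4}$: the closed form
subtracts two numbers of order $1/\xi$ there and loses up to eight digits,
while at the switch point both branches still agree to ~$10^{-12}$
absolute.

For polydisperse tracers the package follows the standard log-normal
granulometry: core diameters $d$ with median $d_m$ and log-scale
$\sigma$, per-size moments $m(d) = M_s (\pi/6) d^3$, averaged by
Gauss–Legendre quadrature on the log-diameter axis over $\pm 4\sigma$
(32 nodes by default; weights renormalized to unit sum because the
$\pm4\sigma$ window truncates ~$6\times10^{-5}$ of the mass). The
monodisperse model is the default: it suffices for the harmonic-generation
mechanism, and no granulometry parameters are published for the reference
tracer, so the log-normal option is config-exposed rather than assumed.

## Brownian constraint as a Debye low-pass

The diagnostic mechanism is that a stiff or crowded microenvironment
hinders Brownian rotation of the whole hydrodynamic particle, which
suppresses the fast components of the response. The package models this as
first-order Debye relaxation applied per harmonic order:

$$a_k \;\mapsto\; \frac{a_k}{1 + i\,2\pi k f_0 \tau_B},$$

with one effective relaxation time $\tau_B$ per sample environment.
$\tau_B = 0$ is the unconstrained identity; for $\tau_B > 0$ the
attenuation grows with $k$, so the voltage-domain ratio

$$R(\tau_B) = R_0\,
\sqrt{\frac{1 + (2\pi\,5 f_0\,\tau_B)^2}{1 + (2\pi\,3 f_0\,\tau_B)^2}}$$

increases monotonically from the unconstrained $R_0$ toward $\tfrac53 R_0$.
Debye attenuation is deliberately the *minimal* model with the right
monotone low-pass signature; rigorous non-equilibrium dynamics would
require solving the rotational Fokker–Planck equation, which is out of
scope here, and the calibrated $\tau_B$ values are device-model parameters,
not biological viscosity measurements.

Synthesis therefore proceeds in the harmonic domain: Fourier sine
coefficients $a_k$ of one drive period are computed by FFT of an
oversampled period (8192 points; the response is analytic, so the
coefficients converge spectrally), Debye-attenuated, differentiated
analytically ($\sin \to k\omega\cos$ with the Debye phase lag), summed over
odd orders up to 99 (below Nyquist at 1 MS/s) or until coefficients fall
under $10^{-15}$ of the largest, and completed with the residual
fundamental feedthrough and seeded white Gaussian noise. Central
differences (second-order) are used by `induced_voltage()` only for
externally supplied magnetization series.

## Reference acquisition and defaults

| Parameter | Default | Why |
|---|---|---|
| Drive amplitude | 9 mT | reference spectrometer setting |
| Drive frequency $f_0$ | 5 kHz | reference spectrometer setting |
| Sampling rate | 1 MS/s | captures H5 at 25 kHz with large margin |
| Record length | 0.1 s | gives exactly $\Delta f = 10$ Hz bins |
| Repeats per sample | 10 | repeat-averaging protocol |
| Amplifier gain | 10 | receive-chain amplification |
| Temperature | 300.15 K | 27 °C incubation temperature |
| Particle moment $m$ | 3.3×10⁻¹⁸ A m² | see below |
| Concentration $c$ | 10¹⁹ m⁻³ | mV-scale harmonics; cancels in R |
| Feedthrough | 0.01 V | imperfect fundamental compensation |
| Noise level | auto (~40 dB H5 SNR) | see below |

With 10⁵ samples at 1 MS/s every harmonic of 5 kHz is an exact integer
multiple of the 10 Hz bin width, so single-bin extraction is exact and no
interpolation is ever needed.

**Particle moment.** The published tissue ratios span 1.806–2.744, and the
Debye mechanism can only raise the unconstrained ratio $R_0$ by at most
5/3. The default moment was chosen once so that $R_0 \approx 1.74$
($\xi_{\text{peak}} \approx 7.2$ at 9 mT): below the smallest tissue value
and with ceiling $\tfrac53 R_0 \approx 2.90$ above the largest, so *every*
reference group is reachable by calibrating $\tau_B \in [0, \infty)$. No
moment or saturation magnetization is published for the multi-core
reference tracer; the value is a config-exposed default, not a material
claim.

**Noise.** The instrument noise is additive white Gaussian on the voltage.
When no level is configured, panel generation picks one value for the whole
panel (noise is an instrument property) such that the weakest group's H5
bin keeps ≈ 40 dB SNR, using the closed form
$E|N_{\text{bin}}| = \sigma\sqrt{3\pi n/32}$ for a periodic-Hann-windowed
record of length $n$. This puts per-repeat ratio scatter at roughly 0.3–1 %
— comfortably in the "stable repeat measurement" regime the protocol
reports, while leaving the 10-repeat averaging something real to do.

## Spectral processing choices

- **Periodic (DFT) Hann window**, $w_j = \tfrac12(1-\cos(2\pi j/n))$:
  keeps on-bin tones exactly on-bin over the record; coherent gain exactly
  0.5.
- **Single-bin magnitudes, no neighbor summation.** The Hann window spreads
  an on-bin tone into exactly the two adjacent bins, with an identical
  spread factor for every harmonic, so the factor cancels in H3/H5. Bins
  two or more away receive nothing, which is also why the 5 kHz residual
  feedthrough (bin 500) cannot contaminate H3 (bin 1500) or H5 (bin 2500),
  and why no background-spectrum subtraction is applied.
- **No gain corrections.** Window gain, amplifier gain, coil sensitivity
  and concentration scale both harmonics equally; reported magnitudes are
  labeled instrument-scale and only the ratio is interpreted.
- **Averaging semantics.** "Averaging the 10 acquisitions" is implemented
  as the mean of per-repeat *ratios* (not the ratio of averaged spectra):
  it matches the protocol wording and yields a per-sample dispersion for
  free. For a single repeat the dispersion is reported as 0 by convention.
- **SNR gate.** A sample passes QC only if both H3 and H5 exceed a
  configurable magnitude floor. The physical 50 ng detection limit of the
  reference instrument is not reproducible in software, so the floor is a
  configuration value (default 0).

## Calibration and the synthetic panel

`calibrate_tau_for_ratio()` inverts $R(\tau_B)$ by bisection on the
monotone ratio–$\tau_B$ curve to $10^{-4}$ relative, after checking
feasibility against $[R_0, \tfrac53 R_0)$; infeasible targets raise errors
naming the offending band. `generate_tissue_panel()` then emulates the
seven-group reference panel (Normal-1 1.898, Normal-2 2.002, BLN 1.806,
IBC 2.744, MC 2.446, MLN 2.251, ANT 2.166; one specimen each, 10 repeats)
with per-trace noise streams keyed by `(seed, sample_id, repeat_index)`,
so any single trace can be re-simulated bit-identically in isolation.

What the generator emulates: per-group ratio levels, repeat-to-repeat
instrument noise, concentration independence, the feedthrough residual, and
the low-pass mechanism behind ratio elevation. What it does **not**
emulate: biological heterogeneity within a tissue group (each group has one
$\tau_B$), particle aggregation and partial immobilization, non-equilibrium
(Fokker–Planck) dynamics, tracer-uptake variability, positioning or drift
errors. Passing recovery tests on this generator therefore validates the
*processing chain and its claimed invariances*, not the clinical
performance of the biomarker.

## Classification bands

Stratification uses three-way labels: benign below `benign_max`, malignant
above `malignant_min`, indeterminate between (boundary values inclusive to
indeterminate — the conservative call for a diagnostic). The reference data
place benign samples at 1.806–2.002, the transitional tumor-adjacent group
at 2.166 and malignancies at 2.251–2.744, and describe the benign range
only as "below approximately 2.0". A literal ceiling of 2.0 would misplace
the highest benign sample (2.002), so the default ceiling is set at 2.1 —
above the highest benign observation, below the transitional value — with
`malignant_min = 2.2`. Any ceiling in (2.002, 2.166] and floor in
[2.166, 2.251) yields identical labels on the reference panel;
`stratification_report()` prints exactly this label-preserving window so
the arbitrariness stays visible. These are empirical pilot-cohort bands,
not validated diagnostic cut-offs, and no ROC analysis is attempted at
n = 1 specimen per group.

## Numerical choices and degenerate inputs

- Langevin series switch at $|\xi| < 10^{-4}$ (see above); quadrature
  degenerates to the median diameter for one node or $\sigma = 0$.
- Harmonic extraction refuses off-bin frequencies (error naming
  $\Delta f$) and frequencies at or above Nyquist, rather than silently
  interpolating.
- `fs * duration` must be an integer sample count; trace files carry their
  provenance and are validated against it on read.
- An H5 at or below the QC floor raises a low-signal error instead of
  returning an unreliable ratio.
- Bisection brackets grow geometrically from $1/(2\pi f_0)$; 200 iterations
  bound the worst case far beyond the $10^{-4}$ tolerance.

## Problem sizes used in the shipped checks

The test suite exercises full-length records (10⁵ samples) wherever a
claim depends on the reference bin geometry, and 10 ms records (still
exactly on-bin, at 100 Hz resolution) for properties that are independent
of record length. The repeat-recovery study simulates 200 independently
seeded panels × 7 groups × 10 repeats against the noiseless reference,
checking that ≥ 95 % of the 1400 panel-group means fall within 3 standard
errors; with $n = 10$ repeats the expected coverage of a 3-SE interval is
≈ 98.5 % (Student t, 9 df), so the margin is real but not lax.

## Known limitations

- Equilibrium Langevin response only; the Debye factor is a surrogate for
  relaxation dynamics, adequate for the monotone ratio–constraint signature
  but not for quantitative viscometry.
- One $\tau_B$ per environment: no distribution of constraint states or
  partially immobilized fractions.
- Feedthrough is modeled as a clean fundamental; real receive chains may
  leak harmonics of the drive amplifier, which would require a background
  acquisition to remove.
- Absolute signal amplitudes are instrument-scale; only ratios are
  physically meaningful outputs.
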