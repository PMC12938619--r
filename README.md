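# mpsharmonics

Simulation and analysis of **magnetic particle spectroscopy (MPS) harmonic
ratios** for tissue characterization.

Superparamagnetic iron-oxide tracers driven by a sinusoidal field respond
through the nonlinear Langevin magnetization

```
M(H) = m c L(ξ),   L(ξ) = coth(ξ) − 1/ξ,   ξ = m B / (kB T)
```

(`m` particle moment, `c` concentration, `B` drive flux density). Because
`L` is odd and saturating, the receive-coil voltage contains only **odd
harmonics** of the 5 kHz drive. Stiff or dense tissue microenvironments
hinder the Brownian rotation of the particles; this acts as a physical
low-pass filter that attenuates the fifth harmonic more than the third and
thereby **elevates the ratio R = H3/H5**. Since concentration scales H3 and
H5 equally, R is self-normalized — a rapid (0.1 s/acquisition), tracer-dose-
independent biomarker for separating malignant from benign tissue, e.g. in
intraoperative lymph-node assessment.

The package provides, as plain R functions plus a thin CLI:

- **Langevin core** — `langevin()`, `dimensionless_field()`,
  `equilibrium_magnetization()` for mono- and polydisperse (log-normal)
  ensembles with Gauss–Legendre size quadrature.
- **Signal synthesis** — `synthesize_acquisition()` builds receive-coil
  voltage traces (Faraday induction, per-harmonic Debye attenuation by an
  effective Brownian relaxation time `tau_B`, ×10 amplifier gain, residual
  fundamental feedthrough, seeded Gaussian noise);
  `calibrate_tau_for_ratio()` inverts the forward model so that
  `generate_tissue_panel()` can emulate tissue groups with prescribed
  ratios, 10 repeats per sample.
- **Harmonic analysis** — `amplitude_spectrum()` (periodic Hann window +
  FFT, 10 Hz bins), `harmonic_amplitude()` (exact single-bin magnitudes at
  15 and 25 kHz), `harmonic_ratio()`, `average_ratio()`, `snr_gate()`.
- **Stratification** — `classify_ratio()` with benign / indeterminate /
  malignant bands, `percent_increase()`, `ratio_differential()`,
  `gradient_check()`, `stratification_report()`.
- **I/O & CLI** — `#`-metadata delimited-text traces, YAML run configs, and
  `mps_cli()` with `simulate` / `analyze` / `report` / `validate`
  subcommands (wrapper script in `inst/cli/mps_harmonics.R`).

## Worked example

Simulate the built-in seven-group tissue panel (two normal controls, benign
lymph node BLN, invasive breast cancer IBC, mucinous carcinoma MC,
metastatic lymph node MLN, tumor-adjacent tissue ANT; one sample each,
10 noisy repeats of 0.1 s at 1 MS/s), analyze it end to end, and stratify:

```r
library(mpsharmonics)
panel <- generate_tissue_panel(default_tissue_panel(), seed = 1)
res   <- analyze_traces(panel$traces)
stratification_report(res, truth = panel$truth)
```

```
Stratification by mean H3/H5 ratio
  bands: benign < 2.1, malignant > 2.2 (boundary values indeterminate)
     group n_samples mean_ratio std_ratio         label
1      BLN         1      1.808  0.002486        benign
2 Normal-1         1      1.897  0.003781        benign
3 Normal-2         1      2.004  0.006483        benign
4      ANT         1      2.166  0.006946 indeterminate
5      MLN         1      2.250  0.009911     malignant
6       MC         1      2.449  0.011260     malignant
7      IBC         1      2.749  0.027474     malignant
  benign/malignant separation: max benign 2.004, min malignant 2.250 (gap 0.245)
  labels unchanged for benign_max in (2.004, 2.166], malignant_min in [2.166, 2.250)
  ground truth: 7/7 labels agree, max |recovery error| 1.82e-03
```

Each `mean_ratio` is the arithmetic mean of 10 per-repeat H3/H5 values;
`std_ratio` is their sample dispersion (about 0.1–1 % of the mean at the
default ~40 dB H5 SNR). The panel recovers its calibration targets to
better than 0.2 %, the three malignancies exceed the 2.2 band, the benign
group stays below it, and the tumor-adjacent tissue lands in between — the
transitional "field effect" signature. The classic summary statistics
follow directly:

```r
percent_increase(2.744, 1.898)   # IBC vs Normal-1: 44.57 % -> rounds to 45 %
ratio_differential(2.251, 1.806) # MLN - BLN: 0.445
gradient_check(c(1.898, 2.166, 2.744)) # Normal-1 < ANT < IBC: TRUE
```

The same pipeline is available from a shell:

```sh
Rscript inst/cli/mps_harmonics.R validate --seed 1
```

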