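# Shared fixtures: the reference configuration and a shortened acquisition
# (10 ms record, 100 Hz bins -- harmonics of 5 kHz stay exactly on-bin) used
# where full 0.1 s records would only cost time.

ref_ensemble <- function(...) particle_ensemble(...)
ref_drive <- function() drive_field()
ref_env <- function(tau_B = 0) mps_environment(tau_B = tau_B)
ref_coil <- function(...) coil_model(...)

short_acq <- function(noise_sigma = 0, n_repeats = 2, seed = 1L) {
  acquisition_config(fs = 1e6, duration = 0.01, n_repeats = n_repeats,
                     noise_sigma = noise_sigma, seed = seed)
}

full_acq <- function(noise_sigma = 0, seed = 1L) {
  acquisition_config(fs = 1e6, duration = 0.1, n_repeats = 10,
                     noise_sigma = noise_sigma, seed = seed)
}

# Moment giving peak dimensionless field 0.1 under the 9 mT / 300.15 K
# defaults (small-signal regime for Taylor-series oracles).
small_signal_moment <- function() {
  0.1 * physical_constants()$kB * 300.15 / 9e-3
}

# Independent Fourier-sine projection oracle: coefficient of sin(2 pi k f0 t)
# of a periodic series sampled over an integer number of periods.
project_harmonic <- function(x, t, f0, k) {
  2 * mean(x * sin(2 * pi * k * f0 * t))
}

noiseless_pipeline_ratio <- function(ensemble, drive, env, coil, acq,
                                     f0 = drive$frequency_Hz) {
  tr <- synthesize_acquisition(ensemble, drive, env, coil, acq)
  harmonic_ratio(amplitude_spectrum(tr), f0)
}
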