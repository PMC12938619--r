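# Receive-chain synthesis: induction, Debye constraint, noise, calibration.

test_that("induced voltage differentiates and scales the magnetization", {
  coil <- ref_coil(feedthrough_amplitude = 0)
  fs <- 1e6
  expect_equal(induced_voltage(rep(3.5, 100), coil, fs),
               rep(0, 100))
  # pure tone via the analytic path: amplitude mu0 * p * V * g * A * 2 pi f
  A <- 2; f <- 5000
  t <- (0:9999) / fs
  M <- A * sin(2 * pi * f * t)
  dM <- A * 2 * pi * f * cos(2 * pi * f * t)
  u <- induced_voltage(M, coil, fs, dM_dt = dM)
  expected <- physical_constants()$mu0 * coil$sensitivity * coil$sample_volume *
    coil$gain * A * 2 * pi * f
  expect_equal(max(abs(u)), expected, tolerance = 1e-6)
  # central-difference fallback is second-order accurate
  u2 <- induced_voltage(M, coil, fs)
  interior <- 2:9999
  expect_equal(u2[interior], u[interior],
               tolerance = (2 * pi * f / fs)^2)
  expect_error(induced_voltage(c(1, 2), coil, fs), "length >= 3")
})

test_that("differentiation scales a harmonic ratio by k-over-k", {
  # magnetization H3:H5 of A3:A5 maps to voltage (3 A3):(5 A5)
  coil <- ref_coil(feedthrough_amplitude = 0)
  fs <- 1e6; f0 <- 5000
  t <- (0:19999) / fs
  M <- 0.8 * sin(2 * pi * 3 * f0 * t) + 0.2 * sin(2 * pi * 5 * f0 * t)
  dM <- 0.8 * 2 * pi * 3 * f0 * cos(2 * pi * 3 * f0 * t) +
    0.2 * 2 * pi * 5 * f0 * cos(2 * pi * 5 * f0 * t)
  sp <- amplitude_spectrum(induced_voltage(M, coil, fs, dM_dt = dM), fs = fs)
  expect_equal(harmonic_ratio(sp, f0), (3 * 0.8) / (5 * 0.2), tolerance = 1e-9)
})

test_that("Debye constraint attenuates higher orders more and elevates the ratio", {
  comp <- c(1, 0, 0.4, 0, 0.1) + 0i
  f0 <- 5000
  expect_equal(apply_brownian_constraint(comp, 0, f0), comp)
  # half-power point of order 3: 2 pi * 3 f0 * tau = 1
  tau3 <- 1 / (2 * pi * 3 * f0)
  out <- apply_brownian_constraint(comp, tau3, f0)
  expect_equal(Mod(out[3]), Mod(comp[3]) / sqrt(2), tolerance = 1e-12)
  # attenuation magnitude strictly decreasing with order
  att <- Mod(apply_brownian_constraint(rep(1 + 0i, 9), 2e-5, f0))
  expect_true(all(diff(att) < 0))
  # ratio elevation follows the Debye moduli algebra
  tau <- 3e-5
  out2 <- apply_brownian_constraint(comp, tau, f0)
  before <- Mod(comp[3]) / Mod(comp[5])
  after <- Mod(out2[3]) / Mod(out2[5])
  expect_equal(after, before * sqrt(1 + (2 * pi * 5 * f0 * tau)^2) /
                 sqrt(1 + (2 * pi * 3 * f0 * tau)^2), tolerance = 1e-12)
  expect_gte(after, before)
  expect_error(apply_brownian_constraint(comp, -1e-6, f0), "nonnegative")
})

test_that("synthesis is deterministic per (seed, sample, repeat) and noise is keyed", {
  acq <- short_acq(noise_sigma = 1e-4)
  args <- list(ref_ensemble(), ref_drive(), ref_env(2e-5), ref_coil(), acq)
  t1 <- do.call(synthesize_acquisition, c(args, sample_id = "A", repeat_index = 1))
  t2 <- do.call(synthesize_acquisition, c(args, sample_id = "A", repeat_index = 1))
  expect_identical(t1$voltage, t2$voltage)
  t3 <- do.call(synthesize_acquisition, c(args, sample_id = "A", repeat_index = 2))
  expect_false(identical(t1$voltage, t3$voltage))
  t4 <- do.call(synthesize_acquisition, c(args, sample_id = "B", repeat_index = 1))
  expect_false(identical(t1$voltage, t4$voltage))
})

test_that("noiseless unconstrained pipeline reproduces the equilibrium harmonic ratio", {
  # oracle: direct Fourier projection of the magnetization series, times the
  # k * omega scaling of differentiation
  ens <- ref_ensemble(); drv <- ref_drive()
  f0 <- drv$frequency_Hz
  t <- (0:8191) / (8192 * f0)
  M <- equilibrium_magnetization(ens, drv, ref_env(), t)
  want <- (3 * abs(project_harmonic(M, t, f0, 3))) /
    (5 * abs(project_harmonic(M, t, f0, 5)))
  got <- noiseless_pipeline_ratio(ens, drv, ref_env(), ref_coil(), short_acq())
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("small-signal end-to-end ratio matches the 25.2/xi^2 Taylor oracle", {
  ens <- particle_ensemble(moment = small_signal_moment(), concentration = 1e19)
  xi <- dimensionless_field(ens$moment, 9e-3, 300.15)
  expect_equal(xi, 0.1, tolerance = 1e-12)
  r <- noiseless_pipeline_ratio(ens, ref_drive(), ref_env(),
                                ref_coil(feedthrough_amplitude = 0), short_acq())
  expect_equal(r, 25.2 / xi^2, tolerance = 0.02)
})

test_that("calibration inverts the ratio-tau curve and respects feasibility", {
  ens <- ref_ensemble(); drv <- ref_drive(); env <- ref_env(); coil <- ref_coil()
  r0 <- noiseless_pipeline_ratio(ens, drv, env, coil, short_acq())
  expect_equal(calibrate_tau_for_ratio(r0, ens, drv, env, coil), 0)
  tau_lo <- calibrate_tau_for_ratio(1.806, ens, drv, env, coil)
  tau_hi <- calibrate_tau_for_ratio(2.744, ens, drv, env, coil)
  expect_true(is.finite(tau_lo) && is.finite(tau_hi))
  expect_gt(tau_hi, tau_lo)
  # forward round trip through the full synthesis + FFT pipeline
  for (target in c(1.806, 2.744)) {
    tau <- calibrate_tau_for_ratio(target, ens, drv, env, coil)
    got <- noiseless_pipeline_ratio(ens, drv, ref_env(tau), coil, full_acq())
    expect_equal(got, target, tolerance = 1e-3)
  }
  expect_error(calibrate_tau_for_ratio(r0 * 0.9, ens, drv, env, coil),
               "below the unconstrained")
  expect_error(calibrate_tau_for_ratio(r0 * 5 / 3 + 0.01, ens, drv, env, coil),
               "asymptote")
})

test_that("the ratio is invariant to gain, sensitivity and concentration", {
  drv <- ref_drive(); env <- ref_env(2.4e-5); acq <- short_acq()
  base <- noiseless_pipeline_ratio(ref_ensemble(), drv, env, ref_coil(), acq)
  r_gain <- noiseless_pipeline_ratio(ref_ensemble(), drv, env,
                                     ref_coil(gain = 37), acq)
  r_sens <- noiseless_pipeline_ratio(ref_ensemble(), drv, env,
                                     ref_coil(sensitivity = 100), acq)
  expect_equal(r_gain, base, tolerance = 1e-12)
  expect_equal(r_sens, base, tolerance = 1e-12)
  r_conc <- noiseless_pipeline_ratio(ref_ensemble(concentration = 1e20), drv,
                                     env, ref_coil(), acq)
  expect_equal(r_conc, base, tolerance = 1e-9)
})

test_that("panel generation calibrates each group and keys every trace", {
  groups <- data.frame(label = c("low", "high"),
                       target_ratio = c(1.9, 2.6), n_samples = c(2L, 1L))
  panel <- tissue_panel_config(groups, acq = short_acq(n_repeats = 3))
  out <- generate_tissue_panel(panel, seed = 42, noise = FALSE)
  expect_length(out$traces, (2 + 1) * 3)
  expect_equal(nrow(out$truth), 3)
  expect_equal(out$noise_sigma, 0)
  expect_true(all(out$truth$tau_B[out$truth$group == "high"] >
                    out$truth$tau_B[out$truth$group == "low"]))
  # zero noise: every repeat of a sample analyzes to the identical ratio
  res <- analyze_traces(out$traces)
  per <- split(res$repeats$ratio, res$repeats$sample_id)
  for (rr in per) expect_equal(max(rr) - min(rr), 0)
  # recovered ratios hit the calibration targets
  m <- merge(res$samples, out$truth, by = "sample_id")
  expect_equal(m$mean_ratio, m$target_ratio, tolerance = 1e-3)
  # infeasible group target is reported by name
  bad <- tissue_panel_config(data.frame(label = "impossible",
                                        target_ratio = 50, n_samples = 1L),
                             acq = short_acq())
  expect_error(generate_tissue_panel(bad), "impossible")
})

test_that("automatic noise level yields about 40 dB SNR on the weakest H5", {
  groups <- data.frame(label = c("g1", "g2"), target_ratio = c(1.9, 2.6),
                       n_samples = 1L)
  panel <- tissue_panel_config(groups, acq = short_acq(noise_sigma = NULL,
                                                       n_repeats = 2))
  out <- generate_tissue_panel(panel, seed = 3)
  expect_gt(out$noise_sigma, 0)
  # weakest group's measured H5 should sit near 100x the expected noise bin
  res <- analyze_traces(out$traces)
  h5_min <- min(res$samples$h5)
  n <- panel$acq$n_samples
  noise_bin <- out$noise_sigma * sqrt(3 * pi * n / 32)
  expect_equal(h5_min / noise_bin, 100, tolerance = 0.15)
})
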