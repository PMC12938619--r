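# Equilibrium Langevin magnetization physics.

test_that("langevin matches arbitrary-precision reference values", {
  # coth(1) - 1 and the xi = 0.1 series, evaluated independently at 30 digits
  expect_identical(langevin(0), 0)
  expect_equal(langevin(1), 0.313035285499331, tolerance = 1e-14)
  expect_equal(langevin(0.1), 0.033311132253990, tolerance = 1e-12)
  # large-field asymptote L(xi) -> 1 - 1/xi
  expect_equal(langevin(50), 1 - 1 / 50, tolerance = 1e-6)
})

test_that("langevin is odd, strictly increasing, bounded, and smooth at the series branch", {
  xi <- c(10^seq(-8, 1, by = 0.25), 2, 5, 20, 100)
  expect_equal(langevin(-xi), -langevin(xi))
  grid <- sort(c(-xi, 0, xi))
  v <- langevin(grid)
  expect_true(all(diff(v) > 0))
  expect_true(all(abs(v) < 1))
  # both branches agree near the 1e-4 switch point; the comparison is
  # absolute because the closed form itself cancels catastrophically there
  eps <- 1e-4
  direct <- 1 / tanh(c(eps * 0.999, eps * 1.001)) - 1 / c(eps * 0.999, eps * 1.001)
  expect_lt(max(abs(langevin(c(eps * 0.999, eps * 1.001)) - direct)), 1e-11)
  expect_error(langevin(NaN), "finite")
  expect_error(langevin(Inf), "finite")
})

test_that("dimensionless field is m*B/(kB*T), linear in each argument", {
  expect_equal(dimensionless_field(1e-18, 9e-3, 300), 2.172891,
               tolerance = 1e-6)
  expect_identical(dimensionless_field(1e-18, 0, 300), 0)
  expect_equal(dimensionless_field(2e-18, 9e-3, 300),
               2 * dimensionless_field(1e-18, 9e-3, 300))
  expect_equal(dimensionless_field(1e-18, 4.5e-3, 300),
               dimensionless_field(1e-18, 9e-3, 300) / 2)
  expect_error(dimensionless_field(-1e-18, 9e-3, 300), "positive")
  expect_error(dimensionless_field(1e-18, 9e-3, 0), "positive")
})

test_that("equilibrium magnetization is periodic, odd under half-period shift, linear in c", {
  ens <- ref_ensemble()
  f0 <- 5000
  n <- 400
  t <- (0:(n - 1)) / (n * f0) * 2           # two periods
  M <- equilibrium_magnetization(ens, ref_drive(), ref_env(), t)
  expect_equal(M[1:(n / 2)], M[(n / 2 + 1):n])                 # period 1/f0
  half <- n / 4                                               # 1/(2 f0) shift
  expect_equal(M[(half + 1):(2 * half)], -M[1:half], tolerance = 1e-12)
  ens2 <- particle_ensemble(moment = ens$moment,
                            concentration = 2 * ens$concentration)
  M2 <- equilibrium_magnetization(ens2, ref_drive(), ref_env(), t)
  expect_identical(M2, 2 * M)
  zero <- equilibrium_magnetization(ens, drive_field(amplitude_T = 1e-300), ref_env(), t)
  expect_true(all(abs(zero) < 1e-250))
  expect_error(equilibrium_magnetization(ens, ref_drive(), ref_env(), numeric(0)),
               "nonempty")
  expect_error(equilibrium_magnetization(ens, ref_drive(), ref_env(), c(0, 1, 3)),
               "uniform")
})

test_that("small-signal harmonic coefficients match the Taylor oracle", {
  # oracle: for L(xi) ~ xi/3 - xi^3/45 + 2 xi^5/945 and xi(t) = xi_p sin(wt),
  # a3 = m c xi_p^3/180 and a5 = m c xi_p^5/7560
  ens <- particle_ensemble(moment = small_signal_moment(), concentration = 1e19)
  f0 <- 5000
  t <- (0:8191) / (8192 * f0)
  M <- equilibrium_magnetization(ens, ref_drive(), ref_env(), t)
  mc <- ens$moment * ens$concentration
  xi_p <- dimensionless_field(ens$moment, 9e-3, 300.15)
  a3 <- project_harmonic(M, t, f0, 3)
  a5 <- project_harmonic(M, t, f0, 5)
  expect_equal(abs(a3), mc * xi_p^3 / 180, tolerance = 0.02)
  expect_equal(abs(a5), mc * xi_p^5 / 7560, tolerance = 0.02)
})

test_that("magnetization of a sinusoidal drive has odd harmonics only", {
  ens <- ref_ensemble()   # xi_p ~ 7.2, well inside the nonlinear regime
  f0 <- 5000
  acqn <- 20000
  t <- (0:(acqn - 1)) / 1e6
  M <- equilibrium_magnetization(ens, ref_drive(), ref_env(), t)
  sp <- amplitude_spectrum(M, fs = 1e6)
  h3 <- harmonic_amplitude(sp, f0, 3)
  even <- vapply(c(2, 4, 6, 8), function(k) harmonic_amplitude(sp, f0, k),
                 numeric(1))
  expect_true(all(even < 1e-10 * h3))
})

test_that("log-normal quadrature integrates the size distribution", {
  g <- lognormal_granulometry(median_diameter = 5e-9, log_sigma = 0.3, Ms = 3e5)
  q <- lognormal_quadrature(g, 32)
  expect_equal(sum(q$weights), 1, tolerance = 1e-12)
  # closed-form log-normal mean e^(mu + sigma^2/2)
  expect_equal(sum(q$weights * q$nodes), 5e-9 * exp(0.3^2 / 2),
               tolerance = 1e-3)
  # degenerate cases collapse to the median diameter
  q1 <- lognormal_quadrature(g, 1)
  expect_equal(q1, list(nodes = 5e-9, weights = 1))
  g0 <- lognormal_granulometry(5e-9, 0, 3e5)
  expect_equal(lognormal_quadrature(g0, 32), list(nodes = 5e-9, weights = 1))
  expect_error(lognormal_granulometry(5e-9, -0.1, 3e5), "log_sigma")
})

test_that("polydisperse magnetization averages sizes and stays linear in c", {
  g <- lognormal_granulometry(median_diameter = 2.4e-8, log_sigma = 0.2, Ms = 3e5)
  ens <- particle_ensemble(concentration = 1e19, granulometry = g)
  expect_equal(ens$moment, 3e5 * pi / 6 * (2.4e-8)^3)
  t <- (0:799) / (800 * 5000)
  M <- equilibrium_magnetization(ens, ref_drive(), ref_env(), t)
  ens2 <- particle_ensemble(concentration = 3e19, granulometry = g)
  expect_equal(equilibrium_magnetization(ens2, ref_drive(), ref_env(), t), 3 * M)
  # a polydisperse ensemble is not equivalent to its median-size monodisperse one
  mono <- particle_ensemble(moment = ens$moment, concentration = 1e19)
  Mm <- equilibrium_magnetization(mono, ref_drive(), ref_env(), t)
  expect_gt(max(abs(M - Mm)) / max(abs(M)), 1e-3)
})
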