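test_that("amplitude-averaged lifetime is the amplitude-weighted mean", {
  expect_equal(amplitude_avg_lifetime(1, 2, 0, 1), 2)
  expect_equal(amplitude_avg_lifetime(1, 1, 1, 3), 2)
  expect_equal(amplitude_avg_lifetime(0.8, 0.1, 0.2, 1.7), 0.42)
  expect_error(amplitude_avg_lifetime(0, 1, 0, 2), "both be zero")
  expect_error(amplitude_avg_lifetime(-1, 1, 1, 2), "non-negative")
  expect_error(amplitude_avg_lifetime(1, 0, 1, 2), "positive")
})

test_that("histogram container validates its invariants", {
  expect_error(decay_histogram(c(0:6, 8), rep(1, 8)), "uniform")
  expect_error(decay_histogram(0:9, c(-1, rep(1, 9))), "non-negative")
  expect_error(decay_histogram(seq(0, 30, length.out = 32), rep(1, 32),
                               rep_rate = 40), "period")
})

test_that("decay fitting rejects starved histograms", {
  h <- simulate_decay(list(c(1, 1)), n_photons = 200, seed = 1)
  expect_error(fit_biexponential(h), "few photons")
})

test_that("a monoexponential decay is recovered by the tail fit", {
  h <- simulate_decay(list(c(1, 1.0)), n_photons = 1e5, seed = 1)
  fit <- fit_biexponential(h)
  expect_equal(fit$tau_avg, 1.0, tolerance = 0.02)
  expect_true(fit$tau1 > 0.9 && fit$tau2 < 1.3)
  expect_lt(fit$background, 5)
  expect_true(fit$tau_avg >= fit$tau1 && fit$tau_avg <= fit$tau2)
})

test_that("reconvolution fit recovers both components through the IRF", {
  h <- simulate_decay(list(c(0.8, 0.3), c(0.2, 1.7)), irf_fwhm = 0.25,
                      n_photons = 5e5, seed = 4)
  fit <- fit_biexponential(h)
  expect_equal(fit$tau1, 0.3, tolerance = 0.1)
  expect_equal(fit$tau2, 1.7, tolerance = 0.05)
  expect_equal(fit$a2 / fit$a1, 0.25, tolerance = 0.1)
  expect_lt(fit$goodness, 1.5)
})

test_that("slow components wrap around at the repetition period", {
  # tau = 10 ns at 40 MHz: photons from earlier pulses raise the t = 0 bin
  # by the geometric factor 1/(1 - exp(-25/10)) = 1.089
  h <- simulate_decay(list(c(1, 10)), n_photons = 1e6, seed = 3)
  # without wrapping the first bin would hold n (1 - exp(-dt/tau)) photons
  enhancement <- h$counts[1] / (1e6 * (1 - exp(-h$dt / 10)))
  expect_gt(enhancement, 1.04)
  expect_equal(enhancement, 1 / (1 - exp(-25 / 10)), tolerance = 0.03)
})

test_that("power-law calibration is exact on noiseless data", {
  eta <- c(1, 10, 100, 900)
  fit <- fit_forster_hoffman(0.05 * eta^0.5, eta)
  expect_equal(fit$prefactor, 0.05, tolerance = 1e-12)
  expect_equal(fit$alpha, 0.5, tolerance = 1e-12)
  expect_error(fit_forster_hoffman(1, 1), "3 points")
  expect_error(fit_forster_hoffman(c(-1, 1, 2), eta[1:3]), "positive")
})

test_that("power-law calibration is scale equivariant", {
  eta <- c(2, 20, 80, 300, 900)
  tau <- 0.03 * eta^0.42
  f1 <- fit_forster_hoffman(tau, eta)
  f2 <- fit_forster_hoffman(10 * tau, eta)
  expect_equal(f2$prefactor, 10 * f1$prefactor, tolerance = 1e-10)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-12)
})

test_that("exponent is recovered from noisy calibration data", {
  eta <- 10^seq(0, 3, length.out = 8)
  tau_true <- 0.05 * eta^0.5
  set.seed(21)
  tau <- tau_true * rlnorm(8, 0, 0.05)  # 5% lognormal noise
  fit <- fit_forster_hoffman(tau, eta)
  se_alpha <- sqrt(fit$covariance["alpha", "alpha"])
  expect_lt(abs(fit$alpha - 0.5), 2 * se_alpha + 0.02)
})

test_that("intersection viscosity inverts the calibration", {
  eta <- c(1, 10, 100)  # bulk lifetimes stay below the 1.7 ns plateau
  fh <- fit_forster_hoffman(0.05 * eta^0.55, eta)
  res <- intersect_viscosity(fh, 1.7, phi_eta_powerlaw(0.55))
  expect_equal(res$eta_I, (1.7 / 0.05)^(1 / 0.55), tolerance = 1e-9)
  expect_equal(res$phi_I, min(0.15 * (res$eta_I / 2e4)^0.55, 1), tolerance = 1e-9)
  # plateau equal to the eta = 1 lifetime: boundary case
  fh2 <- fit_forster_hoffman(0.05 * eta[1:3]^0.5, eta[1:3])
  expect_error(intersect_viscosity(fh2, 0.01, phi_eta_powerlaw()),
               "no intersection")
  # tabulated quantum-yield relation
  tab <- data.frame(eta = c(1, 1e2, 1e4, 1e6), phi = c(1e-3, 1e-2, 0.15, 1))
  res2 <- intersect_viscosity(fh, 1.7, tab)
  expect_true(res2$phi_I > 1e-3 && res2$phi_I < 1)
})

test_that("refitting a simulated draw of a fit recovers its parameters", {
  fit0 <- list(a1 = 0.7, tau1 = 0.4, a2 = 0.3, tau2 = 1.5)
  h <- simulate_decay(list(c(fit0$a1, fit0$tau1), c(fit0$a2, fit0$tau2)),
                      n_photons = 5e5, seed = 8)
  fit <- fit_biexponential(h)
  expect_equal(fit$tau1, fit0$tau1, tolerance = 0.05)
  expect_equal(fit$tau2, fit0$tau2, tolerance = 0.05)
  expect_equal(fit$a2 / fit$a1, fit0$a2 / fit0$a1, tolerance = 0.1)
})
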