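test_that("profiles normalise to their interface anchor", {
  p <- zscan_profile(c(0, 5, 10), c(100, 100, 100))
  expect_equal(normalize_profile(p, "homogeneous")$value, c(1, 1, 1))
  p2 <- zscan_profile(c(0, 5, 10), c(50, 60, 70))
  expect_equal(normalize_profile(p2, "sample")$value, c(1, 1.2, 1.4))
  p3 <- zscan_profile(c(0, 5), c(0, 10))
  expect_error(normalize_profile(p3), "strictly positive")
  expect_error(zscan_profile(c(1, 5), c(1, 2)), "include 0")
  expect_error(zscan_profile(c(0, 5, 4), c(1, 2, 3)), "increasing")
})

test_that("U isolates the surface term and is anchored at 1", {
  h <- data.frame(z_f = c(0, 5, 10), value = c(1, 1.5, 1.8))
  u <- compute_U(h, h)
  expect_equal(u$u, c(1, 1, 1))
  i_n <- data.frame(z_f = c(0, 5, 10), value = c(1, 1.2, 1.4))
  expect_equal(compute_U(i_n, h)$u[1], 1)
  expect_error(compute_U(data.frame(z_f = c(0, 4), value = c(1, 1)), h),
               "grids")
  noisy <- data.frame(z_f = c(0, 5, 10), value = c(1, 1.6, 1.8))
  expect_warning(compute_U(noisy, h), "exceeds 1")
})

test_that("forward-modelled U decreases to the predicted asymptote", {
  # K = 5 um, phi00 = 0.2 /um: U falls from 1 towards 1/(1 + 1) = 0.5
  z <- c(0, 2, 5, 10, 20, 40)
  r_th <- 9 / (9 + z^2)
  u <- (1 / 0.2 + 5 * r_th) / (1 / 0.2 + 5)
  expect_equal(u[1], 1)
  expect_true(all(diff(u) < 0))
  expect_equal((1 + 5 * 0.2)^-1, 0.5)
  expect_lt(u[length(u)] - 0.5, 0.02)
})

test_that("brightness-ratio estimator inverts the asymptote exactly", {
  depths <- c(5, 7, 10, 20, 30)
  for (k in c(0, 0.1, 1, 10, 100)) {
    u_inf <- 1 / (1 + 0.2 * k)
    u <- data.frame(z_f = c(0, depths), u = c(1, rep(u_inf, 5)))
    est <- estimate_K(u, phi00 = 0.2, depths = depths)
    expect_equal(est$k, k, tolerance = 1e-12)
    expect_equal(est$sd, 0)
  }
  u <- data.frame(z_f = c(0, 5, 10), u = c(1, 0.5, 0.5))
  expect_equal(estimate_K(u, 0.2, c(5, 10))$k, 5)
  expect_error(estimate_K(u, 0.2, c(5, 15)), "absent")
  expect_error(estimate_K(u, 0.2, numeric(0)), "non-empty")
  u0 <- data.frame(z_f = c(0, 5), u = c(1, 0))
  expect_error(estimate_K(u0, 0.2, 5), "undefined")
  above <- data.frame(z_f = c(0, 5), u = c(1, 1.05))
  expect_warning(est <- estimate_K(above, 0.2, 5), "K = 0")
  expect_equal(est$k, 0)
})

test_that("exact inversion removes the finite-depth bias of the asymptote", {
  k_true <- 40; phi00 <- 0.25
  z <- c(5, 10, 20); r_th <- c(0.05, 0.012, 0.003)
  u_vals <- (1 / phi00 + k_true * r_th) / (1 / phi00 + k_true)
  u <- data.frame(z_f = c(0, z), u = c(1, u_vals))
  plain <- estimate_K(u, phi00, z)
  exact <- estimate_K(u, phi00, z, r_th = r_th)
  expect_lt(plain$k, k_true)       # asymptote estimator biased low
  expect_equal(exact$k, k_true, tolerance = 1e-10)
  expect_equal(exact$sd, 0, tolerance = 1e-8)
})

test_that("surface density conversion and unit audit agree with Avogadro", {
  p <- photophysics_params(phi_b = 0.15, tau_b = 1, tau_s = 1.7)
  expect_equal(sigma_from_K(0, 1e-7, p)$sigma, 0)
  # 1 um x 1e-7 mol/L with identical photophysics: 60.22 molecules/um^2
  got <- sigma_from_K(1, 1e-7, p)
  hand <- 1 * 1e-7 * 6.02214076e23 / 1e15
  expect_equal(got$sigma, hand, tolerance = 1e-6)
  expect_error(sigma_from_K(-1, 1e-7, p), "non-negative")
  # uncertainty propagates linearly
  expect_equal(sigma_from_K(2, 1e-7, p, k_sd = 0.5)$sigma_sd, hand / 2,
               tolerance = 1e-6)
  # tube partition against the same hand conversion, to 6 significant figures
  r <- tube_partition_ratio(1e4, 1e-6, 100)
  expect_equal(r, 2 * 1e4 / (100 * 1e-6 * 6.02214076e23 / 1e15),
               tolerance = 1e-7)
})

test_that("tube partition reproduces the microfluidic estimate", {
  # 1% monolayer (1e-2 nm^-2 = 1e4 um^-2), 1 uM, 200 um diameter tube
  r <- tube_partition_ratio(1e4, 1e-6, 100)
  expect_equal(signif(r, 1), 0.3)
  expect_equal(tube_partition_ratio(0, 1e-6, 100), 0)
  expect_equal(tube_partition_ratio(1e4, 1e-6, 200), r / 2)
  expect_error(tube_partition_ratio(1e4, 1e-6, 0), "positive")
})

test_that("coverage fraction follows the molecular footprint", {
  expect_equal(coverage_fraction(3300), 0.0033)
  expect_equal(coverage_fraction(1e4), 0.01)
  expect_equal(coverage_fraction(0), 0)
})

test_that("lifetime collapse rescales to [0, 1] and flags degenerate input", {
  lp <- data.frame(z_f = c(0, 5), tau = c(1.7, 1.2))
  rt <- collapse_Rtau(lp, tau_b = 0.7)
  expect_equal(rt$r_tau, c(1, 0.5))
  flat <- data.frame(z_f = c(0, 5), tau = c(0.7, 0.7))
  expect_error(collapse_Rtau(flat, 0.7), "no detectable surface")
})

test_that("monoexponential relation links R_tau back to R_th exactly", {
  p <- photophysics_params(phi_b = 0.05, tau_b = 0.6, tau_s = 1.7)
  z <- c(0, 1, 2, 5, 10, 20, 30)
  r_th <- 4 / (4 + z^2)
  for (k in c(0.5, 3, 20)) {
    kappa <- k * 0.25
    tau <- (kappa * r_th + 1) / (kappa * r_th / p$tau_s + 1 / p$tau_b)
    rt <- collapse_Rtau(data.frame(z_f = z, tau = tau), p$tau_b)
    rec <- rt$r_tau * mono_ratio(rt, k, 0.25, p)$ratio
    expect_equal(rec, r_th, tolerance = 1e-10)
  }
  # limits: no adsorption, and at the surface
  rt1 <- data.frame(z_f = c(0, 5), r_tau = c(1, 0.4))
  expect_equal(mono_ratio(rt1, 0, 0.2, p)$ratio, c(1, 1))
  expect_equal(mono_ratio(rt1, 10, 0.2, p)$ratio[1], 1)
})

test_that("monoexponential relation holds on ray-traced weights", {
  dr <- water_dr()
  p <- photophysics_params(phi_b = 0.05, tau_b = 0.6, tau_s = 1.7)
  k <- 8
  kappa <- k * dr$phi00
  tau <- (kappa * dr$r_th + 1) / (kappa * dr$r_th / p$tau_s + 1 / p$tau_b)
  rt <- collapse_Rtau(data.frame(z_f = dr$z_f_grid, tau = tau), p$tau_b)
  rec <- rt$r_tau * mono_ratio(rt, k, dr$phi00, p)$ratio
  expect_lt(max(abs(rec - dr$r_th) / pmax(dr$r_th, 1e-9)), 0.02)
})

test_that("sigma grows with K and the asymptote falls with K", {
  p <- photophysics_params(phi_b = 0.01, tau_b = 0.3, tau_s = 1.7)
  ks <- c(0.1, 1, 5, 20, 100)
  sig <- vapply(ks, function(k) sigma_from_K(k, 1e-7, p)$sigma, numeric(1))
  u_inf <- 1 / (1 + 0.2 * ks)
  expect_true(all(diff(sig) > 0))
  expect_true(all(diff(u_inf) < 0))
})
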