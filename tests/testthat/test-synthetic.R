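test_that("decay generator conserves photons and is deterministic", {
  h <- simulate_decay(list(c(0.8, 0.3), c(0.2, 1.7)), n_photons = 1e5, seed = 2)
  expect_lt(abs(sum(h$counts) - 1e5), 3 * sqrt(1e5))
  h2 <- simulate_decay(list(c(0.8, 0.3), c(0.2, 1.7)), n_photons = 1e5, seed = 2)
  expect_identical(h$counts, h2$counts)
  h3 <- simulate_decay(list(c(0.8, 0.3), c(0.2, 1.7)), n_photons = 1e5, seed = 3)
  expect_false(identical(h$counts, h3$counts))
  expect_error(simulate_decay(list(c(1, -2))), "lifetime")
  expect_error(simulate_decay(list(), n_photons = 10), "non-empty")
})

test_that("simulated decays are recoverable by the fitter", {
  h <- simulate_decay(list(c(1, 1)), n_photons = 1e5, seed = 6)
  expect_equal(fit_biexponential(h)$tau_avg, 1, tolerance = 0.02)
})

test_that("noiseless z-scan reproduces the analytic forward model", {
  dr <- water_dr()
  p <- water_photo()
  tr <- ground_truth(500, photophysics = p, noise_cv = 0, seed = 1)
  prof <- simulate_zscan(dr, tr, i0 = 1e5)
  kappa <- tr$k_true * dr$phi00
  expected <- 1e5 * dr$h_pred * (1 + kappa * dr$r_th) / (1 + kappa)
  expect_equal(prof$intensity, expected, tolerance = 1e-12)
  expect_equal(prof$surface_kind, "hydrophobic")
})

test_that("zero adsorption gives a bulk-only profile with U identically 1", {
  dr <- water_dr()
  tr <- ground_truth(0, photophysics = water_photo(), noise_cv = 0, seed = 1)
  prof <- simulate_zscan(dr, tr, i0 = 1e4)
  expect_equal(prof$intensity / 1e4, dr$h_pred, tolerance = 1e-12)
  expect_equal(prof$surface_kind, "hydrophilic")
  u <- compute_U(normalize_profile(prof, "sample"),
                 data.frame(z_f = dr$z_f_grid, value = dr$h_pred))
  expect_equal(u$u, rep(1, length(u$u)), tolerance = 1e-12)
})

test_that("strong adsorption produces an interface spike", {
  dr <- water_dr()
  tr <- ground_truth(3300, photophysics = water_photo(), noise_cv = 0, seed = 1)
  prof <- simulate_zscan(dr, tr)
  i_n <- normalize_profile(prof, "sample")
  # normalised signal drops far below the homogeneous rise once the focus
  # leaves the surface sheet: the z = 0 point is a spike
  expect_lt(i_n$value[i_n$z_f == 10] / dr$h_pred[dr$z_f_grid == 10], 0.05)
})

test_that("simulated lifetimes interpolate between surface and bulk", {
  dr <- water_dr()
  p <- photophysics_params(phi_b = 0.01, tau_b = 0.4, tau_s = 1.7)
  tr <- ground_truth(2000, photophysics = p, noise_cv = 0, seed = 1)
  prof <- simulate_zscan(dr, tr)
  # far from the interface the surface weight K phi(0,z_F) is small but not
  # zero at 40 um, so the bulk limit is approached within ~10%
  expect_equal(prof$lifetime[length(prof$lifetime)], p$tau_b, tolerance = 0.1)
  expect_true(all(diff(prof$lifetime) < 0))
  kappa <- tr$k_true * dr$phi00 # much greater than 1 here
  expect_gt(kappa, 10)
  expect_equal(prof$lifetime[1], p$tau_s, tolerance = 0.05)
})

test_that("lifetime collapse is approximate across photophysics, exact via the model", {
  # profiles generated from one ray-traced R_th with different lifetimes
  # collapse onto similar (not identical) curves: the residual spread is the
  # model-predicted amplitude-weighting effect, and mapping each curve
  # through the monoexponential relation recovers the single R_th exactly
  dr <- water_dr()
  p1 <- photophysics_params(phi_b = 0.01, tau_b = 0.4, tau_s = 1.7)
  p2 <- photophysics_params(phi_b = 0.05, tau_b = 0.8, tau_s = 1.7)
  k_shared <- 40
  curves <- lapply(list(p1, p2), function(p) {
    kappa <- k_shared * dr$phi00
    tau <- (kappa * dr$r_th + 1) / (kappa * dr$r_th / p$tau_s + 1 / p$tau_b)
    collapse_Rtau(data.frame(z_f = dr$z_f_grid, tau = tau), p$tau_b)
  })
  expect_lt(max(abs(curves[[1]]$r_tau - curves[[2]]$r_tau)), 0.2)
  for (i in 1:2) {
    p <- list(p1, p2)[[i]]
    rec <- curves[[i]]$r_tau *
      mono_ratio(curves[[i]], k_shared, dr$phi00, p)$ratio
    expect_equal(rec, dr$r_th, tolerance = 1e-9)
  }
})

test_that("solvent property curves match the stated viscosity range", {
  s <- solvent_properties(c(0, 20, 40, 60, 80, 99))
  expect_gt(s$eta[1], 0.9); expect_lt(s$eta[1], 1.1)
  expect_gt(s$eta[6], 800); expect_lt(s$eta[6], 1000)
  expect_true(all(diff(s$eta) > 0))
  expect_true(all(diff(s$n) > 0))
  expect_equal(solvent_properties(0)$n, 1.333)
  expect_equal(solvent_properties(100)$n, 1.473)
  expect_error(solvent_properties(101), "0, 100")
})

test_that("study photophysics follows the anchored power laws", {
  p <- study_photophysics(0)
  expect_equal(p$tau_b, 0.12)            # instrument floor in water
  expect_equal(p$phi_s, 0.15)
  eta <- solvent_properties(99)$eta
  p99 <- study_photophysics(99)
  expect_equal(p99$phi_b, 0.15 * (eta / 2e4)^0.5, tolerance = 1e-9)
  expect_gt(p99$tau_b, 0.12)
})

test_that("a full synthetic study is deterministic and recoverable", {
  cfg <- microscope_config()
  zf <- c(0, 1, 2, 3, 5, 7, 10, 15, 20, 30)
  st <- generate_study(cfg, wt_list = c(0, 99), z_f_grid = zf,
                       n_rays = 5e4, seed = 5)
  st2 <- generate_study(cfg, wt_list = c(0, 99), z_f_grid = zf,
                        n_rays = 5e4, seed = 5)
  expect_identical(st[[1]]$hydrophobic$intensity, st2[[1]]$hydrophobic$intensity)
  expect_identical(st[[2]]$decay_bulk$counts, st2[[2]]$decay_bulk$counts)
  # hydrophilic side: no adsorption injected at any composition
  for (el in st) expect_equal(el$truth$sigma_true > 0, TRUE)
  sig_hat <- vapply(st, function(el) {
    fit <- suppressWarnings(fit_adsorption(
      el$hydrophobic, reference = el$hydrophilic,
      depth_response = el$depth_response,
      photophysics = el$truth$photophysics, rho_molar = el$truth$rho))
    fit$sigma
  }, numeric(1))
  truth <- vapply(st, function(el) el$truth$sigma_true, numeric(1))
  expect_equal(sig_hat, truth, tolerance = 0.2)
  # the injected decreasing adsorption trend (about tenfold) is reproduced
  expect_gt(sig_hat[1] / sig_hat[2], 4)
  # hydrophilic profiles analyse to sigma consistent with zero
  fit0 <- suppressWarnings(fit_adsorption(
    st[[1]]$hydrophilic, reference = NULL,
    depth_response = st[[1]]$depth_response,
    photophysics = st[[1]]$truth$photophysics, rho_molar = st[[1]]$truth$rho))
  expect_lt(fit0$sigma, 3 * max(fit0$sigma_sd, 1))
})
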