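# run expr with a local RNG state seeded by `seed`, restoring the caller's
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Viscosity and refractive index of glycerol/water mixtures
#'
#' Viscosity from the Cheng (2008) correlation for glycerol-water mixtures,
#' evaluated at 23 degC (a typical lab temperature, at which the 0-99 wt%
#' range spans roughly 1-900 mPa s); refractive index by linear
#' interpolation between water (1.333) and glycerol (1.473).
#'
#' @param wt_glycerol Mass percent glycerol, in [0, 100]; vectorised.
#' @return A data frame with columns `wt_glycerol`, `eta` (mPa s) and `n`.
#' @examples
#' solvent_properties(c(0, 50, 99))
#' @export
solvent_properties <- function(wt_glycerol) {
  if (any(wt_glycerol < 0 | wt_glycerol > 100))
    stop("'wt_glycerol' must lie in [0, 100]", call. = FALSE)
  temp <- 23
  cm <- wt_glycerol / 100
  a <- 0.705 - 0.0017 * temp
  b <- (4.9 + 0.036 * temp) * a^2.5
  mu_w <- 1.790 * exp((-1230 - temp) * temp / (36100 + 360 * temp))
  mu_g <- 12100 * exp((-1233 + temp) * temp / (9900 + 70 * temp))
  alpha <- 1 - cm + a * b * cm * (1 - cm) / (a * cm + b * (1 - cm))
  eta <- mu_w^alpha * mu_g^(1 - alpha)
  data.frame(wt_glycerol = wt_glycerol, eta = eta,
             n = 1.333 + (1.473 - 1.333) * cm)
}

#' Molecular-rotor photophysics for a glycerol/water study
#'
#' Builds [photophysics_params()] for a given solvent composition from
#' Forster-Hoffmann power laws anchored at the common extrapolation point of
#' bulk and interface lifetimes (eta = 2e4 mPa s, where tau = tau_s and
#' Phi = phi_s): \eqn{\tau_B(\eta) = \tau_s (\eta/2\times10^4)^\alpha}
#' (with an instrument floor of 0.12 ns) and
#' \eqn{\Phi_B(\eta) = \Phi_s (\eta/2\times10^4)^\alpha}.  The adsorbed
#' species is assigned the anchor values themselves.
#'
#' @param wt_glycerol Mass percent glycerol.
#' @param alpha Forster-Hoffmann exponent.
#' @param tau_s,phi_s Surface lifetime (ns) and quantum yield.
#' @param eta_anchor Anchor viscosity (mPa s).
#' @param tau_floor Instrument-limited minimum measurable lifetime (ns).
#' @return A [photophysics_params()].
#' @export
study_photophysics <- function(wt_glycerol, alpha = 0.5, tau_s = 1.7,
                               phi_s = 0.15, eta_anchor = 2e4,
                               tau_floor = 0.12) {
  eta <- solvent_properties(wt_glycerol)$eta
  photophysics_params(phi_b = phi_s * (eta / eta_anchor)^alpha,
                      tau_b = max(tau_s * (eta / eta_anchor)^alpha, tau_floor),
                      tau_s = tau_s, phi_s = phi_s)
}

#' Ground truth for a synthetic experiment
#'
#' @param sigma_true Adsorbed surface density (um^-2, >= 0).
#' @param rho Bulk dye concentration (mol/L).
#' @param photophysics A [photophysics_params()].
#' @param wt_glycerol Solvent composition (mass percent glycerol).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal) intensity noise.
#' @param seed Integer seed.
#' @return An object of class `ground_truth`; includes the implied
#'   brightness ratio `k_true` (um) given a unit-free surface/bulk pair.
#' @export
ground_truth <- function(sigma_true, rho = 1e-7, photophysics = NULL,
                         wt_glycerol = 0, noise_cv = 0.01, seed = 1) {
  if (sigma_true < 0) stop("'sigma_true' must be non-negative", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be non-negative", call. = FALSE)
  if (is.null(photophysics)) photophysics <- study_photophysics(wt_glycerol)
  p <- photophysics
  k_true <- sigma_true / (rho * MOLAR_TO_PER_UM3) * p$eps_ratio * p$phi_s / p$phi_b
  structure(list(sigma_true = sigma_true, rho = rho, photophysics = p,
                 wt_glycerol = wt_glycerol, noise_cv = noise_cv,
                 seed = seed, k_true = k_true),
            class = "ground_truth")
}

#' Simulate a TCSPC decay histogram
#'
#' Draws Poisson counts per bin around the expected multi-exponential decay
#' under periodic (wrapped) pulsed excitation, optionally convolved with a
#' Gaussian instrument response.
#'
#' @param components List of `c(amplitude, lifetime_ns)` pairs; amplitudes
#'   are relative decay amplitudes (photon shares are amplitude x lifetime).
#' @param irf_fwhm Optional Gaussian IRF FWHM (ns); the IRF is centred at
#'   one tenth of the window.
#' @param n_photons Expected total photon count.
#' @param rep_rate Laser repetition rate (MHz).
#' @param n_bins Number of histogram bins spanning one period.
#' @param seed Integer seed.
#' @return A [decay_histogram()].
#' @examples
#' h <- simulate_decay(list(c(0.8, 0.3), c(0.2, 1.7)), n_photons = 1e5)
#' sum(h$counts)
#' @export
simulate_decay <- function(components, irf_fwhm = NULL, n_photons = 1e5,
                           rep_rate = 40, n_bins = 256, seed = 1) {
  if (n_photons < 1) stop("'n_photons' must be at least 1", call. = FALSE)
  if (!length(components)) stop("'components' must be non-empty", call. = FALSE)
  comp <- lapply(components, function(cmp) {
    if (length(cmp) != 2 || cmp[1] < 0 || cmp[2] <= 0)
      stop("each component must be c(amplitude >= 0, lifetime > 0)", call. = FALSE)
    cmp
  })
  period <- 1e3 / rep_rate
  dt <- period / n_bins
  edges <- seq(0, period, length.out = n_bins + 1)
  centres <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  if (is.null(irf_fwhm)) {
    mu <- Reduce(`+`, lapply(comp, function(cmp)
      wrapped_exp_bins(cmp[1], cmp[2], edges, period)))
  } else {
    sigma <- irf_fwhm / 2.354820045
    t0 <- period / 10
    mu <- Reduce(`+`, lapply(comp, function(cmp)
      irf_exp_density(centres, cmp[1], cmp[2], sigma, t0, period))) * dt
  }
  mu <- mu * n_photons / sum(mu)
  counts <- with_seed(seed, rpois(n_bins, mu))
  decay_histogram(centres, counts, rep_rate = rep_rate, irf_fwhm = irf_fwhm)
}

#' Simulate a z-scan over a ray-traced depth response
#'
#' Forward model of the surface+bulk signal: the detected intensity at
#' nominal depth \eqn{z_F} is proportional to
#' \eqn{H(z_F)\,(1 + K\phi(0,0)R_{th}(z_F))/(1 + K\phi(0,0))}, normalised
#' to `i0` at the interface, with multiplicative lognormal noise of the
#' requested coefficient of variation.  Per-depth amplitude-averaged
#' lifetimes mix the surface and bulk lifetimes with amplitude weights
#' proportional to intensity/lifetime of each species (excited-state
#' populations), the convention under which the monoexponential
#' lifetime-collapse relation is exact.
#'
#' @param depth_response A [trace_depth_response()] whose grid includes
#'   every requested depth and \eqn{z_F = 0}.
#' @param truth A [ground_truth()].
#' @param z_f Depths to simulate (um); defaults to the traced grid.
#' @param i0 Interface intensity scale (counts/s).
#' @return A [zscan_profile()] with intensities and lifetimes.
#' @export
simulate_zscan <- function(depth_response, truth, z_f = NULL, i0 = 1e5) {
  stopifnot(inherits(depth_response, "depth_response"),
            inherits(truth, "ground_truth"))
  if (is.null(z_f)) z_f <- depth_response$z_f_grid
  idx <- match(z_f, depth_response$z_f_grid)
  if (anyNA(idx))
    stop("depth response does not cover the requested z_F grid", call. = FALSE)
  if (anyNA(depth_response$r_th))
    stop("depth response lacks the z_F = 0 reference", call. = FALSE)
  p <- truth$photophysics
  kappa <- truth$k_true * depth_response$phi00
  r <- depth_response$r_th[idx]
  h <- depth_response$h_pred[idx]
  intensity <- i0 * h * (1 + kappa * r) / (1 + kappa)
  if (truth$noise_cv > 0) {
    sdlog <- sqrt(log(1 + truth$noise_cv^2))
    fac <- with_seed(truth$seed,
                     rlnorm(length(intensity), -sdlog^2 / 2, sdlog))
    intensity <- intensity * fac
  }
  # amplitude weights: excited-state populations I/tau per species
  tau <- (kappa * r + 1) / (kappa * r / p$tau_s + 1 / p$tau_b)
  zscan_profile(z_f, intensity, lifetime = tau,
                surface_kind = if (truth$sigma_true > 0) "hydrophobic" else "hydrophilic",
                wt_glycerol = truth$wt_glycerol,
                dye_concentration = truth$rho)
}

#' Adsorption trend used by the default synthetic study
#'
#' Interpolates a surface-density trend with the shape reported for a
#' cationic rotor on hydrophobic glass: strongest adsorption in pure water
#' (3300 um^-2), a plateau at intermediate glycerol content and a roughly
#' tenfold drop towards 99 wt%.
#'
#' @param wt_glycerol Mass percent glycerol; vectorised.
#' @return Surface density (um^-2).
#' @export
default_sigma_curve <- function(wt_glycerol) {
  approx(x = c(0, 10, 30, 60, 70, 99, 100),
         y = c(3300, 2000, 1500, 1500, 800, 330, 320),
         xout = wt_glycerol, rule = 2)$y
}

#' Generate a complete synthetic adsorption study
#'
#' For each solvent composition: derives viscosity, refractive index and
#' photophysics; ray-traces the depth response for that sample index;
#' simulates one hydrophobic (adsorbing, surface density from `sigma_curve`)
#' and one hydrophilic (non-adsorbing) z-scan; and simulates one bulk and
#' one surface TCSPC histogram.  Deterministic for a fixed seed.
#'
#' @param config A [microscope_config()]; its `n_sample` is overridden per
#'   solvent.
#' @param wt_list Solvent compositions (mass percent glycerol).
#' @param sigma_curve Function mapping wt% to the true adsorbed density
#'   (um^-2); defaults to [default_sigma_curve()].
#' @param z_f_grid Depths for the z-scans (um).
#' @param n_rays Rays per focus position for the ray tracing.
#' @param noise_cv Intensity noise level.
#' @param rho Dye concentration (mol/L).
#' @param n_photons Photons per decay histogram.
#' @param seed Integer seed.
#' @return A list of class `synthetic_study`, one element per composition,
#'   each with `wt_glycerol`, `eta`, `n_sample`, `truth`, `depth_response`,
#'   `hydrophobic`, `hydrophilic`, `decay_bulk` and `decay_surface`.
#' @export
generate_study <- function(config, wt_list, sigma_curve = default_sigma_curve,
                           z_f_grid = c(0, 1, 2, 3, 5, 7, 10, 15, 20, 30),
                           n_rays = 2e5, noise_cv = 0.01, rho = 1e-7,
                           n_photons = 1e5, seed = 1) {
  stopifnot(inherits(config, "microscope_config"))
  out <- vector("list", length(wt_list))
  for (i in seq_along(wt_list)) {
    wt <- wt_list[i]
    props <- solvent_properties(wt)
    p <- study_photophysics(wt)
    args <- unclass(config)
    args$n_sample <- props$n
    cfg <- do.call(microscope_config, args)
    dr <- trace_depth_response(cfg, z_f_grid = z_f_grid, n_rays = n_rays,
                               seed = seed + 101 * i)
    truth_o <- ground_truth(sigma_curve(wt), rho = rho, photophysics = p,
                            wt_glycerol = wt, noise_cv = noise_cv,
                            seed = seed + 101 * i + 1)
    truth_i <- ground_truth(0, rho = rho, photophysics = p, wt_glycerol = wt,
                            noise_cv = noise_cv, seed = seed + 101 * i + 2)
    # bulk decay: two components whose amplitude-averaged lifetime is tau_b
    decay_bulk <- simulate_decay(list(c(0.5, 0.7 * p$tau_b), c(0.5, 1.3 * p$tau_b)),
                                 n_photons = n_photons,
                                 seed = seed + 101 * i + 3)
    decay_surface <- simulate_decay(list(c(1, p$tau_s)),
                                    n_photons = n_photons,
                                    seed = seed + 101 * i + 4)
    out[[i]] <- list(wt_glycerol = wt, eta = props$eta, n_sample = props$n,
                     truth = truth_o,
                     depth_response = dr,
                     hydrophobic = simulate_zscan(dr, truth_o),
                     hydrophilic = simulate_zscan(dr, truth_i),
                     decay_bulk = decay_bulk,
                     decay_surface = decay_surface)
  }
  structure(out, class = "synthetic_study")
}
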