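# molecules per um^3 for a 1 M solution (Avogadro / 1e15 um^3 per litre)
MOLAR_TO_PER_UM3 <- 6.02214076e8

#' Confocal z-scan profile
#'
#' Detected intensity (and optionally amplitude-averaged lifetime) versus
#' nominal focus depth for one surface/solvent condition.
#'
#' @param z_f Strictly increasing nominal focus depths (um); must include 0
#'   (the interface), where the profile is anchored.
#' @param intensity Detected signal (counts/s), non-negative.
#' @param lifetime Optional amplitude-averaged lifetime per depth (ns).
#' @param surface_kind `"hydrophobic"` or `"hydrophilic"`.
#' @param wt_glycerol Solvent composition, mass percent glycerol.
#' @param dye_concentration Dye concentration (mol/L).
#' @return An object of class `zscan_profile`.
#' @export
zscan_profile <- function(z_f, intensity, lifetime = NULL,
                          surface_kind = c("hydrophobic", "hydrophilic"),
                          wt_glycerol = NA_real_,
                          dye_concentration = NA_real_) {
  surface_kind <- match.arg(surface_kind)
  z_f <- as.numeric(z_f); intensity <- as.numeric(intensity)
  if (length(z_f) != length(intensity))
    stop("'z_f' and 'intensity' lengths differ", call. = FALSE)
  if (any(diff(z_f) <= 0))
    stop("'z_f' must be strictly increasing", call. = FALSE)
  if (!any(z_f == 0))
    stop("'z_f' must include 0 (the interface anchor)", call. = FALSE)
  if (any(intensity < 0)) stop("'intensity' must be non-negative", call. = FALSE)
  if (!is.null(lifetime)) {
    lifetime <- as.numeric(lifetime)
    if (length(lifetime) != length(z_f))
      stop("'lifetime' length differs from 'z_f'", call. = FALSE)
    if (any(lifetime <= 0)) stop("'lifetime' must be positive", call. = FALSE)
  }
  structure(list(z_f = z_f, intensity = intensity, lifetime = lifetime,
                 surface_kind = surface_kind, wt_glycerol = wt_glycerol,
                 dye_concentration = dye_concentration),
            class = "zscan_profile")
}

#' @export
print.zscan_profile <- function(x, ...) {
  cat(sprintf("z-scan profile: %d depths (%g-%g um), %s surface",
              length(x$z_f), min(x$z_f), max(x$z_f), x$surface_kind))
  if (!is.na(x$wt_glycerol)) cat(sprintf(", %g wt%% glycerol", x$wt_glycerol))
  cat("\n")
  if (!is.null(x$lifetime)) cat("  includes per-depth amplitude-averaged lifetimes\n")
  invisible(x)
}

#' Photophysical parameters of the bulk and adsorbed species
#'
#' @param eps_ratio Extinction-coefficient ratio of surface to bulk species,
#'   \eqn{\epsilon_S/\epsilon_B}; defaults to 1 (the extinction coefficient
#'   reflects the ground-state conformation, which adsorption barely
#'   perturbs).
#' @param phi_b Bulk fluorescence quantum yield \eqn{\Phi_B}.
#' @param phi_s Surface quantum yield \eqn{\Phi_S}; defaults to 0.15, the
#'   value at which bulk and interface lifetimes extrapolate to a common
#'   point on the viscosity axis.
#' @param tau_b Bulk amplitude-averaged lifetime (ns).
#' @param tau_s Surface lifetime (ns).
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(phi_b, tau_b, tau_s,
                                phi_s = 0.15, eps_ratio = 1) {
  vals <- c(eps_ratio = eps_ratio, phi_b = phi_b, phi_s = phi_s,
            tau_b = tau_b, tau_s = tau_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all photophysical parameters must be positive and finite", call. = FALSE)
  if (phi_b > 1 || phi_s > 1)
    stop("quantum yields must not exceed 1", call. = FALSE)
  structure(as.list(vals), class = "photophysics_params")
}

#' @export
print.photophysics_params <- function(x, ...) {
  cat(sprintf(paste0("photophysics: Phi_B = %.3g, Phi_S = %.3g, ",
                     "tau_B = %.3g ns, tau_S = %.3g ns, eps_S/eps_B = %.3g\n"),
              x$phi_b, x$phi_s, x$tau_b, x$tau_s, x$eps_ratio))
  invisible(x)
}

#' Normalise a z-scan profile to its interface value
#'
#' Divides the intensity by its value at \eqn{z_F = 0}, yielding
#' \eqn{H(z_F)} for a homogeneous reference scan or \eqn{I_N(z_F)} for a
#' sample scan (surface + bulk).
#'
#' @param profile A [zscan_profile()].
#' @param mode `"homogeneous"` (bulk-only reference) or `"sample"`; recorded
#'   in the result for bookkeeping, the arithmetic is identical.
#' @return A data frame with columns `z_f` and `value`, with `value[z_f==0] == 1`.
#' @examples
#' p <- zscan_profile(c(0, 5, 10), c(50, 60, 70))
#' normalize_profile(p, "homogeneous")$value  # 1.0 1.2 1.4
#' @export
normalize_profile <- function(profile, mode = c("homogeneous", "sample")) {
  mode <- match.arg(mode)
  stopifnot(inherits(profile, "zscan_profile"))
  anchor <- profile$intensity[profile$z_f == 0]
  if (anchor <= 0)
    stop("intensity at z_F = 0 must be strictly positive to normalise", call. = FALSE)
  out <- data.frame(z_f = profile$z_f, value = profile$intensity / anchor)
  attr(out, "mode") <- mode
  out
}

#' Surface-contribution ratio U(z_F) = I_N / H
#'
#' Dividing the normalised sample scan by the normalised homogeneous
#' reference cancels the bulk response and isolates the surface term:
#' for a noiseless scan with adsorption, U decreases from 1 at the
#' interface towards the asymptote \eqn{U_\infty = (1 + \phi(0,0) K)^{-1}}.
#' Noise can push U above 1; such values are flagged with a warning but not
#' clipped.
#'
#' @param i_n Normalised sample curve (data frame `z_f`, `value`), from
#'   [normalize_profile()].
#' @param h Normalised homogeneous curve on the same depth grid.
#' @return A data frame with columns `z_f` and `u`.
#' @export
compute_U <- function(i_n, h) {
  if (!identical(as.numeric(i_n$z_f), as.numeric(h$z_f)))
    stop("depth grids of the sample and homogeneous curves differ", call. = FALSE)
  if (abs(i_n$value[i_n$z_f == 0] - 1) > 1e-12 ||
      abs(h$value[h$z_f == 0] - 1) > 1e-12)
    stop("both curves must be normalised to 1 at z_F = 0", call. = FALSE)
  u <- i_n$value / h$value
  n_above <- sum(u > 1 + 1e-12)
  if (n_above > 0)
    warning(sprintf("U exceeds 1 at %d depth(s); expected for noisy data, not clipped",
                    n_above), call. = FALSE)
  data.frame(z_f = i_n$z_f, u = u)
}

#' Surface-to-bulk brightness ratio K from U(z_F)
#'
#' Per-depth estimates \eqn{K_i = (1 - U_i)/(\phi(0,0)\, U_i)} from the
#' far-field asymptote of the surface+bulk signal model, summarised as a
#' mean and standard deviation over the chosen depths.  When the ray-traced
#' interface contribution `r_th` at those depths is supplied, the exact
#' inversion \eqn{K_i = (1 - U_i) / (\phi(0,0)(U_i - R_{th,i}))} is used
#' instead, which removes the residual bulk term at shallow depths; with
#' `weighting = "ivar"` the per-depth estimates are combined with
#' delta-method inverse-variance weights (appropriate for multiplicative
#' intensity noise), which matters when the surface dominates the signal.
#'
#' U values above 1 (noise) are mapped to \eqn{K_i = 0} with a warning.
#'
#' @param u U curve (data frame `z_f`, `u`) from [compute_U()].
#' @param phi00 Detection density at the interface, \eqn{\phi(0,0)} (um^-1).
#' @param depths Depths (um) at which to evaluate K; all must be present in
#'   `u$z_f`.  Default: 5, 7, 10, 20 and 30 um.
#' @param r_th Optional interface-contribution values \eqn{R_{th}(z_i)} at
#'   `depths` (same order), from [predict_Rth()].
#' @param weighting `"uniform"` (plain mean and sd) or `"ivar"`.
#' @return A list with `k` (um), `sd` (um), `k_i` (per-depth estimates) and
#'   `depths`.
#' @examples
#' u <- data.frame(z_f = c(0, 5, 10), u = c(1, 0.5, 0.5))
#' estimate_K(u, phi00 = 0.2, depths = c(5, 10))$k  # 5
#' @export
estimate_K <- function(u, phi00, depths = c(5, 7, 10, 20, 30),
                       r_th = NULL, weighting = c("uniform", "ivar")) {
  weighting <- match.arg(weighting)
  if (length(depths) == 0) stop("'depths' must be non-empty", call. = FALSE)
  if (!(phi00 > 0)) stop("'phi00' must be positive", call. = FALSE)
  idx <- match(depths, u$z_f)
  if (anyNA(idx))
    stop("depths absent from the U curve: ",
         paste(depths[is.na(idx)], collapse = ", "), call. = FALSE)
  ui <- u$u[idx]
  if (any(ui == 0)) stop("U = 0 at a chosen depth: K undefined", call. = FALSE)
  if (any(ui < 0)) stop("negative U: malformed input", call. = FALSE)
  if (!is.null(r_th)) {
    if (length(r_th) != length(depths))
      stop("'r_th' must match 'depths' in length", call. = FALSE)
    denom <- ui - r_th
    one_minus_r <- 1 - r_th
  } else {
    denom <- ui
    one_minus_r <- rep(1, length(ui))
  }
  k_i <- (1 - ui) / (phi00 * denom)
  bad <- ui > 1 | denom <= 0
  if (any(bad)) {
    warning(sprintf("U > 1 (or below R_th) at %d depth(s); treating as K = 0 there",
                    sum(bad)), call. = FALSE)
    k_i[bad] <- 0
  }
  if (weighting == "ivar" && length(k_i) > 1) {
    # delta method under multiplicative noise: sd(K_i)/K propto
    # u (1 - r) / ((u - r)(1 - u)); weights are the inverse squares
    rel <- ui * one_minus_r / (pmax(denom, 1e-12) * pmax(1 - ui, 1e-12))
    wgt <- 1 / rel^2
    wgt[bad] <- 0
    if (sum(wgt) == 0) wgt <- rep(1, length(k_i))
    k <- sum(wgt * k_i) / sum(wgt)
    v <- sum(wgt * (k_i - k)^2) / sum(wgt)
    n_eff <- sum(wgt)^2 / sum(wgt^2)
    s <- sqrt(v * n_eff / max(n_eff - 1, 1))
  } else {
    k <- mean(k_i)
    s <- if (length(k_i) > 1) sd(k_i) else 0
  }
  list(k = k, sd = s, k_i = k_i, depths = depths)
}

#' Adsorbed surface density from the brightness ratio
#'
#' Inverts \eqn{K = \sigma \epsilon_S \Phi_S / (\rho \epsilon_B \Phi_B)}:
#' \eqn{\sigma = K \rho\, (\Phi_B/\Phi_S) / (\epsilon_S/\epsilon_B)}, with
#' the molar concentration converted to molecules per um^3
#' (1 M = 6.02214e8 um^-3).  The uncertainty on K propagates linearly.
#'
#' @param k Brightness ratio K (um).
#' @param rho_molar Bulk dye concentration (mol/L).
#' @param p A [photophysics_params()].
#' @param k_sd Standard deviation of K (um).
#' @return A list with `sigma` (um^-2), `sigma_sd` (um^-2) and `rho`
#'   (molecules um^-3).
#' @examples
#' p <- photophysics_params(phi_b = 0.15, tau_b = 1, tau_s = 1.7, phi_s = 0.15)
#' sigma_from_K(1, 1e-7, p)$sigma  # 60.22 um^-2
#' @export
sigma_from_K <- function(k, rho_molar, p, k_sd = 0) {
  stopifnot(inherits(p, "photophysics_params"))
  if (k < 0 || k_sd < 0) stop("'k' and 'k_sd' must be non-negative", call. = FALSE)
  if (!(rho_molar > 0)) stop("'rho_molar' must be positive", call. = FALSE)
  rho <- rho_molar * MOLAR_TO_PER_UM3
  fac <- rho * (p$phi_b / p$phi_s) / p$eps_ratio
  list(sigma = k * fac, sigma_sd = k_sd * fac, rho = rho)
}

#' Lifetime data collapse R_tau(z_F)
#'
#' Rescales an amplitude-averaged lifetime profile to the interval [0, 1]:
#' \eqn{R_\tau(z_F) = (\langle\tau\rangle(z_F) - \tau_B) /
#' (\langle\tau\rangle(0) - \tau_B)}.  Profiles for different solvent
#' compositions collapse onto the ray-traced interface contribution
#' \eqn{R_{th}} when a surface species is present.
#'
#' @param lifetime_profile Data frame with columns `z_f` (um) and `tau` (ns),
#'   or a [zscan_profile()] carrying lifetimes.
#' @param tau_b Bulk amplitude-averaged lifetime (ns).
#' @return A data frame with columns `z_f` and `r_tau`.
#' @export
collapse_Rtau <- function(lifetime_profile, tau_b) {
  if (inherits(lifetime_profile, "zscan_profile")) {
    if (is.null(lifetime_profile$lifetime))
      stop("profile carries no lifetimes", call. = FALSE)
    lifetime_profile <- data.frame(z_f = lifetime_profile$z_f,
                                   tau = lifetime_profile$lifetime)
  }
  tau0 <- lifetime_profile$tau[lifetime_profile$z_f == 0]
  if (length(tau0) != 1)
    stop("lifetime profile must include z_F = 0", call. = FALSE)
  if (abs(tau0 - tau_b) < 1e-8 * max(tau_b, 1))
    stop("interface lifetime equals the bulk lifetime: no detectable surface species",
         call. = FALSE)
  data.frame(z_f = lifetime_profile$z_f,
             r_tau = (lifetime_profile$tau - tau_b) / (tau0 - tau_b))
}

#' Monoexponential relation between R_th and R_tau
#'
#' For monoexponential surface and bulk decays, the theoretical and
#' lifetime-based interface contributions are linked by
#' \deqn{R_{th}/R_\tau = \phi(0,0)^{-1} / (\phi(0,0)^{-1} +
#'   (\tau_B/\tau_S) K (1 - R_\tau)).}
#' Returns that ratio, so `r_tau$r_tau * mono_ratio(...)` reconstructs
#' \eqn{R_{th}}.
#'
#' @param r_tau Data frame `z_f`, `r_tau` from [collapse_Rtau()].
#' @param k Brightness ratio K (um).
#' @param phi00 Detection density at the interface (um^-1).
#' @param p A [photophysics_params()] providing `tau_b` and `tau_s`.
#' @return A data frame with columns `z_f` and `ratio`.
#' @export
mono_ratio <- function(r_tau, k, phi00, p) {
  stopifnot(inherits(p, "photophysics_params"))
  if (k < 0) stop("'k' must be non-negative", call. = FALSE)
  if (!(phi00 > 0)) stop("'phi00' must be positive", call. = FALSE)
  ratio <- (1 / phi00) /
    (1 / phi00 + (p$tau_b / p$tau_s) * k * (1 - r_tau$r_tau))
  data.frame(z_f = r_tau$z_f, ratio = ratio)
}

#' Adsorbed-to-bulk molecule ratio in a tube
#'
#' For a solution at bulk number density \eqn{\rho} in equilibrium with a
#' wall coverage \eqn{\sigma} in a tube of radius r, the ratio of adsorbed
#' to free molecules is \eqn{N_{ads}/N_{bulk} = 2\sigma/(r\rho)}.
#'
#' @param sigma Surface density (um^-2).
#' @param rho_molar Bulk concentration (mol/L).
#' @param radius Tube radius (um).
#' @return Dimensionless ratio.
#' @examples
#' # 1% monolayer coverage, 1 uM dye, 200 um diameter tube:
#' tube_partition_ratio(1e4, 1e-6, 100)  # ~0.33
#' @export
tube_partition_ratio <- function(sigma, rho_molar, radius) {
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  if (!(rho_molar > 0)) stop("'rho_molar' must be positive", call. = FALSE)
  if (!(radius > 0)) stop("'radius' must be positive", call. = FALSE)
  2 * sigma / (radius * rho_molar * MOLAR_TO_PER_UM3)
}

#' Monolayer coverage fraction
#'
#' @param sigma Surface density (um^-2).
#' @param s_mol Molecular footprint (nm^2); ~1 nm^2 for a small dye.
#' @return Dimensionless coverage fraction (\eqn{\sigma s_{mol}}).
#' @examples
#' coverage_fraction(3300)  # 0.0033, i.e. ~0.3% of a monolayer
#' @export
coverage_fraction <- function(sigma, s_mol = 1) {
  if (sigma < 0 || s_mol < 0) stop("inputs must be non-negative", call. = FALSE)
  sigma * s_mol * 1e-6 # nm^2 -> um^2
}
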