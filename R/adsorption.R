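#' Fit the surface+bulk adsorption model to a z-scan
#'
#' The central estimator of the package.  A z-scan of a sample with both a
#' physisorbed surface sheet and a homogeneous bulk solution is divided by a
#' bulk-only reference (a measured homogeneous/hydrophilic scan, or the
#' ray-traced prediction), giving the surface-contribution ratio
#' \eqn{U(z_F)}.  The surface-to-bulk brightness ratio \eqn{K} is estimated
#' per depth from U and \eqn{\phi(0,0)} and converted to the adsorbed
#' surface density \eqn{\sigma} using the photophysics of both species.
#'
#' When a [trace_depth_response()] object is supplied, the per-depth
#' estimates use the exact inversion of the signal model (accounting for the
#' residual interface contribution \eqn{R_{th}(z_i)} at finite depth) with
#' inverse-variance weights; otherwise the far-field asymptote estimator
#' \eqn{K_i = (1-U_i)/(\phi(0,0) U_i)} with an unweighted mean is used.
#'
#' @param sample A [zscan_profile()] of the adsorbing (hydrophobic) surface.
#' @param reference Optional bulk-only [zscan_profile()] on the same depth
#'   grid (homogeneous solution / non-adsorbing surface).  If `NULL`, the
#'   ray-traced `h_pred` from `depth_response` is used.
#' @param depth_response Optional [trace_depth_response()] covering the
#'   sample depths; supplies `phi00`, `r_th` and (if needed) the predicted H.
#' @param photophysics A [photophysics_params()].
#' @param rho_molar Bulk dye concentration (mol/L).
#' @param depths Depths (um) at which K is evaluated (default 5, 7, 10, 20,
#'   30 um); must be present in the sample grid.
#' @param phi00 Detection density at the interface (um^-1); overrides the
#'   value carried by `depth_response`.
#' @param smooth If `TRUE`, apply a centred moving average of width 3 to
#'   both normalised curves before forming U (off by default; no smoothing
#'   is the reference behaviour).
#' @return An object of class `adsorption_fit` with components `k_value` and
#'   `k_sd` (um), `u_inf`, `sigma` and `sigma_sd` (um^-2), `k_i`,
#'   `depths_used`, `phi00_used`, `rho` (molecules um^-3), the U curve `u`,
#'   `h_source` (`"measured"` or `"ray-traced"`) and the inputs used.
#' @seealso [estimate_K()], [sigma_from_K()], [simulate_zscan()]
#' @export
fit_adsorption <- function(sample, reference = NULL, depth_response = NULL,
                           photophysics, rho_molar,
                           depths = c(5, 7, 10, 20, 30),
                           phi00 = NULL, smooth = FALSE) {
  stopifnot(inherits(sample, "zscan_profile"),
            inherits(photophysics, "photophysics_params"))
  if (is.null(reference) && is.null(depth_response))
    stop(paste("no bulk reference: provide a measured homogeneous scan",
               "('reference') or a ray-traced prediction ('depth_response')"),
         call. = FALSE)
  if (is.null(phi00)) {
    if (is.null(depth_response))
      stop("'phi00' must be given when no depth response is supplied", call. = FALSE)
    phi00 <- depth_response$phi00
  }
  if (is.na(phi00) || !(phi00 > 0))
    stop("'phi00' must be a positive density (um^-1)", call. = FALSE)

  i_n <- normalize_profile(sample, "sample")
  if (!is.null(reference)) {
    h <- normalize_profile(reference, "homogeneous")
    h_source <- "measured"
  } else {
    if (anyNA(depth_response$h_pred))
      stop("depth response lacks the z_F = 0 slice needed to predict H", call. = FALSE)
    hv <- approx(depth_response$z_f_grid, depth_response$h_pred,
                 xout = sample$z_f, rule = 1)$y
    if (anyNA(hv))
      stop("depth response does not cover the sample depth grid", call. = FALSE)
    h <- data.frame(z_f = sample$z_f, value = hv)
    h_source <- "ray-traced"
  }
  if (smooth) {
    i_n$value <- moving_average3(i_n$value)
    h$value <- moving_average3(h$value)
  }
  u <- compute_U(i_n, h)

  if (!is.null(depth_response)) {
    r_th <- approx(depth_response$z_f_grid, depth_response$r_th,
                   xout = depths, rule = 1)$y
    if (anyNA(r_th))
      stop("depth response does not cover the requested depths", call. = FALSE)
    kest <- estimate_K(u, phi00, depths, r_th = r_th, weighting = "ivar")
  } else {
    kest <- estimate_K(u, phi00, depths)
  }
  sig <- sigma_from_K(max(kest$k, 0), rho_molar, photophysics, kest$sd)

  structure(list(k_value = kest$k,
                 k_sd = kest$sd,
                 k_i = kest$k_i,
                 u_inf = 1 / (1 + phi00 * max(kest$k, 0)),
                 sigma = sig$sigma,
                 sigma_sd = sig$sigma_sd,
                 rho = sig$rho,
                 depths_used = depths,
                 phi00_used = phi00,
                 h_source = h_source,
                 u = u,
                 photophysics = photophysics,
                 rho_molar = rho_molar,
                 sample = sample,
                 call = match.call()),
            class = "adsorption_fit")
}

# centred moving average of width 3, endpoints kept
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  out
}

#' @export
print.adsorption_fit <- function(x, ...) {
  cat("Surface adsorption fit (z-scan surface+bulk model)\n")
  cat(sprintf("  K       = %.4g +/- %.2g um (surface/bulk brightness ratio)\n",
              x$k_value, x$k_sd))
  cat(sprintf("  U_inf   = %.4g   (phi(0,0) = %.3g um^-1, H: %s)\n",
              x$u_inf, x$phi00_used, x$h_source))
  cat(sprintf("  sigma   = %.4g +/- %.2g um^-2 (%.3g%% of a monolayer at 1 nm^2)\n",
              x$sigma, x$sigma_sd, 100 * coverage_fraction(max(x$sigma, 0))))
  invisible(x)
}

#' @export
summary.adsorption_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.adsorption_fit")
}

#' @export
print.summary.adsorption_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  bulk: %.3g M (%.4g molecules um^-3)\n", f$rho_molar, f$rho))
  print(f$photophysics)
  tab <- data.frame(z_f = f$depths_used,
                    U = f$u$u[match(f$depths_used, f$u$z_f)],
                    K_i = f$k_i)
  cat("  per-depth estimates:\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.adsorption_fit <- function(object, ...) {
  c(K = object$k_value, sigma = object$sigma, u_inf = object$u_inf)
}

#' @param x An `adsorption_fit`.
#' @param ... Further plot arguments.
#' @rdname fit_adsorption
#' @export
plot.adsorption_fit <- function(x, ...) {
  plot(x$u$z_f, x$u$u, type = "b", xlab = expression(z[F] ~ "(um)"),
       ylab = "U", ...)
  abline(h = x$u_inf, lty = 2)
  points(x$depths_used, x$u$u[match(x$depths_used, x$u$z_f)],
         pch = 19, col = 2)
  legend("topright", bty = "n",
         legend = c("U(z_F)", "depths used", expression(U[infinity])),
         pch = c(1, 19, NA), lty = c(1, NA, 2), col = c(1, 2, 1))
  invisible(x)
}
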