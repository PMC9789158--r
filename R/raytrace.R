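#' Default axial bin edges for the depth response
#'
#' Slices of 0.25 um near the interface and focal region, widening
#' geometrically (factor 1.08) far beyond the deepest caustic, where the
#' profile follows its smooth far-field decay.  The grid starts at 0 and
#' extends to at least three times the deepest nominal focus, so that the
#' analytic `1/z^2` tail correction used for normalisation stays below the
#' percent level.
#'
#' @param z_f_max Deepest nominal focus depth to be traced (um).
#' @return Numeric vector of bin edges (um), starting at 0.
#' @export
default_z_grid <- function(z_f_max) {
  stopifnot(is.numeric(z_f_max), length(z_f_max) == 1L, z_f_max >= 0)
  z_unif <- max(20, 1.8 * z_f_max + 10)
  z_max <- max(150, 3 * z_f_max + 50)
  edges <- seq(0, z_unif, by = 0.25)
  wid <- 0.25
  while (edges[length(edges)] < z_max) {
    wid <- wid * 1.08
    edges <- c(edges, edges[length(edges)] + wid)
  }
  edges
}

#' Monte Carlo ray-traced confocal depth response
#'
#' Computes the probability density \eqn{\phi(z \mid z_F)} that a detected
#' photon from a homogeneous sample originates from depth \eqn{z} when the
#' nominal focus (stage readout) is at depth \eqn{z_F}, by Monte Carlo
#' geometric-optics ray tracing.  Excitation rays are sampled uniformly over
#' the pupil area, aimed at the nominal focus, and refracted by Snell's law
#' at the coverslip/sample interface; detection is reverse-traced from
#' emitter positions through the interface and an ideal sine-condition
#' objective onto the pinhole.  Each axial profile is normalised over depth
#' including an analytic \eqn{1/z^2} far-field tail beyond the grid.
#'
#' @param config A [microscope_config()].
#' @param z_f_grid Strictly increasing nominal focus depths (um).  Include 0
#'   to obtain `phi00`, `r_th` and `h_pred`.
#' @param z_grid Strictly increasing axial bin edges (um) starting at 0, or
#'   `NULL` for [default_z_grid()].
#' @param n_rays Excitation rays per focus position (>= 1e4).
#' @param n_det Detection rays per (r, z) grid cell.
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical results.
#' @return An object of class `depth_response`: a list with `z_f_grid`,
#'   `z_grid` (bin centres, um), `z_edges`, `phi` (matrix, rows = depths,
#'   columns = focus positions, um^-1), `phi00` (um^-1), `r_th`, `h_pred`,
#'   `totals` (raw per-ray signal, arbitrary units), `tail_c` (normalised
#'   far-field coefficients: beyond the grid, phi is approximately
#'   `tail_c/z^2`, so the analytic tail mass is `tail_c/max(z_edges)`), `n_rays`,
#'   `n_det`, `seed` and `config`.
#' @examples
#' \donttest{
#' cfg <- microscope_config()
#' dr <- trace_depth_response(cfg, z_f_grid = c(0, 5, 10), n_rays = 2e4)
#' dr$phi00
#' }
#' @export
trace_depth_response <- function(config, z_f_grid, z_grid = NULL,
                                 n_rays = 1e6, n_det = 256, seed = 1) {
  stopifnot(inherits(config, "microscope_config"))
  if (length(z_f_grid) < 1 || any(diff(z_f_grid) <= 0) || any(z_f_grid < 0))
    stop("'z_f_grid' must be non-negative and strictly increasing", call. = FALSE)
  if (is.null(z_grid)) z_grid <- default_z_grid(max(z_f_grid))
  if (z_grid[1] != 0) stop("'z_grid' must start at 0", call. = FALSE)
  if (any(diff(z_grid) <= 0))
    stop("'z_grid' must be strictly increasing", call. = FALSE)
  if (n_rays < 1e4) stop("'n_rays' must be at least 1e4", call. = FALSE)
  if (diff(z_grid)[1] > 0.25)
    stop("first axial slice must be at most 0.25 um wide", call. = FALSE)

  res <- .rt_trace_cpp(na = config$na,
                       n_immersion = config$n_immersion,
                       n_sample = config$n_sample,
                       pinhole_radius_obj = pinhole_radius_object(config),
                       aberration_free = isTRUE(config$design_aberration_free),
                       zf_grid = as.numeric(z_f_grid),
                       z_edges = as.numeric(z_grid),
                       n_rays = as.integer(n_rays),
                       n_det = as.integer(n_det),
                       dr = 0.1,
                       seed = as.integer(seed))

  centres <- (z_grid[-1] + z_grid[-length(z_grid)]) / 2
  i0 <- match(0, z_f_grid)
  phi <- res$phi
  surface <- phi[1, ] # density of the first slice (width <= 0.25 um)
  if (!is.na(i0)) {
    phi00 <- surface[i0]
    r_th <- surface / phi00
    h_pred <- res$totals / res$totals[i0]
  } else {
    phi00 <- NA_real_
    r_th <- rep(NA_real_, length(z_f_grid))
    h_pred <- rep(NA_real_, length(z_f_grid))
  }

  structure(list(z_f_grid = as.numeric(z_f_grid),
                 z_grid = centres,
                 z_edges = as.numeric(z_grid),
                 phi = phi,
                 phi00 = phi00,
                 r_th = r_th,
                 h_pred = h_pred,
                 totals = res$totals,
                 tail_c = res$tail_c,
                 n_rays = n_rays,
                 n_det = n_det,
                 seed = seed,
                 config = config),
            class = "depth_response")
}

#' @export
print.depth_response <- function(x, ...) {
  cat("Confocal depth response (Monte Carlo ray tracing)\n")
  cat(sprintf("  %d focus positions (%.3g-%.3g um), %d axial slices to %.3g um\n",
              length(x$z_f_grid), min(x$z_f_grid), max(x$z_f_grid),
              length(x$z_grid), max(x$z_edges)))
  cat(sprintf("  n_rays = %g per focus, n_det = %d, seed = %d\n",
              x$n_rays, x$n_det, x$seed))
  if (!is.na(x$phi00))
    cat(sprintf("  phi(0,0) = %.4g um^-1\n", x$phi00))
  invisible(x)
}

#' @param x A `depth_response`.
#' @param which Either `"phi"` (axial densities for a few focus positions)
#'   or `"rth"` (normalised interface contribution vs focus depth).
#' @param ... Passed to the underlying plotting functions.
#' @rdname trace_depth_response
#' @export
plot.depth_response <- function(x, which = c("phi", "rth"), ...) {
  which <- match.arg(which)
  if (which == "phi") {
    sel <- unique(round(seq(1, length(x$z_f_grid), length.out = min(5, length(x$z_f_grid)))))
    graphics::matplot(x$z_grid, x$phi[, sel, drop = FALSE], type = "l", lty = 1,
                      xlab = expression(z ~ "(um)"),
                      ylab = expression(phi(z ~ "|" ~ z[F]) ~ "(um"^-1 * ")"), ...)
    legend("topright", legend = sprintf("z_F = %g um", x$z_f_grid[sel]),
           col = seq_along(sel), lty = 1, bty = "n")
  } else {
    plot(x$z_f_grid, x$r_th, type = "b", xlab = expression(z[F] ~ "(um)"),
         ylab = expression(R[th]), ...)
  }
  invisible(x)
}

#' Detection density at the interface with the focus at the interface
#'
#' \eqn{\phi(0,0)}, the value at \eqn{z = 0} of the normalised axial
#' detection density when the nominal focus sits on the interface.  This is
#' the one model quantity in the brightness-ratio estimator that is not
#' accessible to experiment.  The density is read from the first axial slice
#' (width 0.25 um by default, always <= 0.25 um).
#'
#' @inheritParams trace_depth_response
#' @return Scalar density (um^-1).
#' @export
phi00 <- function(config, n_rays = 1e6, seed = 1) {
  dr <- trace_depth_response(config, z_f_grid = 0, n_rays = n_rays, seed = seed)
  dr$phi00
}

#' Predicted homogeneous-solution signal rise H(z_F)
#'
#' Normalised signal from a homogeneous dye solution as the focus plunges
#' into it, \eqn{H(z_F) = I_H(z_F)/I_H(0)}.  In index-matched mode
#' (`design_aberration_free = TRUE`) H rises monotonically from 1 towards 2;
#' with refractive-index mismatch it may peak and decline.
#'
#' @inheritParams trace_depth_response
#' @return A data frame with columns `z_f` and `H`.
#' @export
predict_H <- function(config, z_f_grid, n_rays = 1e6, seed = 1) {
  if (!any(z_f_grid == 0))
    stop("'z_f_grid' must include 0: H is normalised to the interface", call. = FALSE)
  dr <- trace_depth_response(config, z_f_grid = z_f_grid, n_rays = n_rays, seed = seed)
  data.frame(z_f = dr$z_f_grid, H = dr$h_pred)
}

#' Normalised interface contribution R_th(z_F)
#'
#' \eqn{R_{th}(z_F) = \phi(0, z_F)/\phi(0, 0)}: the detection density of the
#' surface slice as the focus moves away from the interface, normalised to
#' its value at surface focus.  Decays as \eqn{1/z_F^2} in the far field.
#'
#' @param depth_response A [trace_depth_response()] result whose `z_f_grid`
#'   includes 0.
#' @return A data frame with columns `z_f` and `r_th`.
#' @export
predict_Rth <- function(depth_response) {
  stopifnot(inherits(depth_response, "depth_response"))
  if (anyNA(depth_response$r_th))
    stop("depth response lacks the z_F = 0 reference slice", call. = FALSE)
  data.frame(z_f = depth_response$z_f_grid, r_th = depth_response$r_th)
}

# Normalise a sampled axial profile A(z) over bins with edges `z_edges`,
# applying the same analytic 1/z^2 tail correction as the ray tracer: the
# far-field coefficient is fitted on the outer 40% of the grid and the tail
# integral c/z_end added to the normalisation.  Returns densities (um^-1).
normalize_axial_profile <- function(A, z_edges) {
  n <- length(z_edges) - 1L
  stopifnot(length(A) == n)
  zc <- (z_edges[-1] + z_edges[-(n + 1)]) / 2
  w <- diff(z_edges)
  z_end <- z_edges[n + 1]
  sel <- zc >= 0.6 * z_end
  cc <- sum(A[sel] * zc[sel]^2 * w[sel]) / sum(w[sel])
  total <- sum(A * w) + cc / z_end
  A / total
}
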