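#' Confocal microscope configuration
#'
#' Bundles the optical geometry and refractive indices that define the
#' ray-traced depth response.  Defaults describe a 20x dry objective of
#' NA 0.75 with a 56.6 um pinhole and a #1.5H coverslip (170 um, n = 1.523)
#' over an aqueous sample.
#'
#' The objective is assumed perfectly corrected for the design coverslip, so
#' the only aberration source in the ray-tracing model is the refraction
#' step at the coverslip/sample interface.  Setting
#' `design_aberration_free = TRUE` suppresses that step ("index-matched"
#' mode): rays proceed unrefracted into the sample.
#'
#' @param na Numerical aperture.  Must satisfy
#'   `0 < na < min(n_coverslip, n_sample)` so that every aperture ray
#'   refracts into the sample without total internal reflection (NA may
#'   exceed `n_immersion` is *not* allowed for the dry objectives modelled
#'   here).
#' @param magnification Lateral magnification (> 1).
#' @param pinhole_diameter Pinhole diameter at the image plane (um).
#' @param wavelength_ex,wavelength_em Excitation/emission wavelengths (nm).
#'   Kept as metadata; the geometric-optics model is achromatic.
#' @param n_immersion Immersion refractive index (1.0 for a dry objective).
#' @param n_coverslip,coverslip_thickness Coverslip refractive index and
#'   thickness (um); the objective is assumed corrected for these.
#' @param n_sample Sample refractive index.
#' @param design_aberration_free If `TRUE`, disable refraction at the
#'   coverslip/sample interface (index-matched mode).
#' @return An object of class `microscope_config`.
#' @examples
#' cfg <- microscope_config()
#' cfg
#' # pinhole radius conjugated into object space:
#' cfg$pinhole_diameter / (2 * cfg$magnification)
#' @export
microscope_config <- function(na = 0.75,
                              magnification = 20,
                              pinhole_diameter = 56.6,
                              wavelength_ex = 470,
                              wavelength_em = 600,
                              n_immersion = 1.0,
                              n_coverslip = 1.523,
                              coverslip_thickness = 170,
                              n_sample = 1.333,
                              design_aberration_free = FALSE) {
  stopifnot(is.numeric(na), length(na) == 1L,
            is.numeric(magnification), length(magnification) == 1L,
            is.numeric(pinhole_diameter), length(pinhole_diameter) == 1L,
            is.logical(design_aberration_free), length(design_aberration_free) == 1L)
  if (!(na > 0)) stop("'na' must be positive", call. = FALSE)
  if (magnification <= 1) stop("'magnification' must exceed 1", call. = FALSE)
  if (pinhole_diameter <= 0) stop("'pinhole_diameter' must be positive", call. = FALSE)
  if (any(c(n_immersion, n_coverslip, n_sample) < 1))
    stop("refractive indices must be >= 1", call. = FALSE)
  if (coverslip_thickness <= 0)
    stop("'coverslip_thickness' must be positive", call. = FALSE)
  if (na >= min(n_coverslip, n_sample))
    stop("total internal reflection: 'na' must be below min(n_coverslip, n_sample)",
         call. = FALSE)
  if (na >= n_immersion && design_aberration_free)
    stop("index-matched mode requires na < n_immersion", call. = FALSE)

  structure(list(na = na,
                 magnification = magnification,
                 pinhole_diameter = pinhole_diameter,
                 wavelength_ex = wavelength_ex,
                 wavelength_em = wavelength_em,
                 n_immersion = n_immersion,
                 n_coverslip = n_coverslip,
                 coverslip_thickness = coverslip_thickness,
                 n_sample = n_sample,
                 design_aberration_free = design_aberration_free),
            class = "microscope_config")
}

#' @export
print.microscope_config <- function(x, ...) {
  cat("Confocal microscope configuration\n")
  cat(sprintf("  objective : %gx, NA %.3g (n_immersion = %.4g%s)\n",
              x$magnification, x$na, x$n_immersion,
              if (x$design_aberration_free) ", index-matched mode" else ""))
  cat(sprintf("  pinhole   : %.3g um at image plane (%.3g um in object space)\n",
              x$pinhole_diameter, x$pinhole_diameter / (2 * x$magnification)))
  cat(sprintf("  coverslip : %.4g um, n = %.4g (assumed fully corrected)\n",
              x$coverslip_thickness, x$n_coverslip))
  cat(sprintf("  sample    : n = %.4g\n", x$n_sample))
  cat(sprintf("  lambda    : %g / %g nm (ex/em)\n", x$wavelength_ex, x$wavelength_em))
  invisible(x)
}

# object-space pinhole radius (um) for the reverse-trace acceptance test
pinhole_radius_object <- function(config) {
  config$pinhole_diameter / (2 * config$magnification)
}
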