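#' TCSPC decay histogram
#'
#' @param t Bin centres (ns), strictly increasing and uniformly spaced.
#' @param counts Non-negative photon counts per bin.
#' @param rep_rate Laser repetition rate (MHz); the histogram range must fit
#'   within one period.
#' @param irf_fwhm Optional Gaussian instrument-response FWHM (ns); when set,
#'   [fit_biexponential()] performs reconvolution instead of tail fitting.
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(t, counts, rep_rate = 40, irf_fwhm = NULL) {
  t <- as.numeric(t); counts <- as.numeric(counts)
  if (length(t) != length(counts)) stop("'t' and 'counts' lengths differ", call. = FALSE)
  if (length(t) < 8) stop("histogram too short", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("'t' must be strictly increasing", call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("'t' must be uniformly spaced", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (!(rep_rate > 0)) stop("'rep_rate' must be positive", call. = FALSE)
  period <- 1e3 / rep_rate
  if (t[length(t)] + dt[1] / 2 > period * (1 + 1e-9))
    stop("histogram range exceeds the laser period", call. = FALSE)
  structure(list(t = t, counts = counts, rep_rate = rep_rate,
                 irf_fwhm = irf_fwhm, dt = dt[1], period = period),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC histogram: %d bins of %.4g ns, %.3g photons, %g MHz%s\n",
              length(x$t), x$dt, sum(x$counts), x$rep_rate,
              if (!is.null(x$irf_fwhm)) sprintf(", IRF FWHM %.3g ns", x$irf_fwhm)
              else ""))
  invisible(x)
}

# expected bin masses of a periodically wrapped exponential with t = 0
# amplitude `a` (counts/ns before wrapping); closed form geometric sum
wrapped_exp_bins <- function(a, tau, edges, period) {
  a * tau * (exp(-edges[-length(edges)] / tau) - exp(-edges[-1] / tau)) /
    (1 - exp(-period / tau))
}

# Gaussian-IRF convolved exponential density (exGaussian), amplitude a at
# the unconvolved t = t0 origin; includes one wrap on either side
irf_exp_density <- function(t, a, tau, sigma, t0, period) {
  g <- function(ts) {
    exp(pmin(sigma^2 / (2 * tau^2) - ts / tau, 700)) *
      pnorm(ts / sigma - sigma / tau)
  }
  a * (g(t - t0) + g(t - t0 + period) + g(t - t0 + 2 * period) + g(t - t0 - period))
}

#' Amplitude-averaged lifetime
#'
#' \eqn{\langle\tau\rangle = (A_1\tau_1 + A_2\tau_2)/(A_1 + A_2)}: the
#' amplitude-weighted mean of the component lifetimes of a biexponential
#' decay.
#'
#' @param a1,a2 Component amplitudes (>= 0, not both zero).
#' @param tau1,tau2 Component lifetimes (ns, > 0).
#' @return Lifetime (ns).
#' @examples
#' amplitude_avg_lifetime(0.8, 0.1, 0.2, 1.7)  # 0.42
#' @export
amplitude_avg_lifetime <- function(a1, tau1, a2, tau2) {
  if (any(c(a1, a2) < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  if (any(c(tau1, tau2) <= 0)) stop("lifetimes must be positive", call. = FALSE)
  if (a1 + a2 == 0) stop("amplitudes must not both be zero", call. = FALSE)
  (a1 * tau1 + a2 * tau2) / (a1 + a2)
}

#' Biexponential fit of a TCSPC histogram
#'
#' Maximum-likelihood (Poisson) fit of a two-component exponential decay
#' plus constant background.  By default a tail fit is performed from the
#' bin after the histogram maximum (appropriate when the instrument
#' response is not modelled); if the histogram carries `irf_fwhm`, a
#' Gaussian-IRF reconvolution fit over the full window is used instead,
#' with the IRF position as an additional parameter.  Periodic wrap-around
#' of slow components at the laser repetition rate is always included.
#' Optimisation runs from several starts derived from log-slope heuristics
#' on the early and late parts of the decay.
#'
#' @param hist A [decay_histogram()].
#' @param fit_window Optional `c(t_start, t_end)` (ns) restricting the fit.
#' @return An object of class `biexp_fit`: amplitudes `a1`, `a2` (counts/ns
#'   at t = 0, ordered so that `tau1 <= tau2`), lifetimes `tau1`, `tau2`
#'   (ns), `background` (counts/ns), `tau_avg` (amplitude-averaged, ns),
#'   `fit_window`, `goodness` (Poisson deviance per degree of freedom),
#'   `vcov_log` (covariance of the log-parameters) and `se` (delta-method
#'   standard errors).
#' @examples
#' h <- simulate_decay(list(c(1, 1.0)), n_photons = 2e4, seed = 1)
#' fit <- fit_biexponential(h)
#' fit$tau_avg
#' @export
fit_biexponential <- function(hist, fit_window = NULL) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (sum(hist$counts) < 1000)
    stop("too few photons (< 1000) for a stable biexponential fit", call. = FALSE)
  reconv <- !is.null(hist$irf_fwhm)
  t <- hist$t; counts <- hist$counts; dt <- hist$dt; period <- hist$period
  imax <- which.max(counts)

  if (is.null(fit_window)) {
    fit_window <- if (reconv) c(t[1], t[length(t)]) else c(t[min(imax + 1, length(t))], t[length(t)])
  }
  sel <- t >= fit_window[1] & t <= fit_window[2]
  if (sum(sel) < 10) stop("fit window contains fewer than 10 bins", call. = FALSE)
  ts <- t[sel]; cs <- counts[sel]
  edges <- c(ts - dt / 2, ts[length(ts)] + dt / 2)

  t0_init <- t[imax]
  sigma_irf <- if (reconv) hist$irf_fwhm / 2.354820045 else NA_real_

  model <- function(par) {
    a1 <- exp(par[1]); tau1 <- exp(par[2])
    a2 <- exp(par[3]); tau2 <- exp(par[4])
    bg <- exp(par[5])
    if (reconv) {
      t0 <- par[6]
      mu <- (irf_exp_density(ts, a1, tau1, sigma_irf, t0, period) +
               irf_exp_density(ts, a2, tau2, sigma_irf, t0, period) + bg) * dt
    } else {
      # amplitudes are referenced to t = 0, the start of the record, so a
      # tail fit reports the same amplitudes as the generating model
      mu <- wrapped_exp_bins(a1, tau1, edges, period) +
        wrapped_exp_bins(a2, tau2, edges, period) + bg * dt
    }
    pmax(mu, 1e-12)
  }
  nll <- function(par) {
    mu <- model(par)
    sum(mu - cs * log(mu))
  }

  # log-slope heuristics: fast component from the first quarter of the
  # window, slow component from the last half
  slope_tau <- function(idx) {
    idx <- idx[cs[idx] > 0]
    if (length(idx) < 3) return(NA_real_)
    fit <- lm(log(cs[idx]) ~ ts[idx])
    s <- unname(coef(fit)[2])
    if (is.na(s) || s >= 0) NA_real_ else -1 / s
  }
  n <- length(ts)
  decay_part <- if (reconv) which(ts > t0_init + 2 * sigma_irf) else seq_len(n)
  if (length(decay_part) < 10) decay_part <- seq(max(1, n - 20), n)
  tau_fast <- slope_tau(decay_part[seq_len(max(4, floor(length(decay_part) / 4)))])
  tau_slow <- slope_tau(decay_part[seq(floor(length(decay_part) / 2), length(decay_part))])
  if (is.na(tau_slow)) tau_slow <- (ts[n] - ts[1]) / 4
  if (is.na(tau_fast) || tau_fast >= tau_slow) tau_fast <- tau_slow / 4
  a_tot <- max(cs[1] / dt, 1)
  bg0 <- max(min(cs) / dt, 1e-3)

  starts <- list(c(log(0.7 * a_tot), log(tau_fast), log(0.3 * a_tot), log(tau_slow)),
                 c(log(0.5 * a_tot), log(tau_fast / 2), log(0.5 * a_tot), log(tau_slow)),
                 c(log(0.9 * a_tot), log(tau_fast), log(0.1 * a_tot), log(2 * tau_slow)))
  # box bounds keep lifetimes physical (between a fifth of a bin and three
  # laser periods) and the IRF position near the observed peak
  lower <- c(rep(-30, 1), log(dt / 5), -30, log(dt / 5), -30)
  upper <- c(rep(45, 1), log(3 * period), 45, log(3 * period), 45)
  if (reconv) { lower <- c(lower, t0_init - 5 * sigma_irf - dt)
                upper <- c(upper, t0_init + 5 * sigma_irf + dt) }
  best <- NULL
  for (s0 in starts) {
    par0 <- c(s0, log(bg0))
    if (reconv) par0 <- c(par0, t0_init)
    par0 <- pmin(pmax(par0, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(optim(par0, nll, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(maxit = 2000, factr = 1e4)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$convergence > 1)
    stop("biexponential fit failed to converge after multiple starts; ",
         "last status: ", if (is.null(best)) "optimizer error" else best$convergence,
         call. = FALSE)

  hess <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  vcov_log <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) matrix(NA_real_, length(best$par), length(best$par)))
  else matrix(NA_real_, length(best$par), length(best$par))

  p <- unname(best$par)
  a1 <- exp(p[1]); tau1 <- exp(p[2]); a2 <- exp(p[3]); tau2 <- exp(p[4])
  bg <- exp(p[5])
  # enforce tau1 <= tau2
  perm <- c(1, 2, 3, 4)
  if (tau1 > tau2) {
    tmp <- c(a2, tau2, a1, tau1); a1 <- tmp[1]; tau1 <- tmp[2]; a2 <- tmp[3]; tau2 <- tmp[4]
    perm <- c(3, 4, 1, 2)
  }
  keep <- c(perm, 5, if (reconv) 6)
  vcov_log <- vcov_log[keep, keep, drop = FALSE]
  est <- c(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2, background = bg)
  se <- sqrt(pmax(diag(vcov_log)[1:5], 0)) * est # delta method from log scale

  mu <- model(p)
  dev <- 2 * sum(ifelse(cs > 0, cs * log(cs / mu), 0) - (cs - mu))
  dof <- max(length(cs) - length(p), 1)

  structure(list(a1 = a1, a2 = a2, tau1 = tau1, tau2 = tau2,
                 background = bg,
                 tau_avg = amplitude_avg_lifetime(a1, tau1, a2, tau2),
                 fit_window = fit_window,
                 goodness = dev / dof,
                 se = se,
                 vcov_log = vcov_log,
                 logLik = -best$value,
                 reconvolution = reconv,
                 hist = hist),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("Biexponential decay fit (%s, Poisson MLE)\n",
              if (x$reconvolution) "IRF reconvolution" else "tail"))
  cat(sprintf("  tau1 = %.4g ns (A1 = %.4g), tau2 = %.4g ns (A2 = %.4g)\n",
              x$tau1, x$a1, x$tau2, x$a2))
  cat(sprintf("  <tau> = %.4g ns (amplitude-averaged), background = %.3g/ns\n",
              x$tau_avg, x$background))
  cat(sprintf("  deviance/dof = %.3g over window [%.3g, %.3g] ns\n",
              x$goodness, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @export
coef.biexp_fit <- function(object, ...) {
  c(a1 = object$a1, tau1 = object$tau1, a2 = object$a2, tau2 = object$tau2,
    background = object$background)
}

#' Forster-Hoffmann viscosity calibration
#'
#' Fits the molecular-rotor power law \eqn{\tau = C \eta^\alpha} by least
#' squares on the log-log scale.
#'
#' @param tau Lifetimes (ns), at least 3 values.
#' @param eta Viscosities (mPa s), matching `tau`.
#' @return An object of class `fh_fit` with `prefactor` (ns at 1 mPa s),
#'   `alpha`, `covariance` (2x2, on `(prefactor, alpha)`), the log-scale lm
#'   fit and the data.
#' @examples
#' eta <- c(1, 10, 100, 900)
#' fit <- fit_forster_hoffman(0.05 * eta^0.5, eta)
#' coef(fit)  # prefactor 0.05, alpha 0.5
#' @export
fit_forster_hoffman <- function(tau, eta) {
  if (length(tau) != length(eta)) stop("'tau' and 'eta' lengths differ", call. = FALSE)
  if (length(tau) < 3) stop("at least 3 points are required", call. = FALSE)
  if (any(tau <= 0) || any(eta <= 0))
    stop("'tau' and 'eta' must be positive", call. = FALSE)
  fit <- lm(log(tau) ~ log(eta))
  cf <- coef(fit)
  C <- exp(cf[[1]]); alpha <- cf[[2]]
  # vcov.lm warns on exactly collinear (noiseless) data; the zero
  # covariance it returns is correct there
  vl <- suppressWarnings(vcov(fit))
  J <- diag(c(C, 1)) # d(prefactor)/d(intercept) = C
  covariance <- J %*% vl %*% t(J)
  dimnames(covariance) <- list(c("prefactor", "alpha"), c("prefactor", "alpha"))
  structure(list(prefactor = C, alpha = alpha, covariance = covariance,
                 lm = fit, tau = tau, eta = eta),
            class = "fh_fit")
}

#' @export
print.fh_fit <- function(x, ...) {
  se <- sqrt(diag(x$covariance))
  cat(sprintf("Forster-Hoffmann fit: tau = C eta^alpha\n"))
  cat(sprintf("  C     = %.4g +/- %.2g ns (at 1 mPa s)\n", x$prefactor, se[1]))
  cat(sprintf("  alpha = %.4g +/- %.2g\n", x$alpha, se[2]))
  invisible(x)
}

#' @export
coef.fh_fit <- function(object, ...) {
  c(prefactor = object$prefactor, alpha = object$alpha)
}

#' @param object An `fh_fit`.
#' @param newdata Viscosities (mPa s) at which to evaluate the power law.
#' @param ... Unused.
#' @rdname fit_forster_hoffman
#' @export
predict.fh_fit <- function(object, newdata, ...) {
  object$prefactor * newdata^object$alpha
}

#' Quantum-yield versus viscosity power law
#'
#' Returns \eqn{\Phi(\eta) = \Phi_{ref} (\eta/\eta_{ref})^\alpha} capped at
#' 1, anchored by default at the common point where bulk and interface
#' lifetimes extrapolate to meet (eta = 2e4 mPa s, Phi = 0.15).  Use this
#' when no tabulated quantum-yield calibration is available.
#'
#' @param alpha Forster-Hoffmann exponent.
#' @param eta_ref,phi_ref Anchor point (mPa s, dimensionless).
#' @return A function of viscosity (mPa s) returning a quantum yield.
#' @export
phi_eta_powerlaw <- function(alpha = 0.5, eta_ref = 2e4, phi_ref = 0.15) {
  stopifnot(alpha > 0, eta_ref > 0, phi_ref > 0, phi_ref <= 1)
  function(eta) pmin(phi_ref * (eta / eta_ref)^alpha, 1)
}

#' Extrapolated intersection viscosity of bulk and surface lifetimes
#'
#' Inverts a bulk Forster-Hoffmann fit at the plateau lifetime measured at
#' the interface: \eqn{\eta_I = (\tau_{plateau}/C)^{1/\alpha}}, the
#' viscosity at which a free-swimming rotor would match the adsorbed
#' species; the associated quantum yield \eqn{\Phi_I} follows from the
#' supplied \eqn{\Phi(\eta)} relation.
#'
#' @param fh_bulk An [fit_forster_hoffman()] result for the bulk lifetimes.
#' @param tau_surface_plateau Interface lifetime plateau (ns); must exceed
#'   every fitted bulk lifetime.
#' @param phi_of_eta A function of viscosity returning the quantum yield
#'   (e.g. [phi_eta_powerlaw()]) or a data frame with columns `eta`, `phi`
#'   (interpolated log-linearly).
#' @return A list with `eta_I` (mPa s) and `phi_I`.
#' @examples
#' fh <- fit_forster_hoffman(0.05 * c(1, 10, 100, 900)^0.55, c(1, 10, 100, 900))
#' intersect_viscosity(fh, 1.7, phi_eta_powerlaw(0.55))$eta_I
#' @export
intersect_viscosity <- function(fh_bulk, tau_surface_plateau, phi_of_eta) {
  stopifnot(inherits(fh_bulk, "fh_fit"))
  if (tau_surface_plateau < max(fh_bulk$tau))
    stop("surface plateau lies below the fitted bulk lifetimes: no intersection",
         call. = FALSE)
  eta_I <- (tau_surface_plateau / fh_bulk$prefactor)^(1 / fh_bulk$alpha)
  if (is.data.frame(phi_of_eta)) {
    phi_I <- exp(approx(log(phi_of_eta$eta), log(phi_of_eta$phi),
                        xout = log(eta_I), rule = 2)$y)
  } else {
    phi_I <- phi_of_eta(eta_I)
  }
  list(eta_I = eta_I, phi_I = phi_I)
}
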