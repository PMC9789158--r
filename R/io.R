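#' Read a z-scan profile from CSV
#'
#' Expects columns `z_um`, `intensity` and optionally `tau_ns`, with
#' metadata as `# key: value` comment lines (recognised keys:
#' `surface_kind`, `wt_glycerol`, `dye_concentration`).  Malformed rows are
#' rejected with their line numbers; the depth grid must be strictly
#' increasing and include 0.
#'
#' @param path CSV file path.
#' @return A [zscan_profile()].
#' @export
read_zscan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_idx <- grep("^\\s*#", lines)
  meta <- parse_meta(lines[meta_idx])
  body_idx <- setdiff(which(nzchar(trimws(lines))), meta_idx)
  if (!length(body_idx)) stop("no data rows in ", path, call. = FALSE)
  dat <- read.csv(text = paste(lines[body_idx], collapse = "\n"),
                  stringsAsFactors = FALSE)
  req <- c("z_um", "intensity")
  miss <- setdiff(req, names(dat))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (cl in intersect(c("z_um", "intensity", "tau_ns"), names(dat))) {
    vals <- suppressWarnings(as.numeric(dat[[cl]]))
    bad <- which(is.na(vals) & !is.na(dat[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric '%s' value at data line(s): %s", cl,
                   paste(body_idx[bad + 1], collapse = ", ")), call. = FALSE)
    dat[[cl]] <- vals
  }
  if (anyNA(dat$z_um) || anyNA(dat$intensity))
    stop("missing values in required columns", call. = FALSE)
  if (!any(dat$z_um == 0))
    stop("depth grid lacks the z = 0 anchor: profiles must include the interface",
         call. = FALSE)
  zscan_profile(dat$z_um, dat$intensity,
                lifetime = if ("tau_ns" %in% names(dat)) dat$tau_ns,
                surface_kind = meta$surface_kind %||% "hydrophobic",
                wt_glycerol = as.numeric(meta$wt_glycerol %||% NA),
                dye_concentration = as.numeric(meta$dye_concentration %||% NA))
}

#' Write a z-scan profile to CSV
#'
#' Inverse of [read_zscan()]; a write/read round trip preserves values to
#' full precision.
#'
#' @param profile A [zscan_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_zscan <- function(profile, path) {
  stopifnot(inherits(profile, "zscan_profile"))
  hdr <- c(sprintf("# surface_kind: %s", profile$surface_kind),
           if (!is.na(profile$wt_glycerol))
             sprintf("# wt_glycerol: %.17g", profile$wt_glycerol),
           if (!is.na(profile$dye_concentration))
             sprintf("# dye_concentration: %.17g", profile$dye_concentration))
  dat <- data.frame(z_um = profile$z_f, intensity = profile$intensity)
  if (!is.null(profile$lifetime)) dat$tau_ns <- profile$lifetime
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.csv(format(dat, digits = 17, trim = TRUE), con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a TCSPC decay histogram from CSV
#'
#' Expects columns `t_ns` and `counts`, with a `# rep_rate_MHz: <value>`
#' header comment (and optionally `# irf_fwhm_ns: <value>`).
#'
#' @param path CSV file path.
#' @return A [decay_histogram()].
#' @export
read_decay <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_idx <- grep("^\\s*#", lines)
  meta <- parse_meta(lines[meta_idx])
  dat <- read.csv(text = paste(lines[setdiff(seq_along(lines), meta_idx)],
                               collapse = "\n"))
  if (!all(c("t_ns", "counts") %in% names(dat)))
    stop("decay CSV must have columns 't_ns' and 'counts'", call. = FALSE)
  decay_histogram(dat$t_ns, dat$counts,
                  rep_rate = as.numeric(meta$rep_rate_MHz %||% 40),
                  irf_fwhm = if (!is.null(meta$irf_fwhm_ns))
                    as.numeric(meta$irf_fwhm_ns))
}

#' Write a TCSPC decay histogram to CSV
#'
#' @param hist A [decay_histogram()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  hdr <- c(sprintf("# rep_rate_MHz: %.17g", hist$rep_rate),
           if (!is.null(hist$irf_fwhm))
             sprintf("# irf_fwhm_ns: %.17g", hist$irf_fwhm))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  write.csv(data.frame(t_ns = format(hist$t, digits = 17, trim = TRUE),
                       counts = hist$counts),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Run a full adsorption analysis from a configuration
#'
#' Orchestrates the pipeline: read the sample scan (and the homogeneous
#' reference, if given), obtain \eqn{\phi(0,0)} and the bulk response from
#' either the configuration or a ray trace, fit the adsorption model and
#' write the results (a JSON summary and a per-depth CSV of the K
#' estimates) together with a log recording the phi(0,0) source, seed and
#' package version.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{sample}{path to the sample z-scan CSV (required)}
#'     \item{reference}{path to a homogeneous reference scan (optional)}
#'     \item{phi00}{detection density at the interface, um^-1 (optional)}
#'     \item{microscope}{list of [microscope_config()] arguments, used to
#'       ray-trace phi00/H when not supplied (optional)}
#'     \item{photophysics}{list of [photophysics_params()] arguments
#'       (required)}
#'     \item{rho_molar}{dye concentration, mol/L (required)}
#'     \item{depths}{depths for K (default 5, 7, 10, 20, 30 um)}
#'     \item{smooth}{logical, moving-average pre-smoothing (default FALSE)}
#'     \item{n_rays, seed}{ray-tracing controls (defaults 1e6, 1)}
#'     \item{out_dir}{output directory (default `"."`)}
#'   }
#' @param quiet Suppress the progress log (written to stderr).
#' @return The [fit_adsorption()] object, invisibly; side effects are
#'   `adsorption_result.json` and `k_per_depth.csv` in `out_dir`.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configurations requires the 'yaml' package", call. = FALSE)
    config <- yaml::yaml.load_file(config)
  }
  log_msg <- function(...) if (!quiet) message("[rotorscan] ", sprintf(...))
  need <- function(nm) {
    if (is.null(config[[nm]])) stop("config entry '", nm, "' is required", call. = FALSE)
    config[[nm]]
  }
  sample <- read_zscan(need("sample"))
  reference <- if (!is.null(config$reference)) read_zscan(config$reference)
  if (is.null(reference) && is.null(config$microscope) && is.null(config$phi00))
    stop(paste("no homogeneous reference: provide 'reference' (a measured",
               "bulk scan) or 'microscope' (to ray-trace the predicted H)"),
         call. = FALSE)
  photo <- do.call(photophysics_params, need("photophysics"))
  depths <- config$depths %||% c(5, 7, 10, 20, 30)
  seed <- config$seed %||% 1
  n_rays <- config$n_rays %||% 1e6

  dr <- NULL
  phi00_src <- "user-supplied"
  if (!is.null(config$microscope)) {
    cfg <- do.call(microscope_config, config$microscope)
    log_msg("ray tracing depth response (n_rays = %g, seed = %d)", n_rays, seed)
    zf <- sort(unique(c(0, depths, sample$z_f)))
    dr <- trace_depth_response(cfg, z_f_grid = zf, n_rays = n_rays, seed = seed)
    phi00_src <- "ray-traced"
  }
  fit <- tryCatch(
    fit_adsorption(sample, reference = reference, depth_response = dr,
                   photophysics = photo, rho_molar = need("rho_molar"),
                   depths = depths, phi00 = config$phi00,
                   smooth = isTRUE(config$smooth)),
    error = function(e) stop("adsorption fit stage: ", conditionMessage(e),
                             call. = FALSE))

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(k_value = fit$k_value, k_sd = fit$k_sd, u_inf = fit$u_inf,
              sigma = fit$sigma, sigma_sd = fit$sigma_sd,
              depths_used = fit$depths_used, phi00_used = fit$phi00_used,
              rho = fit$rho, h_source = fit$h_source,
              phi00_source = phi00_src, seed = seed,
              version = as.character(utils::packageVersion("rotorscan")))
  jsonlite::write_json(res, file.path(out_dir, "adsorption_result.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(z_f = fit$depths_used, k_i = fit$k_i),
            file.path(out_dir, "k_per_depth.csv"), row.names = FALSE)
  log_msg("phi(0,0) = %.4g um^-1 (%s); H: %s", fit$phi00_used, phi00_src,
          fit$h_source)
  log_msg("K = %.4g +/- %.2g um; sigma = %.4g +/- %.2g um^-2",
          fit$k_value, fit$k_sd, fit$sigma, fit$sigma_sd)
  invisible(fit)
}
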