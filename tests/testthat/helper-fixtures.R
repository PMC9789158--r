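# Shared, lazily built Monte Carlo fixtures.  Ray counts are kept moderate:
# the quantities asserted on are ratios that converge quickly, and every
# tolerance used in the tests is wide compared with the Monte Carlo error at
# these sizes.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# aqueous-sample depth response on the grid used by the analysis examples
water_dr <- function() fixture("water_dr",
  trace_depth_response(microscope_config(),
                       z_f_grid = c(0, 1, 2, 3, 5, 7, 10, 15, 20, 30, 40),
                       n_rays = 2e5, n_det = 256, seed = 11))

# far-field grid (surface slice vs deep focus)
farfield_dr <- function() fixture("farfield_dr",
  trace_depth_response(microscope_config(),
                       z_f_grid = c(0, 15, 20, 25, 30, 35, 40),
                       n_rays = 3e5, n_det = 512, seed = 13))

# quick water-condition photophysics
water_photo <- function() study_photophysics(0)
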