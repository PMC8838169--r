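# Shared fixtures: a default geometry and small simulated speckle pairs.

test_optics <- function() optical_params(lambda0_nm = 1300, n = 1.3,
                                         dz_air_um = 4, dx_um = 15.625)

# Interframe product with a pure axial phase ramp (rad/px) and unit amplitude.
ramp_product <- function(slope, M = 80L, J = 40L, optics = test_optics()) {
  b <- matrix(exp(1i * slope * seq_len(M)), M, J)
  structure(list(b = b, optics = optics, t0 = 0, t1 = 1),
            class = "interframe_product")
}

# Simulated two-frame speckle pair under a uniform interframe strain.
speckle_pair <- function(strain, seed = 1L, snr_db = 30,
                         n_rows = 320L, n_cols = 96L, surface_px = 30L,
                         optics = test_optics()) {
  spec <- strain_field_spec("uniform", k_pos = strain,
                            time_profile = "linear")
  sim <- simulate_series(spec, speckle_params(seed = seed, snr_db = snr_db),
                         optics, n_frames = 2L, dt = 1,
                         n_rows = n_rows, n_cols = n_cols,
                         surface_px = surface_px)
  interframe_product(sim$series$frames[[1]], sim$series$frames[[2]])
}

# Direct strain_map stub for arithmetic tests on accumulate_strain().
stub_map <- function(value, M = 6L, J = 5L, t0 = 0, t1 = 1,
                     optics = test_optics()) {
  vectorOCE:::new_strain_map(matrix(value, M, J), matrix(TRUE, M, J),
                             100, 100, optics, t0 = t0, t1 = t1)
}

# Synthetic depth profile for kinetics tests.
stub_profile <- function(depth_um, strain, t = 0, wz = 80, wx = 800) {
  structure(list(depth_um = depth_um, strain = strain,
                 avg_window_z_um = wz, avg_window_x_um = wx,
                 depth_limit_um = max(depth_um), t = t,
                 n_cols = 1L, normalized = FALSE),
            class = "depth_profile")
}

# Interior rows of the default speckle pair grids (well below surface, above
# the deep edge) for window-mean comparisons.
interior_rows <- 80:280
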