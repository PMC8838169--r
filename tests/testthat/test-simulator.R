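test_that("diffusion concentration follows the half-space erfc solution", {
  p <- diffusion_params(D = 1e-9, C0 = 1)
  expect_equal(diffusion_concentration(0, 100, p), 1)
  # z = 2 sqrt(D t): C/C0 = erfc(1)
  t <- 300
  z <- 2 * sqrt(1e-9 * t) * 1e6
  expect_equal(diffusion_concentration(z, t, p), 0.1572992, tolerance = 1e-6)
  # t = 0 limit is a step function
  expect_equal(diffusion_concentration(c(0, 1, 50), 0, p), c(1, 0, 0))
  # penetration scale after 300 s is ~0.55 mm
  expect_equal(penetration_depth_mm(1e-9, 300), 0.5477226, tolerance = 1e-6)
})

test_that("strain-field templates obey their closed forms", {
  d <- diffusion_params(D = 1e-9, C0 = 1)
  z <- seq(0, 1500, by = 5)
  # uniform: constant at all depths
  su <- strain_field_spec("uniform", k_pos = 1e-4)
  expect_equal(strain_field(su, z, 100), rep(1e-4, length(z)))
  # alternating-sign surface limit: eps(0) = k_pos when C0 = 1
  sa <- strain_field_spec("alternating_sign", k_pos = 0.2, k_neg = 0.8,
                          diffusion = d)
  eps <- strain_field(sa, z, 300)
  expect_equal(eps[1], 0.2)
  # sign change where C = 1 - k_pos/k_neg = 0.75: cross-check the closed form
  # z* = 2 sqrt(Dt) erfcinv(0.75) against an independent root finder
  z_closed <- 2 * sqrt(1e-9 * 300) * 1e6 * pracma::erfcinv(0.75)
  z_root <- uniroot(function(zz) strain_field(sa, c(0, zz), 300)[2],
                    c(10, 1400), tol = 1e-10)$root
  expect_equal(z_root, z_closed, tolerance = 1e-6)
  # deeper than z*: shrinkage; shallower: dilatation
  expect_true(all(eps[z < z_closed - 5] > 0))
  expect_true(all(eps[z > z_closed + 5 & z < 1200] < 0))
  # subsurface layer adds a thin negative band
  sl <- strain_field_spec("subsurface_layer", k_pos = 0.0, layer_depth_um = 70,
                          layer_strain = -0.05, diffusion = d)
  el <- strain_field(sl, z, 60)
  expect_true(all(el[z < 70] == -0.05))
  expect_true(all(el[z >= 70] == 0))
  # fields beyond the validated regime are rejected
  sbad <- strain_field_spec("uniform", k_pos = 0.9)
  expect_error(strain_field(sbad, z, 1), "0.5")
})

test_that("displacement is the depth integral of strain", {
  z <- seq(0, 500, by = 1)
  # constant integrand
  U <- displacement_field(z, rep(0.01, length(z)))
  expect_equal(U[length(U)], 5, tolerance = 1e-12)
  expect_equal(displacement_field(z, rep(0, length(z))), rep(0, length(z)))
  # single-front profile vs an independently coded trapezoid quadrature
  d <- diffusion_params(D = 1e-9)
  sf <- strain_field_spec("single_front", k_pos = 0.1, diffusion = d)
  zf <- seq(0, 1200, by = 0.5)
  eps_f <- strain_field(sf, zf, 300)
  Uf <- displacement_field(zf, eps_f)
  trap <- sum((eps_f[-1] + eps_f[-length(eps_f)]) / 2 * diff(zf))
  expect_equal(Uf[length(Uf)], trap, tolerance = 1e-12)
  # and against adaptive quadrature (grid-discretization limited)
  quadr <- integrate(function(zz) strain_field(sf, zz, 300), 0, 1200,
                     rel.tol = 1e-10)$value
  expect_equal(Uf[length(Uf)], quadr, tolerance = 1e-6)
})

test_that("ground truth is self-consistent: eps equals dU/dz on the grid", {
  spec <- strain_field_spec("alternating_sign", k_pos = 0.05, k_neg = 0.2,
                            diffusion = diffusion_params(D = 5e-10))
  z <- seq(0, 1000, by = 2)
  tr <- ground_truth_bundle(spec, z, c(60, 300, 600))
  for (k in 1:3) {
    dUdz <- diff(tr$U_true[, k]) / diff(z)
    mid <- (tr$eps_true[-1, k] + tr$eps_true[-length(z), k]) / 2
    expect_lt(max(abs(dUdz - mid)), 1e-9)
  }
  expect_true(all(tr$C >= 0 & tr$C <= 1))
  # Eulerian reference starts at zero and tracks the differenced field at
  # small strain
  expect_equal(tr$eps_eulerian[, 1], rep(0, length(z)))
})

test_that("speckle frames are deterministic in the seed", {
  op <- test_optics()
  sp <- speckle_params(seed = 42)
  s1 <- speckle_scan(sp, op, n_rows = 120, n_cols = 24, surface_px = 12)
  s2 <- speckle_scan(sp, op, n_rows = 120, n_cols = 24, surface_px = 12)
  expect_identical(s1$data, s2$data)
  s3 <- speckle_scan(speckle_params(seed = 43), op, n_rows = 120,
                     n_cols = 24, surface_px = 12)
  expect_false(identical(s1$data, s3$data))
})

test_that("fully developed speckle has Rayleigh amplitude and uniform phase", {
  op <- test_optics()
  # stationary conditions for the statistics: no attenuation, no noise
  sp <- speckle_params(seed = 8, atten_per_um = 0, snr_db = Inf)
  sc <- speckle_scan(sp, op, n_rows = 450, n_cols = 128, surface_px = 10)
  # subsample every 3rd row: axially adjacent pixels share the PSF and are
  # not independent draws
  px <- sc$data[seq(30, 430, by = 3), ]   # > 1e4 in-tissue samples
  A <- Mod(px); ph <- Arg(px)
  expect_gt(length(A), 1e4)
  sigma <- sqrt(mean(A^2) / 2)
  ks_a <- suppressWarnings(
    stats::ks.test(A, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks_a$p.value, 0.01)
  ks_p <- suppressWarnings(stats::ks.test(ph, "punif", -pi, pi))
  expect_gt(ks_p$p.value, 0.01)
})

test_that("a rigid sub-wavelength shift produces the closed-form phase", {
  op <- test_optics()
  sp <- speckle_params(seed = 7, snr_db = 30)
  s0 <- speckle_scan(sp, op, n_rows = 200, n_cols = 40, surface_px = 20)
  s1 <- speckle_scan(sp, op, U_field = 0.1, n_rows = 200, n_cols = 40,
                     surface_px = 20)  # U = 100 nm everywhere
  pr <- interframe_product(s0, s1)
  # amplitude-weighted mean phase over the bulk
  phase <- Arg(sum(pr$b[30:190, ]))
  expect_equal(phase, 4 * pi * 1.3 * 0.1 / 1.3, tolerance = 0.01)
})

test_that("simulated series carry exact linear ground truth and reproduce", {
  op <- test_optics()
  spec <- strain_field_spec("uniform", k_pos = 1e-4, time_profile = "linear")
  sp <- speckle_params(seed = 5)
  sim <- simulate_series(spec, sp, op, n_frames = 11, dt = 1,
                         n_rows = 100, n_cols = 16, surface_px = 10)
  # cumulative ground truth at t = 10 s is 1e-3
  expect_equal(unique(sim$truth$eps_true[, 11]), 1e-3)
  expect_equal(length(sim$series), 11L)
  sim2 <- simulate_series(spec, sp, op, n_frames = 11, dt = 1,
                          n_rows = 100, n_cols = 16, surface_px = 10)
  expect_identical(lapply(sim$series$frames, `[[`, "data"),
                   lapply(sim2$series$frames, `[[`, "data"))
  expect_error(simulate_series(spec, sp, op, n_frames = 1), "n_frames")
})
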