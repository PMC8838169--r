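test_that("interframe product reproduces hand-computed conjugate products", {
  op <- test_optics()
  mk <- function(v) complex_bscan(matrix(v, 2, 2), op)
  # quarter-turn between frames
  pr <- interframe_product(mk(1 + 0i), complex_bscan(
    matrix(exp(1i * pi / 2), 2, 2), op, timestamp = 1))
  expect_equal(Arg(pr$b), matrix(pi / 2, 2, 2))
  # identical frames: zero phase, |b| = A^2
  a <- matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2, 2)
  pr0 <- interframe_product(complex_bscan(a, op), complex_bscan(a, op, 1))
  expect_equal(Arg(pr0$b), matrix(0, 2, 2))
  expect_equal(Mod(pr0$b), Mod(a)^2)
  # hand complex arithmetic: (-1+i) * conj(1+i) = 2i
  pr2 <- interframe_product(mk(1 + 1i), complex_bscan(
    matrix(-1 + 1i, 2, 2), op, 1))
  expect_equal(pr2$b, matrix(2i, 2, 2))
  expect_equal(Arg(pr2$b[1, 1]), pi / 2)
  # contract errors
  expect_error(interframe_product(mk(1 + 0i), complex_bscan(
    matrix(1 + 0i, 3, 2), op)), "shape")
  op2 <- optical_params(1310, 1.3, 4, 15.625)
  expect_error(interframe_product(mk(1 + 0i), complex_bscan(
    matrix(1 + 0i, 2, 2), op2)), "optics")
})

test_that("phase identity: arg(a * conj(a)) is zero to machine precision", {
  set.seed(1)
  a <- complex(real = rnorm(1000), imaginary = rnorm(1000))
  expect_lt(max(abs(Arg(a * Conj(a)))), 1e-14)
})

test_that("phase-to-displacement conversion is the closed form and linear", {
  op <- test_optics()
  expect_identical(as.numeric(displacement_from_phase(0, op)), 0)
  expect_equal(as.numeric(displacement_from_phase(pi, op)), 250)
  # the wrap-ambiguity quantum: 2*pi of phase is one lambda0/(2n) of motion
  expect_equal(as.numeric(displacement_from_phase(2 * pi, op)), 500)
  phi <- matrix(runif(20, -1, 1), 4, 5)
  expect_equal(as.numeric(displacement_from_phase(2 * phi, op)),
               as.numeric(2 * displacement_from_phase(phi, op)))
  expect_false(attr(displacement_from_phase(0.5, op), "wrap_risk"))
  expect_true(attr(displacement_from_phase(0.99 * pi, op), "wrap_risk"))
})

test_that("both estimators are exact on a noise-free phase ramp", {
  op <- test_optics()
  pr <- ramp_product(0.1)
  truth <- 1.3 * 0.1 / (4 * pi * 4)  # lambda0 * slope / (4 pi dz_air)
  sv <- vector_axial_gradient(pr)
  sl <- lsq_axial_gradient(pr)
  expect_lt(max(abs(sv$eps / truth - 1), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(sl$eps / truth - 1), na.rm = TRUE), 1e-10)
  # and they agree with each other
  expect_lt(abs(mean(sv$eps, na.rm = TRUE) / mean(sl$eps, na.rm = TRUE) - 1),
            1e-12)
})

test_that("zero interframe motion gives exactly zero vector strain", {
  op <- test_optics()
  set.seed(3)
  b <- matrix(rexp(80 * 40), 80, 40) + 0i  # real positive everywhere
  pr <- structure(list(b = b, optics = op, t0 = 0, t1 = 1),
                  class = "interframe_product")
  sv <- vector_axial_gradient(pr)
  expect_equal(max(abs(sv$eps), na.rm = TRUE), 0)
})

test_that("window contract errors and all-zero windows are masked", {
  pr <- ramp_product(0.1, M = 20L, J = 10L)
  expect_error(vector_axial_gradient(pr, window_z_um = 5000), "window")
  expect_error(lsq_axial_gradient(pr, window_x_um = 5000), "window")
  # all-zero input: output masked everywhere, no NaN leakage
  prz <- ramp_product(0.1)
  prz$b[] <- 0 + 0i
  svz <- vector_axial_gradient(prz)
  expect_false(any(svz$mask))
  expect_true(all(is.na(svz$eps)))
})

test_that("accumulation is the running sum with mask intersection", {
  maps <- replicate(300, stub_map(1e-6), simplify = FALSE)
  cum <- accumulate_strain(maps)
  expect_equal(cum$eps_cum, matrix(3e-4, 6, 5))
  expect_equal(cum$n_frames, 300L)
  # identity
  one <- accumulate_strain(list(stub_map(0.42)))
  expect_equal(one$eps_cum, matrix(0.42, 6, 5))
  # alternating signs cancel
  alt <- accumulate_strain(rep(list(stub_map(2e-3), stub_map(-2e-3)), 5))
  expect_equal(alt$eps_cum, matrix(0, 6, 5))
  # empty input is a contract error
  expect_error(accumulate_strain(list()), "non-empty")
  # mask intersection: invalid pixel stays invalid in the sum
  m1 <- stub_map(1e-3); m2 <- stub_map(1e-3)
  m2$mask[2, 2] <- FALSE; m2$eps[2, 2] <- NA_real_
  cum2 <- accumulate_strain(list(m1, m2))
  expect_true(is.na(cum2$eps_cum[2, 2]))
  expect_equal(cum2$eps_cum[1, 1], 2e-3)
})

test_that("accumulation is associative across groupings", {
  set.seed(7)
  maps <- lapply(1:6, function(i) stub_map(rnorm(1, sd = 1e-3)))
  all_at_once <- accumulate_strain(maps)
  grouped <- accumulate_strain(list(accumulate_strain(maps[1:2]),
                                    accumulate_strain(maps[3:6])))
  expect_equal(grouped$eps_cum, all_at_once$eps_cum, tolerance = 1e-12)
  expect_equal(grouped$n_frames, all_at_once$n_frames)
})

test_that("surface detection finds step edges and handles degenerate input", {
  # step edge at row 41 (40 air pixels above)
  A <- matrix(0, 100, 20)
  A[41:100, ] <- 1
  s <- detect_surface(A, threshold_frac = 0.5)
  expect_true(all(s$surf == 40L))
  # uniform amplitude: surface at the very first row
  s2 <- detect_surface(matrix(1, 50, 10))
  expect_true(all(s2$surf == 0L))
  expect_error(detect_surface(matrix(0, 10, 10)), "all-zero")
})

test_that("surface detection locates a simulated speckle surface within 2 px", {
  op <- test_optics()
  sc <- speckle_scan(speckle_params(seed = 7), op, n_rows = 200,
                     n_cols = 40, surface_px = 50)
  s <- detect_surface(Mod(sc$data))
  expect_lte(median(abs(s$surf - 50)), 2)
})

test_that("series contracts: time order, spacing and minimum length", {
  op <- test_optics()
  f <- function(t) complex_bscan(matrix(1 + 0i, 8, 8), op, timestamp = t)
  expect_error(bscan_series(list(f(0), f(2), f(1)), dt = 1), "increasing")
  expect_error(bscan_series(list(f(0), f(1), f(2.5)), dt = 1), "spacing")
  one <- bscan_series(list(f(0)), dt = 1)
  expect_error(strain_series(one), ">= 2 frames")
})

test_that("a two-frame zero-motion series accumulates only noise", {
  op <- test_optics()
  spec <- strain_field_spec("uniform", k_pos = 0, time_profile = "constant")
  sim <- simulate_series(spec, speckle_params(seed = 13, snr_db = 30), op,
                         n_frames = 2, dt = 1, n_rows = 200, n_cols = 48,
                         surface_px = 20)
  maps <- strain_series(sim$series)
  vals <- maps[[1]]$eps_cum[60:180, ]
  m <- mean(vals, na.rm = TRUE)
  sdm <- stats::sd(vals, na.rm = TRUE) / sqrt(50)  # conservative: correlated px
  expect_lt(abs(m), 3 * max(sdm, 1e-7))
})
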