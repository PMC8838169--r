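#' Interframe complex conjugate product of two B-scans
#'
#' Element-wise product `b = a2 * Conj(a1)` of a deformed frame with the
#' conjugate of the reference frame. Its argument is the interframe phase
#' variation `Phi = phi2 - phi1` in (-pi, pi], and its modulus is the product
#' of the two amplitudes, so low-signal pixels carry little weight in any
#' subsequent complex averaging.
#'
#' @param scan1,scan2 Reference and deformed [complex_bscan()] objects with
#'   identical grid shape and optics.
#' @return An object of class `interframe_product` with elements `b` (complex
#'   matrix), `optics`, and the pair timestamps `t0`, `t1`.
#' @export
interframe_product <- function(scan1, scan2) {
  stopifnot(inherits(scan1, "complex_bscan"), inherits(scan2, "complex_bscan"))
  if (!identical(dim(scan1$data), dim(scan2$data)))
    stop("interframe_product: scans differ in grid shape")
  if (!same_optics(scan1$optics, scan2$optics))
    stop("interframe_product: scans differ in optics")
  structure(list(b = scan2$data * Conj(scan1$data),
                 optics = scan1$optics,
                 t0 = scan1$timestamp, t1 = scan2$timestamp),
            class = "interframe_product")
}

#' Interframe phase-variation map
#' @param prod An [interframe_product()].
#' @return Matrix of phases in (-pi, pi].
#' @export
phase_map <- function(prod) Arg(prod$b)

#' Convert interframe phase variation to axial displacement
#'
#' `U = lambda0 * Phi / (4 * pi * n)`: the displacement of scatterers along
#' the beam that produces a phase variation `Phi` at central wavelength
#' `lambda0` in a medium of refractive index `n`. The relation is unambiguous
#' only for `|U| < lambda0 / (2 n)` (half a wavelength in the medium); beyond
#' that the phase wraps. The returned object carries a `wrap_risk` attribute
#' set when any `|Phi|` approaches pi.
#'
#' @param phase Matrix (or vector) of phase variations in radians.
#' @param optics An [optical_params()] object supplying `lambda0` and `n`.
#' @return Displacements in nm, same shape as `phase`; attribute `wrap_risk`.
#' @examples
#' op <- optical_params(1300, 1.3, 4, 15)
#' displacement_from_phase(pi, op)  # 250 nm
#' @export
displacement_from_phase <- function(phase, optics) {
  stopifnot(inherits(optics, "optical_params"), all(is.finite(phase)))
  u <- optics$lambda0_nm * phase / (4 * pi * optics$n)
  attr(u, "wrap_risk") <- any(abs(phase) > 0.9 * pi)
  u
}

new_strain_map <- function(eps, mask, window_z_um, window_x_um, optics,
                           t0 = NA_real_, t1 = NA_real_,
                           depth_convention = "optical") {
  structure(list(eps = eps, mask = mask,
                 window_z_um = window_z_um, window_x_um = window_x_um,
                 optics = optics, t0 = t0, t1 = t1,
                 depth_convention = depth_convention),
            class = "strain_map")
}

#' @export
print.strain_map <- function(x, ...) {
  cat(sprintf(
    "strain_map: %d x %d px, window %g x %g um, %d%% valid, convention %s\n",
    nrow(x$eps), ncol(x$eps), x$window_z_um, x$window_x_um,
    round(100 * mean(x$mask)), x$depth_convention))
  invisible(x)
}

# Phase slope (rad/px along the air-sampled axis) to dimensionless strain.
# strain = (lambda0 / 4 pi) * dPhi/dz_air; because physical depth is optical
# depth / n, the same number equals (lambda0 / 4 pi n) * dPhi/dz_physical:
# the estimate is independent of n.
slope_to_strain <- function(slope_rad_px, optics) {
  (optics$lambda0_nm * 1e-3) * slope_rad_px / (4 * pi * optics$dz_air_um)
}

#' Vector-method local axial strain estimation
#'
#' Estimates the local axial gradient of the interframe phase variation by
#' operating on the complex signal itself ("vector" processing), without ever
#' extracting the phase until the final step. Per output pixel: the
#' interframe product is optionally pre-averaged over a small
#' `preavg_px x preavg_px` neighbourhood, axial lag products
#' `d(m,j) = b(m+lag, j) * Conj(b(m, j))` are formed, and `d` is summed over
#' the processing window. Amplitude weighting is intrinsic: strong pixels
#' dominate the complex sum, and isolated noise pixels with near-random phase
#' (errors of order pi) largely cancel. The phase slope is
#' `Arg(sum d) / lag_px`, which needs no unwrapping as long as the per-lag
#' phase advance stays below pi even when the accumulated interframe phase
#' spans many cycles.
#'
#' @param prod An [interframe_product()].
#' @param window_z_um,window_x_um Processing-window size in physical um
#'   (defaults 100 x 100); converted to odd pixel counts >= 3. The effective
#'   resolution of the strain map is about half the window.
#' @param lag_px Axial lag of the phase-difference products (pixels, >= 1).
#'   The lag must span the axial speckle correlation length (about one PSF
#'   width): products of pixels inside the same speckle correlation cell
#'   carry a real-positive self-correlation component that biases the slope
#'   towards zero. The default (6 px, about 1.5 PSF widths at the default
#'   4 um/px sampling) keeps this bias below ~0.5%; scale it with
#'   `psf_fwhm / dz_air` for other samplings. For `lag_px > 2` the estimate
#'   is coarse-to-fine: a wrap-safe 2-px-lag pass estimates the phase ramp,
#'   which is removed from the long-lag products before the precise pass, so
#'   the wrap limit is set by the coarse lag
#'   (`|interframe strain| < lambda0 / (8 dz_air)`).
#' @param preavg_px Side of the complex pre-averaging neighbourhood in pixels
#'   (1 disables).
#' @param clip_quantile Optional quantile in (0, 1]; lag-product magnitudes
#'   above this quantile are clipped to it, limiting the dominance of
#'   specular reflexes. `NULL` (default) disables clipping.
#' @param rereference If `TRUE`, performs one re-referencing pass: the
#'   first-pass slope ramp is removed from the lag products, the residual
#'   slope re-estimated from the re-summed window, and the ramp added back.
#' @return A `strain_map`: full-grid strain `eps` (NA outside the valid
#'   region), logical `mask`, window metadata, and the pair timestamps.
#' @export
vector_axial_gradient <- function(prod, window_z_um = 100, window_x_um = 100,
                                  lag_px = 6L, preavg_px = 4L,
                                  clip_quantile = NULL, rereference = FALSE) {
  stopifnot(inherits(prod, "interframe_product"), lag_px >= 1L,
            preavg_px >= 1L)
  b <- prod$b
  M <- nrow(b); J <- ncol(b)
  optics <- prod$optics
  dzp <- dz_phys_um(optics)
  wz <- odd_px(window_z_um, dzp)
  wx <- odd_px(window_x_um, optics$dx_um)
  if (wz + lag_px + preavg_px - 1L > M || wx + preavg_px - 1L > J)
    stop("processing window larger than the grid")

  if (preavg_px > 1L) {
    bv <- box_sum_valid(b, preavg_px, preavg_px) / (preavg_px^2)
    b <- embed_valid(bv, M, J, preavg_px, preavg_px)
  }
  ok <- is.finite(Re(b))
  b[!ok] <- 0 + 0i

  d <- b[(1L + lag_px):M, , drop = FALSE] * Conj(b[1L:(M - lag_px), , drop = FALSE])
  dok <- ok[(1L + lag_px):M, , drop = FALSE] & ok[1L:(M - lag_px), , drop = FALSE]
  d[!dok] <- 0 + 0i

  if (!is.null(clip_quantile)) {
    mag <- Mod(d)
    q <- stats::quantile(mag[dok & mag > 0], clip_quantile, names = FALSE)
    over <- mag > q
    d[over] <- d[over] * (q / mag[over])
  }

  Md <- nrow(d)
  nvalid <- box_sum_valid(dok * 1.0, wz, wx)

  # coarse-to-fine: a short-lag pass (wrap-safe) supplies a ramp estimate
  # that is removed from the long-lag products before the precise pass, so
  # the summed phase never approaches +/- pi even for strong interframe
  # strain while the final precision comes from the long lag
  if (lag_px > 2L) {
    lc <- 2L
    dc <- b[(1L + lc):M, , drop = FALSE] * Conj(b[1L:(M - lc), , drop = FALSE])
    s1v <- Arg(box_sum_valid(dc, wz, wx)) / lc
    # expand the coarse ramp to the lag-product grid, clamping indices so
    # edge pixels take the nearest interior estimate
    ozc <- (wz - 1L) %/% 2L; oxc <- (wx - 1L) %/% 2L
    ridx <- pmin(pmax(seq_len(Md) - ozc, 1L), nrow(s1v))
    cidx <- pmin(pmax(seq_len(J) - oxc, 1L), ncol(s1v))
    s1 <- s1v[ridx, cidx, drop = FALSE]
    S <- box_sum_valid(d * exp(-1i * s1 * lag_px), wz, wx)
    s1c <- box_sum_valid(s1, wz, wx) / (wz * wx)
    slope <- s1c + Arg(S) / lag_px
  } else {
    S <- box_sum_valid(d, wz, wx)
    slope <- Arg(S) / lag_px
  }

  if (isTRUE(rereference)) {
    s_full <- embed_valid(slope, Md, J, wz, wx)
    s_full[is.na(s_full)] <- 0
    d2 <- d * exp(-1i * s_full * lag_px)
    S2 <- box_sum_valid(d2, wz, wx)
    slope <- slope + Arg(S2) / lag_px
    S <- S2
  }

  valid <- (Mod(S) > 0) & (nvalid >= 0.5 * wz * wx)
  slope[!valid] <- NA_real_
  eps_valid <- slope_to_strain(slope, optics)

  # lag products live between rows m and m+lag: re-centre onto the scan grid
  ev <- embed_valid(eps_valid, Md, J, wz, wx)
  shift <- lag_px %/% 2L
  eps <- matrix(NA_real_, M, J)
  eps[(1L + shift):(Md + shift), ] <- ev
  mask <- !is.na(eps)
  new_strain_map(eps, mask, window_z_um, window_x_um, optics,
                 t0 = prod$t0, t1 = prod$t1)
}

#' Least-squares local axial strain estimation
#'
#' The classical phase-resolved alternative kept as a cross-validation
#' oracle: the interframe product is complex pre-averaged (like the vector
#' path) to denoise the phase, the phase is (optionally) unwrapped along
#' depth per column, the per-column ordinary least-squares slope of phase vs
#' axial pixel is computed over the window's axial extent, and slopes are
#' averaged laterally across the window (equivalent to pooled OLS with
#' per-column intercepts). Without unwrapping the fit is biased as soon as
#' the phase ramp aliases, the documented failure mode the vector method
#' avoids.
#'
#' @inheritParams vector_axial_gradient
#' @param unwrap Unwrap the phase along depth per column before fitting
#'   (default `TRUE`).
#' @param fail_jump_rad Post-unwrap adjacent-pixel phase jump (radians) above
#'   which the transition is deemed an unwrap failure; windows containing a
#'   failed transition are masked invalid.
#' @return A `strain_map`.
#' @export
lsq_axial_gradient <- function(prod, window_z_um = 100, window_x_um = 100,
                               preavg_px = 4L, unwrap = TRUE,
                               fail_jump_rad = 0.95 * pi) {
  stopifnot(inherits(prod, "interframe_product"), preavg_px >= 1L)
  b0 <- prod$b
  M <- nrow(b0); J <- ncol(b0)
  optics <- prod$optics
  wz <- odd_px(window_z_um, dz_phys_um(optics))
  wx <- odd_px(window_x_um, optics$dx_um)
  if (wz + preavg_px - 1L > M || wx + preavg_px - 1L > J)
    stop("processing window larger than the grid")

  # complex pre-averaging; work on the valid sub-rectangle only (zero-filled
  # edges would feed flat zero-phase rows into the equal-weight fit)
  if (preavg_px > 1L) {
    b <- box_sum_valid(b0, preavg_px, preavg_px) / (preavg_px^2)
    oz <- (preavg_px - 1L) %/% 2L; ox <- oz
  } else {
    b <- b0; oz <- 0L; ox <- 0L
  }
  Ms <- nrow(b); Js <- ncol(b)

  phi <- Arg(b)
  fail <- matrix(FALSE, Ms - 1L, Js)
  if (isTRUE(unwrap)) {
    phi <- apply(phi, 2L, unwrap_phase)
    fail <- abs(diff(phi)) > fail_jump_rad
  }

  h <- (wz - 1L) %/% 2L
  k <- seq.int(-h, h)
  w <- k / sum(k^2)
  slope_col <- matrix(0, Ms - wz + 1L, Js)
  for (i in seq_along(k)) {
    rows <- (h + 1L + k[i]):(Ms - h + k[i])
    slope_col <- slope_col + w[i] * phi[rows, , drop = FALSE]
  }

  slope <- box_sum_valid(slope_col, 1L, wx) / wx
  # windows containing any failed unwrap transition are masked: sum the
  # failure indicator over the window footprint (wz-1 transitions x wx cols)
  fcount <- box_sum_valid(fail * 1.0, wz - 1L, wx)
  slope[fcount > 0] <- NA_real_

  eps_valid <- slope_to_strain(slope, optics)
  eps_sub <- embed_valid(eps_valid, Ms, Js, wz, wx)
  eps <- matrix(NA_real_, M, J)
  eps[(1L + oz):(Ms + oz), (1L + ox):(Js + ox)] <- eps_sub
  mask <- !is.na(eps)
  new_strain_map(eps, mask, window_z_um, window_x_um, optics,
                 t0 = prod$t0, t1 = prod$t1)
}

#' Accumulate interframe strain maps into cumulative strain
#'
#' Element-wise running sum of interframe strain maps on the intersection of
#' their validity masks: the cumulative axial strain as a function of
#' observation time.
#'
#' @param maps List of `strain_map` (or `cumulative_strain_map`) objects with
#'   identical grid shape and depth convention.
#' @return A `cumulative_strain_map` with elements `eps_cum`, `mask`,
#'   `t` (elapsed observation time, s) and `n_frames` (number of summed
#'   interframe maps).
#' @export
accumulate_strain <- function(maps) {
  if (inherits(maps, "strain_map") || inherits(maps, "cumulative_strain_map"))
    maps <- list(maps)
  if (!is.list(maps) || length(maps) == 0L)
    stop("accumulate_strain: need a non-empty list of maps")
  get_eps <- function(m) if (inherits(m, "cumulative_strain_map")) m$eps_cum else m$eps
  get_n <- function(m) if (inherits(m, "cumulative_strain_map")) m$n_frames else 1L
  d0 <- dim(get_eps(maps[[1]]))
  conv <- maps[[1]]$depth_convention
  mask <- maps[[1]]$mask
  total <- matrix(0, d0[1], d0[2])
  n_frames <- 0L
  for (m in maps) {
    e <- get_eps(m)
    if (!identical(dim(e), d0))
      stop("accumulate_strain: maps differ in grid shape")
    if (!identical(m$depth_convention, conv))
      stop("accumulate_strain: maps differ in depth convention")
    mask <- mask & m$mask
    e[!m$mask] <- 0
    total <- total + e
    n_frames <- n_frames + get_n(m)
  }
  total[!mask] <- NA_real_
  t0 <- maps[[1]]$t0; t1 <- maps[[length(maps)]]$t1
  structure(list(eps_cum = total, mask = mask,
                 t = if (is.finite(t1 - t0)) t1 - t0 else NA_real_,
                 n_frames = n_frames,
                 window_z_um = maps[[1]]$window_z_um,
                 window_x_um = maps[[1]]$window_x_um,
                 optics = maps[[1]]$optics,
                 t0 = t0, t1 = t1,
                 depth_convention = conv),
            class = "cumulative_strain_map")
}

#' @export
print.cumulative_strain_map <- function(x, ...) {
  cat(sprintf(
    "cumulative_strain_map: %d x %d px, %d interframe maps, t = %g s\n",
    nrow(x$eps_cum), ncol(x$eps_cum), x$n_frames, x$t))
  invisible(x)
}

#' Detect the sample surface from a structural amplitude image
#'
#' Per column, the surface is the first axial pixel at which the laterally
#' median-smoothed amplitude exceeds `threshold_frac` times the smoothed
#' column maximum. Columns in which the threshold is never exceeded are
#' filled from the nearest detected column and flagged. The returned index is
#' the number of pixels of air above the sample (0 = surface at the first
#' row).
#'
#' @param structural Non-negative amplitude matrix, or a [complex_bscan()]
#'   (the modulus is used).
#' @param threshold_frac Fraction of the column maximum (default 0.3).
#' @param smooth_px Lateral median-smoothing width in columns (default 5).
#' @return Object of class `surface_map`: integer vector `surf` (0-based
#'   air-pixel counts, one per column), logical `filled` flags, and the
#'   threshold metadata.
#' @export
detect_surface <- function(structural, threshold_frac = 0.3, smooth_px = 5L) {
  if (inherits(structural, "complex_bscan")) structural <- Mod(structural$data)
  stopifnot(is.matrix(structural), all(structural >= 0),
            threshold_frac > 0, threshold_frac <= 1)
  if (all(structural == 0)) stop("detect_surface: all-zero amplitude frame")
  sm <- running_median_cols(structural, as.integer(smooth_px))
  J <- ncol(sm)
  surf <- integer(J); filled <- logical(J)
  for (j in seq_len(J)) {
    cmax <- max(sm[, j])
    if (cmax <= 0) { filled[j] <- TRUE; surf[j] <- NA_integer_; next }
    idx <- which(sm[, j] >= threshold_frac * cmax)[1]
    if (is.na(idx)) { filled[j] <- TRUE; surf[j] <- NA_integer_ }
    else surf[j] <- idx - 1L
  }
  if (all(is.na(surf))) stop("detect_surface: no column exceeds the threshold")
  if (any(filled)) {
    good <- which(!is.na(surf))
    for (j in which(is.na(surf)))
      surf[j] <- surf[good[which.min(abs(good - j))]]
  }
  structure(list(surf = surf, filled = filled,
                 threshold_frac = threshold_frac, smooth_px = smooth_px),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("surface_map: %d columns, surface rows %d..%d (%d filled)\n",
              length(x$surf), min(x$surf), max(x$surf), sum(x$filled)))
  invisible(x)
}

#' Cumulative strain maps from a B-scan series
#'
#' Runs the full interframe pipeline over a series: for every consecutive
#' frame pair, the interframe conjugate product is formed and the local axial
#' strain is estimated (vector method by default), then the interframe maps
#' are accumulated into cumulative-strain maps at every timestamp.
#'
#' @param series A [bscan_series()] with at least 2 frames.
#' @param window_z_um,window_x_um Processing-window size (um).
#' @param method `"vector"` (default) or `"lsq"`.
#' @param ... Further arguments passed to the estimator.
#' @return List of `cumulative_strain_map`, one per interframe interval, in
#'   time order (element k sums the first k interframe maps).
#' @export
strain_series <- function(series, window_z_um = 100, window_x_um = 100,
                          method = c("vector", "lsq"), ...) {
  stopifnot(inherits(series, "bscan_series"))
  if (length(series$frames) < 2L)
    stop("strain_series: need >= 2 frames")
  method <- match.arg(method)
  est <- switch(method, vector = vector_axial_gradient, lsq = lsq_axial_gradient)
  out <- vector("list", length(series$frames) - 1L)
  interframe <- vector("list", length(series$frames) - 1L)
  for (k in seq_len(length(series$frames) - 1L)) {
    pr <- interframe_product(series$frames[[k]], series$frames[[k + 1L]])
    interframe[[k]] <- est(pr, window_z_um = window_z_um,
                           window_x_um = window_x_um, ...)
    out[[k]] <- accumulate_strain(interframe[seq_len(k)])
  }
  out
}
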