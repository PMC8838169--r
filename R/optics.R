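#' Optical acquisition parameters
#'
#' Bundles the acquisition geometry of an OCT B-scan: the central wavelength
#' of the source in vacuum, the refractive index of the sample, and the axial
#' and lateral pixel pitches. The axial pitch is measured in air (optical
#' path), which is how spectral-domain OCT systems sample depth; the physical
#' in-tissue axial pitch is `dz_air / n`.
#'
#' @param lambda0_nm Central wavelength in vacuum (nm). Must be positive.
#' @param n Refractive index of the sample (dimensionless, >= 1).
#' @param dz_air_um Axial pixel pitch measured in air (um/pixel).
#' @param dx_um Lateral pixel pitch (um/pixel).
#' @return An object of class `optical_params`.
#' @examples
#' optical_params(lambda0_nm = 1300, n = 1.3, dz_air_um = 3.9, dx_um = 15.6)
#' @export
optical_params <- function(lambda0_nm = 1300, n = 1.38, dz_air_um = 3.90625,
                           dx_um = 15.625) {
  stopifnot(is.numeric(lambda0_nm), length(lambda0_nm) == 1L, lambda0_nm > 0,
            is.numeric(n), length(n) == 1L, n >= 1,
            is.numeric(dz_air_um), length(dz_air_um) == 1L, dz_air_um > 0,
            is.numeric(dx_um), length(dx_um) == 1L, dx_um > 0)
  structure(list(lambda0_nm = as.numeric(lambda0_nm), n = as.numeric(n),
                 dz_air_um = as.numeric(dz_air_um), dx_um = as.numeric(dx_um)),
            class = "optical_params")
}

#' @export
print.optical_params <- function(x, ...) {
  cat(sprintf(
    "optical_params: lambda0 = %g nm, n = %g, dz_air = %g um/px, dx = %g um/px\n",
    x$lambda0_nm, x$n, x$dz_air_um, x$dx_um))
  invisible(x)
}

#' Physical in-tissue axial pixel pitch (um)
#' @param optics An [optical_params()] object.
#' @return Axial pixel pitch below the sample surface, in physical um.
#' @export
dz_phys_um <- function(optics) optics$dz_air_um / optics$n

same_optics <- function(a, b, tol = 1e-9) {
  all(abs(c(a$lambda0_nm - b$lambda0_nm, a$n - b$n,
            a$dz_air_um - b$dz_air_um, a$dx_um - b$dx_um)) <= tol)
}

#' A single complex-valued OCT B-scan
#'
#' A B-scan is a 2D grid of complex backscatter values `a = A exp(i phi)`,
#' rows indexing depth (axial, increasing downwards) and columns indexing the
#' lateral position.
#'
#' @param data Complex (or numeric) matrix, at least 2 x 2, all values finite.
#' @param optics An [optical_params()] object.
#' @param timestamp Acquisition time in seconds from the start of the series.
#' @return An object of class `complex_bscan`.
#' @export
complex_bscan <- function(data, optics, timestamp = 0) {
  stopifnot(is.matrix(data), nrow(data) >= 2L, ncol(data) >= 2L,
            inherits(optics, "optical_params"),
            is.numeric(timestamp), length(timestamp) == 1L,
            is.finite(timestamp))
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (!all(is.finite(Re(data)) & is.finite(Im(data))))
    stop("complex_bscan: all values must be finite")
  structure(list(data = data, optics = optics,
                 timestamp = as.numeric(timestamp)),
            class = "complex_bscan")
}

#' @export
print.complex_bscan <- function(x, ...) {
  cat(sprintf("complex_bscan: %d x %d px, t = %g s\n",
              nrow(x$data), ncol(x$data), x$timestamp))
  print(x$optics)
  invisible(x)
}

#' @export
dim.complex_bscan <- function(x) dim(x$data)

#' Time-ordered series of complex B-scans
#'
#' All frames must share grid shape and optics; timestamps must be strictly
#' increasing and uniformly spaced at `dt` within a 1% tolerance.
#'
#' @param frames List of [complex_bscan()] objects in acquisition order.
#' @param dt Interframe interval in seconds.
#' @return An object of class `bscan_series`.
#' @export
bscan_series <- function(frames, dt = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L, dt > 0)
  if (!all(vapply(frames, inherits, logical(1), "complex_bscan")))
    stop("bscan_series: frames must all be complex_bscan objects")
  d0 <- dim(frames[[1]]$data)
  for (f in frames) {
    if (!identical(dim(f$data), d0))
      stop("bscan_series: frames do not share a common grid shape")
    if (!same_optics(f$optics, frames[[1]]$optics))
      stop("bscan_series: frames do not share optics")
  }
  ts <- vapply(frames, `[[`, numeric(1), "timestamp")
  if (length(ts) > 1L) {
    gaps <- diff(ts)
    if (any(gaps <= 0))
      stop("bscan_series: timestamps must be strictly increasing")
    if (any(abs(gaps - dt) > 0.01 * dt))
      stop("bscan_series: interframe spacing deviates from dt by more than 1%")
  }
  structure(list(frames = frames, dt = as.numeric(dt),
                 timestamps = ts, optics = frames[[1]]$optics),
            class = "bscan_series")
}

#' @export
print.bscan_series <- function(x, ...) {
  cat(sprintf("bscan_series: %d frames of %d x %d px, dt = %g s\n",
              length(x$frames), nrow(x$frames[[1]]$data),
              ncol(x$frames[[1]]$data), x$dt))
  invisible(x)
}

#' @export
length.bscan_series <- function(x) length(x$frames)
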