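# B-scan container: a single binary file holding a JSON header (grid shape,
# timestamps, optics attributes) followed by raw little-endian float64
# real/imag planes, one pair per frame. A JSON sidecar (<path>.json)
# duplicates the attributes for human inspection. Round trips are bit-exact.

OCE_MAGIC <- "OCEBSCN1"

#' Write a B-scan series container
#'
#' @param series A [bscan_series()].
#' @param path Output file path (conventionally `.oce`).
#' @return `path`, invisibly. Also writes a `<path>.json` sidecar with the
#'   acquisition attributes.
#' @export
write_bscan_series <- function(series, path) {
  stopifnot(inherits(series, "bscan_series"))
  op <- series$optics
  hdr <- list(n_rows = nrow(series$frames[[1]]$data),
              n_cols = ncol(series$frames[[1]]$data),
              n_frames = length(series$frames),
              dt_s = series$dt,
              timestamps_s = series$timestamps,
              lambda0_nm = op$lambda0_nm, n = op$n,
              dz_air_um = op$dz_air_um, dx_um = op$dx_um)
  hjson <- jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(OCE_MAGIC, con, nchars = 8L, eos = NULL)
  hraw <- charToRaw(as.character(hjson))
  writeBin(length(hraw), con, size = 4L, endian = "little")
  writeBin(hraw, con)
  for (f in series$frames) {
    writeBin(as.numeric(Re(f$data)), con, size = 8L, endian = "little")
    writeBin(as.numeric(Im(f$data)), con, size = 8L, endian = "little")
  }
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a B-scan series container
#'
#' @param path Path written by [write_bscan_series()].
#' @return A [bscan_series()].
#' @export
read_bscan_series <- function(path) {
  if (!file.exists(path)) stop("read_bscan_series: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readChar(con, nchars = 8L, useBytes = TRUE)
  if (!identical(magic, OCE_MAGIC))
    stop("read_bscan_series: not a B-scan container (bad magic)")
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  if (length(hlen) != 1L || hlen <= 0L || hlen > 1e7)
    stop("read_bscan_series: corrupt header length")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  for (att in c("lambda0_nm", "n", "dz_air_um", "dx_um", "n_rows", "n_cols",
                "n_frames", "dt_s", "timestamps_s"))
    if (is.null(hdr[[att]]))
      stop("read_bscan_series: container is missing required attribute '",
           att, "'")
  op <- optical_params(hdr$lambda0_nm, hdr$n, hdr$dz_air_um, hdr$dx_um)
  M <- hdr$n_rows; J <- hdr$n_cols
  frames <- vector("list", hdr$n_frames)
  for (k in seq_len(hdr$n_frames)) {
    re <- readBin(con, "numeric", n = M * J, size = 8L, endian = "little")
    im <- readBin(con, "numeric", n = M * J, size = 8L, endian = "little")
    if (length(re) != M * J || length(im) != M * J)
      stop("read_bscan_series: truncated frame data")
    frames[[k]] <- complex_bscan(
      matrix(complex(real = re, imaginary = im), M, J), op,
      timestamp = hdr$timestamps_s[k])
  }
  bscan_series(frames, hdr$dt_s)
}

#' Write a ground-truth bundle alongside a simulated container
#'
#' Stores the depth/time grids and the concentration, cumulative-strain and
#' displacement matrices as a JSON header plus raw float64 planes (same
#' binary convention as the B-scan container).
#'
#' @param truth A [ground_truth_bundle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth_bundle"))
  hdr <- list(n_depths = length(truth$z_um), n_times = length(truth$t_s),
              z_um = truth$z_um, t_s = truth$t_s,
              template = truth$spec$template,
              k_pos = truth$spec$k_pos, k_neg = truth$spec$k_neg,
              layer_depth_um = truth$spec$layer_depth_um,
              layer_strain = truth$spec$layer_strain,
              D_m2s = truth$spec$diffusion$D, C0 = truth$spec$diffusion$C0,
              time_profile = truth$spec$time_profile)
  hjson <- charToRaw(as.character(
    jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA)))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("OCETRUT1", con, nchars = 8L, eos = NULL)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (m in list(truth$C, truth$eps_true, truth$U_true, truth$eps_eulerian))
    writeBin(as.numeric(m), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a ground-truth bundle
#' @param path Path written by [write_ground_truth()].
#' @return A [ground_truth_bundle()].
#' @export
read_ground_truth <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readChar(con, nchars = 8L, useBytes = TRUE)
  if (!identical(magic, "OCETRUT1"))
    stop("read_ground_truth: not a ground-truth file")
  hlen <- readBin(con, "integer", size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)))
  L <- hdr$n_depths; Tn <- hdr$n_times
  rd <- function() matrix(readBin(con, "numeric", n = L * Tn, size = 8L,
                                  endian = "little"), L, Tn)
  C <- rd(); eps <- rd(); U <- rd(); eul <- rd()
  spec <- strain_field_spec(hdr$template, hdr$k_pos, hdr$k_neg,
                            hdr$layer_depth_um, hdr$layer_strain,
                            diffusion_params(hdr$D_m2s, hdr$C0),
                            time_profile = hdr$time_profile)
  structure(list(z_um = hdr$z_um, t_s = hdr$t_s, C = C, eps_true = eps,
                 U_true = U, eps_eulerian = eul, spec = spec),
            class = "ground_truth_bundle")
}

#' Export a strain map as single-precision TIFF plus CSV of window means
#'
#' The TIFF stores the strain affinely rescaled to `[0, 1]` (32-bit float;
#' out-of-range floats are not portable in baseline TIFF); the offset and
#' scale needed to recover physical strain are recorded in a `<path>.json`
#' sidecar. The validity mask is written as an 8-bit TIFF
#' (`<path>_mask.tif`), and block means of the strain over the processing
#' window go to `<path>.csv` (columns `depth_px`, `lateral_px`, `strain`),
#' which is the map at its effective resolution.
#'
#' @param map A `strain_map` or `cumulative_strain_map`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
export_strain_map <- function(map, path) {
  eps <- if (inherits(map, "cumulative_strain_map")) map$eps_cum else map$eps
  optics <- map$optics
  rng <- range(eps, na.rm = TRUE)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  img <- (eps - rng[1]) / scale
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  tiff::writeTIFF(matrix(as.numeric(map$mask), nrow(eps)),
                  sub("\\.tiff?$", "_mask.tif", path),
                  bits.per.sample = 8L)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale,
         note = "strain = tiff_value * scale + offset; mask==0 is invalid",
         window_z_um = map$window_z_um, window_x_um = map$window_x_um,
         depth_convention = map$depth_convention),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  wz <- odd_px(map$window_z_um, dz_phys_um(optics))
  wx <- odd_px(map$window_x_um, optics$dx_um)
  zb <- seq(1L, nrow(eps) - wz + 1L, by = max(1L, wz %/% 2L))
  xb <- seq(1L, ncol(eps) - wx + 1L, by = max(1L, wx %/% 2L))
  rows <- expand.grid(depth_px = zb, lateral_px = xb)
  rows$strain <- mapply(function(i, j)
    mean(eps[i:(i + wz - 1L), j:(j + wx - 1L)], na.rm = TRUE),
    rows$depth_px, rows$lateral_px)
  utils::write.csv(rows, sub("\\.tiff?$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' Write a depth profile to CSV
#' @param p A [depth_profile()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(p, path) {
  utils::write.csv(data.frame(depth_um = p$depth_um, time_s = p$t,
                              strain = p$strain),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a waterfall diagram to CSV (long format)
#' @param w A [strain_waterfall()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_waterfall_csv <- function(w, path) {
  df <- data.frame(time_s = rep(w$time_s, times = length(w$depth_um)),
                   depth_um = rep(w$depth_um, each = length(w$time_s)),
                   strain = as.vector(w$strain))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an extrema track to CSV
#' @param track An [extrema_kinetics()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Render a waterfall diagram to PNG
#' @param w A [strain_waterfall()].
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
plot_waterfall <- function(w, path) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(x = w$time_s, y = w$depth_um, z = w$strain,
                  col = pal, ylim = rev(range(w$depth_um)),
                  xlab = "time (s)", ylab = "depth (um)",
                  main = "cumulative strain waterfall")
  invisible(path)
}

#' Render extrema/neutral-line kinetics to PNG
#' @param track An [extrema_kinetics()] result.
#' @param path PNG path.
#' @return `path`, invisibly.
#' @export
plot_track <- function(track, path) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off(), add = TRUE)
  ylim <- rev(range(c(track$depth_min_um, track$depth_max_um,
                      track$depth_neutral_um), na.rm = TRUE))
  graphics::plot(track$time_s, track$depth_max_um, col = "red", pch = 19,
                 ylim = ylim, xlab = "time (s)", ylab = "depth (um)",
                 main = "strain extrema and neutral line")
  graphics::points(track$time_s, track$depth_min_um, col = "blue", pch = 19)
  graphics::lines(track$time_s, track$depth_neutral_um, col = "black",
                  lwd = 2)
  graphics::legend("topright", c("max (dilatation)", "min (shrinkage)",
                                 "neutral line"),
                   col = c("red", "blue", "black"),
                   pch = c(19, 19, NA), lty = c(NA, NA, 1))
  invisible(path)
}
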