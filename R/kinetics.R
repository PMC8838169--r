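#' Laterally averaged strain depth profile
#'
#' Extracts the depth dependence of cumulative strain below the detected
#' surface: per column, strain is read off from the per-column surface
#' downwards (depth 0 at the surface), columns within the lateral averaging
#' window are averaged, and the result is smoothed axially over the axial
#' averaging window. Depth is reported in physical um (optical pixels times
#' `dz_air / n`). When the strain is very small the axial window is
#' automatically widened from 80 to 160 um to suppress noise (triggered when
#' the 95th percentile of |strain| falls below `widen_threshold`).
#'
#' @param map A `cumulative_strain_map` (or `strain_map`).
#' @param surface A [detect_surface()] result.
#' @param optics An [optical_params()]; defaults to the map's.
#' @param avg_window_z_um,avg_window_x_um Averaging-window size (um),
#'   default 80 x 800.
#' @param depth_limit_um Maximum analyzable depth below the surface (um),
#'   default 900.
#' @param x_center Centre column of the lateral window (default: middle).
#' @param auto_widen Widen the axial window to 160 um for weak strains.
#' @param widen_threshold Widening trigger on the 95th percentile of
#'   |strain| (default 2e-4).
#' @return Object of class `depth_profile`: `depth_um` (strictly increasing,
#'   0 at the surface), `strain`, averaging metadata and the observation
#'   time `t`.
#' @export
depth_profile <- function(map, surface, optics = map$optics,
                          avg_window_z_um = 80, avg_window_x_um = 800,
                          depth_limit_um = 900, x_center = NULL,
                          auto_widen = TRUE, widen_threshold = 2e-4) {
  eps <- if (inherits(map, "cumulative_strain_map")) map$eps_cum else map$eps
  stopifnot(inherits(surface, "surface_map"),
            inherits(optics, "optical_params"))
  M <- nrow(eps); J <- ncol(eps)
  dzp <- dz_phys_um(optics)
  wx <- max(1L, as.integer(round(avg_window_x_um / optics$dx_um)))
  if (wx > J) stop("depth_profile: lateral averaging window exceeds the grid")
  if (is.null(x_center)) x_center <- (J + 1L) %/% 2L
  j0 <- max(1L, x_center - wx %/% 2L)
  j1 <- min(J, j0 + wx - 1L)
  j0 <- max(1L, j1 - wx + 1L)
  cols <- j0:j1

  surf <- surface$surf[cols]
  L <- min(floor(depth_limit_um / dzp), min(M - surf))
  if (L * dzp < avg_window_z_um)
    stop("depth_profile: analyzable depth smaller than one axial window")
  vals <- matrix(NA_real_, L, length(cols))
  for (jj in seq_along(cols))
    vals[, jj] <- eps[surf[jj] + seq_len(L), cols[jj]]
  lat <- rowMeans(vals, na.rm = TRUE)
  lat[!is.finite(lat)] <- NA_real_

  wz_px <- as.integer(round(avg_window_z_um / dzp))
  if (wz_px %% 2L == 0L) wz_px <- wz_px + 1L
  prof <- running_mean_partial(lat, max(1L, wz_px))

  if (isTRUE(auto_widen) && avg_window_z_um < 160 &&
      is.finite(widen_threshold)) {
    q95 <- stats::quantile(abs(prof), 0.95, na.rm = TRUE, names = FALSE)
    if (is.finite(q95) && q95 < widen_threshold)
      return(depth_profile(map, surface, optics,
                           avg_window_z_um = 160,
                           avg_window_x_um = avg_window_x_um,
                           depth_limit_um = depth_limit_um,
                           x_center = x_center, auto_widen = FALSE))
  }

  structure(list(depth_um = (seq_len(L) - 1) * dzp, strain = prof,
                 avg_window_z_um = avg_window_z_um,
                 avg_window_x_um = avg_window_x_um,
                 depth_limit_um = depth_limit_um,
                 t = if (!is.null(map$t)) map$t else NA_real_,
                 n_cols = length(cols), normalized = FALSE),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf(
    "depth_profile: %d depths to %.0f um, window %g x %g um, t = %g s%s\n",
    length(x$depth_um), max(x$depth_um), x$avg_window_z_um,
    x$avg_window_x_um, x$t, if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize a depth profile to its maximal positive strain
#'
#' Divides the whole profile by its maximal positive strain value, so the
#' positive peak becomes 1. Profiles containing no positive strain cannot be
#' normalized this way and raise an error.
#'
#' @param p A [depth_profile()].
#' @return The normalized `depth_profile` (idempotent).
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "depth_profile"))
  pos <- p$strain[is.finite(p$strain) & p$strain > 0]
  if (length(pos) == 0L)
    stop("normalize_profile: no positive strain in profile; ",
         "normalization undefined")
  p$strain <- p$strain / max(pos)
  p$normalized <- TRUE
  p
}

#' Stack depth profiles into a waterfall diagram
#'
#' A waterfall diagram is a strain matrix indexed by (time, depth): each row
#' is one profile, rows ascend in time.
#'
#' @param profiles List of [depth_profile()] sharing the same depth axis.
#' @return Object of class `strain_waterfall` with `strain`
#'   (time x depth matrix), `time_s`, `depth_um`.
#' @export
strain_waterfall <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (!all(vapply(profiles, inherits, logical(1), "depth_profile")))
    stop("strain_waterfall: need a list of depth_profile objects")
  d0 <- profiles[[1]]$depth_um
  for (p in profiles)
    if (length(p$depth_um) != length(d0) ||
        any(abs(p$depth_um - d0) > 1e-9))
      stop("strain_waterfall: profiles do not share a depth axis")
  m <- do.call(rbind, lapply(profiles, `[[`, "strain"))
  structure(list(strain = m,
                 time_s = vapply(profiles, `[[`, numeric(1), "t"),
                 depth_um = d0,
                 avg_window_z_um = profiles[[1]]$avg_window_z_um,
                 avg_window_x_um = profiles[[1]]$avg_window_x_um),
            class = "strain_waterfall")
}

#' @export
print.strain_waterfall <- function(x, ...) {
  cat(sprintf("strain_waterfall: %d times x %d depths (to %.0f um)\n",
              nrow(x$strain), ncol(x$strain), max(x$depth_um)))
  invisible(x)
}

#' Track strain extrema and the neutral line over time
#'
#' Per waterfall row (timestamp): the global maximum and global minimum of
#' the profile (ties broken towards the shallower depth), and the neutral
#' (zero-strain) depth, linearly interpolated at the first sign change
#' encountered when moving from the positive extremum towards the negative
#' one — defined only when the two extrema bracket zero. Extrema lying within
#' one axial averaging window of the deep end of the analyzable range are
#' flagged unreliable (a minimum lying at or beyond the detectable depth
#' cannot be located correctly).
#'
#' @param w A [strain_waterfall()].
#' @param min_prominence Minimum |value| for an extremum to be reported
#'   (suppresses noise ties; default 0 reports all).
#' @return Object of class `extrema_track`, a data.frame with columns
#'   `time_s`, `depth_min_um`, `value_min`, `depth_max_um`, `value_max`,
#'   `depth_neutral_um`, `min_at_edge`, `max_at_edge`.
#' @export
extrema_kinetics <- function(w, min_prominence = 0) {
  stopifnot(inherits(w, "strain_waterfall"), nrow(w$strain) >= 1L)
  nt <- nrow(w$strain)
  depth <- w$depth_um
  edge <- max(depth) - w$avg_window_z_um
  out <- data.frame(time_s = w$time_s,
                    depth_min_um = NA_real_, value_min = NA_real_,
                    depth_max_um = NA_real_, value_max = NA_real_,
                    depth_neutral_um = NA_real_,
                    min_at_edge = FALSE, max_at_edge = FALSE)
  for (r in seq_len(nt)) {
    v <- w$strain[r, ]
    ok <- is.finite(v)
    if (!any(ok)) next
    vmax <- max(v[ok]); vmin <- min(v[ok])
    imax <- which(ok & v == vmax)[1]
    imin <- which(ok & v == vmin)[1]
    if (imax == imin) {  # constant profile: extrema indistinct
      if (abs(vmax) >= min_prominence) {
        out$depth_max_um[r] <- depth[imax]; out$value_max[r] <- vmax
      }
      next
    }
    if (abs(vmax) >= min_prominence) {
      out$depth_max_um[r] <- depth[imax]; out$value_max[r] <- vmax
      out$max_at_edge[r] <- depth[imax] >= edge
    }
    if (abs(vmin) >= min_prominence) {
      out$depth_min_um[r] <- depth[imin]; out$value_min[r] <- vmin
      out$min_at_edge[r] <- depth[imin] >= edge
    }
    if (vmin < 0 && vmax > 0) {
      step <- sign(imin - imax)
      i <- imax
      while (i != imin) {
        a <- v[i]; b <- v[i + step]
        if (is.finite(a) && is.finite(b) && a > 0 && b <= 0) {
          out$depth_neutral_um[r] <-
            depth[i] + (depth[i + step] - depth[i]) * a / (a - b)
          break
        }
        i <- i + step
      }
    }
  }
  class(out) <- c("extrema_track", "data.frame")
  out
}
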