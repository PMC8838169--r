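# Internal numeric helpers shared across the engine and kinetics modules.

# Summed-area table of a numeric matrix (zero-padded on top/left).
sat2d <- function(x) {
  M <- nrow(x); J <- ncol(x)
  p <- matrix(0, M + 1L, J + 1L)
  p[-1L, -1L] <- x
  p <- apply(p, 2L, cumsum)
  t(apply(p, 1L, cumsum))
}

# Sums over all wz x wx windows fully inside the matrix ("valid" output,
# size (M-wz+1) x (J-wx+1)). Works on numeric or complex input.
box_sum_valid <- function(x, wz, wx) {
  M <- nrow(x); J <- ncol(x)
  stopifnot(wz >= 1L, wx >= 1L)
  if (wz > M || wx > J)
    stop("processing window larger than the grid")
  one <- function(m) {
    p <- sat2d(m)
    p[(wz + 1L):(M + 1L), (wx + 1L):(J + 1L), drop = FALSE] -
      p[1L:(M - wz + 1L), (wx + 1L):(J + 1L), drop = FALSE] -
      p[(wz + 1L):(M + 1L), 1L:(J - wx + 1L), drop = FALSE] +
      p[1L:(M - wz + 1L), 1L:(J - wx + 1L), drop = FALSE]
  }
  if (is.complex(x)) {
    re <- one(Re(x)); im <- one(Im(x))
    matrix(complex(real = re, imaginary = im), nrow = nrow(re))
  } else {
    one(x)
  }
}

# Embed a "valid" window-sum matrix back onto the full grid at window
# centers (wz, wx odd); outside cells are NA.
embed_valid <- function(v, M, J, wz, wx) {
  out <- matrix(NA_real_, M, J)
  if (is.complex(v)) out <- matrix(NA_complex_, M, J)
  oz <- (wz - 1L) %/% 2L; ox <- (wx - 1L) %/% 2L
  out[(1L + oz):(M - wz + 1L + oz), (1L + ox):(J - wx + 1L + ox)] <- v
  out
}

# Convert a window size in physical um to an odd pixel count >= 3.
odd_px <- function(um, pitch_um) {
  px <- max(3L, as.integer(round(um / pitch_um)))
  if (px %% 2L == 0L) px <- px + 1L
  px
}

# 1D phase unwrap along a vector: remove 2*pi jumps between neighbours.
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1L], d))
}

# Running mean along a vector with partial windows at the edges (window w odd).
running_mean_partial <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x); h <- (w - 1L) %/% 2L
  ok <- is.finite(x)
  xv <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xv)); cn <- c(0, cumsum(as.numeric(ok)))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  ifelse(k > 0, s / k, NA_real_)
}

# Lateral (column-wise) running median across columns for surface detection.
running_median_cols <- function(x, w) {
  if (w <= 1L) return(x)
  J <- ncol(x); h <- (w - 1L) %/% 2L
  out <- x
  for (j in seq_len(J)) {
    lo <- max(1L, j - h); hi <- min(J, j + h)
    out[, j] <- apply(x[, lo:hi, drop = FALSE], 1L, stats::median)
  }
  out
}
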