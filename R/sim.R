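#' Diffusion parameters for the osmotic agent
#'
#' Constant-source half-space diffusion of an osmotic agent into the tissue:
#' diffusivity `D`, normalized surface concentration `C0`, and the intended
#' observation duration.
#'
#' @param D Diffusion coefficient (m^2/s), > 0. Glycerol in cartilage is of
#'   order 1e-9 m^2/s.
#' @param C0 Normalized surface concentration in (0, 1].
#' @param duration Observation duration (s).
#' @return Object of class `diffusion_params`.
#' @export
diffusion_params <- function(D = 1e-9, C0 = 1, duration = 600) {
  stopifnot(D > 0, C0 > 0, C0 <= 1, duration > 0)
  structure(list(D = D, C0 = C0, duration = duration),
            class = "diffusion_params")
}

#' Concentration of a diffusing agent below the surface
#'
#' Half-space solution with a constant-concentration boundary:
#' `C(z, t) = C0 * erfc(z / (2 sqrt(D t)))`. At `t = 0` the limiting step
#' function is returned. The penetration length scale is `sqrt(D t)`
#' (about 0.55 mm for D = 1e-9 m^2/s after 300 s).
#'
#' @param z_um Depth(s) below the surface (um, >= 0).
#' @param t_s Elapsed time (s, >= 0).
#' @param p A [diffusion_params()] object.
#' @return Normalized concentration value(s) in `[0, C0]`.
#' @export
diffusion_concentration <- function(z_um, t_s, p) {
  stopifnot(inherits(p, "diffusion_params"), all(z_um >= 0), t_s >= 0)
  if (t_s <= 0) return(ifelse(z_um <= 0, p$C0, 0))
  L <- 2 * sqrt(p$D * t_s) * 1e6   # um
  p$C0 * pracma::erfc(z_um / L)
}

#' Specification of an imposed osmotic strain field
#'
#' Defines the ground-truth cumulative strain field `eps(z, t)` the simulator
#' imposes. Templates:
#' \describe{
#'   \item{uniform}{`eps = k_pos` everywhere (times `t` if
#'     `time_profile = "linear"`, i.e. `k_pos` is a rate in 1/s).}
#'   \item{ramp}{linear in depth, 0 at the surface to `k_pos` at the deepest
#'     point.}
#'   \item{single_front}{`eps = k_pos * C(z, t)`: dilatation following the
#'     diffusion front.}
#'   \item{alternating_sign}{`eps = C * (k_pos - k_neg * (1 - C))`: positive
#'     near the surface where `C ~ C0`, negative deeper, changing sign where
#'     `C = 1 - k_pos / k_neg` — the alternating-sign osmotic profile seen
#'     under strongly hypertonic agents.}
#'   \item{subsurface_layer}{`single_front` plus an additive thin shrinkage
#'     band of thickness `layer_depth_um` and strain `layer_strain` at the
#'     surface (the ~60-80 um subsurface shrinkage layer).}
#' }
#' Parameter sets producing `|eps| > 0.5` anywhere are rejected: the
#' estimator is not validated beyond cumulative strains of ~0.4-0.5.
#'
#' @param template One of `"uniform"`, `"ramp"`, `"single_front"`,
#'   `"alternating_sign"`, `"subsurface_layer"`.
#' @param k_pos,k_neg Dilatation / shrinkage coefficients (|k| <= 1).
#' @param layer_depth_um,layer_strain Thin-layer parameters.
#' @param diffusion A [diffusion_params()] object.
#' @param time_profile `"constant"` (static cumulative field) or `"linear"`
#'   (field grows linearly with time; only meaningful for `uniform`/`ramp`).
#' @return Object of class `strain_field_spec`.
#' @export
strain_field_spec <- function(template = c("uniform", "ramp", "single_front",
                                           "alternating_sign",
                                           "subsurface_layer"),
                              k_pos = 0, k_neg = 0,
                              layer_depth_um = 70, layer_strain = -0.05,
                              diffusion = diffusion_params(),
                              time_profile = c("constant", "linear")) {
  template <- match.arg(template)
  time_profile <- match.arg(time_profile)
  stopifnot(abs(k_pos) <= 1, abs(k_neg) <= 1, layer_depth_um > 0,
            inherits(diffusion, "diffusion_params"))
  if (template == "alternating_sign" && k_neg == 0)
    stop("alternating_sign template needs k_neg > 0")
  structure(list(template = template, k_pos = k_pos, k_neg = k_neg,
                 layer_depth_um = layer_depth_um, layer_strain = layer_strain,
                 diffusion = diffusion, time_profile = time_profile),
            class = "strain_field_spec")
}

#' Evaluate the ground-truth cumulative strain field
#'
#' @param spec A [strain_field_spec()].
#' @param z_um Depths below the surface (um).
#' @param t_s Elapsed time (s).
#' @return Cumulative strain at each depth (dimensionless).
#' @export
strain_field <- function(spec, z_um, t_s) {
  stopifnot(inherits(spec, "strain_field_spec"), all(z_um >= 0), t_s >= 0)
  tf <- if (spec$time_profile == "linear") t_s else 1
  eps <- switch(spec$template,
    uniform = rep(spec$k_pos * tf, length(z_um)),
    ramp = spec$k_pos * tf * (z_um / max(z_um, 1)),
    single_front = {
      C <- diffusion_concentration(z_um, t_s, spec$diffusion)
      spec$k_pos * C
    },
    alternating_sign = {
      C <- diffusion_concentration(z_um, t_s, spec$diffusion)
      C * (spec$k_pos - spec$k_neg * (1 - C))
    },
    subsurface_layer = {
      C <- diffusion_concentration(z_um, t_s, spec$diffusion)
      spec$k_pos * C + spec$layer_strain * (z_um < spec$layer_depth_um)
    })
  if (max(abs(eps)) > 0.5)
    stop("strain_field: parameters produce |strain| > 0.5, outside the ",
         "validated regime")
  eps
}

#' Integrate a strain profile into an axial displacement profile
#'
#' `U(z) = integral of eps from 0 to z` (um), with zero displacement at the
#' surface: deeper material moves relative to the surface.
#'
#' @param z_um Strictly increasing depths (um) starting at or near 0.
#' @param eps Strain at each depth.
#' @return Displacement (um) at each depth.
#' @export
displacement_field <- function(z_um, eps) {
  stopifnot(length(z_um) == length(eps), !is.unsorted(z_um))
  as.numeric(pracma::cumtrapz(z_um, eps))
}

#' Ground-truth bundle: concentration, strain, displacement over time
#'
#' Besides the imposed material (engineering) cumulative strain `eps_true`
#' and its displacement integral `U_true`, the bundle carries
#' `eps_eulerian`: the frame-by-frame sum of incremental strains evaluated on
#' the fixed pixel grid, i.e. what an ideal instrument that sums interframe
#' strains at fixed depth (the standard cumulative-strain bookkeeping)
#' reports, measured from the first listed time. For small strains the two
#' coincide; for a uniform field of engineering strain `e` the Eulerian sum
#' converges to `log(1 + e)`.
#'
#' @param spec A [strain_field_spec()].
#' @param z_um Depth grid below the surface (um).
#' @param t_s Vector of frame times (s).
#' @return Object of class `ground_truth_bundle` with matrices `C`,
#'   `eps_true`, `U_true`, `eps_eulerian` of size
#'   `length(z_um) x length(t_s)`.
#' @export
ground_truth_bundle <- function(spec, z_um, t_s) {
  L <- length(z_um); Tn <- length(t_s)
  C <- eps <- U <- eul <- matrix(0, L, Tn)
  for (k in seq_len(Tn)) {
    C[, k] <- diffusion_concentration(z_um, t_s[k], spec$diffusion)
    eps[, k] <- strain_field(spec, z_um, t_s[k])
    U[, k] <- displacement_field(z_um, eps[, k])
  }
  for (k in seq_len(Tn)[-1]) {
    # material point now observed at grid depth z sat at zeta at t_{k-1}
    zmap <- z_um + U[, k - 1L]
    zeta <- stats::approx(zmap, z_um, xout = z_um, rule = 2)$y
    e1 <- stats::approx(z_um, eps[, k - 1L], xout = zeta, rule = 2)$y
    e2 <- stats::approx(z_um, eps[, k], xout = zeta, rule = 2)$y
    eul[, k] <- eul[, k - 1L] + (e2 - e1) / (1 + e1)
  }
  structure(list(z_um = z_um, t_s = t_s, C = C, eps_true = eps, U_true = U,
                 eps_eulerian = eul, spec = spec),
            class = "ground_truth_bundle")
}

#' Convert Eulerian-summed cumulative strain to engineering strain
#'
#' Summing interframe strains on a fixed pixel grid accumulates increments of
#' `d eps / (1 + eps)`, so for depth-uniform deformation the sum converges to
#' the logarithmic (Hencky) strain `log(1 + e)`. This helper inverts that:
#' `exp(x) - 1`. It is exact for depth-uniform fields and a first-order
#' correction otherwise (no axial re-registration is attempted).
#'
#' @param x Numeric (Eulerian cumulative strain), or a
#'   `cumulative_strain_map` whose `eps_cum` is converted in place.
#' @return Same type as `x`.
#' @export
engineering_strain <- function(x) {
  if (inherits(x, "cumulative_strain_map")) {
    x$eps_cum <- exp(x$eps_cum) - 1
    return(x)
  }
  exp(x) - 1
}

#' Speckle-field simulation parameters
#'
#' @param density_per_psf Scatterers per axial PSF length per column
#'   (default 20: fully developed speckle).
#' @param psf_fwhm_um Axial PSF FWHM in um (optical path). `NULL` derives it
#'   from the source: `(2 ln 2 / pi) * lambda0^2 / delta_lambda`
#'   (about 8.3 um for 1300 nm / 90 nm).
#' @param delta_lambda_nm Source spectral width (nm), used when
#'   `psf_fwhm_um` is `NULL`.
#' @param atten_per_um Amplitude attenuation coefficient (1/um of physical
#'   depth).
#' @param snr_db Signal-to-noise ratio of the additive circular complex
#'   noise, in dB relative to the mean in-tissue signal power.
#' @param seed Master seed; fixes scatterer placement and all noise streams.
#' @return Object of class `speckle_params`.
#' @export
speckle_params <- function(density_per_psf = 20, psf_fwhm_um = NULL,
                           delta_lambda_nm = 90, atten_per_um = 0.0015,
                           snr_db = 30, seed = 1L) {
  stopifnot(density_per_psf > 0, is.null(psf_fwhm_um) || psf_fwhm_um > 0,
            delta_lambda_nm > 0, atten_per_um >= 0)
  structure(list(density_per_psf = density_per_psf,
                 psf_fwhm_um = psf_fwhm_um,
                 delta_lambda_nm = delta_lambda_nm,
                 atten_per_um = atten_per_um,
                 snr_db = snr_db, seed = as.integer(seed)),
            class = "speckle_params")
}

psf_fwhm <- function(sp, optics) {
  if (!is.null(sp$psf_fwhm_um)) return(sp$psf_fwhm_um)
  (2 * log(2) / pi) * (optics$lambda0_nm * 1e-3)^2 / (sp$delta_lambda_nm * 1e-3)
}

# Draw the random scatterer population once; positions are physical depths
# below the surface (um), persistent across frames.
make_scatterers <- function(sp, optics, n_rows, n_cols, surface_px) {
  fwhm_opt <- psf_fwhm(sp, optics)
  fwhm_phys <- fwhm_opt / optics$n
  zmax <- (n_rows - surface_px) * dz_phys_um(optics) + 3 * fwhm_phys
  n_per_col <- max(2L, ceiling(sp$density_per_psf * zmax / fwhm_phys))
  set.seed(sp$seed)
  N <- n_per_col * n_cols
  # unit-strength scatterers: phase randomness comes from the positions
  # (many carrier wraps per PSF), which keeps the summed field circular
  # Gaussian (Rayleigh amplitude) already at moderate densities
  list(zeta = stats::runif(N, 0, zmax),
       s = rep(1, N),
       col = rep(seq_len(n_cols), each = n_per_col),
       fwhm_opt = fwhm_opt, zmax = zmax)
}

# Render one complex frame from the scatterer population under a displacement
# field U(z) (um). U may be NULL (no motion), a scalar, or a function of
# physical depth.
render_frame <- function(scat, sp, optics, n_rows, n_cols, surface_px,
                         U = NULL, noise_seed = NULL, timestamp = 0) {
  lam <- optics$lambda0_nm * 1e-3   # um
  zeta <- scat$zeta
  if (!is.null(U)) {
    u <- if (is.function(U)) U(zeta) else rep_len(as.numeric(U), length(zeta))
    zeta <- zeta + u
  }
  amp <- scat$s * exp(-sp$atten_per_um * pmax(zeta, 0))
  keep <- zeta >= 0
  zeta <- zeta[keep]; amp <- amp[keep]; col <- scat$col[keep]
  phase <- 4 * pi * optics$n * zeta / lam
  field <- amp * exp(1i * phase)
  pos <- surface_px + 1 + optics$n * zeta / optics$dz_air_um  # fractional row
  sigma <- psf_fwhm(sp, optics) / (2 * sqrt(2 * log(2)))
  K <- as.integer(ceiling(3 * sigma / optics$dz_air_um))
  accR <- numeric(n_rows * n_cols); accI <- numeric(n_rows * n_cols)
  base_row <- round(pos)
  for (o in seq.int(-K, K)) {
    m <- base_row + o
    inb <- m >= 1 & m <= n_rows
    if (!any(inb)) next
    w <- exp(-(((m[inb] - pos[inb]) * optics$dz_air_um)^2) / (2 * sigma^2))
    v <- field[inb] * w
    idx <- (col[inb] - 1L) * n_rows + m[inb]
    r <- rowsum(cbind(Re(v), Im(v)), idx)
    ii <- as.integer(rownames(r))
    accR[ii] <- accR[ii] + r[, 1L]
    accI[ii] <- accI[ii] + r[, 2L]
  }
  img <- matrix(complex(real = accR, imaginary = accI), n_rows, n_cols)
  if (is.finite(sp$snr_db) && !is.null(noise_seed)) {
    tissue <- img[(surface_px + 1L):n_rows, , drop = FALSE]
    P <- mean(Mod(tissue)^2)
    sn <- sqrt(P * 10^(-sp$snr_db / 10))
    set.seed(noise_seed)
    img <- img + sn / sqrt(2) *
      matrix(complex(real = stats::rnorm(n_rows * n_cols),
                     imaginary = stats::rnorm(n_rows * n_cols)),
             n_rows, n_cols)
  }
  complex_bscan(img, optics, timestamp = timestamp)
}

#' Simulate one speckle B-scan
#'
#' Point-scatterer measurement model: each column sums scatterer
#' contributions `s_k * exp(i 4 pi n z_k / lambda0) * G(m dz_air - n z_k)`
#' with a Gaussian axial PSF `G`, amplitude attenuation `exp(-mu z)`, and
#' additive circular complex noise at `snr_db`. A displacement field moves
#' scatterers to `z_k + U(z_k)` before rendering, so the interframe phase of
#' two scans rendered from the same seed equals `4 pi n U / lambda0`.
#'
#' @param sp A [speckle_params()]; `sp$seed` fixes the scatterer population
#'   and the noise, so identical calls give identical frames.
#' @param optics An [optical_params()].
#' @param U_field `NULL`, a scalar (um), or a function of physical depth (um)
#'   returning axial displacement (um).
#' @param n_rows,n_cols Grid size (pixels).
#' @param surface_px Air pixels above the sample surface.
#' @param timestamp Frame time (s).
#' @return A [complex_bscan()].
#' @export
speckle_scan <- function(sp, optics, U_field = NULL, n_rows = 512L,
                         n_cols = 256L, surface_px = 40L, timestamp = 0) {
  stopifnot(inherits(sp, "speckle_params"), inherits(optics, "optical_params"),
            n_rows > surface_px)
  scat <- make_scatterers(sp, optics, n_rows, n_cols, surface_px)
  if (length(scat$zeta) == 0L) stop("speckle_scan: zero scatterers")
  render_frame(scat, sp, optics, n_rows, n_cols, surface_px,
               U = U_field, noise_seed = sp$seed + 1L, timestamp = timestamp)
}

#' Simulate a B-scan series under an imposed osmotic strain field
#'
#' Renders `n_frames` frames at `t = t_start, t_start + dt, ...` from one
#' persistent scatterer population. At each frame time the cumulative strain
#' field of `spec` is evaluated on the depth grid, integrated into a
#' displacement field (zero at the surface), and the scatterers are moved to
#' `z + U(z, t)`. Ground truth (concentration, cumulative strain,
#' displacement) is bundled at every timestamp. Fully reproducible from
#' `sp$seed`.
#'
#' @param spec A [strain_field_spec()].
#' @param sp A [speckle_params()].
#' @param optics An [optical_params()].
#' @param n_frames Number of frames (>= 2).
#' @param dt Interframe interval (s).
#' @param n_rows,n_cols Grid size (pixels).
#' @param surface_px Air pixels above the surface.
#' @param t_start Time of the first frame (s).
#' @return List with `series` (a [bscan_series()]), `truth`
#'   (a [ground_truth_bundle()]), and `surface_px`.
#' @export
simulate_series <- function(spec, sp, optics, n_frames = 11L, dt = 1,
                            n_rows = 512L, n_cols = 256L, surface_px = 40L,
                            t_start = 0) {
  stopifnot(inherits(spec, "strain_field_spec"), n_frames >= 2L, dt > 0)
  scat <- make_scatterers(sp, optics, n_rows, n_cols, surface_px)
  L <- n_rows - surface_px
  z <- (seq_len(L) - 1) * dz_phys_um(optics)
  t_s <- t_start + (seq_len(n_frames) - 1) * dt
  truth <- ground_truth_bundle(spec, z, t_s)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    Ufun <- stats::approxfun(z, truth$U_true[, k], rule = 2, yleft = 0)
    frames[[k]] <- render_frame(
      scat, sp, optics, n_rows, n_cols, surface_px, U = Ufun,
      noise_seed = (sp$seed + 104729L * k) %% .Machine$integer.max,
      timestamp = t_s[k])
  }
  list(series = bscan_series(frames, dt), truth = truth,
       surface_px = surface_px)
}
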