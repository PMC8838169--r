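#' Published cumulative-strain extrema for common osmotic agents
#'
#' Reported cumulative axial strain extrema (dimensionless) in porcine costal
#' cartilage after 600 s of agent diffusion, for glycerol at several
#' concentrations and for ~40% iohexol (Omnipaque), as printed in the
#' literature. Shipped as a small reference table for worked examples and
#' cross-regime comparisons.
#'
#' @return data.frame with columns `agent`, `concentration_pct`,
#'   `strain_min`, `strain_max`, `observation_s`.
#' @export
published_strain_extrema <- function() {
  utils::read.csv(system.file("extdata", "published_strain_extrema.csv",
                              package = "vectorOCE"))
}

#' Ratios of strain extrema between concentration regimes
#'
#' Computes the characteristic intensity ratios between glycerol
#' concentration regimes from [published_strain_extrema()]: how much stronger
#' shrinkage and dilatation become as the agent concentration grows.
#'
#' @return Named list of dimensionless ratios.
#' @export
concentration_regime_ratios <- function() {
  x <- published_strain_extrema()
  g <- function(c_pct, col) x[x$agent == "glycerol" &
                                x$concentration_pct == c_pct, col]
  list(
    shrinkage_100_vs_35 = abs(g(100, "strain_min") / g(35, "strain_min")),
    dilatation_100_vs_35 = g(100, "strain_max") / g(35, "strain_max"),
    dilatation_35_vs_7 = g(35, "strain_max") / g(7, "strain_max"),
    dilatation_100_vs_7 = g(100, "strain_max") / g(7, "strain_max"),
    shrinkage_100_vs_25 = abs(g(100, "strain_min") / g(25, "strain_min")))
}

#' Declared spatial resolution of a strain map
#'
#' The effective resolution of phase-gradient strain maps is about half the
#' processing window used for the local slope estimation.
#'
#' @param window_um Processing-window size (um), default 100.
#' @return Resolution in um.
#' @export
strain_resolution_um <- function(window_um = 100) window_um / 2

#' Diffusion penetration depth scale
#'
#' The characteristic penetration length of a diffusion front,
#' `sqrt(D * t)`.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param t_s Elapsed time (s).
#' @return Penetration scale in mm.
#' @export
penetration_depth_mm <- function(D = 1e-9, t_s = 300) sqrt(D * t_s) * 1e3
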