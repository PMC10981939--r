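#' Accessible volume of a size-exclusion bead
#'
#' The fraction of a bead's polymer matrix reachable by a small tracer,
#' estimated as the inside/outside intensity ratio of a dextran solution.
#' Ratios above 1 are clamped to 1 with a warning (a fully accessible bead).
#'
#' @param dextran_in,dextran_out background-corrected dextran intensities
#'   inside and outside the bead; `dextran_out` must be positive.
#' @return rho0 in (0, 1], vectorized.
#' @export
accessible_volume <- function(dextran_in, dextran_out) {
  if (any(!is.finite(dextran_out)) || any(dextran_out <= 0))
    stop_invalid("outside dextran intensity must be positive")
  if (any(dextran_in < 0)) stop_invalid("inside dextran intensity must be >= 0")
  rho0 <- dextran_in / dextran_out
  if (any(rho0 > 1)) {
    warning(sum(rho0 > 1), " accessible-volume ratio(s) > 1 clamped to 1")
    rho0 <- pmin(rho0, 1)
  }
  rho0
}

#' Fill fraction of a labelled protein in a size-exclusion bead
#'
#' `f = I_in / (I_out * rho0)`: the tracer-corrected inside/outside
#' concentration ratio, a proxy for the fraction of the protein's assemblies
#' smaller than the bead cutoff. Values are deliberately not clamped --
#' fills slightly above 1 are legitimate noise and must survive for the
#' step-CV metric.
#'
#' @param I_in,I_out background-corrected intensities; `I_out > 0`.
#' @param rho0 accessible volume from [accessible_volume()]; `> 0`.
#' @return fill fraction(s), vectorized.
#' @export
fill_fraction <- function(I_in, I_out, rho0) {
  if (any(!is.finite(I_out)) || any(I_out <= 0) ||
      any(!is.finite(rho0)) || any(rho0 <= 0))
    stop_invalid("`I_out` and `rho0` must be positive")
  if (any(I_in < 0)) stop_invalid("`I_in` must be >= 0")
  I_in / (I_out * rho0)
}

#' Step coefficient of variation of a fill-fraction profile
#'
#' The fill curve over ascending cutoffs is decomposed into successive
#' concentration steps, starting from 0 below the smallest cutoff and, by
#' default, appending a final step to 1 at an extrapolation size (1 um, the
#' scale above which microscopy shows no visible organization). The CV of
#' these steps (population SD / mean) summarizes the organization pattern:
#' a single dominant jump (all assemblies at one small scale) gives a high
#' CV, while organization spread across the mesoscale gives a low CV.
#'
#' @param fill fill fractions at the cutoffs.
#' @param cutoffs cutoff sizes in nm (>= 2; sorted internally).
#' @param extrapolate append the final step to fill = 1 at
#'   `extrapolate_to`? Default `TRUE`.
#' @param extrapolate_to extrapolation size in nm (anchor only; its value
#'   does not enter the CV).
#' @return The step CV (scale-free).
#' @export
step_cv <- function(fill, cutoffs, extrapolate = TRUE, extrapolate_to = 1000) {
  stopifnot(length(fill) == length(cutoffs))
  if (length(cutoffs) < 2) stop_invalid("need at least 2 cutoffs")
  o <- order(cutoffs)
  f <- fill[o]
  steps <- diff(c(0, f, if (extrapolate) 1))
  m <- mean(steps)
  if (m <= 0) stop_invalid("undefined CV: mean step is not positive")
  pop_sd(steps) / m
}

#' Hydrodynamic radius from the Stokes-Einstein relation
#'
#' `r = kB * T / (6 * pi * eta * D)`, converted to nm for a diffusion
#' constant given in um^2/s. Alternatively, in calibration mode, the radius
#' is obtained relative to a reference species of known radius measured in
#' the same medium: `r = r_ref * D_ref / D` (the medium viscosity cancels).
#'
#' @param D diffusion constant in um^2/s (> 0).
#' @param temperature temperature in kelvin; default 298.15.
#' @param eta dynamic viscosity in Pa s; default water at 25 C (8.9e-4).
#' @param reference optional list with `r` (nm) and `D` (um^2/s) of a
#'   calibration species; when given, `temperature` and `eta` are ignored.
#' @return hydrodynamic radius in nm, vectorized over `D`.
#' @export
stokes_einstein_radius <- function(D, temperature = 298.15, eta = 8.9e-4,
                                   reference = NULL) {
  if (any(!is.finite(D)) || any(D <= 0)) stop_invalid("`D` must be positive")
  if (!is.null(reference)) {
    if (!all(c("r", "D") %in% names(reference)) ||
        reference$r <= 0 || reference$D <= 0)
      stop_invalid("`reference` needs positive elements `r` and `D`")
    return(reference$r * reference$D / D)
  }
  if (temperature <= 0 || eta <= 0)
    stop_invalid("`temperature` and `eta` must be positive")
  kb <- 1.380649e-23                     # J/K
  d_si <- D * 1e-12                      # um^2/s -> m^2/s
  r_m <- kb * temperature / (6 * pi * eta * d_si)
  r_m * 1e9
}
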