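#' Hydraulic conductance of a vessel segment
#'
#' Steady one-dimensional flow in a vessel of radius `r` and length `L` has
#' conductance
#' \deqn{G = \frac{\pi r^4}{2(\zeta + 2)\,\mu L}}
#' where `zeta` parameterises the velocity profile: 2 gives the parabolic
#' (Poiseuille) profile with the textbook resistance \eqn{8 \mu L / \pi r^4},
#' 9 the blunter profile appropriate for cerebral arteries and the model
#' default.
#'
#' @param r_mm segment radius, mm.
#' @param L_mm segment length, mm.
#' @param mu dynamic viscosity, Pa s (default 3.5e-3).
#' @param zeta dimensionless velocity-profile constant (default 9).
#' @return Conductance in SI units, m^3 Pa^-1 s^-1. Vectorised.
#' @examples
#' vessel_conductance(0.2, 2) # ~3.26e-11
#' @export
vessel_conductance <- function(r_mm, L_mm, mu = 3.5e-3, zeta = 9) {
  if (any(r_mm <= 0) || any(L_mm <= 0) || any(mu <= 0) || any(zeta < 0)) {
    stop("vessel_conductance: radius, length and viscosity must be positive, zeta non-negative",
         call. = FALSE)
  }
  r <- r_mm * MM_TO_M
  L <- L_mm * MM_TO_M
  pi * r^4 / (2 * (zeta + 2) * mu * L)
}

#' Hydraulic resistance of a vessel segment
#'
#' Reciprocal of [vessel_conductance()], in the interface unit Pa s/ml.
#'
#' @inheritParams vessel_conductance
#' @return Resistance, Pa s ml^-1.
#' @export
vessel_resistance <- function(r_mm, L_mm, mu = 3.5e-3, zeta = 9) {
  1 / vessel_conductance(r_mm, L_mm, mu, zeta) / PASML_TO_PASM3
}

#' Arterial wall thickness as a function of radius
#'
#' Empirical double-exponential fit of human measurements relating lumen
#' radius to wall thickness:
#' \deqn{h = r_0\,(a e^{b r_0} + c e^{d r_0})}
#' with a = 0.2802, b = -0.5053 mm^-1, c = 0.1324, d = -0.01114 mm^-1.
#' For small vessels the thickness-to-radius ratio tends to a + c = 0.4126.
#'
#' @param r0_mm reference (unstressed) radius, mm.
#' @return Wall thickness, mm. Vectorised.
#' @examples
#' wall_thickness(0.2) # ~0.0771 mm
#' @export
wall_thickness <- function(r0_mm) {
  if (any(r0_mm <= 0)) stop("wall_thickness: radius must be positive", call. = FALSE)
  a <- 0.2802; b <- -0.5053; cc <- 0.1324; d <- -0.01114
  r0_mm * (a * exp(b * r0_mm) + cc * exp(d * r0_mm))
}

#' Radius of a compliant vessel at a given pressure
#'
#' Linear elastic pressure-area law for a thin-walled tube,
#' \deqn{P = P_0 + \frac{E h}{r_0^2 (1 - \nu^2)} (r - r_0),}
#' solved for the radius:
#' \deqn{r = r_0 + (P - P_0)\, \frac{r_0^2 (1-\nu^2)}{E h}.}
#' At the reference (diastolic) pressure `P0` the radius equals the
#' reference radius.
#'
#' @param P pressure, Pa.
#' @param P0 reference pressure, Pa.
#' @param r0_mm reference radius, mm.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio of the wall (default 0.5, incompressible).
#' @param h_mm wall thickness, mm; defaults to `wall_thickness(r0_mm)`.
#' @return Radius, mm. Vectorised. Errors if any radius collapses to zero
#'   or below (the offending element indices are reported).
#' @export
radius_from_pressure <- function(P, P0, r0_mm, E, nu = 0.5,
                                 h_mm = wall_thickness(r0_mm)) {
  if (any(E <= 0) || any(h_mm <= 0) || any(r0_mm <= 0)) {
    stop("radius_from_pressure: E, h and r0 must be positive", call. = FALSE)
  }
  if (any(nu < 0) || any(nu >= 1)) {
    stop("radius_from_pressure: nu must lie in [0, 1)", call. = FALSE)
  }
  r0 <- r0_mm * MM_TO_M
  h <- h_mm * MM_TO_M
  r <- r0 + (P - P0) * r0^2 * (1 - nu^2) / (E * h)
  if (any(r <= 0)) {
    bad <- which(r <= 0)
    stop("vessel collapse: non-positive radius at element(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  r / MM_TO_M
}

#' Distensibility of a compliant vessel
#'
#' Relative cross-sectional area change per unit pressure for the linear
#' pressure-area law,
#' \deqn{D = \frac{1}{A}\frac{dA}{dP} = \frac{2 (1-\nu^2) r_0^2}{r E h},}
#' on the order of 1e-6 Pa^-1 (1e-3 mmHg^-1) for cerebral arteries, in line
#' with clinical measurements.
#'
#' @inheritParams radius_from_pressure
#' @param r_mm current radius, mm; defaults to the reference radius.
#' @return Distensibility, Pa^-1. Vectorised.
#' @examples
#' distensibility(0.2, E = 1.6e6) # ~2.4e-6 Pa^-1
#' @export
distensibility <- function(r0_mm, E, nu = 0.5, r_mm = r0_mm,
                           h_mm = wall_thickness(r0_mm)) {
  r0 <- r0_mm * MM_TO_M
  r <- r_mm * MM_TO_M
  h <- h_mm * MM_TO_M
  2 * (1 - nu^2) * r0^2 / (r * E * h)
}
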