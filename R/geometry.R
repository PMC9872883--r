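#' Measurement geometry
#'
#' Wavelength and section thickness of the measurement, both in micrometres.
#' These set the conversion between refractive-index/absorption differences
#' and the per-layer phase/amplitude anisotropy parameters.
#'
#' @param wavelength Laser wavelength in micrometres (default 0.6328, He-Ne).
#' @param thickness Section thickness in micrometres (default 40).
#' @return An object of class `mm_geometry`.
#' @examples
#' measurement_geometry(0.6328, 40)
#' @export
measurement_geometry <- function(wavelength = 0.6328, thickness = 40) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L || !is.finite(wavelength) ||
      wavelength <= 0)
    stop("invalid geometry: wavelength must be a single positive number")
  if (!is.numeric(thickness) || length(thickness) != 1L || !is.finite(thickness) ||
      thickness <= 0)
    stop("invalid geometry: thickness must be a single positive number")
  structure(list(wavelength = wavelength, thickness = thickness),
            class = "mm_geometry")
}

#' @export
print.mm_geometry <- function(x, ...) {
  cat(sprintf("Measurement geometry: lambda = %g um, l = %g um\n",
              x$wavelength, x$thickness))
  invisible(x)
}

#' Polarization channel labels
#'
#' The six probing channels: linear 0, 90, 45, 135 degrees and right/left
#' circular.
#' @return Character vector of the six channel labels.
#' @export
probe_states <- function() c("0", "90", "45", "135", "rcp", "lcp")

#' Optical constants of an anisotropic layer
#'
#' Refractive indices and absorption coefficients for each of the six
#' polarization channels.  Differences between orthogonal channels define the
#' medium's birefringence and dichroism.
#'
#' @param n Named numeric vector of refractive indices for the channels in
#'   [probe_states()].  A single number is recycled.
#' @param tau Named numeric vector of absorption coefficients (per
#'   micrometre), same channels.  A single number is recycled.
#' @return An object of class `optical_constants`.
#' @examples
#' oc <- optical_constants(n = c("0" = 1.401, "90" = 1.4, "45" = 1.4,
#'                               "135" = 1.4, rcp = 1.4, lcp = 1.4),
#'                         tau = 0.02)
#' @export
optical_constants <- function(n = 1.4, tau = 0) {
  ch <- probe_states()
  expand <- function(x, what, lower_ok) {
    if (length(x) == 1L && is.null(names(x))) x <- setNames(rep(x, 6L), ch)
    if (is.null(names(x)) || !setequal(names(x), ch))
      stop(sprintf("'%s' must be named with the six channels: %s",
                   what, paste(ch, collapse = ", ")))
    x <- x[ch]
    if (any(!is.finite(x))) stop(sprintf("'%s' must be finite", what))
    x
  }
  n <- expand(n, "n", FALSE)
  tau <- expand(tau, "tau", TRUE)
  if (any(n <= 0)) stop("refractive indices must be positive")
  if (any(tau < 0)) stop("absorption coefficients must be non-negative")
  structure(list(n = n, tau = tau), class = "optical_constants")
}

.PARAM_NAMES <- c("phi_0_90", "phi_45_135", "phi_circ",
                  "delta_0_90", "delta_45_135", "delta_circ")

#' Mean anisotropy parameters of a layer
#'
#' The six per-layer anisotropy parameters: linear birefringence between the
#' 0/90 and 45/135 degree channels, circular birefringence (optical activity),
#' and the three matching dichroism (diattenuation) parameters.  Phase terms
#' are in radians; amplitude terms are dimensionless per-layer log-amplitude
#' differences.
#'
#' @param phi_0_90,phi_45_135,phi_circ Phase (birefringence) parameters, rad.
#' @param delta_0_90,delta_45_135,delta_circ Amplitude (dichroism) parameters.
#' @return Named numeric vector of class `anisotropy_params`.
#' @examples
#' anisotropy_params(phi_0_90 = pi / 2)
#' @export
anisotropy_params <- function(phi_0_90 = 0, phi_45_135 = 0, phi_circ = 0,
                              delta_0_90 = 0, delta_45_135 = 0, delta_circ = 0) {
  p <- c(phi_0_90 = phi_0_90, phi_45_135 = phi_45_135, phi_circ = phi_circ,
         delta_0_90 = delta_0_90, delta_45_135 = delta_45_135,
         delta_circ = delta_circ)
  if (!all(is.finite(p))) stop("anisotropy parameters must be finite")
  structure(p, class = "anisotropy_params")
}

#' @export
print.anisotropy_params <- function(x, digits = 4, ...) {
  cat("Per-layer anisotropy parameters:\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Anisotropy parameters from optical constants
#'
#' Converts channel-wise refractive indices and absorption coefficients to the
#' six per-layer anisotropy parameters: each phase term is
#' `(2*pi/lambda) * dn * l` for the corresponding orthogonal refractive-index
#' difference `dn`, and each amplitude term is `(2*pi/lambda) * dtau * l`
#' analogously.
#'
#' @param oc An [optical_constants()] object.
#' @param geom A [measurement_geometry()] object.
#' @return An [anisotropy_params()] vector.
#' @examples
#' geom <- measurement_geometry(0.6328, 40)
#' oc <- optical_constants(n = c("0" = 1.401, "90" = 1.4, "45" = 1.4,
#'                               "135" = 1.4, rcp = 1.4, lcp = 1.4))
#' params_from_optics(oc, geom)  # phi_0_90 ~ 0.397 rad
#' @export
params_from_optics <- function(oc, geom) {
  stopifnot(inherits(oc, "optical_constants"), inherits(geom, "mm_geometry"))
  k <- 2 * pi * geom$thickness / geom$wavelength
  n <- oc$n; tau <- oc$tau
  anisotropy_params(
    phi_0_90     = k * (n[["0"]] - n[["90"]]),
    phi_45_135   = k * (n[["45"]] - n[["135"]]),
    phi_circ     = k * (n[["rcp"]] - n[["lcp"]]),
    delta_0_90   = k * (tau[["0"]] - tau[["90"]]),
    delta_45_135 = k * (tau[["45"]] - tau[["135"]]),
    delta_circ   = k * (tau[["rcp"]] - tau[["lcp"]])
  )
}

#' Generalized linear birefringence and dichroism
#'
#' Combines the two linear components of each kind in quadrature:
#' `phi_L = sqrt(phi_0_90^2 + phi_45_135^2)` and
#' `delta_L = sqrt(delta_0_90^2 + delta_45_135^2)`.  Both are invariant to the
#' in-plane orientation of the optical axis (a rotation of the sample mixes
#' the 0/90 and 45/135 components but preserves the quadrature sum).
#'
#' @param p An [anisotropy_params()] vector.
#' @return Named numeric vector `c(phi_L, delta_L)`.
#' @examples
#' generalized_linear(anisotropy_params(phi_0_90 = 3, phi_45_135 = 4))  # phi_L = 5
#' @export
generalized_linear <- function(p) {
  stopifnot(inherits(p, "anisotropy_params"))
  c(phi_L   = sqrt(p[["phi_0_90"]]^2 + p[["phi_45_135"]]^2),
    delta_L = sqrt(p[["delta_0_90"]]^2 + p[["delta_45_135"]]^2))
}
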