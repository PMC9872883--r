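# Differential (logarithmic) Mueller calculus: the per-layer generator of a
# homogeneous anisotropic layer, its matrix exponential (forward model) and
# the principal-logarithm inverse with Minkowski (G-) splitting into the mean
# (anisotropy) and depolarizing components.

.G_SIGN <- c(1, -1, -1, -1)  # Minkowski metric diag(1,-1,-1,-1)

# G-antisymmetric projection: the component satisfying G X^T G = -X.
# Mean (non-depolarizing) anisotropy lives here.
.g_antisym <- function(X) {
  GXG <- outer(.G_SIGN, .G_SIGN) * t(X)
  (X - GXG) / 2
}

# Complementary G-symmetric projection (depolarizing component).
.g_sym <- function(X) {
  GXG <- outer(.G_SIGN, .G_SIGN) * t(X)
  (X + GXG) / 2
}

#' Per-layer differential (generator) matrix
#'
#' Builds the first-order differential Mueller matrix of a homogeneous layer
#' from its six mean anisotropy parameters.  Dichroism terms occupy the
#' symmetric first-row/first-column positions; birefringence terms occupy the
#' antisymmetric positions of the lower 3x3 block.  The generator is stored
#' per layer, i.e. already multiplied by the layer thickness.
#'
#' @param p An [anisotropy_params()] vector.
#' @param depol Optional 4x4 G-symmetric depolarizing component (defaults to
#'   zero).  Its G-antisymmetric part must vanish.
#' @return Object of class `differential_matrix` with elements `mean_part`
#'   and `depol_part`.
#' @examples
#' build_differential(anisotropy_params(phi_0_90 = 0.4))
#' @export
build_differential <- function(p, depol = NULL) {
  stopifnot(inherits(p, "anisotropy_params"))
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- p[["delta_0_90"]]
  m[1, 3] <- m[3, 1] <- p[["delta_45_135"]]
  m[1, 4] <- m[4, 1] <- p[["delta_circ"]]
  m[2, 3] <- p[["phi_circ"]];    m[3, 2] <- -p[["phi_circ"]]
  m[2, 4] <- -p[["phi_45_135"]]; m[4, 2] <- p[["phi_45_135"]]
  m[3, 4] <- p[["phi_0_90"]];    m[4, 3] <- -p[["phi_0_90"]]
  if (is.null(depol)) depol <- matrix(0, 4, 4)
  depol <- as.matrix(depol)
  stopifnot(identical(dim(depol), c(4L, 4L)))
  if (max(abs(.g_antisym(depol))) > 1e-12 * max(1, max(abs(depol))))
    stop("'depol' must be G-symmetric (a pure depolarizing generator)")
  structure(list(mean_part = m, depol_part = depol),
            class = "differential_matrix")
}

#' Read the six anisotropy parameters back from a differential matrix
#'
#' @param d A `differential_matrix`.
#' @return An [anisotropy_params()] vector.
#' @export
extract_params <- function(d) {
  stopifnot(inherits(d, "differential_matrix"))
  m <- d$mean_part
  anisotropy_params(
    phi_0_90 = m[3, 4], phi_45_135 = m[4, 2], phi_circ = m[2, 3],
    delta_0_90 = m[1, 2], delta_45_135 = m[1, 3], delta_circ = m[1, 4]
  )
}

#' @export
print.differential_matrix <- function(x, digits = 4, ...) {
  cat("Per-layer differential Mueller matrix\nmean (anisotropy) part:\n")
  print(round(x$mean_part, digits))
  if (any(x$depol_part != 0)) {
    cat("depolarizing part:\n")
    print(round(x$depol_part, digits))
  }
  invisible(x)
}

#' Normalized 4x4 Mueller matrix
#'
#' Validates and f11-normalizes a 4x4 Mueller matrix.  Entries with magnitude
#' above 1 after normalization trigger a warning (passive media should not
#' exceed it) but are kept.
#'
#' @param f Numeric 4x4 matrix.
#' @param normalize Divide by `f[1,1]` (default TRUE).  `f[1,1] <= 0` is an
#'   error.
#' @return The matrix with class `mueller_matrix` and attribute `normalized`.
#' @export
mueller_matrix <- function(f, normalize = TRUE) {
  f <- unname(as.matrix(f))
  stopifnot(identical(dim(f), c(4L, 4L)))
  if (!all(is.finite(f))) stop("Mueller matrix entries must be finite")
  if (normalize) {
    if (f[1, 1] <= 0) stop("f11 must be positive for normalization")
    f <- f / f[1, 1]
  }
  if (max(abs(f)) > 1 + 1e-9)
    warning("|f_ik| > 1: matrix is not passive", call. = FALSE)
  structure(f, class = c("mueller_matrix", "matrix"),
            normalized = isTRUE(normalize) || abs(f[1, 1] - 1) < 1e-12)
}

#' @export
print.mueller_matrix <- function(x, digits = 4, ...) {
  cat("Mueller matrix", if (isTRUE(attr(x, "normalized"))) "(f11-normalized)",
      "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Forward Mueller matrix of a homogeneous layer
#'
#' Matrix exponential of the total per-layer generator
#' (`mean_part + depol_part`), normalized so that `f11 = 1`.  The semigroup
#' property holds: a layer of double thickness is the matrix square.
#'
#' @param d A `differential_matrix` (per-layer generator).
#' @param geom Optional [measurement_geometry()] carried as metadata.
#' @return A [mueller_matrix()].
#' @examples
#' M <- forward_mueller(build_differential(anisotropy_params(phi_45_135 = -pi / 2)))
#' @export
forward_mueller <- function(d, geom = NULL) {
  stopifnot(inherits(d, "differential_matrix"))
  Gtot <- d$mean_part + d$depol_part
  if (!all(is.finite(Gtot))) stop("non-finite generator")
  Ef <- .expm_stack(matrix(as.numeric(Gtot), 16, 1))
  M <- mueller_matrix(matrix(Ef, 4, 4), normalize = TRUE)
  attr(M, "geometry") <- geom
  M
}

#' Reconstruct the differential decomposition of a Mueller matrix
#'
#' The default `matrix_log` mode takes the principal matrix logarithm of the
#' normalized Mueller matrix and splits it into its G-antisymmetric (mean
#' anisotropy) and G-symmetric (depolarizing) components; the six anisotropy
#' parameters are read from the mean component.  Phases are recovered modulo
#' 2*pi and reported in (-pi, pi].
#'
#' The `elementwise` mode applies the same G-projection per mirror element
#' pair of the matrix itself, `0.5 * (f_ik - g_i g_k f_ki)`, without taking a
#' logarithm.  It is identity-consistent and accurate to third order in the
#' anisotropy (the second-order term of log M is G-symmetric and cancels),
#' and is retained for comparison with the full logarithm.
#'
#' @param M A [mueller_matrix()] (normalized) or plain 4x4 matrix.
#' @param geom Optional [measurement_geometry()] (metadata only; generators
#'   are per-layer).
#' @param mode `"matrix_log"` (default) or `"elementwise"`.
#' @param tol Tolerance on the imaginary residual of the principal logarithm
#'   before the matrix is declared non-physical.
#' @return An [anisotropy_params()] vector with attributes `depol_part` (the
#'   G-symmetric component, `matrix_log` mode) and `mode`.
#' @examples
#' p <- anisotropy_params(phi_0_90 = 0.6, delta_0_90 = 0.1)
#' reconstruct_differential(forward_mueller(build_differential(p)))
#' @export
reconstruct_differential <- function(M, geom = NULL,
                                     mode = c("matrix_log", "elementwise"),
                                     tol = 1e-6) {
  mode <- match.arg(mode)
  f <- unclass(as.matrix(M))
  stopifnot(identical(dim(f), c(4L, 4L)))
  if (abs(f[1, 1] - 1) > 1e-8) f <- mueller_matrix(f, normalize = TRUE)
  f <- unclass(f)
  if (mode == "matrix_log") {
    L <- .logm_stack(matrix(as.numeric(f), 16, 1), tol = tol)
    if (any(is.na(L)))
      stop("non-physical matrix: principal logarithm does not exist ",
           "(or has imaginary residual above tolerance)")
    L <- matrix(L, 4, 4)
    mean_part <- .g_antisym(L)
    depol_part <- .g_sym(L)
  } else {
    off <- f - diag(diag(f))
    mean_part <- .g_antisym(off)
    depol_part <- NULL
  }
  p <- anisotropy_params(
    phi_0_90 = mean_part[3, 4], phi_45_135 = mean_part[4, 2],
    phi_circ = mean_part[2, 3], delta_0_90 = mean_part[1, 2],
    delta_45_135 = mean_part[1, 3], delta_circ = mean_part[1, 4]
  )
  attr(p, "depol_part") <- depol_part
  attr(p, "mode") <- mode
  p
}

#' Degree of depolarization (percent)
#'
#' Gil-Bernabeu depolarization index expressed in percent:
#' `Lambda = (1 - sqrt((sum(f^2) - f11^2) / (3 * f11^2))) * 100`.
#' Zero for every non-depolarizing (pure) Mueller matrix, 100 for the ideal
#' depolarizer `diag(1, 0, 0, 0)`.
#'
#' @param M A [mueller_matrix()] or plain 4x4 matrix (normalized or not; the
#'   index is scale-invariant).
#' @return Scalar in `[0, 100]`.
#' @examples
#' depolarization_degree(diag(c(1, 0.5, 0.5, 0.5)))  # 50
#' @export
depolarization_degree <- function(M) {
  f <- unclass(as.matrix(M))
  stopifnot(identical(dim(f), c(4L, 4L)))
  pd <- sqrt(max(0, (sum(f^2) - f[1, 1]^2) / (3 * f[1, 1]^2)))
  100 * (1 - min(1, pd))
}
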