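# Layer-by-layer anisotropy observable maps: per-pixel differential
# reconstruction of a Mueller map into the four observables (generalized
# linear birefringence and dichroism, circular birefringence and dichroism).

#' Layered anisotropy maps from a Mueller map
#'
#' Runs the differential reconstruction at every pixel and returns the four
#' observable maps for the given phase plane: `phi_L` (generalized linear
#' birefringence, quadrature of the 0/90 and 45/135 components), `phi_circ`,
#' `delta_L`, and `delta_circ`.  Pixels where the reconstruction fails
#' (non-physical matrix, sentinel input) are flagged in the validity mask and
#' carried as NaN.
#'
#' @param map A [mueller_map()] (normalized).
#' @param phi_k Phase plane label (rad); defaults to the map's own.
#' @param mode `"matrix_log"` (default, principal logarithm with G-splitting)
#'   or `"elementwise"` (per-element-pair projection, see
#'   [reconstruct_differential()]).
#' @param tol Imaginary-residual tolerance of the per-pixel logarithm.
#' @return Object of class `anisotropy_maps`: list with the four observable
#'   matrices, the six raw component maps (`components`), logical `valid`
#'   mask, `phase_plane`, `geometry`, `mode`.
#' @export
layered_anisotropy <- function(map, phi_k = NULL,
                               mode = c("matrix_log", "elementwise"),
                               tol = 1e-6) {
  stopifnot(inherits(map, "mueller_map"))
  mode <- match.arg(mode)
  if (is.null(phi_k)) phi_k <- map$phase_plane
  f <- map$f
  d <- dim(f)
  A <- d[1]; B <- d[2]
  S <- .map_to_stack(f)                      # 16 x N
  idx <- function(i, j) (j - 1L) * 4L + i
  if (mode == "matrix_log") {
    L <- .logm_stack(S, tol = tol)
    gpick <- function(i, j, sign_mirror) (L[idx(i, j), ] - sign_mirror * L[idx(j, i), ]) / 2
  } else {
    L <- S
    gpick <- function(i, j, sign_mirror) (L[idx(i, j), ] - sign_mirror * L[idx(j, i), ]) / 2
  }
  # G-projection per mirror pair: m_ij = (f_ij - g_i g_j f_ji)/2
  g <- .G_SIGN
  comp <- list(
    phi_0_90     = gpick(3, 4, g[3] * g[4]),
    phi_45_135   = gpick(4, 2, g[4] * g[2]),
    phi_circ     = gpick(2, 3, g[2] * g[3]),
    delta_0_90   = gpick(1, 2, g[1] * g[2]),
    delta_45_135 = gpick(1, 3, g[1] * g[3]),
    delta_circ   = gpick(1, 4, g[1] * g[4])
  )
  valid <- Reduce(`&`, lapply(comp, is.finite))
  comp <- lapply(comp, function(x) { x[!valid] <- NaN; matrix(x, A, B) })
  obs <- list(
    phi_L      = sqrt(comp$phi_0_90^2 + comp$phi_45_135^2),
    phi_circ   = comp$phi_circ,
    delta_L    = sqrt(comp$delta_0_90^2 + comp$delta_45_135^2),
    delta_circ = comp$delta_circ
  )
  frac_bad <- 1 - mean(valid)
  if (frac_bad > 0.5)
    warning(sprintf("degraded map quality: %.0f%% sentinel pixels",
                    100 * frac_bad), call. = FALSE)
  structure(c(obs, list(components = comp, valid = matrix(valid, A, B),
                        phase_plane = phi_k, geometry = map$geometry,
                        mode = mode)),
            class = "anisotropy_maps")
}

#' @export
print.anisotropy_maps <- function(x, ...) {
  cat(sprintf("Anisotropy maps %d x %d%s (%s reconstruction)\n",
              nrow(x$phi_L), ncol(x$phi_L),
              if (!is.null(x$phase_plane))
                sprintf(" at phi = %.3g rad", x$phase_plane) else "",
              x$mode))
  for (o in c("phi_L", "phi_circ", "delta_L", "delta_circ"))
    cat(sprintf("  %-10s mean %.4g\n", o, mean(x[[o]][x$valid])))
  if (!all(x$valid))
    cat(sprintf("  %d sentinel pixel(s)\n", sum(!x$valid)))
  invisible(x)
}

#' Plot an anisotropy observable map
#'
#' @param x An `anisotropy_maps` object.
#' @param observable Which map to draw.
#' @param ... Passed to [graphics::image()].
#' @export
plot.anisotropy_maps <- function(x, observable = "phi_L", ...) {
  m <- x[[observable]]
  image(t(m[nrow(m):1, , drop = FALSE]), col = hcl.colors(64, "viridis"),
        axes = FALSE, main = observable, ...)
  box()
  invisible(x)
}

#' Per-plane statistic profile
#'
#' Evaluates one statistic of one observable on each phase plane of a layered
#' stack — the structure underlying layered (3D) anisotropy tomography
#' curves.
#'
#' @param stack List of `anisotropy_maps` objects (>= 2 planes).
#' @param statistic Either an index 1..4 selecting a moment `Zn` (literal
#'   mode), or a function of a numeric vector.
#' @param observable One of `"phi_L"`, `"phi_circ"`, `"delta_L"`,
#'   `"delta_circ"`.
#' @return data.frame with columns `phi_k` and `value`, ordered by plane.
#' @export
plane_profile <- function(stack, statistic = 1, observable = "phi_L") {
  stopifnot(is.list(stack), length(stack) >= 2L)
  vals <- vapply(stack, function(m) {
    stopifnot(inherits(m, "anisotropy_maps"))
    v <- m[[observable]][m$valid]
    if (is.function(statistic)) statistic(v)
    else unname(mm_moments(v)[[paste0("Z", statistic)]])
  }, numeric(1))
  phis <- vapply(stack, function(m) m$phase_plane %||% NA_real_, numeric(1))
  out <- data.frame(phi_k = phis, value = vals)
  out[order(out$phi_k), , drop = FALSE]
}
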