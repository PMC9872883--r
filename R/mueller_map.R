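# Per-pixel Mueller-matrix maps.  Internally an A x B x 4 x 4 array; helpers
# convert to/from the 16 x N stack layout used by the compiled kernels
# (N = A*B pixels in row-major pixel order, each column one unrolled 4x4).

#' Per-pixel Mueller-matrix map
#'
#' @param f Array of dimension `c(A, B, 4, 4)`: `f[a, b, , ]` is the Mueller
#'   matrix of pixel `(a, b)` (row-major convention, origin top-left).
#' @param geometry A [measurement_geometry()].
#' @param phase_plane Optional phase plane (rad) this map belongs to.
#' @param normalize Divide each pixel by its `f11` (default TRUE).  Pixels
#'   with `f11 <= 0` become NaN sentinels rather than errors.
#' @return Object of class `mueller_map`.
#' @export
mueller_map <- function(f, geometry = measurement_geometry(),
                        phase_plane = NULL, normalize = TRUE) {
  stopifnot(is.array(f), length(dim(f)) == 4L, all(dim(f)[3:4] == 4L),
            dim(f)[1] >= 1L, dim(f)[2] >= 1L)
  if (normalize) {
    f11 <- f[, , 1, 1]
    bad <- !is.finite(f11) | f11 <= 0
    f11[bad] <- NA_real_
    f <- f / as.vector(f11)  # recycles over the 4x4 slices
  }
  structure(list(f = f, geometry = geometry, phase_plane = phase_plane,
                 normalized = isTRUE(normalize)),
            class = "mueller_map")
}

#' @export
print.mueller_map <- function(x, ...) {
  d <- dim(x$f)
  cat(sprintf("Mueller map: %d x %d pixels%s%s\n", d[1], d[2],
              if (isTRUE(x$normalized)) ", f11-normalized" else "",
              if (!is.null(x$phase_plane))
                sprintf(", phase plane %.3g rad", x$phase_plane) else ""))
  nbad <- sum(!is.finite(x$f[, , 1, 1]))
  if (nbad > 0) cat(sprintf("  %d sentinel pixel(s)\n", nbad))
  invisible(x)
}

#' @export
dim.mueller_map <- function(x) dim(x$f)[1:2]

#' Extract the Mueller matrix at one pixel
#' @param map A [mueller_map()].
#' @param a,b Pixel row and column (1-based).
#' @return A [mueller_matrix()].
#' @export
mueller_at <- function(map, a, b) {
  stopifnot(inherits(map, "mueller_map"))
  mueller_matrix(map$f[a, b, , ], normalize = FALSE)
}

# A x B x 4 x 4  ->  16 x N (pixel-major columns)
.map_to_stack <- function(f) {
  d <- dim(f)
  n <- d[1] * d[2]
  t(matrix(f, nrow = n, ncol = 16L))
}

# 16 x N -> A x B x 4 x 4
.stack_to_map <- function(S, A, B) {
  array(t(S), dim = c(A, B, 4L, 4L))
}

#' Build a Mueller map from per-pixel generator fields
#'
#' Exponentiates, pixel by pixel, the per-layer generator assembled from six
#' anisotropy component fields plus an optional depolarizing diagonal rate.
#' Used by the phantom generator and useful for constructing test scenes.
#'
#' @param fields Named list of A x B matrices: `phi_0_90`, `phi_45_135`,
#'   `phi_circ`, `delta_0_90`, `delta_45_135`, `delta_circ`.  Missing entries
#'   default to zero.
#' @param depol_rate Scalar or A x B matrix: isotropic depolarizing
#'   attenuation applied to the three polarized channels
#'   (`-depol_rate * diag(0,1,1,1)` added to the generator).
#' @param geometry,phase_plane Metadata, see [mueller_map()].
#' @return A [mueller_map()].
#' @export
mueller_map_from_fields <- function(fields, depol_rate = 0,
                                    geometry = measurement_geometry(),
                                    phase_plane = NULL) {
  nm <- .PARAM_NAMES
  have <- intersect(nm, names(fields))
  stopifnot(length(have) >= 1L)
  d <- dim(fields[[have[1]]])
  A <- d[1]; B <- d[2]; n <- A * B
  get0 <- function(k) {
    x <- fields[[k]]
    if (is.null(x)) numeric(n) else { stopifnot(all(dim(x) == c(A, B))); as.numeric(x) }
  }
  ph09 <- get0("phi_0_90"); ph45 <- get0("phi_45_135"); phc <- get0("phi_circ")
  d09 <- get0("delta_0_90"); d45 <- get0("delta_45_135"); dc <- get0("delta_circ")
  dep <- if (length(depol_rate) == 1L) rep(depol_rate, n) else as.numeric(depol_rate)
  G <- matrix(0, 16, n)
  # column-major unrolling of the 4x4: index (i,j) -> (j-1)*4 + i
  idx <- function(i, j) (j - 1L) * 4L + i
  G[idx(1, 2), ] <- d09;  G[idx(2, 1), ] <- d09
  G[idx(1, 3), ] <- d45;  G[idx(3, 1), ] <- d45
  G[idx(1, 4), ] <- dc;   G[idx(4, 1), ] <- dc
  G[idx(2, 3), ] <- phc;  G[idx(3, 2), ] <- -phc
  G[idx(2, 4), ] <- -ph45; G[idx(4, 2), ] <- ph45
  G[idx(3, 4), ] <- ph09; G[idx(4, 3), ] <- -ph09
  G[idx(2, 2), ] <- G[idx(3, 3), ] <- G[idx(4, 4), ] <- -dep
  Ef <- .expm_stack(G)
  mueller_map(.stack_to_map(Ef, A, B), geometry = geometry,
              phase_plane = phase_plane, normalize = TRUE)
}

#' Per-pixel degree of depolarization map
#'
#' Applies [depolarization_degree()] to every pixel.
#' @param map A [mueller_map()].
#' @return A x B numeric matrix of percentages.
#' @export
depolarization_map <- function(map) {
  stopifnot(inherits(map, "mueller_map"))
  f <- map$f
  d <- dim(f)
  S <- .map_to_stack(f)
  ss <- colSums(S^2)
  f11 <- S[1, ]
  pd <- sqrt(pmax(0, (ss - f11^2) / (3 * f11^2)))
  matrix(100 * (1 - pmin(1, pd)), d[1], d[2])
}
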