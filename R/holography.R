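# Off-axis polarization interferometry: forward simulation of carrier-fringe
# interferograms, Fourier-sideband demodulation, Stokes maps from orthogonal
# complex-amplitude projections, and Mueller-map assembly from the six-probe
# measurement scheme.
#
# Stokes indexing follows the intensity-first convention S1..S4 with
# S1 = total intensity.

#' Complex amplitude field of one polarization projection
#'
#' @param E Complex A x B matrix.
#' @param probe One of [probe_states()].
#' @param analyzer Analyzer transmission-axis angle, 0 or 90 (degrees).
#' @return `E` with class `complex_field` and attributes `probe`, `analyzer`.
#' @export
complex_field <- function(E, probe = "0", analyzer = 0) {
  E <- as.matrix(E)
  storage.mode(E) <- "complex"
  if (!all(is.finite(Re(E)) & is.finite(Im(E)))) stop("field must be finite")
  stopifnot(probe %in% probe_states(), analyzer %in% c(0, 90))
  structure(E, class = c("complex_field", "matrix"),
            probe = probe, analyzer = analyzer)
}

# phase ramp exp(i 2 pi (carrier . (a,b))) on the pixel grid, 0-based indices
.carrier_ramp <- function(dim, carrier) {
  a <- matrix(0:(dim[1] - 1L), dim[1], dim[2])
  b <- matrix(0:(dim[2] - 1L), dim[1], dim[2], byrow = TRUE)
  exp(2i * pi * (carrier[1] * a + carrier[2] * b))
}

#' Simulate an off-axis interferogram
#'
#' Intensity of the coherent sum of the object field and a tilted plane-wave
#' reference, `I = |E_obj + A_ref * exp(i 2 pi carrier . (a, b))|^2`.
#' Optional Gaussian shot noise is applied with an explicit seed so the frame
#' is reproducible.
#'
#' @param object_field A [complex_field()].
#' @param carrier Length-2 spatial carrier frequency (cycles/pixel); its
#'   magnitude must lie in (0, 0.5) (Nyquist).
#' @param ref_amplitude Reference beam amplitude (default 1).
#' @param noise_sd Standard deviation of additive intensity noise (default 0).
#' @param seed Seed used when `noise_sd > 0`.
#' @return Object of class `interferogram`: list with `intensity`, `carrier`,
#'   `probe`, `analyzer`.
#' @export
simulate_interferogram <- function(object_field, carrier = c(0.25, 0),
                                   ref_amplitude = 1, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(object_field, "complex_field"))
  cmag <- sqrt(sum(carrier^2))
  if (cmag <= 0 || cmag >= 0.5)
    stop("carrier magnitude must be in (0, 0.5) cycles/pixel")
  Eref <- ref_amplitude * .carrier_ramp(dim(object_field), carrier)
  I <- Mod(unclass(object_field) + Eref)^2
  I <- matrix(as.numeric(I), nrow(I), ncol(I))
  if (noise_sd > 0) {
    I <- I + .with_seed(seed, matrix(rnorm(length(I), sd = noise_sd),
                                     nrow(I), ncol(I)))
    I <- pmax(I, 0)
  }
  structure(list(intensity = I, carrier = carrier,
                 probe = attr(object_field, "probe"),
                 analyzer = attr(object_field, "analyzer")),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  cat(sprintf(
    "Interferogram %d x %d, probe %s, analyzer %d deg, carrier (%.3g, %.3g) cyc/px\n",
    nrow(x$intensity), ncol(x$intensity), x$probe, x$analyzer,
    x$carrier[1], x$carrier[2]))
  invisible(x)
}

# raised-cosine circular low-pass mask in cycles/pixel units
.sideband_mask <- function(dim, radius, edge = 0.2) {
  fa <- (0:(dim[1] - 1L)) / dim[1]; fa[fa > 0.5] <- fa[fa > 0.5] - 1
  fb <- (0:(dim[2] - 1L)) / dim[2]; fb[fb > 0.5] <- fb[fb > 0.5] - 1
  r <- sqrt(outer(fa^2, fb^2, `+`))
  r0 <- radius * (1 - edge)
  w <- 0.5 * (1 + cos(pi * (r - r0) / (radius - r0)))
  w[r <= r0] <- 1
  w[r >= radius] <- 0
  w
}

#' Demodulate an off-axis interferogram
#'
#' Shifts the +1 carrier sideband of the two-dimensional Fourier spectrum to
#' baseband, isolates it with a raised-cosine circular window of radius half
#' the carrier magnitude, and inverse-transforms.  The result is the complex
#' object field times the conjugate reference amplitude.
#'
#' A `degraded` attribute (with a warning) flags frames whose object spectrum
#' is not contained in the window, i.e. the carrier is too small for the
#' object bandwidth.
#'
#' @param ig An `interferogram`.
#' @param carrier Override of the recorded carrier (cycles/pixel).
#' @param ref_amplitude Reference amplitude used to rescale the output
#'   (default 1).
#' @param edge Fractional width of the raised-cosine window edge.
#' @return A [complex_field()] with attribute `degraded` (logical).
#' @export
demodulate <- function(ig, carrier = NULL, ref_amplitude = 1, edge = 0.2) {
  stopifnot(inherits(ig, "interferogram"))
  if (is.null(carrier)) carrier <- ig$carrier
  I <- ig$intensity
  d <- dim(I)
  # shift the +1 sideband (at -carrier in the spectrum of I) to baseband
  base <- I * .carrier_ramp(d, carrier)
  W <- fft(base)
  radius <- sqrt(sum(carrier^2)) / 2
  mask <- .sideband_mask(d, radius)
  # leakage proxy: spectral energy in the annulus just outside the window
  # (short of the displaced DC term) relative to the window content
  fa <- (0:(d[1] - 1L)) / d[1]; fa[fa > 0.5] <- fa[fa > 0.5] - 1
  fb <- (0:(d[2] - 1L)) / d[2]; fb[fb > 0.5] <- fb[fb > 0.5] - 1
  r <- sqrt(outer(fa^2, fb^2, `+`))
  inside <- r <= radius
  ring <- r > radius & r <= 1.6 * radius
  p_ring <- mean(Mod(W[ring])^2)
  p_in <- mean(Mod(W[inside])^2)
  p_tot <- mean(Mod(W)^2)
  # flag only frames whose sideband carries real power yet spills past the
  # window (object bandwidth exceeding it, or the DC term reaching in)
  degraded <- is.finite(p_ring) && is.finite(p_in) && p_tot > 0 &&
    p_in > 1e-9 * p_tot && p_ring > 0.05 * p_in
  if (degraded)
    warning("sideband window overlaps object/DC spectrum: demodulation degraded",
            call. = FALSE)
  E <- fft(W * mask, inverse = TRUE) / length(I) / ref_amplitude
  out <- complex_field(E, probe = ig$probe, analyzer = ig$analyzer)
  attr(out, "degraded") <- degraded
  out
}

#' Stokes maps from orthogonal complex-amplitude projections
#'
#' Pixel-wise: `S1 = |E0|^2 + |E90|^2`, `S2 = |E0|^2 - |E90|^2`,
#' `S3 = 2 Re(E0 * Conj(E90))`, `S4 = 2 Im(E0 * Conj(E90))`.
#'
#' @param E0,E90 [complex_field()]s of the 0- and 90-degree analyzer
#'   projections on matching grids.
#' @return Object of class `stokes_map`: list of four A x B matrices
#'   `S1..S4` plus the probe label.
#' @export
stokes_from_fields <- function(E0, E90) {
  if (!identical(dim(E0), dim(E90))) stop("field grids do not match")
  bare <- function(E) matrix(as.complex(E), nrow(E), ncol(E))
  e0 <- bare(E0); e90 <- bare(E90)
  a0 <- Mod(e0)^2; a90 <- Mod(e90)^2
  cr <- e0 * Conj(e90)
  structure(list(S1 = a0 + a90, S2 = a0 - a90, S3 = 2 * Re(cr),
                 S4 = 2 * Im(cr), probe = attr(E0, "probe")),
            class = "stokes_map")
}

#' @export
print.stokes_map <- function(x, ...) {
  cat(sprintf("Stokes map %d x %d (S1 = intensity), probe %s\n",
              nrow(x$S1), ncol(x$S1), x$probe %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degree of polarization map
#' @param S A `stokes_map`.
#' @return A x B matrix `sqrt(S2^2+S3^2+S4^2)/S1`.
#' @export
degree_of_polarization <- function(S) {
  sqrt(S$S2^2 + S$S3^2 + S$S4^2) / S$S1
}

# Input Stokes vectors of the six probes (S1 = intensity convention).
.probe_stokes_in <- function(probe) {
  switch(probe,
         "0"   = c(1,  1,  0,  0),
         "90"  = c(1, -1,  0,  0),
         "45"  = c(1,  0,  1,  0),
         "135" = c(1,  0, -1,  0),
         "rcp" = c(1,  0,  0,  1),
         "lcp" = c(1,  0,  0, -1),
         stop("unknown probe: ", probe))
}

#' Output Stokes maps of a sample for one probe
#'
#' Propagates a probe's Stokes vector through every pixel of a Mueller map:
#' `S_out = M(a, b) %*% S_in`.
#'
#' @param map A [mueller_map()].
#' @param probe One of [probe_states()].
#' @return A `stokes_map`.
#' @export
stokes_through_sample <- function(map, probe) {
  stopifnot(inherits(map, "mueller_map"))
  S <- .map_to_stack(map$f)          # 16 x N
  sin_ <- .probe_stokes_in(probe)
  d <- dim(map$f)
  out <- lapply(1:4, function(i) {
    rows <- (0:3) * 4L + i           # row i of each pixel matrix
    matrix(colSums(S[rows, , drop = FALSE] * sin_), d[1], d[2])
  })
  structure(list(S1 = out[[1]], S2 = out[[2]], S3 = out[[3]], S4 = out[[4]],
                 probe = probe), class = "stokes_map")
}

#' Orthogonal field projections realizing a fully polarized Stokes map
#'
#' Builds per-pixel complex amplitudes `(E0, E90)` whose Stokes parameters
#' reproduce the given map.  Requires full polarization (a coherent field
#' cannot carry a degree of polarization below 1); the global phase is fixed
#' by taking `E0` real and non-negative.
#'
#' @param S A `stokes_map` with `S1^2 >= S2^2+S3^2+S4^2` (up to tolerance).
#' @param tol Tolerance on the polarization deficit.
#' @return List with [complex_field()]s `E0` and `E90`.
#' @export
fields_from_stokes <- function(S, tol = 1e-9) {
  dop2 <- S$S2^2 + S$S3^2 + S$S4^2
  if (any(dop2 > S$S1^2 * (1 + 1e-9) + tol))
    stop("Stokes map violates S1^2 >= S2^2+S3^2+S4^2")
  deficit <- abs(S$S1^2 - dop2)
  if (any(deficit > tol * pmax(1, S$S1^2)))
    stop("Stokes map is partially polarized; coherent fields require DOP = 1")
  E0 <- (S$S1 + S$S2) / 2
  E0[E0 < 0] <- 0
  E0 <- sqrt(E0)
  E90 <- (S$S3 - 1i * S$S4) / (2 * E0)
  # pixels where E0 ~ 0: field is pure 90-degree component
  small <- E0 < sqrt(.Machine$double.eps) * sqrt(pmax(S$S1, 1e-300))
  if (any(small)) E90[small] <- sqrt(pmax(0, (S$S1 - S$S2)[small] / 2))
  list(E0 = complex_field(E0, probe = S$probe %||% "0", analyzer = 0),
       E90 = complex_field(E90, probe = S$probe %||% "0", analyzer = 90))
}

#' Per-pixel Jones matrices of a non-depolarizing layer
#'
#' Closed-form matrix exponential of the traceless differential Jones matrix
#' built from the six anisotropy component fields.  The induced Mueller map
#' equals [mueller_map_from_fields()] with zero depolarization (the Jones and
#' Mueller exponentials are related by the group homomorphism), which makes
#' this the coherent-field counterpart used by the interferometric
#' simulator: unlike a per-pixel Stokes factorization it carries a smooth,
#' band-limited optical phase.
#'
#' @param fields Named list of component fields as in
#'   [mueller_map_from_fields()].
#' @return List of four complex A x B matrices `J11`, `J12`, `J21`, `J22`.
#' @export
jones_map_from_fields <- function(fields) {
  d <- dim(fields[[1]])
  zero <- matrix(0, d[1], d[2])
  g <- function(k) fields[[k]] %||% zero
  ph09 <- g("phi_0_90"); ph45 <- g("phi_45_135"); phc <- g("phi_circ")
  d09 <- g("delta_0_90"); d45 <- g("delta_45_135"); dc <- g("delta_circ")
  n11 <- (d09 - 1i * ph09) / 2
  n12 <- (d45 + phc) / 2 + 1i * (dc - ph45) / 2
  n21 <- (d45 - phc) / 2 - 1i * (dc + ph45) / 2
  k <- sqrt(n11^2 + n12 * n21)
  shc <- ifelse(Mod(k) < 1e-12, 1 + k^2 / 6, sinh(k) / k)  # sinh(k)/k, stable at 0
  ch <- cosh(k)
  list(J11 = ch + shc * n11, J12 = shc * n12,
       J21 = shc * n21, J22 = ch - shc * n11)
}

# Jones vectors of the six probes (consistent with S4 = 2 Im(E0 Conj(E90)))
.probe_jones_in <- function(probe) {
  switch(probe,
         "0"   = c(1, 0),
         "90"  = c(0, 1),
         "45"  = c(1, 1) / sqrt(2),
         "135" = c(1, -1) / sqrt(2),
         "rcp" = c(1, -1i) / sqrt(2),
         "lcp" = c(1, 1i) / sqrt(2),
         stop("unknown probe: ", probe))
}

#' Coherent probe propagation through a Jones map
#'
#' @param jones Output of [jones_map_from_fields()].
#' @param probe One of [probe_states()].
#' @return List of [complex_field()]s `E0`, `E90` (analyzer projections).
#' @export
propagate_probe <- function(jones, probe) {
  e <- .probe_jones_in(probe)
  list(E0 = complex_field(jones$J11 * e[1] + jones$J12 * e[2],
                          probe = probe, analyzer = 0),
       E90 = complex_field(jones$J21 * e[1] + jones$J22 * e[2],
                           probe = probe, analyzer = 90))
}

#' Assemble a Mueller map from the six probe Stokes maps
#'
#' Half-sum/half-difference Stokes-polarimetric assembly: column 1 of the
#' Mueller matrix is `(S^0 + S^90)/2`, column 2 is `(S^0 - S^90)/2`,
#' column 3 is `(S^45 - S^135)/2`, column 4 is `(S^rcp - S^lcp)/2`,
#' applied row-wise to the four Stokes parameters.  The result is
#' f11-normalized; pixels with non-positive f11 become sentinels.
#'
#' @param stokes Named list of six `stokes_map`s, one per [probe_states()]
#'   label, on one common grid.
#' @param geometry,phase_plane Metadata, see [mueller_map()].
#' @return A [mueller_map()].
#' @export
mueller_from_probes <- function(stokes, geometry = measurement_geometry(),
                                phase_plane = NULL) {
  need <- probe_states()
  if (!all(need %in% names(stokes)))
    stop("missing probe(s): ", paste(setdiff(need, names(stokes)), collapse = ", "))
  d <- dim(stokes[["0"]]$S1)
  comp <- function(i) paste0("S", i)
  f <- array(0, dim = c(d[1], d[2], 4L, 4L))
  for (i in 1:4) {
    si <- comp(i)
    f[, , i, 1] <- (stokes[["0"]][[si]] + stokes[["90"]][[si]]) / 2
    f[, , i, 2] <- (stokes[["0"]][[si]] - stokes[["90"]][[si]]) / 2
    f[, , i, 3] <- (stokes[["45"]][[si]] - stokes[["135"]][[si]]) / 2
    f[, , i, 4] <- (stokes[["rcp"]][[si]] - stokes[["lcp"]][[si]]) / 2
  }
  mueller_map(f, geometry = geometry, phase_plane = phase_plane,
              normalize = TRUE)
}

#' Select a relative-phase plane of an object field
#'
#' The relative phase `arg(E90) - arg(E0)` of the reconstructed field varies
#' across the image; a phase plane `phi_k` is the set of pixels whose wrapped
#' relative phase lies within `tol` of `phi_k`.  The fields themselves are
#' returned unchanged together with the selection mask; slices at `phi_k` and
#' `phi_k + 2*pi` are identical.
#'
#' @param E0,E90 [complex_field()]s.
#' @param phi_k Requested phase plane (rad).
#' @param tol Half-width of the selection window (rad); `Inf` selects every
#'   pixel.
#' @return List `E0`, `E90`, `mask` (logical A x B), `phi_k`.
#' @export
phase_slice <- function(E0, E90, phi_k = 0, tol = Inf) {
  stopifnot(identical(dim(E0), dim(E90)), tol > 0)
  rel <- Arg(unclass(E90) * Conj(unclass(E0)))
  dphi <- Arg(exp(1i * (rel - phi_k)))   # wrapped difference in (-pi, pi]
  mask <- abs(dphi) <= tol
  list(E0 = E0, E90 = E90, mask = mask, phi_k = phi_k %% (2 * pi))
}
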