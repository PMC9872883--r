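# Synthetic tissue phantoms: two classes of layered optical-anisotropy
# fields (benign "adenoma" with a developed fibrillar network vs malignant
# "carcinoma" with smaller, partially destroyed domains) and the Mueller-map
# stacks they induce.
#
# Field model: a spatially correlated standard-normal field G is passed
# through a soft domain mask plogis((G - t)/w) sitting on a uniform
# background lo; the unit-mean texture is scaled by the per-phantom level L.
# The domain threshold t is solved per phantom so that the literal moment
# Z3 of each linear observable hits a target drawn from the class preset,
# while Z1 equals the level draw exactly; Z2 and Z4 follow from the texture.  Orientation fields give
# the two in-plane components of each linear observable; circular anisotropy
# is a smooth overlapping field in both classes.  An isotropic G-symmetric
# attenuation sets the depolarization degree.

#' Phantom specification
#'
#' Collects every generator parameter: class label, grid, correlation
#' lengths, level and moment-target distributions for the linear observables,
#' circular-anisotropy levels, depolarization target, noise level and seed.
#' Use [phantom_preset()] for the frozen class presets.
#'
#' @param class_label `"adenoma"` or `"carcinoma"`.
#' @param dim Grid size `c(A, B)`.
#' @param seed Integer seed; the phantom is bit-reproducible given
#'   `(spec, seed)`.
#' @param params Named list overriding preset entries (advanced use).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(class_label = c("adenoma", "carcinoma"),
                         dim = c(128L, 128L), seed = 1L, params = list()) {
  class_label <- match.arg(class_label)
  stopifnot(length(dim) == 2L, all(dim >= 8L))
  p <- modifyList(.phantom_presets[[class_label]], params)
  if (p$corr_len < 1) stop("correlation length must be >= 1 pixel")
  if (p$lambda_target < 0 || p$lambda_target >= 100)
    stop("unreachable depolarization target: feasible range is [0, 100)")
  structure(list(class_label = class_label, dim = as.integer(dim),
                 seed = as.integer(seed), params = p),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %s, %d x %d, seed %d, Lambda target %.1f%%\n",
              x$class_label, x$dim[1], x$dim[2], x$seed,
              x$params$lambda_target))
  invisible(x)
}

# Frozen class presets.  Levels reproduce the cohort-mean first moments of
# the generalized linear birefringence (0.59 / 0.33) and dichroism
# (0.12 / 0.093) at the phi* = 0.6 rad plane; depolarization targets sit at
# the ends of the 43-48% band; adenoma carries larger, denser fibrillar
# domains (longer correlation length, higher domain fraction), carcinoma
# smaller sparser ones.  Moment targets (z3/z4 of each linear observable)
# were measured once from the generator at the chosen morphology knobs and
# frozen; per-phantom draws jitter around them.
.phantom_presets <- list(
  adenoma = list(
    corr_len = 10, corr_len_orient = 10,
    level_phi = 0.59, level_delta = 0.12, cv_level = 0.03,
    z3_phi = 3.3, sd_z3_phi = 0.08, z3_delta = 390, sd_z3_delta = 10,
    lo = 0.02, spike_frac = 0.004, spike_corr = 2, spike_h = 0.3,
    mask_width = 0.35,
    circ_phi = 0.29, circ_delta = 0.065, circ_cv = 0.12, circ_tex = 0.35,
    lambda_target = 43, lambda_sd = 0.38,
    noise = 0,
    blend_low = 0.3, blend_high = 0.9, blend_top = 1.25
  ),
  carcinoma = list(
    corr_len = 4, corr_len_orient = 4,
    level_phi = 0.33, level_delta = 0.093, cv_level = 0.03,
    z3_phi = 18.5, sd_z3_phi = 0.46, z3_delta = 825, sd_z3_delta = 21,
    lo = 0.02, spike_frac = 0.004, spike_corr = 2, spike_h = 0.5,
    mask_width = 0.35,
    circ_phi = 0.21, circ_delta = 0.072, circ_cv = 0.12, circ_tex = 0.35,
    lambda_target = 48, lambda_sd = 0.37,
    noise = 0,
    blend_low = 0.3, blend_high = 0.9, blend_top = 1.25
  )
)

# Class-neutral texture used outside the diagnostic window of phase planes
# (shared shallow-surface / deep multiple-scattering appearance).
.phantom_neutral <- list(
  corr_len = 7, level_phi = 0.46, level_delta = 0.107,
  t = 0.6, lo = 0.25, mask_width = 0.35,
  circ_phi = 0.25, circ_delta = 0.068
)

#' Frozen phantom presets
#'
#' @param class_label `"adenoma"` or `"carcinoma"`.
#' @param dim,seed Passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(class_label, dim = c(128L, 128L), seed = 1L) {
  phantom_spec(class_label, dim = dim, seed = seed)
}

# Spatially correlated standard-normal field: white noise convolved with a
# Gaussian kernel by FFT (periodic), then empirically standardized.  The 1/e
# autocorrelation decay length equals `corr_len`.
.smooth_gaussian_field <- function(A, B, corr_len) {
  w <- matrix(rnorm(A * B), A, B)
  if (corr_len <= 0.5) return((w - mean(w)) / sd(w))
  sigma <- corr_len / 2
  fa <- (0:(A - 1)) / A; fa[fa > 0.5] <- fa[fa > 0.5] - 1
  fb <- (0:(B - 1)) / B; fb[fb > 0.5] <- fb[fb > 0.5] - 1
  H <- exp(-2 * pi^2 * sigma^2 * outer(fa^2, fb^2, `+`))
  g <- Re(fft(fft(w) * H, inverse = TRUE)) / (A * B)
  (g - mean(g)) / sd(g)
}

# Unit-mean texture: uniform background `lo`, soft fibrillar domains (mask
# threshold `t` on the correlated field G), and an optional sparse
# population of small bright fibril cores (`spike`, a non-negative field
# scaled by amplitude `h`).
.texture_Q <- function(G, t, lo, w, h = 0, spike = NULL) {
  q <- lo + stats::plogis((G - t) / w)
  if (h > 0 && !is.null(spike)) q <- q + h * spike
  q / mean(q)
}

# Gaussian low-pass (amplitude std `sigma_f` in cycles/pixel).  Used by the
# optional `bandlimit` phantom parameter: interferometric closure tests need
# fields whose spectrum fits inside the demodulation sideband window.
.gaussian_lowpass <- function(x, sigma_f) {
  A <- nrow(x); B <- ncol(x)
  fa <- (0:(A - 1)) / A; fa[fa > 0.5] <- fa[fa > 0.5] - 1
  fb <- (0:(B - 1)) / B; fb[fb > 0.5] <- fb[fb > 0.5] - 1
  H <- exp(-outer(fa^2, fb^2, `+`) / (2 * sigma_f^2))
  Re(fft(fft(x) * H, inverse = TRUE)) / (A * B)
}

# soft indicator of the sparse core population: fraction ~p2 of pixels on a
# short-scale independent field
.spike_field <- function(A, B, p2, corr_len = 2, w = 0.35) {
  G2 <- .smooth_gaussian_field(A, B, corr_len)
  stats::plogis((G2 - stats::qnorm(1 - p2)) / w)
}

.lit_s3 <- function(q) mean(q^3) / mean(q^2)^3
.lit_s4 <- function(q) mean(q^4) / mean(q^2)^4

# Solve the domain-threshold knob t so that the third-order shape statistic
# s3 of the unit-mean texture hits `target` at fixed background and core
# amplitude; the densest crossing branch (smallest t) is used, which keeps
# domain contrast moderate.  Returns NA when the target is unreachable.
.solve_t <- function(G, lo, w, h, spike, target, t_range = c(-4, 6),
                     n_grid = 21L) {
  tg <- seq(t_range[1], t_range[2], length.out = n_grid)
  vals <- vapply(tg, function(t) .lit_s3(.texture_Q(G, t, lo, w, h, spike)),
                 numeric(1))
  hit <- which(diff(sign(vals - target)) != 0)
  if (!length(hit)) return(NA_real_)
  ta <- tg[hit[1]]; tb <- tg[hit[1] + 1L]
  fa <- vals[hit[1]] - target
  for (i in 1:60) {
    tm <- (ta + tb) / 2
    fm <- .lit_s3(.texture_Q(G, tm, lo, w, h, spike)) - target
    if (abs(fm) <= 1e-10 * abs(target)) return(tm)
    if (sign(fm) == sign(fa)) { ta <- tm; fa <- fm } else tb <- tm
  }
  (ta + tb) / 2
}

# orientation field in [-pi/2, pi/2), correlated over `corr_len`
.orientation_field <- function(A, B, corr_len) {
  gx <- .smooth_gaussian_field(A, B, corr_len)
  gy <- .smooth_gaussian_field(A, B, corr_len)
  0.5 * atan2(gy, gx)
}

# One solved linear-observable magnitude field: level * texture with the
# drawn literal moments.  Returns the field and its targets.
.linear_field <- function(A, B, p, level_mean, z3_mean, z3_sd) {
  zL <- max(-2.5, min(2.5, rnorm(1)))   # truncated: keeps texture targets feasible
  L <- level_mean * exp(p$cv_level * zL - p$cv_level^2 / 2)
  z3 <- rnorm(1, z3_mean, z3_sd)
  G <- .smooth_gaussian_field(A, B, p$corr_len)
  spike <- .spike_field(A, B, p$spike_frac, p$spike_corr, p$mask_width)
  t <- .solve_t(G, p$lo, p$mask_width, p$spike_h, spike, z3 * L^3)
  if (is.na(t))
    stop(sprintf(
      "unreachable texture target s3 = %.4g for this field realization",
      z3 * L^3))
  B_field <- L * .texture_Q(G, t, p$lo, p$mask_width, p$spike_h, spike)
  list(field = B_field, level = L, z3 = z3, knobs = list(t = t))
}

# class-neutral magnitude field at fixed knobs
.neutral_field <- function(A, B, level) {
  nn <- .phantom_neutral
  G <- .smooth_gaussian_field(A, B, nn$corr_len)
  level * .texture_Q(G, nn$t, nn$lo, nn$mask_width)
}

# Diagnostic-window blend weight: full class texture inside
# [blend_low, blend_high] rad, ramping to the class-neutral texture at the
# surface (phi -> 0) and deep multiple-scattering planes (phi -> blend_top).
.blend_weight <- function(phi, p) {
  .clamp(phi / p$blend_low, 0, 1) *
    .clamp((p$blend_top - phi) / (p$blend_top - p$blend_high), 0, 1)
}

#' Generate a synthetic tissue phantom
#'
#' Draws the per-phantom parameters from the class preset, solves the
#' texture fields, and builds the ground-truth anisotropy component maps and
#' the derived Mueller-map stack for the requested phase planes.  Fully
#' deterministic given `(spec, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param phase_planes Numeric vector of phase planes (rad); default the
#'   0.6 rad analysis plane.  Ground-truth magnitudes scale linearly with
#'   the plane; outside the diagnostic window `[0.3, 0.9]` rad the class
#'   texture blends towards a class-neutral texture (see the package
#'   vignette).
#' @return Object of class `tissue_phantom`: `spec`, `seed`, `phase_planes`,
#'   `truth` (per plane: the six component fields plus the four observable
#'   magnitude fields), `mueller` (per plane: a [mueller_map()]),
#'   `lambda` (drawn depolarization target, percent).
#' @export
generate_phantom <- function(spec, phase_planes = 0.6) {
  stopifnot(inherits(spec, "phantom_spec"), length(phase_planes) >= 1L,
            all(phase_planes >= 0))
  p <- spec$params
  A <- spec$dim[1]; B <- spec$dim[2]
  .with_seed(spec$seed, {
    phi_lin <- .linear_field(A, B, p, p$level_phi, p$z3_phi, p$sd_z3_phi)
    del_lin <- .linear_field(A, B, p, p$level_delta, p$z3_delta, p$sd_z3_delta)
    theta_phi <- .orientation_field(A, B, p$corr_len_orient)
    theta_del <- .orientation_field(A, B, p$corr_len_orient)
    circ_phi <- p$circ_phi * exp(rnorm(1, 0, p$circ_cv) - p$circ_cv^2 / 2) *
      (1 + p$circ_tex * .smooth_gaussian_field(A, B, p$corr_len))
    circ_del <- p$circ_delta * exp(rnorm(1, 0, p$circ_cv) - p$circ_cv^2 / 2) *
      (1 + p$circ_tex * .smooth_gaussian_field(A, B, p$corr_len))
    neut_phi <- .neutral_field(A, B, .phantom_neutral$level_phi)
    neut_del <- .neutral_field(A, B, .phantom_neutral$level_delta)
    neut_circ_phi <- .phantom_neutral$circ_phi *
      (1 + p$circ_tex * .smooth_gaussian_field(A, B, .phantom_neutral$corr_len))
    neut_circ_del <- .phantom_neutral$circ_delta *
      (1 + p$circ_tex * .smooth_gaussian_field(A, B, .phantom_neutral$corr_len))
    lambda <- .clamp(rnorm(1, p$lambda_target, p$lambda_sd), 0, 99.9)
    noise_fields <- if (p$noise > 0)
      lapply(1:6, function(i) matrix(rnorm(A * B, 0, p$noise), A, B))
    else NULL
    geom <- measurement_geometry()
    alpha <- -log(1 - lambda / 100)
    truth <- list(); mueller <- list()
    for (ip in seq_along(phase_planes)) {
      phi_k <- phase_planes[ip]
      s <- phi_k / 0.6
      wgt <- .blend_weight(phi_k, p)
      Bmix <- s * (wgt * phi_lin$field + (1 - wgt) * neut_phi)
      Dmix <- s * (wgt * del_lin$field + (1 - wgt) * neut_del)
      Cphi <- s * (wgt * circ_phi + (1 - wgt) * neut_circ_phi)
      Cdel <- s * (wgt * circ_del + (1 - wgt) * neut_circ_del)
      comp <- list(
        phi_0_90     = Bmix * cos(2 * theta_phi),
        phi_45_135   = Bmix * sin(2 * theta_phi),
        phi_circ     = Cphi,
        delta_0_90   = Dmix * cos(2 * theta_del),
        delta_45_135 = Dmix * sin(2 * theta_del),
        delta_circ   = Cdel
      )
      if (!is.null(p$bandlimit))
        comp <- lapply(comp, .gaussian_lowpass, sigma_f = p$bandlimit)
      if (!is.null(noise_fields))
        comp <- lapply(seq_along(comp), function(i) comp[[i]] + noise_fields[[i]])
      names(comp) <- .PARAM_NAMES
      truth[[ip]] <- list(
        components = comp,
        phi_L = sqrt(comp$phi_0_90^2 + comp$phi_45_135^2),
        phi_circ = comp$phi_circ,
        delta_L = sqrt(comp$delta_0_90^2 + comp$delta_45_135^2),
        delta_circ = comp$delta_circ,
        phase_plane = phi_k
      )
      mueller[[ip]] <- mueller_map_from_fields(comp, depol_rate = alpha,
                                               geometry = geom,
                                               phase_plane = phi_k)
    }
    names(truth) <- names(mueller) <- sprintf("phi_%.3g", phase_planes)
    structure(list(spec = spec, seed = spec$seed, phase_planes = phase_planes,
                   truth = truth, mueller = mueller, lambda = lambda,
                   levels = c(phi_L = phi_lin$level, delta_L = del_lin$level)),
              class = "tissue_phantom")
  })
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("Tissue phantom: %s, %d x %d, seed %d\n", x$spec$class_label,
              x$spec$dim[1], x$spec$dim[2], x$seed))
  cat(sprintf("  planes: %s rad; Lambda = %.1f%%; levels phi_L %.3f, delta_L %.4f\n",
              paste(signif(x$phase_planes, 3), collapse = ", "),
              x$lambda, x$levels[["phi_L"]], x$levels[["delta_L"]]))
  invisible(x)
}

#' Generate a phantom cohort
#'
#' `n` phantoms from one spec template with seeds `base_seed + 0:(n-1)`;
#' per-phantom parameter draws are jittered per the preset spreads.
#'
#' @param class_label `"adenoma"` or `"carcinoma"` (or a [phantom_spec()]
#'   used as template).
#' @param n Number of phantoms.
#' @param base_seed First seed.
#' @param dim Grid size.
#' @param phase_planes Passed to [generate_phantom()].
#' @return List of `tissue_phantom`s.
#' @export
generate_cohort <- function(class_label, n = 26, base_seed = 1L,
                            dim = c(128L, 128L), phase_planes = 0.6) {
  stopifnot(n >= 1)
  lapply(seq_len(n) - 1L, function(i) {
    sp <- if (inherits(class_label, "phantom_spec"))
      phantom_spec(class_label$class_label, dim = class_label$dim,
                   seed = class_label$seed + i, params = class_label$params)
    else phantom_spec(class_label, dim = dim, seed = base_seed + i)
    generate_phantom(sp, phase_planes = phase_planes)
  })
}

#' Empirical autocorrelation decay length of a field
#'
#' Radially averaged normalized autocorrelation; returns the lag at which it
#' first falls below `1/e`.
#'
#' @param x Numeric matrix.
#' @return Decay length in pixels.
#' @export
field_correlation_length <- function(x) {
  x <- x - mean(x)
  A <- nrow(x); B <- ncol(x)
  ac <- Re(fft(Mod(fft(x))^2, inverse = TRUE)) / (A * B)
  ac <- ac / ac[1, 1]
  maxlag <- floor(min(A, B) / 2) - 1L
  prof <- vapply(0:maxlag, function(r) {
    if (r == 0) return(1)
    (ac[r + 1, 1] + ac[1, r + 1]) / 2
  }, numeric(1))
  below <- which(prof < exp(-1))
  if (!length(below)) return(maxlag)
  i <- below[1]
  # linear interpolation between the bracketing lags
  r1 <- i - 2L; r2 <- i - 1L
  v1 <- prof[i - 1L]; v2 <- prof[i]
  r1 + (v1 - exp(-1)) / (v1 - v2) * (r2 - r1)
}
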