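# Independent oracles and scene builders used across the suite.

# Truncated power-series matrix exponential (independent of the package's
# compiled route).
series_expm <- function(G, terms = 20) {
  out <- diag(4)
  term <- diag(4)
  for (k in seq_len(terms)) {
    term <- term %*% G / k
    out <- out + term
  }
  out
}

# Literal moments by an explicit per-pixel loop.
loop_moments <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  P <- length(v)
  s1 <- 0; s2 <- 0; s3 <- 0; s4 <- 0
  for (j in seq_len(P)) {
    s1 <- s1 + v[j]; s2 <- s2 + v[j]^2
    s3 <- s3 + v[j]^3; s4 <- s4 + v[j]^4
  }
  z2 <- s2 / P
  c(Z1 = s1 / P, Z2 = z2, Z3 = (s3 / P) / z2^3, Z4 = (s4 / P) / z2^4)
}

# Random per-layer anisotropy parameters.  `phase_max` bounds the magnitude
# of the total retardance vector (phi_0_90, phi_45_135, phi_circ): the
# principal logarithm is single-valued only below pi total retardance.
random_params <- function(phase_max = 2.5, amp_max = 0.4) {
  v <- rnorm(3)
  v <- v / sqrt(sum(v^2)) * runif(1, 0, phase_max)
  anisotropy_params(
    phi_0_90 = v[1], phi_45_135 = v[2], phi_circ = v[3],
    delta_0_90 = runif(1, -amp_max, amp_max),
    delta_45_135 = runif(1, -amp_max, amp_max),
    delta_circ = runif(1, -amp_max, amp_max)
  )
}

# Band-limited standard-normal field (periodic Gaussian smoothing).
smooth_field <- function(A, corr_len = 8) {
  w <- matrix(rnorm(A * A), A, A)
  fa <- (0:(A - 1)) / A; fa[fa > 0.5] <- fa[fa > 0.5] - 1
  H <- exp(-2 * pi^2 * (corr_len / 2)^2 * outer(fa^2, fa^2, `+`))
  g <- Re(fft(fft(w) * H, inverse = TRUE)) / (A * A)
  (g - mean(g)) / sd(g)
}

# A smooth six-component anisotropy scene on an A x A grid.  The
# orientation field is built without vortices so the scene stays
# band-limited (closure tests depend on that).
smooth_scene <- function(A = 64, corr_len = 10, mag = 0.4,
                         bandlimit = NULL) {
  th <- 0.9 * smooth_field(A, corr_len)
  B <- mag * (1 + 0.4 * smooth_field(A, corr_len))
  sc <- list(phi_0_90 = B * cos(2 * th), phi_45_135 = B * sin(2 * th),
             phi_circ = 0.1 * smooth_field(A, corr_len),
             delta_0_90 = 0.05 * smooth_field(A, corr_len),
             delta_45_135 = 0.04 * smooth_field(A, corr_len),
             delta_circ = 0.02 * smooth_field(A, corr_len))
  if (!is.null(bandlimit))
    sc <- lapply(sc, muellertomo:::.gaussian_lowpass, sigma_f = bandlimit)
  sc
}

# Interferometric measurement of one probe through a Jones map.
measure_probe <- function(jones, probe, carrier = c(0.25, 0), ref = 2) {
  ef <- propagate_probe(jones, probe)
  d0 <- suppressWarnings(demodulate(
    simulate_interferogram(ef$E0, carrier, ref_amplitude = ref),
    ref_amplitude = ref))
  d90 <- suppressWarnings(demodulate(
    simulate_interferogram(ef$E90, carrier, ref_amplitude = ref),
    ref_amplitude = ref))
  stokes_from_fields(d0, d90)
}

read_calibration <- function(which) {
  path <- system.file("extdata", paste0("calibration_", which, ".csv"),
                      package = "muellertomo")
  as.matrix(read.csv(path, header = FALSE))
}
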