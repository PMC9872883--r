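# Off-axis interferogram simulation, Fourier demodulation, Stokes and
# Mueller assembly from the six-probe scheme.

test_that("interferogram intensity follows the coherent-sum model", {
  A <- 32
  zero <- complex_field(matrix(0 + 0i, A, A))
  ig <- simulate_interferogram(zero, carrier = c(0.25, 0), ref_amplitude = 1.5)
  expect_equal(ig$intensity, matrix(1.5^2, A, A))

  # equal-amplitude plane waves give unit-visibility fringes
  one <- complex_field(matrix(1 + 0i, A, A))
  ig <- simulate_interferogram(one, carrier = c(0.25, 0))
  expect_equal(max(ig$intensity), 4, tolerance = 1e-9)
  expect_equal(min(ig$intensity), 0, tolerance = 1e-9)

  expect_error(simulate_interferogram(one, carrier = c(0.5, 0.2)), "Nyquist|carrier")
  expect_error(simulate_interferogram(one, carrier = c(0, 0)), "carrier")

  # shot noise is reproducible given the seed
  i1 <- simulate_interferogram(one, noise_sd = 0.05, seed = 9L)
  i2 <- simulate_interferogram(one, noise_sd = 0.05, seed = 9L)
  expect_identical(i1$intensity, i2$intensity)
})

test_that("demodulation recovers constant fields, ramps, and flags overlap", {
  A <- 64
  # constant-amplitude object: interior amplitude within 1%
  obj <- complex_field(matrix(0.7 + 0i, A, A))
  rec <- demodulate(simulate_interferogram(obj, c(0.25, 0)))
  inner <- Mod(rec[9:(A - 8), 9:(A - 8)])
  expect_lt(max(abs(inner - 0.7)) / 0.7, 0.01)

  # linear phase-ramp object (periodic over the frame): recovered slope to
  # 1e-3 rad/pixel
  slope <- 2 * pi * 2 / A
  ramp <- outer(rep(1, A), 0:(A - 1)) * slope
  obj <- complex_field(0.8 * exp(1i * ramp))
  rec <- demodulate(simulate_interferogram(obj, c(0.25, 0)))
  ph <- Arg(rec[A / 2, ])
  dph <- diff(ph[9:(A - 8)])
  dph <- Arg(exp(1i * dph))  # unwrap increments
  expect_lt(abs(mean(dph) - slope), 1e-3)

  # no reference beam: demodulated field is (near) zero
  ig <- simulate_interferogram(obj, c(0.25, 0), ref_amplitude = 1)
  ig$intensity <- Mod(unclass(obj))^2   # pure object intensity, no fringes
  rec <- suppressWarnings(demodulate(ig))
  expect_lt(max(Mod(rec)), 0.05)

  # carrier too small for the object bandwidth: degraded flag
  set.seed(11)
  rough <- complex_field(exp(1i * 2 * smooth_field(A, 2)))
  expect_warning(demodulate(simulate_interferogram(rough, c(0.06, 0))),
                 "degraded")
})

test_that("Stokes maps from field pairs match the per-pixel loop oracle", {
  A <- 16
  set.seed(12)
  E0 <- complex_field(matrix(complex(real = rnorm(A * A),
                                     imaginary = rnorm(A * A)), A, A))
  E90 <- complex_field(matrix(complex(real = rnorm(A * A),
                                      imaginary = rnorm(A * A)), A, A),
                       analyzer = 90)
  S <- stokes_from_fields(E0, E90)
  for (a in seq_len(A)) for (b in seq_len(A)) {
    e0 <- E0[a, b]; e90 <- E90[a, b]
    expect_identical(S$S1[a, b], Mod(e0)^2 + Mod(e90)^2)
    expect_identical(S$S2[a, b], Mod(e0)^2 - Mod(e90)^2)
    expect_identical(S$S3[a, b], 2 * Re(e0 * Conj(e90)))
    expect_identical(S$S4[a, b], 2 * Im(e0 * Conj(e90)))
  }

  zero <- complex_field(matrix(0 + 0i, A, A), analyzer = 90)
  S <- stokes_from_fields(E0, zero)
  expect_equal(S$S2, S$S1)
  expect_equal(S$S3, matrix(0, A, A)); expect_equal(S$S4, matrix(0, A, A))

  Er <- complex_field(matrix(1.3 + 0i, A, A))
  S <- stokes_from_fields(Er, complex_field(matrix(1.3 + 0i, A, A), analyzer = 90))
  expect_equal(S$S1, S$S3)
  expect_equal(S$S2, matrix(0, A, A))

  expect_error(stokes_from_fields(E0, complex_field(matrix(0i, 4, 4))),
               "grids")
})

test_that("probe outputs through a pure sample stay fully polarized", {
  set.seed(13)
  map <- mueller_map_from_fields(smooth_scene(24), depol_rate = 0)
  for (pr in probe_states()) {
    S <- stokes_through_sample(map, pr)
    expect_lt(max(abs(degree_of_polarization(S) - 1)), 1e-9)
  }
})

test_that("six-probe assembly reproduces the Mueller map", {
  # no sample: input Stokes pass through unchanged -> identity matrix
  A <- 8
  st <- setNames(lapply(probe_states(), function(pr) {
    s <- muellertomo:::.probe_stokes_in(pr)
    structure(list(S1 = matrix(s[1], A, A), S2 = matrix(s[2], A, A),
                   S3 = matrix(s[3], A, A), S4 = matrix(s[4], A, A),
                   probe = pr), class = "stokes_map")
  }), probe_states())
  m <- mueller_from_probes(st)
  expect_equal(m$f[3, 5, , ], diag(4))

  # analytic probe propagation through a random forward model
  set.seed(14)
  map <- mueller_map_from_fields(smooth_scene(16), depol_rate = 0.3)
  st <- setNames(lapply(probe_states(), function(pr)
    stokes_through_sample(map, pr)), probe_states())
  rec <- mueller_from_probes(st)
  expect_lt(max(abs(rec$f - map$f)), 1e-10)

  # global intensity scaling leaves the normalized map unchanged
  st2 <- lapply(st, function(s) { s$S1 <- 7 * s$S1; s$S2 <- 7 * s$S2
                                  s$S3 <- 7 * s$S3; s$S4 <- 7 * s$S4; s })
  rec2 <- mueller_from_probes(st2)
  expect_equal(rec2$f, rec$f, tolerance = 1e-12)

  expect_error(mueller_from_probes(st[1:5]), "missing probe")
})

test_that("phase slices are periodic and preserve fields", {
  set.seed(15)
  A <- 16
  E0 <- complex_field(matrix(complex(real = rnorm(A * A),
                                     imaginary = rnorm(A * A)), A, A))
  E90 <- complex_field(matrix(complex(real = rnorm(A * A),
                                      imaginary = rnorm(A * A)), A, A),
                       analyzer = 90)
  s0 <- phase_slice(E0, E90, 0)
  expect_identical(unclass(s0$E0), unclass(E0))
  expect_true(all(s0$mask))
  s2pi <- phase_slice(E0, E90, 2 * pi, tol = 0.3)
  szero <- phase_slice(E0, E90, 0, tol = 0.3)
  expect_identical(s2pi$mask, szero$mask)

  # uniform relative phase: every non-empty slice has the same statistics
  Eu0 <- complex_field(matrix(0.8 + 0i, A, A))
  Eu90 <- complex_field(matrix(0.5 * exp(1i * 0.6), A, A), analyzer = 90)
  vals <- sapply(c(0.6, 0.6 + 2 * pi), function(phi) {
    s <- phase_slice(Eu0, Eu90, phi, tol = 0.2)
    mean(Mod(unclass(s$E90))[s$mask])
  })
  expect_equal(vals[1], vals[2])
  empty <- phase_slice(Eu0, Eu90, 0.6 + pi, tol = 0.2)
  expect_false(any(empty$mask))
})

test_that("interferometric chain closes on a non-depolarizing phantom", {
  set.seed(16)
  flds <- smooth_scene(64, corr_len = 10, mag = 0.4, bandlimit = 0.03)
  map <- mueller_map_from_fields(flds, depol_rate = 0)
  jones <- jones_map_from_fields(flds)
  st <- setNames(lapply(probe_states(), function(pr)
    measure_probe(jones, pr)), probe_states())
  rec <- mueller_from_probes(st)
  keep <- 5:60  # exclude the 5% FFT border
  err <- abs(rec$f[keep, keep, , ] - map$f[keep, keep, , ])
  expect_lt(median(err), 1e-3)
})

test_that("demodulation error falls as the carrier separates from DC", {
  set.seed(17)
  A <- 64
  obj <- complex_field(0.8 * exp(1i * 0.8 * smooth_field(A, 8)))
  errs <- sapply(c(0.05, 0.10, 0.175, 0.30), function(cx) {
    rec <- suppressWarnings(demodulate(simulate_interferogram(obj, c(cx, 0))))
    median(Mod(rec - unclass(obj))[5:60, 5:60])
  })
  expect_true(all(diff(errs) < 0))
})
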