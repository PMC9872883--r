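# Forward model and inverse differential reconstruction.

test_that("optical constants convert to anisotropy parameters", {
  geom <- measurement_geometry(0.6328, 40)
  base_n <- setNames(rep(1.4, 6), probe_states())
  base_t <- setNames(rep(0.01, 6), probe_states())

  # quarter-wave condition dn = lambda/(4 l) gives a pi/2 retarder
  n <- base_n; n["0"] <- n["90"] + 0.6328 / (4 * 40)
  p <- params_from_optics(optical_constants(n, base_t), geom)
  expect_equal(p[["phi_0_90"]], pi / 2, tolerance = 1e-12)
  expect_equal(unname(unclass(p)[setdiff(names(p), "phi_0_90")]),
               rep(0, 5))

  # isotropic medium has no anisotropy at all
  p0 <- params_from_optics(optical_constants(base_n, base_t), geom)
  expect_equal(max(abs(p0)), 0)

  # hand arithmetic: 2*pi*1e-3*40/0.6328
  n <- base_n; n["0"] <- n["90"] + 1e-3
  p <- params_from_optics(optical_constants(n, base_t), geom)
  expect_equal(p[["phi_0_90"]], 0.3972, tolerance = 1e-4)

  expect_error(measurement_geometry(-1, 40), "invalid geometry")
  expect_error(measurement_geometry(0.6328, 0), "invalid geometry")
})

test_that("differential matrix has the correct sign layout and round-trips", {
  p0 <- anisotropy_params()
  expect_equal(build_differential(p0)$mean_part, matrix(0, 4, 4))

  x <- 0.37
  m <- build_differential(anisotropy_params(phi_0_90 = x))$mean_part
  expect_equal(m[3, 4], x)
  expect_equal(m[4, 3], -x)
  m[3, 4] <- m[4, 3] <- 0
  expect_equal(m, matrix(0, 4, 4))

  set.seed(42)
  for (i in 1:10) {
    p <- random_params()
    expect_equal(unclass(extract_params(build_differential(p))), unclass(p))
  }

  expect_error(build_differential(p0, depol = matrix(rnorm(16), 4)),
               "G-symmetric")
})

test_that("forward Mueller matrix matches the series oracle and calibration", {
  M0 <- forward_mueller(build_differential(anisotropy_params()))
  expect_equal(matrix(unclass(M0), 4, 4), diag(4))

  # quarter-wave retarder against the bundled calibration matrix
  qw <- forward_mueller(build_differential(anisotropy_params(phi_45_135 = -pi / 2)))
  expect_lte(max(abs(unclass(qw) - read_calibration("qwp"))), 0.02)
  expect_equal(abs(qw[2, 4]), 1); expect_equal(abs(qw[4, 2]), 1)
  expect_equal(qw[2, 4], -qw[4, 2])
  expect_equal(qw[3, 3], 1)
  expect_equal(qw[2, 2], 0); expect_equal(qw[4, 4], 0)

  set.seed(1)
  for (i in 1:20) {
    G <- build_differential(random_params(0.4, 0.2))
    M <- forward_mueller(G)
    Mo <- series_expm(G$mean_part)
    expect_lt(max(abs(unclass(M) - Mo / Mo[1, 1])), 1e-10)
  }
})

test_that("forward model is multiplicative over thickness (semigroup)", {
  set.seed(2)
  for (i in 1:10) {
    p <- random_params(1.2, 0.3)
    d1 <- build_differential(p)
    d2 <- build_differential(anisotropy_params(
      phi_0_90 = 2 * p[["phi_0_90"]], phi_45_135 = 2 * p[["phi_45_135"]],
      phi_circ = 2 * p[["phi_circ"]], delta_0_90 = 2 * p[["delta_0_90"]],
      delta_45_135 = 2 * p[["delta_45_135"]], delta_circ = 2 * p[["delta_circ"]]))
    M1 <- unclass(forward_mueller(d1))
    M2 <- unclass(forward_mueller(d2))
    P2 <- M1 %*% M1
    expect_lt(max(abs(M2 - P2 / P2[1, 1])), 1e-10)
  }
})

test_that("matrix-log reconstruction inverts the forward model", {
  id <- reconstruct_differential(mueller_matrix(diag(4)))
  expect_equal(max(abs(id)), 0)

  set.seed(3)
  for (i in 1:50) {
    p <- random_params(2.8, 0.4)
    rec <- reconstruct_differential(forward_mueller(build_differential(p)))
    expect_lt(max(abs(unclass(rec) - unclass(p))), 1e-8)
  }
})

test_that("mean parameters separate exactly from a depolarizing component", {
  set.seed(4)
  for (i in 1:15) {
    p <- random_params(2, 0.3)
    # random G-symmetric depolarizing generator of spectral norm <= 0.3
    S <- matrix(rnorm(16), 4, 4)
    Gs <- muellertomo:::.g_sym(S)
    Gs <- 0.3 * Gs / max(1e-12, norm(Gs, "2"))
    # a random symmetric generator may include gain directions, which
    # legitimately triggers the passivity warning
    M <- suppressWarnings(forward_mueller(build_differential(p, depol = Gs)))
    rec <- reconstruct_differential(M)
    rel <- max(abs(unclass(rec) - unclass(p))) / max(abs(unclass(p)))
    expect_lt(rel, 0.02)
    # the G-symmetric component is recovered too, up to the isotropic
    # diagonal shift introduced by f11-normalization
    dp <- attr(rec, "depol_part")
    off <- !diag(TRUE, 4)
    expect_lt(max(abs((dp - Gs)[off])), 1e-8)
  }
})

test_that("quarter-wave calibration matrix reconstructs a pi/2 retarder", {
  qwp <- mueller_matrix(read_calibration("qwp"))
  p <- reconstruct_differential(qwp)
  expect_lt(abs(abs(p[["phi_45_135"]]) - pi / 2), 0.05)
  others <- unclass(p)[setdiff(names(p), "phi_45_135")]
  expect_lt(max(abs(others)), 0.1)
})

test_that("element-wise mode agrees with the logarithm for weak anisotropy", {
  set.seed(5)
  for (i in 1:20) {
    p <- random_params(0.1, 0.1)
    M <- forward_mueller(build_differential(p))
    r_log <- reconstruct_differential(M, mode = "matrix_log")
    r_el <- reconstruct_differential(M, mode = "elementwise")
    scale <- max(abs(unclass(r_log)), 1e-3)
    expect_lt(max(abs(unclass(r_el) - unclass(r_log))) / scale, 0.05)
  }
})

test_that("non-physical matrices raise errors, not garbage", {
  bad <- diag(c(1, -1, 1, 1))  # log does not exist on the principal branch
  expect_error(reconstruct_differential(mueller_matrix(bad)), "non-physical")
  expect_error(mueller_matrix(diag(c(-1, 1, 1, 1))), "f11 must be positive")
  expect_warning(mueller_matrix(matrix(c(1, 0, 0, 0, 0, 1.5, 0, 0,
                                         0, 0, 1, 0, 0, 0, 0, 1), 4, 4),
                                normalize = FALSE),
                 "passive")
})

test_that("generalized linear parameters combine components in quadrature", {
  expect_equal(unname(generalized_linear(
    anisotropy_params(phi_0_90 = 3, phi_45_135 = 4))), c(5, 0))
  expect_equal(unname(generalized_linear(anisotropy_params())), c(0, 0))

  set.seed(6)
  for (i in 1:20) {
    p <- random_params()
    gl <- generalized_linear(p)
    expect_equal(gl[["phi_L"]],
                 sqrt(sum(unclass(p)[c("phi_0_90", "phi_45_135")]^2)),
                 tolerance = 1e-12)
    expect_equal(gl[["delta_L"]],
                 sqrt(sum(unclass(p)[c("delta_0_90", "delta_45_135")]^2)),
                 tolerance = 1e-12)
    # invariance under sign flips of either linear component
    pf <- unclass(p); pf["phi_0_90"] <- -pf["phi_0_90"]
    pf["delta_45_135"] <- -pf["delta_45_135"]
    expect_equal(generalized_linear(do.call(anisotropy_params, as.list(pf))), gl)
  }
})

test_that("depolarization degree follows the depolarization index", {
  expect_equal(depolarization_degree(diag(4)), 0)
  expect_equal(depolarization_degree(diag(c(1, 0, 0, 0))), 100)
  expect_equal(depolarization_degree(diag(c(1, 0.5, 0.5, 0.5))), 50)

  set.seed(7)
  for (i in 1:10) {
    M <- forward_mueller(build_differential(random_params(2, 0.3)))
    expect_lt(depolarization_degree(M), 1e-6)
  }
})
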