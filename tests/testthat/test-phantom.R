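# Synthetic tissue phantom generator.

test_that("phantoms are bit-reproducible and seeds matter", {
  sp <- phantom_preset("adenoma", dim = c(32, 32), seed = 7)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$mueller[[1]]$f, p2$mueller[[1]]$f)
  expect_identical(p1$truth, p2$truth)

  p3 <- generate_phantom(phantom_preset("adenoma", dim = c(32, 32), seed = 8))
  expect_false(identical(p1$mueller[[1]]$f, p3$mueller[[1]]$f))

  co <- generate_cohort("adenoma", n = 1, base_seed = 7, dim = c(32, 32))
  expect_identical(co[[1]]$mueller[[1]]$f, p1$mueller[[1]]$f)

  co2 <- generate_cohort("adenoma", n = 3, base_seed = 20, dim = c(16, 16))
  expect_equal(sapply(co2, `[[`, "seed"), c(20, 21, 22))
  expect_false(identical(co2[[1]]$mueller[[1]]$f, co2[[2]]$mueller[[1]]$f))
})

test_that("class presets order the linear birefringence level correctly", {
  ade <- generate_cohort("adenoma", n = 4, base_seed = 1, dim = c(48, 48))
  car <- generate_cohort("carcinoma", n = 4, base_seed = 101, dim = c(48, 48))
  m_ade <- mean(sapply(ade, function(p) mean(p$truth[[1]]$phi_L)))
  m_car <- mean(sapply(car, function(p) mean(p$truth[[1]]$phi_L)))
  expect_gt(m_ade, m_car)          # 0.59 vs 0.33 ordering
  expect_equal(m_ade, 0.59, tolerance = 0.05)
  expect_equal(m_car, 0.33, tolerance = 0.05)
})

test_that("the domain correlation length is controllable", {
  long <- generate_phantom(phantom_spec("adenoma", dim = c(128, 128), seed = 3,
                                        params = list(corr_len = 12)))
  short <- generate_phantom(phantom_spec("adenoma", dim = c(128, 128), seed = 3,
                                         params = list(corr_len = 6)))
  l_long <- field_correlation_length(long$truth[[1]]$phi_L)
  l_short <- field_correlation_length(short$truth[[1]]$phi_L)
  expect_equal(l_long / l_short, 2, tolerance = 0.2)
})

test_that("depolarization lands inside the targeted band", {
  for (cl in c("adenoma", "carcinoma")) {
    co <- generate_cohort(cl, n = 4, base_seed = 11, dim = c(48, 48))
    lam <- mean(sapply(co, function(p) mean(depolarization_map(p$mueller[[1]]))))
    target <- muellertomo:::.phantom_presets[[cl]]$lambda_target
    expect_lt(abs(lam - target), 2)
    expect_gt(lam, 41); expect_lt(lam, 50)   # the 43-48% study band (+-2)
  }
})

test_that("unreachable depolarization targets raise a range error", {
  expect_error(phantom_spec("adenoma", params = list(lambda_target = 100)),
               "feasible range")
  expect_error(phantom_spec("adenoma", params = list(lambda_target = -5)),
               "feasible range")
})

test_that("higher moments separate the classes more than lower ones", {
  n <- 8
  ade <- generate_cohort("adenoma", n = n, base_seed = 1, dim = c(96, 96))
  car <- generate_cohort("carcinoma", n = n, base_seed = 101, dim = c(96, 96))
  tab <- cohort_moment_table(list(adenoma = ade, carcinoma = car))
  # geometric (log-scale) standardized separation: the moments are strictly
  # positive scale-family statistics
  dsep <- function(o, m) {
    a <- log(tab[tab$class == "adenoma" & tab$observable == o, paste0("Z", m)])
    c_ <- log(tab[tab$class == "carcinoma" & tab$observable == o, paste0("Z", m)])
    abs(mean(a) - mean(c_)) / sqrt(var(a) + var(c_))
  }
  for (o in c("phi_L", "delta_L")) {
    lo <- max(dsep(o, 1), dsep(o, 2))
    hi <- min(dsep(o, 3), dsep(o, 4))
    expect_gt(hi, lo)
  }
})

test_that("class structure peaks inside the diagnostic window of planes", {
  planes <- c(0.1, 0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  n <- 6
  ade <- generate_cohort("adenoma", n = n, base_seed = 1, dim = c(64, 64),
                         phase_planes = planes)
  car <- generate_cohort("carcinoma", n = n, base_seed = 101, dim = c(64, 64),
                         phase_planes = planes)
  dsep <- sapply(seq_along(planes), function(ip) {
    za <- log(sapply(ade, function(p)
      mm_moments(layered_anisotropy(p$mueller[[ip]])$phi_L)[["Z3"]]))
    zc <- log(sapply(car, function(p)
      mm_moments(layered_anisotropy(p$mueller[[ip]])$phi_L)[["Z3"]]))
    abs(mean(za) - mean(zc)) / sqrt(var(za) + var(zc))
  })
  inside <- planes >= 0.3 & planes <= 0.9
  expect_gt(min(dsep[inside]), max(dsep[!inside]))
})
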