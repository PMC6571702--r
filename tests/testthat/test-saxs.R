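test_that("Guinier fit is exact on a noiseless Gaussian curve", {
  q <- seq(0.004, 0.45, length.out = 400)
  crv <- scattering_curve(q, 7 * exp(-q^2 * 13^2 / 3))
  gf <- guinier_fit(crv)
  expect_equal(gf$rg, 13, tolerance = 1e-9)
  expect_equal(gf$i0, 7, tolerance = 1e-9)
  expect_lte(gf$qmax * gf$rg, 0.8 + 1e-8)
  expect_gte(gf$n_points, 5)
  # tidy/glance expose the estimates
  td <- tidy(gf)
  expect_equal(td$estimate[td$term == "rg"], 13, tolerance = 1e-9)
  expect_equal(glance(gf)$qmax_rg, gf$qmax * gf$rg)
})

test_that("Guinier fit degenerates sensibly", {
  q <- seq(0.01, 0.4, length.out = 60)
  expect_error(guinier_fit(scattering_curve(q, rep(3, 60))), "slope")
  expect_error(guinier_fit(scattering_curve(q[1:3], (4:6) / 10)), "few")
  # rising curve
  expect_error(guinier_fit(scattering_curve(q, exp(q^2 * 50))), "slope")
})

test_that("Guinier recovery from noisy coil curves stays within 3%", {
  rgs <- vapply(1:20, function(s) {
    crv <- synth_saxs_curve(rg = 13, i0 = 3, noise = 0.01, seed = s)
    guinier_fit(crv)$rg
  }, numeric(1))
  expect_lt(abs(mean(rgs) - 13) / 13, 0.03)
  expect_lt(stats::sd(rgs) / 13, 0.03)
})

test_that("chi-square follows the printed definition", {
  expect_identical(chi_square(1:10, as.numeric(1:10)), 0)
  # I_exp = 1.1 I_sim, s = 1: mean((0.1 I / I)^2) = 0.01
  expect_equal(chi_square(1.1 * (1:10), as.numeric(1:10)), 0.01,
               tolerance = 1e-12)
  # scaling I_sim to match I0 removes a pure scale offset
  expect_equal(chi_square(2 * (1:10), as.numeric(1:10), scale = 2), 0)
  # sigma-weighted variant
  expect_equal(chi_square(c(2, 2), c(1, 1), sigma = c(0.5, 0.5),
                          weighted = TRUE), 4)
  # mismatched grids are refused
  a <- scattering_curve(c(0.01, 0.02), c(1, 1))
  b <- scattering_curve(c(0.01, 0.03), c(1, 1))
  expect_error(chi_square(a, b), "grids differ")
})

test_that("beta ratio reproduces the measured table and its invariances", {
  tbl <- hst5_saxs_table()
  beta <- beta_ratio(tbl$i0_zn, tbl$c_p_zn, tbl$i0, tbl$c_p)
  # rows that reproduce from the printed inputs at 2-dp rounding
  reproducible <- tbl$name %in% c("WT", "RAN", "DZM", "DH")
  expect_equal(round(beta[reproducible], 2),
               tbl$beta_printed[reproducible])
  # no mass change: beta exactly 1
  expect_identical(beta_ratio(3, 1, 3, 1), 1)
  # scale invariance of the intensity units
  expect_equal(beta_ratio(8.22 * 1e3, 1.03, 3.07 * 1e3, 1.01),
               beta_ratio(8.22, 1.03, 3.07, 1.01))
  expect_error(beta_ratio(1, 0, 1, 1), "positive")
  expect_error(beta_ratio(-1, 1, 1, 1), "positive")
})

test_that("beta increases with histidine count across variant classes", {
  tbl <- hst5_saxs_table()
  tbl$beta <- beta_ratio(tbl$i0_zn, tbl$c_p_zn, tbl$i0, tbl$c_p)
  cls <- list(`0` = 0, `2` = 2, `3/4` = c(3, 4), `7` = 7)
  band <- vapply(cls, function(nh) range(tbl$beta[tbl$n_his %in% nh]),
                 numeric(2))
  # every class's largest beta is below the next class's smallest
  expect_true(all(band[2, -ncol(band)] < band[1, -1]))
})

test_that("fractal dimension recovers power-law exponents", {
  q <- seq(0.05, 0.2, length.out = 80)
  expect_equal(fractal_dimension(scattering_curve(q, q^-1.6))$dm, 1.6,
               tolerance = 1e-9)
  expect_equal(fractal_dimension(scattering_curve(q, 5 * q^-1))$dm, 1,
               tolerance = 1e-9)
  # Debye coil: Dm -> 2 as the window moves to qRg >> 1
  qq <- seq(0.01, 2, length.out = 800)
  crv <- scattering_curve(qq, debye_form_factor(qq, 13))
  dm_far <- fractal_dimension(crv, q_window = c(0.8, 2))$dm
  expect_equal(dm_far, 2, tolerance = 0.03)
  dm_near <- fractal_dimension(crv, q_window = c(0.05, 0.2))$dm
  expect_lt(dm_near, dm_far)
  expect_error(fractal_dimension(crv, q_window = c(0.0101, 0.0111)),
               "5 points")
})

test_that("Kratky transforms are exact and invertible", {
  q <- seq(0.01, 0.4, length.out = 50)
  crv <- scattering_curve(q, rep(3, 50))
  k <- kratky_transform(crv)
  expect_equal(k$y, 3 * q^2)
  # invert
  expect_equal(k$y / k$x^2, crv$I)
  kd <- kratky_transform(crv, rg = 10, i0 = 2, dimensionless = TRUE)
  expect_equal(kd$x, q * 10)
  expect_equal(kd$y * 2 / (q * 10)^2, crv$I)
  expect_error(kratky_transform(crv, dimensionless = TRUE), "rg and i0")
})

test_that("dimensionless Kratky shapes distinguish globule from coil", {
  # compact (Guinier/globular) form (qRg)^2 exp(-(qRg)^2/3): peak at
  # qRg = sqrt(3) with height 3/e ~ 1.104
  x <- seq(0.05, 6, length.out = 5000)
  y <- x^2 * exp(-x^2 / 3)
  expect_equal(x[which.max(y)], sqrt(3), tolerance = 1e-2)
  expect_equal(max(y), 3 * exp(-1), tolerance = 1e-4)
  # Gaussian-coil Debye curve: monotone rise to a plateau of 2, no peak
  q <- seq(0.001, 1.5, length.out = 600)
  crv <- scattering_curve(q, debye_form_factor(q, 13))
  kd <- kratky_transform(crv, rg = 13, i0 = 1, dimensionless = TRUE)
  expect_true(all(diff(kd$y) > 0))
  expect_equal(kd$y[length(kd$y)], 2, tolerance = 0.02)
})

test_that("scattering curve constructor validates its invariants", {
  expect_error(scattering_curve(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(scattering_curve(c(-0.1, 0.1), c(1, 1)))
  expect_error(scattering_curve(c(0.1, 0.2), c(1, NA)))
  expect_error(scattering_curve(c(0.1, 0.2), c(1, 1), sigma = c(1, -1)))
})
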