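test_that("power-law fit recovers an exact Sneddon cone", {
  g <- indenter_geometry("perfect_cone", theta_deg = 25)
  mat <- material(2e3, 0.5)
  crv <- generate_exact_curve(g, mat, domain = c(5e-9, 500e-9),
                              n_points = 100)
  f <- fit_power_law(crv)
  expect_true(f$converged)
  expect_equal(f$m, 2, tolerance = 1e-6)
  expect_equal(f$c, (2 / pi) * mat$E_star * tan(g$theta),
               tolerance = 1e-6)
  expect_gt(f$r_squared, 1 - 1e-10)
})

test_that("power-law fit rejects unusable input", {
  expect_error(fit_power_law(force_curve(c(1, 2, 3) * 1e-9,
                                         c(1, 2, 3) * 1e-9)),
               "at least")
  expect_error(fit_power_law(force_curve(c(0, 1, 2, 3, 4) * 1e-9,
                                         1e-9 * (1:5))),
               "positive depths")
})

test_that("noiseless fits of blunted curves have near-perfect R^2 and 1 < m <= 2", {
  for (g in list(sc_geom(100e-9, 35), sc_geom(20e-9, 25),
                 pyr_geom(200e-9, 35, 4L))) {
    crv <- generate_exact_curve(g, soft_sample(),
                                domain = c(2.5 * g$R / 200, 2.5 * g$R))
    f <- fit_power_law(crv)
    expect_gt(f$r_squared, 0.999)
    expect_true(f$m > 1 && f$m <= 2)
  }
  # the shallow blunted-segment window is essentially a pure power law
  expect_gt(fit_power_law(blunted_window_curve(25, 20e-9, 1.25))$r_squared,
            0.9999)
  # spherical-cap-dominated window: exponent falls below 3/2
  f <- fit_power_law(blunted_window_curve(25, 20e-9, 1.25))
  expect_lt(f$m, 1.5)
})

test_that("classic fit is an exact projection on self-generated data", {
  for (g in list(sc_geom(100e-9, 35), pyr_geom(200e-9, 35, 4L))) {
    crv <- generate_exact_curve(g, soft_sample(),
                                domain = c(1.5e-9, 1.5 * g$R))
    cf <- fit_classic(crv, g, nu = 0.5)
    expect_equal(cf$E, 20e3, tolerance = 1e-10)
    expect_equal(cf$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("classic fit degenerates to a Hertz fit below the transition", {
  g <- sc_geom(100e-9, 35)
  h_T <- transition_depth(g)
  crv <- generate_exact_curve(g, soft_sample(),
                              domain = c(h_T / 50, 0.8 * h_T))
  cf <- fit_classic(crv, g, nu = 0.5)
  hertz <- fit_curve(crv, geom = g, method = "hertz")
  expect_equal(cf$E, hertz$E, tolerance = 1e-10)
})

test_that("method selection follows the depth/radius flowchart", {
  g100 <- sc_geom(100e-9, 35)
  expect_identical(select_method(5e-9, g100), "hertz")
  expect_identical(select_method(250e-9, g100), "simplified_blunt")
  expect_identical(select_method(1000e-9, sc_geom(20e-9, 25)),
                   "sneddon_cone")
  expect_identical(select_method(500e-9, g100), "large_depth")
  # boundary precedence: h < 3R wins over the large-depth branch
  expect_identical(select_method(299e-9, g100), "simplified_blunt")
  expect_error(select_method(-1, g100), "positive")
})

test_that("fit_curve dispatches and labels methods", {
  g <- sc_geom(100e-9, 35)
  crv <- generate_exact_curve(g, soft_sample(), c(1e-9, 250e-9))
  auto <- fit_curve(crv, method = "auto")
  expect_identical(auto$method, "simplified_blunt")
  expect_equal(auto$domain_ratio, 2.5)
  expect_identical(fit_curve(crv, method = "classic")$method,
                   "classic_blunt")
  shallow <- generate_exact_curve(g, soft_sample(), c(0.1e-9, 8e-9))
  expect_identical(fit_curve(shallow, method = "auto")$method, "hertz")
  expect_equal(fit_curve(shallow, method = "auto")$E, 20e3,
               tolerance = 5e-3)
})

test_that("large-depth fit recovers the modulus beyond 3R", {
  g <- sc_geom(20e-9, 35)
  crv <- generate_exact_curve(g, soft_sample(),
                              domain = c(3 * g$R, 10 * g$R),
                              n_points = 100)
  est <- fit_large_depth(crv, g, nu = 0.5)
  expect_equal(est$E, 20e3, tolerance = 0.03)
  shallow <- generate_exact_curve(g, soft_sample(), c(1e-9, 40e-9))
  expect_warning(fit_large_depth(shallow, g, 0.5), "3R")
})

test_that("simplified and classic fits agree on noiseless shallow curves", {
  g <- sc_geom(200e-9, 35)
  crv <- generate_exact_curve(g, soft_sample(), c(1.5e-9, 300e-9))
  E1 <- fit_curve(crv, method = "classic")$E
  E2 <- fit_curve(crv, method = "simplified")$E
  expect_equal(E2 / E1, 1, tolerance = 0.03)
})
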