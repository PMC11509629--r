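test_that("depth-contact radius relation has the analytic anchors", {
  g25 <- sc_geom(20e-9, 25)
  b <- transition_radius(g25)
  # both correction terms cancel at a = b, leaving h_T = b^2/R
  expect_equal(depth_from_contact_radius(b, g25), b^2 / g25$R,
               tolerance = 1e-14)
  # frozen value from an independent bisection inversion of the depth
  # relation, computed once before the implementation was written
  expect_equal(depth_from_contact_radius(1.25 * b, g25),
               4.153487311956e-08, tolerance = 1e-10)
  # deep-indentation anchor: h/R = 8.35 at a = 5b for a 35-degree cone
  g35 <- sc_geom(20e-9, 35)
  h <- depth_from_contact_radius(5 * transition_radius(g35), g35)
  expect_equal(h / g35$R, 8.35, tolerance = 2e-3)
  # domain error below the transition
  expect_error(depth_from_contact_radius(0.9 * b, g25), "a >= b")
})

test_that("depth and force are strictly increasing in contact radius", {
  for (g in list(sc_geom(20e-9, 25), sc_geom(100e-9, 35),
                 pyr_geom(200e-9, 35, 4L))) {
    b <- transition_radius(g)
    a <- seq(b, 10 * b, length.out = 400)
    h <- depth_from_contact_radius(a, g)
    Fv <- if (g$family == "sphero_conical") force_blunted_cone(a, g)
          else force_blunted_pyramid(a, g)
    expect_true(all(diff(h) > 0))
    expect_true(all(diff(Fv) > 0))
  }
})

test_that("depth inversion round-trips and labels regimes", {
  for (g in list(sc_geom(20e-9, 25), pyr_geom(50e-9, 35, 4L))) {
    h_T <- transition_depth(g)
    # h = 0 -> a = 0, spherical cap
    cs0 <- contact_radius_from_depth(0, g)
    expect_identical(cs0$a, 0)
    expect_identical(cs0$regime, "spherical_cap")
    # both branches agree at the transition
    csT <- contact_radius_from_depth(h_T, g)
    expect_equal(csT$a, transition_radius(g), tolerance = 1e-12)
    # round-trip across both regimes
    for (mult in c(0.5, 1, 2, 5)) {
      h <- mult * h_T
      cs <- contact_radius_from_depth(h, g)
      h_back <- if (cs$regime == "spherical_cap") cs$a^2 / g$R
                else depth_from_contact_radius(cs$a, g)
      expect_equal(h_back / h, 1, tolerance = 1e-8)
    }
  }
})

test_that("blunted cone force is Hertz-continuous at the transition", {
  for (th in c(25, 35)) for (R in c(20e-9, 200e-9)) {
    g <- sc_geom(R, th)
    b <- transition_radius(g)
    h_T <- transition_depth(g)
    mat <- soft_sample()
    expect_equal(force_blunted_cone(b, g, mat),
                 force_hertz(h_T, R, mat), tolerance = 1e-12)
    # equals (4/3) E* sqrt(R) h_T^(3/2) in closed form
    expect_equal(force_blunted_cone(b, g, mat),
                 (4 / 3) * mat$E_star * b^3 / R, tolerance = 1e-12)
  }
  # same cancellation for the pyramid
  g <- pyr_geom(200e-9, 35, 4L)
  expect_equal(force_blunted_pyramid(transition_radius(g), g),
               force_hertz(transition_depth(g), g$R), tolerance = 1e-12)
})

test_that("blunted cone approaches the Sneddon cone at large depth", {
  g <- sc_geom(20e-9, 35)
  b <- transition_radius(g)
  dev <- sapply(c(30, 300, 3000), function(mult) {
    a <- mult * b
    h <- depth_from_contact_radius(a, g)
    force_blunted_cone(a, g) / force_sneddon_cone(h, theta = g$theta) - 1
  })
  expect_true(all(abs(dev) < c(0.05, 5e-3, 5e-4)))
  expect_true(all(diff(abs(dev)) < 0))  # deviation shrinks monotonically
})

test_that("force satisfies the contact stiffness theorem dF/dh = 2 E* a", {
  # independent physics identity: the stiffness of any axisymmetric
  # frictionless contact is 2 E* a, which the closed-form force must obey
  for (g in list(sc_geom(20e-9, 25), pyr_geom(100e-9, 35, 4L))) {
    b <- transition_radius(g)
    a <- seq(1.05 * b, 3 * b, length.out = 800)
    h <- depth_from_contact_radius(a, g)
    Fv <- if (g$family == "sphero_conical") force_blunted_cone(a, g)
          else force_blunted_pyramid(a, g)
    S <- diff(Fv) / diff(h)
    a_mid <- (a[-1] + a[-length(a)]) / 2
    expect_equal(S / (2 * a_mid), rep(1, length(a_mid)),
                 tolerance = 1e-4)
  }
})

test_that("blunted pyramid converges to the blunted cone as k grows", {
  cone <- sc_geom(100e-9, 35)
  b <- transition_radius(cone)
  a <- seq(1.1 * b, 4 * b, length.out = 50)
  F_cone <- force_blunted_cone(a, cone)
  F_k1e4 <- force_blunted_pyramid(
    a, indenter_geometry("blunted_pyramid", R = 100e-9, theta_deg = 35,
                         k = 10000L))
  expect_equal(F_k1e4 / F_cone, rep(1, length(a)), tolerance = 1e-6)
  # a 4-sided pyramid is "sharper" in cross-section: less force at equal a
  F_k4 <- force_blunted_pyramid(a, pyr_geom(100e-9, 35, 4L))
  expect_true(all(F_k4 < F_cone))
})

test_that("Hertz force matches the hand-expanded value and scales in E", {
  mat <- soft_sample()
  # E = 20 kPa, nu = 0.5, R = 100 nm, h = 10 nm (frozen hand computation)
  expect_equal(force_hertz(10e-9, 100e-9, mat) * 1e11, 1.1243653903,
               tolerance = 1e-9)
  expect_identical(force_hertz(0, 100e-9, mat), 0)
  expect_equal(force_hertz(10e-9, 100e-9, material(40e3, 0.5)) /
                 force_hertz(10e-9, 100e-9, mat), 2, tolerance = 1e-14)
})

test_that("Sneddon cone force matches its closed form", {
  mat <- material(1e3, 0.5)
  # prefactor (2/pi) E* tan(25 deg) for E = 1 kPa, nu = 0.5
  expect_equal(force_sneddon_cone(1, theta_deg = 25, mat = mat),
               395.814234, tolerance = 1e-7)
  expect_identical(force_sneddon_cone(0, theta_deg = 25), 0)
})

test_that("general axisymmetric law reduces to Hertz and Sneddon exactly", {
  mat <- soft_sample()
  h <- c(1e-9, 5e-9, 2e-8)
  R <- 150e-9
  expect_equal(force_axisymmetric(h, B = 1 / (2 * R), n = 2, mat = mat),
               force_hertz(h, R, mat), tolerance = 1e-14)
  th <- 35 * pi / 180
  expect_equal(force_axisymmetric(h, B = 1 / tan(th), n = 1, mat = mat),
               force_sneddon_cone(h, theta = th, mat = mat),
               tolerance = 1e-14)
  expect_error(force_axisymmetric(1e-9, B = 1, n = -1), "n")
})

test_that("depth-corrected sphere behaves as an h -> 0 Hertz correction", {
  R <- 1e-6
  mat <- soft_sample()
  h_small <- 1e-12
  expect_equal(force_sphere_corrected(h_small, R, mat) /
                 force_hertz(h_small, R, mat), 1.014, tolerance = 1e-4)
  # Z < 1 near h = R: naive Hertz underestimates the modulus there
  h_deep <- 0.95 * R
  expect_lt(force_sphere_corrected(h_deep, R, mat) /
              force_hertz(h_deep, R, mat), 1)
  # fitted exponent over (0, R) sits between linear and Hertzian
  h <- seq(R / 200, 0.99 * R, length.out = 200)
  crv <- force_curve(h, force_sphere_corrected(h, R, mat))
  m <- fit_power_law(crv)$m
  expect_true(m > 1 && m < 1.5)
  expect_warning(force_sphere_corrected(1.1 * R, R, mat), "h >= R")
})

test_that("large-depth approximation matches the exact model for h > 3R", {
  for (th in c(25, 35)) {
    g <- sc_geom(20e-9, th)
    for (mult in c(3, 5, 10)) {
      h <- mult * g$R
      a <- contact_radius_from_depth(h, g)$a
      ratio <- suppressWarnings(force_large_depth(h, g)) /
        force_blunted_cone(a, g)
      expect_equal(ratio, 1, tolerance = 0.05)
      if (mult == 10) expect_equal(ratio, 1, tolerance = 0.02)
    }
  }
  # sharp-tip limit: R -> 0 recovers the Sneddon cone at fixed depth
  g_sharp <- sc_geom(1e-12, 35)
  h <- 100e-9
  expect_equal(suppressWarnings(force_large_depth(h, g_sharp)) /
                 force_sneddon_cone(h, theta = g_sharp$theta), 1,
               tolerance = 1e-4)
  expect_warning(force_large_depth(2 * 20e-9, sc_geom(20e-9, 35)),
                 "3R")
})

test_that("generated exact curves splice Hertz and blunted regimes", {
  g <- sc_geom(100e-9, 35)
  h_T <- transition_depth(g)
  mat <- soft_sample()
  # domain entirely below the transition: identical to pure Hertz
  crv <- generate_exact_curve(g, mat, domain = c(h_T / 100, 0.9 * h_T),
                              n_points = 50)
  expect_equal(crv$force, force_hertz(crv$h, g$R, mat), tolerance = 1e-14)
  # continuity at the spliced point
  eps <- h_T * 1e-9
  c2 <- generate_exact_curve(g, mat, domain = c(h_T - eps, h_T + eps),
                             n_points = 3)
  expect_equal(c2$force[1] / c2$force[3], 1, tolerance = 1e-6)
  expect_equal(force_hertz(h_T, g$R, mat),
               force_blunted_cone(transition_radius(g), g, mat),
               tolerance = 1e-12)
  # strictly increasing in both columns across regimes
  c3 <- generate_exact_curve(g, mat, domain = c(h_T / 10, 5 * h_T),
                             n_points = 200)
  expect_true(all(diff(c3$h) > 0) && all(diff(c3$force) > 0))
  expect_error(generate_exact_curve(g, mat, domain = c(5e-9, 1e-9)),
               "domain")
})

test_that("window fits are stable against sampling density", {
  f100 <- fit_power_law(blunted_window_curve(25, 20e-9, 1.25, n = 100))
  f1000 <- fit_power_law(blunted_window_curve(25, 20e-9, 1.25, n = 1000))
  expect_equal(f100$m, f1000$m, tolerance = 1e-3)
  expect_equal(f100$c / f1000$c, 1, tolerance = 2e-2)
})
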