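test_that("the self-locking load angle follows theta = arctan(mu) - alpha", {
  expect_equal(load_angle(atan(0.7), 0.7), 0)
  expect_equal(degrees(load_angle(0, 1)), 45)
  expect_equal(degrees(load_angle(radians(10), 0.5)), atan(0.5) * 180 / pi - 10,
               tolerance = 1e-12)
  expect_equal(degrees(load_angle(radians(10), 0.5)), 16.56505,
               tolerance = 1e-4)

  # agrees with the tangent form of the force balance,
  # tan(theta) = (mu - tan a) / (1 + mu tan a), wherever both are defined
  mu <- 0.8
  alphas <- radians(c(5, 20, 35, 55, 70))
  expect_equal(tan(load_angle(alphas, mu)),
               (mu - tan(alphas)) / (1 + mu * tan(alphas)),
               tolerance = 1e-12)
})

test_that("pressure angles follow the contact geometry", {
  expect_equal(degrees(pressure_angle_single(1, 1, 1)), 90)
  expect_equal(degrees(pressure_angle_single(1, 1, 0)), 30)
  expect_equal(pressure_angle_single(0.1, 1, 0.2), asin(0.3 / 1.1))
  expect_error(pressure_angle_single(1, 1, 1.5), "exceed")

  expect_equal(pressure_angle_double(1, 1, 4), 0)
  expect_equal(degrees(pressure_angle_double(1, 1, 2)), 60)
  expect_equal(degrees(pressure_angle_double(1, 1, 1e-9)), 90,
               tolerance = 1e-6)
  expect_error(pressure_angle_double(1, 1, 4.5), "single-contact")
})

test_that("attachment requires strict self-locking", {
  expect_true(can_attach(radians(20), mu = 0.5))
  expect_false(can_attach(atan(0.5), mu = 0.5)) # boundary disengages
  expect_false(can_attach(radians(1), mu = 0))  # frictionless never locks
  g <- adhesion_geometry(r = 0.1, R = 1, h = 0.2, mu = 0.5)
  expect_identical(g$regime, "single")
  expect_true(can_attach(g))
  expect_identical(can_attach(g), load_angle(g$alpha, g$mu) > 0)
  g2 <- adhesion_geometry(r = 0.1, R = 1, d = 1.5, mu = 0.5)
  expect_identical(g2$regime, "double")
})

test_that("two-contact forces solve the equilibrium system", {
  # theta = 0: vertical drive, equal normals, no horizontal component
  fb <- force_distribution(3, 0, radians(45), 0.5)
  expect_equal(fb$Fp, 0)
  expect_equal(fb$Fv, 3)
  expect_equal(fb$N1, fb$N2)

  # theta = 90 degrees: no vertical support
  fb90 <- force_distribution(3, pi / 2, radians(45), 0.5)
  expect_equal(fb90$Fv, 0, tolerance = 1e-15)

  # agrees with an independent linear solve
  fb10 <- force_distribution(3, radians(10), radians(45), 0.5)
  or <- force_balance_oracle(3, radians(10), radians(45), 0.5)
  expect_equal(fb10$N1, or$N1, tolerance = 1e-12)
  expect_equal(fb10$N2, or$N2, tolerance = 1e-12)

  # matches the printed closed form for k away from its singular points
  expect_equal(fb10$k, k_closed_form(radians(10), radians(45), 0.5),
               tolerance = 1e-12)

  # friction-cone boundary is singular
  expect_error(force_distribution(3, 0, atan(0.5), 0.5), "singular")

  # beyond the limit angle the lower normal reverses and is flagged
  past <- force_distribution(3, radians(30), radians(45), 0.5)
  expect_lt(past$N1, 0)
  expect_identical(past$regime, "upper_contact")
})

test_that("equilibrium residuals vanish across the (theta, alpha) grid", {
  mu <- 0.5
  F <- 3
  grid <- tidyr::expand_grid(theta = radians(seq(0, 89, by = 4)),
                             alpha = radians(seq(1, 89, by = 4)))
  grid <- grid[abs(tan(grid$alpha) - mu) > 0.05, ]
  worst <- max(purrr::pmap_dbl(grid, function(theta, alpha) {
    fb <- force_distribution(F, theta, alpha, mu)
    ca <- cos(alpha)
    sa <- sin(alpha)
    max(abs(c(
      fb$Fp - F * sin(theta),
      fb$Fv - F * cos(theta),
      fb$Ff1 - mu * fb$N1,
      fb$Ff2 - mu * fb$N2,
      fb$Fp - (fb$N1 - fb$N2) * (mu * ca - sa),
      fb$Fv - (fb$N1 + fb$N2) * (mu * sa + ca)
    )))
  }))
  expect_lte(worst, 1e-10 * F)

  # driving-force decomposition conserves the magnitude
  th <- radians(seq(0, 90, by = 3))
  fps <- vapply(th, function(t) force_distribution(3, t, radians(40), 0.3)$Fp, 0)
  fvs <- vapply(th, function(t) force_distribution(3, t, radians(40), 0.3)$Fv, 0)
  expect_equal(sqrt(fps^2 + fvs^2), rep(3, length(th)), tolerance = 1e-12)
})

test_that("the limit load angle is the root of the force ratio", {
  expect_equal(degrees(limit_load_angle(radians(45), 0)), 45)
  expect_equal(degrees(limit_load_angle(radians(45), 0.5)), 18.43495,
               tolerance = 1e-4)
  expect_error(limit_load_angle(radians(20), 0.5), "tan\\(alpha\\) > mu")
  # mu approaching tan(alpha): limit angle goes to zero
  expect_lt(limit_load_angle(radians(45), 0.999), radians(0.1))

  # agrees with a bisection root-find on N1(theta) to 1e-8 rad
  for (al in radians(c(35, 45, 60, 75))) {
    root <- uniroot(
      function(th) force_distribution(1, th, al, 0.5)$N1,
      lower = radians(0.01), upper = radians(89), tol = 1e-12
    )$root
    expect_equal(limit_load_angle(al, 0.5), root, tolerance = 1e-8)
  }
})

test_that("sweep tables reproduce the monotone relationships", {
  sw1 <- adhesion_sweep("theta_vs_alpha_mu", alpha_deg = seq(0, 80, 5),
                        mu = c(0.3, 0.6))
  by_mu <- split(sw1, sw1$mu)
  for (tab in by_mu) {
    expect_true(all(diff(tab$theta_deg[order(tab$alpha_deg)]) < 0))
  }
  # theta increases with mu at fixed alpha
  wide <- tidyr::pivot_wider(sw1, id_cols = "alpha_deg", names_from = "mu",
                             values_from = "theta_deg")
  expect_true(all(wide[["0.6"]] > wide[["0.3"]]))

  sw2 <- adhesion_sweep("alpha_vs_R_over_r", R_over_r = seq(1, 10, 1),
                        h_over_R = 0.3)
  expect_true(all(diff(sw2$alpha_deg) < 0)) # bigger particles, smaller angle

  sw3 <- adhesion_sweep("alpha_vs_d_R_r", d_over_R = seq(0.2, 1.8, 0.2),
                        R_over_r = 5)
  expect_true(all(diff(sw3$alpha_deg) < 0)) # wider spacing, smaller angle

  sw4 <- adhesion_sweep("forces_vs_theta", alpha_deg = 45, mu = 0.5, F = 3,
                        theta_deg = 0:89)
  expect_false(any(sw4$singular))
  # N2 grows over the grasping range (its analytic maximum sits at
  # tan(theta) = (mu sin a + cos a)/(sin a - mu cos a), ~71.6 deg here)
  expect_true(all(diff(sw4$N2[sw4$theta_deg <= 60]) > 0))
  expect_true(all(diff(sw4$N1) < 0))
  # N1 crosses zero at the limit angle
  lim <- degrees(limit_load_angle(radians(45), 0.5))
  expect_equal(sw4$theta_deg[which(sw4$N1 < 0)[1] - 1], floor(lim))
})
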