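test_that("the unloading power-law fit recovers known parameters", {
  B <- 2.5e6
  h_f <- 150e-9
  m <- 1.6
  h <- seq(650e-9, 150.5e-9, length.out = 120)
  curve <- tibble::tibble(
    time_s = seq_along(h),
    load_mN = B * (h - h_f)^m * 1e3,
    displacement_nm = h * 1e9,
    segment = "unloading"
  )
  # prepend a trivial loading ramp so the record is complete
  load <- tibble::tibble(time_s = 0, load_mN = max(curve$load_mN),
                         displacement_nm = max(curve$displacement_nm),
                         segment = "loading")
  fit <- fit_unloading(dplyr::bind_rows(load, curve))
  expect_true(fit$converged)
  expect_equal(fit$m, m, tolerance = 1e-4)
  expect_equal(fit$h_f, h_f, tolerance = 1e-4)
  expect_equal(fit$B, B, tolerance = 1e-3)
  expect_equal(fit$S, m * B * (max(h) - h_f)^(m - 1), tolerance = 1e-4)

  # linear unloading: exponent 1, stiffness equals B
  lin <- dplyr::mutate(curve, load_mN = 3e5 * (displacement_nm * 1e-9 - h_f) * 1e3)
  fitl <- fit_unloading(dplyr::bind_rows(load, lin))
  expect_equal(fitl$m, 1, tolerance = 1e-6)
  expect_equal(fitl$S, 3e5, tolerance = 1e-3)

  # a rising "unloading" branch is invalid
  bad <- dplyr::mutate(curve, load_mN = rev(load_mN))
  expect_error(fit_unloading(dplyr::bind_rows(load, bad)), "monotone")
  expect_error(fit_unloading(curve[1:5, ]), "fewer than 10")
})

test_that("contact area follows the Oliver-Pharr contact depth", {
  cfg <- indentation_config()
  # epsilon 0.75, h_max 1000 nm, P_max 3 mN, S 30 mN/um -> h_c 925 nm
  A <- contact_area(1000e-9, 3e-3, 30e-3 / 1e-6, cfg)
  expect_equal(A, 24.56 * (925e-9)^2)
  expect_equal(A * 1e12, 21.02, tolerance = 1e-3)

  # rigid-contact limit: infinite stiffness gives h_c = h_max
  expect_equal(contact_area(1000e-9, 3e-3, Inf, cfg),
               24.56 * (1000e-9)^2)
  # h_max below epsilon * P_max / S leaves no positive contact depth
  expect_error(contact_area(100e-9, 3e-3, 2e4, cfg), "contact depth")
  # the optional tip-rounding term enlarges the area
  cfg_tip <- indentation_config(tip_correction = TRUE)
  expect_gt(contact_area(1000e-9, 3e-3, 30e-3 / 1e-6, cfg_tip), A)
})

test_that("hardness and moduli follow their defining relations", {
  expect_equal(hardness(3e-3, 15e-12) / 1e9, 0.2)
  expect_equal(hardness(3e-3, 30e-12), hardness(3e-3, 15e-12) / 2)
  # scale invariance
  expect_equal(hardness(2 * 3e-3, 2 * 15e-12), hardness(3e-3, 15e-12))

  expect_equal(reduced_modulus(2, pi, beta = 1), 1)
  expect_equal(reduced_modulus(2, pi, beta = 1.034), 1 / 1.034)

  # rigid indenter limit: E -> (1 - nu^2) E_r
  expect_equal(specimen_modulus(1e9, nu = 0.3, E_i = 1e30),
               0.91e9, tolerance = 1e-9)
  # 0.91 / (1/1 - (1 - 0.07^2)/1140) GPa, computed by hand
  expect_equal(specimen_modulus(1e9) / 1e9, 0.9107949, tolerance = 1e-6)
  # symmetric construction: E_r = E_i / (2 (1 - nu_i^2)), nu = nu_i -> E = E_i
  E_i <- 1140e9
  nu_i <- 0.07
  expect_equal(specimen_modulus(E_i / (2 * (1 - nu_i^2)), nu = nu_i,
                                nu_i = nu_i, E_i = E_i), E_i)
  expect_error(specimen_modulus(2000e9), "compliance")

  # the compliance relation and its inverse compose to identity
  E <- 1.2e9
  nu <- 0.3
  Er <- 1 / ((1 - nu^2) / E + (1 - nu_i^2) / E_i)
  expect_equal(specimen_modulus(Er, nu, nu_i, E_i), E,
               tolerance = 1e-12)
})

test_that("Oliver-Pharr round trip recovers the generator's truth", {
  for (H in c(0.05, 0.2)) {
    for (Er in c(0.5, 1.5)) {
      res <- analyze_indentation(generate_indentation_curve(H, Er))
      expect_lt(abs(res$H_GPa - H) / H, 0.02)
      expect_lt(abs(res$Er_GPa - Er) / Er, 0.02)
    }
  }
  # with 1% load noise the recovery stays within 5% almost always
  ok <- purrr::map_lgl(1:100, function(s) {
    cur <- generate_indentation_curve(0.1, 1.0, noise_frac = 0.01, seed = s)
    res <- tryCatch(analyze_indentation(cur), error = function(e) NULL)
    !is.null(res) &&
      abs(res$H_GPa - 0.1) / 0.1 < 0.05 && abs(res$Er_GPa - 1.0) < 0.05
  })
  expect_gte(mean(ok), 0.95)

  # segment auto-split gives the same analysis as the labelled record
  cur <- generate_indentation_curve(0.2, 1.2)
  res_lab <- analyze_indentation(cur)
  res_auto <- analyze_indentation(dplyr::select(cur, -"segment"))
  expect_equal(res_auto$H_GPa, res_lab$H_GPa, tolerance = 1e-4)
})

test_that("condition summaries report means, SDs and dry/wet ratios", {
  mk <- function(H, Er, E, cond) {
    tibble::tibble(H_GPa = H, Er_GPa = Er, E_GPa = E, condition = cond)
  }
  res <- dplyr::bind_rows(
    mk(0.197, 1.105, 1.0, "dry"), mk(0.197, 1.105, 1.0, "dry"),
    mk(0.071, 0.693, 0.6, "wet"), mk(0.071, 0.693, 0.6, "wet")
  )
  s <- summarize_indentation(res)
  expect_equal(s$by_condition$H_sd_GPa, c(0, 0))
  expect_equal(s$ratios$hardness_ratio, 2.77)
  expect_equal(s$ratios$modulus_ratio, 1.59)

  expect_error(
    summarize_indentation(dplyr::bind_rows(mk(0.2, 1, 1, "dry"),
                                           mk(0.1, 1, 1, "wet"))),
    "at least 2"
  )
})
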