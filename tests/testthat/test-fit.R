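test_that("goodness-of-fit statistics match hand computations", {
  g <- goodness(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g$sse, 1)
  expect_equal(g$sst, 2)
  expect_equal(g$r_squared, 0.5)

  y <- c(2, 4, 6, 9)
  expect_equal(goodness(y, y)$r_squared, 1)
  expect_equal(goodness(y, rep(mean(y), 4))$r_squared, 0)
  expect_error(goodness(c(5, 5, 5), c(5, 5, 4)), "SST is zero")
  expect_error(goodness(1:3, 1:4), "lengths differ")

  # R^2 invariant under affine rescaling of y; SSE scales quadratically
  y2 <- 3 * y + 7
  yh <- c(2.1, 3.9, 6.3, 8.8)
  expect_equal(goodness(3 * yh + 7, y2)$r_squared,
               goodness(yh, y)$r_squared)
  expect_equal(goodness(y2, 3 * yh + 7)$sse, 9 * goodness(y, yh)$sse)
})

test_that("exact data are fitted exactly by every matching family", {
  x <- seq(0, 10, length.out = 60)

  pf <- fit_curve(tibble::tibble(x_um = x, y_um = 1 + 2 * x - 0.3 * x^2),
                  "poly2")
  expect_equal(unname(pf$coefficients), c(1, 2, -0.3), tolerance = 1e-9)
  expect_equal(pf$r_squared, 1, tolerance = 1e-12)

  m <- fourier_model(10, 4, -2, 1, 0.5, 0.6)
  ff <- fit_curve(sample_boundary_points(m, c(0, 20), 100, 0), "fourier2")
  expect_true(ff$converged)
  expect_equal(ff$coefficients, m$coefficients, tolerance = 1e-6)
  expect_equal(ff$sse, 0, tolerance = 1e-10)

  g2 <- function(x) 5 * exp(-((x - 3) / 1.5)^2) + 2 * exp(-((x - 7) / 2)^2)
  gf <- fit_curve(tibble::tibble(x_um = x, y_um = g2(x)), "gaussian2")
  expect_true(gf$converged)
  expect_equal(gf$r_squared, 1, tolerance = 1e-9)

  expect_error(fit_curve(tibble::tibble(x_um = x, y_um = rep(1, 60)),
                         "poly2"), "SST is zero")
  expect_error(fit_curve(tibble::tibble(x_um = c(1, 2, 2, 3, 4, 5),
                                        y_um = 1:6), "poly2"),
               "monotone")
  expect_error(fit_curve(tibble::tibble(x_um = 1:4, y_um = 1:4), "fourier2"),
               "at least 6")
})

test_that("model selection maximises R^2 with a parsimony tie-break", {
  mk <- function(family, r2) {
    structure(list(family = family, r_squared = r2, converged = TRUE),
              class = c("claw_fit", "claw_model"))
  }
  fits <- list(mk("gaussian2", 0.95), mk("fourier2", 0.99),
               mk("poly2", 0.90), mk("poly3", 0.94))
  expect_equal(select_model(fits)$family, "fourier2")
  expect_equal(select_model(list(mk("poly3", 0.99), mk("poly2", 0.99)))$family,
               "poly2")
  bad <- list(structure(list(family = "fourier2", converged = FALSE),
                        class = c("claw_fit", "claw_model")))
  expect_error(select_model(bad), "no fit converged")
})

test_that("the Fourier family wins on Fourier-generated data", {
  m <- claw_reference_models()$curve2
  wins <- purrr::map_lgl(1:10, function(s) {
    pts <- sample_boundary_points(m, c(0, 265), n = 120, noise_sd = 2,
                                  seed = s)
    best <- select_model(fit_all_families(pts))
    best$family == "fourier2"
  })
  expect_gte(sum(wins), 9)
})

test_that("analytic derivatives follow the closed forms", {
  cf <- claw_reference_models()$curve2$coefficients
  ev <- evaluate_model(claw_reference_models()$curve2, 0)
  expect_equal(ev$y, cf[["a0"]] + cf[["a1"]] + cf[["a2"]])
  expect_equal(ev$dy, cf[["w"]] * (cf[["b1"]] + 2 * cf[["b2"]]))
  expect_equal(ev$d2y, -cf[["w"]]^2 * (cf[["a1"]] + 4 * cf[["a2"]]))

  # the first reference curve opens concave at the origin
  ev1 <- evaluate_model(claw_reference_models()$curve1, 0)
  expect_lt(ev1$d2y, 0)

  pf <- fit_curve(tibble::tibble(x_um = seq(0, 5, by = 0.5),
                                 y_um = 2 + 0.5 * seq(0, 5, by = 0.5)^2),
                  "poly2")
  ev2 <- evaluate_model(pf, c(-3, 0, 11))
  expect_equal(ev2$d2y, rep(1, 3), tolerance = 1e-9)
})

test_that("curvature matches closed forms and is translation invariant", {
  expect_equal(curvature_k(0, 2), 2)           # parabola y = x^2 at vertex
  expect_equal(curvature_k(0, 0), 0)           # straight line
  # circle of radius 10: K = 1/R everywhere from analytic derivatives
  R <- 10
  x <- seq(-6, 6, length.out = 101)
  dy <- -x / sqrt(R^2 - x^2)
  d2y <- -R^2 / (R^2 - x^2)^(3 / 2)
  expect_equal(curvature_k(dy, d2y), rep(1 / R, length(x)),
               tolerance = 1e-9)

  prof <- curvature_profile(fourier_model(5, 2, 1, 0.5, -0.3, 0.8),
                            c(0, 10), n_grid = 101)
  shifted <- curvature_profile(fourier_model(105, 2, 1, 0.5, -0.3, 0.8),
                               c(0, 10), n_grid = 101)
  expect_equal(prof$curvature, shifted$curvature, tolerance = 1e-12)
  expect_true(all(prof$curvature >= 0))
  expect_true(all((prof$shape == "concave") == (prof$d2y < 0)))
  expect_equal(attr(prof, "max_curvature"), max(prof$curvature))
})

test_that("fourier2 parameter recovery stays within 3 standard errors", {
  m <- claw_reference_models()$curve2
  amp <- diff(range(evaluate_model(m, seq(0, 265, 0.5))$y))
  hits <- purrr::map_lgl(1:20, function(s) {
    pts <- sample_boundary_points(m, c(0, 265), n = 200,
                                  noise_sd = 0.02 * amp, seed = 100 + s)
    fit <- fit_curve(pts, "fourier2")
    if (!fit$converged || is.null(fit$std_errors)) return(FALSE)
    all(abs(fit$coefficients - m$coefficients) / fit$std_errors < 3)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("tidiers expose coefficients and fit quality", {
  m <- fourier_model(10, 4, -2, 1, 0.5, 0.6)
  fit <- fit_curve(sample_boundary_points(m, c(0, 20), 100, 0.1, seed = 1),
                   "fourier2")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 100)
  au <- augment(fit)
  expect_equal(au$.resid, au$y_um - au$.fitted)
})
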