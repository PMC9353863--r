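#' Second-order Fourier boundary model
#'
#' The boundary curves of the claw silhouette are well described by a
#' truncated Fourier series of order two,
#' \deqn{f(x) = a_0 + a_1\cos(xw) + b_1\sin(xw) + a_2\cos(2xw) + b_2\sin(2xw),}
#' with amplitudes in micrometres and angular frequency `w` in rad/um.
#'
#' @param a0,a1,b1,a2,b2 amplitudes (um).
#' @param w angular frequency (rad/um), nonzero.
#' @return an object of class `fourier_model`.
#' @export
#' @examples
#' m <- fourier_model(216.4, 125.5, -40.1, 29.52, 4.189, 0.02373)
#' evaluate_model(m, c(0, 50, 100))
fourier_model <- function(a0, a1, b1, a2, b2, w) {
  coefs <- c(a0 = a0, a1 = a1, b1 = b1, a2 = a2, b2 = b2, w = w)
  if (!all(is.finite(coefs))) stop_claw("all coefficients must be finite")
  if (w == 0) stop_claw("w must be nonzero")
  structure(list(family = "fourier2", coefficients = coefs),
    class = c("fourier_model", "claw_model")
  )
}

#' Reference claw boundary models
#'
#' Second-order Fourier models previously fitted to the four characteristic
#' boundary curves (two outer, two inner) of an adult bamboo weevil
#' (*Cyrtotrachelus buqueti*) foreclaw, digitised from denoised scanning
#' electron micrographs. They let curvature profiling and the adhesion
#' worked examples run without access to raw image data. Coordinates are in
#' micrometres.
#'
#' @return named list of four [fourier_model()] objects
#'   (`curve1` ... `curve4`).
#' @export
#' @examples
#' mods <- claw_reference_models()
#' evaluate_model(mods$curve2, 0)
claw_reference_models <- function() {
  list(
    curve1 = fourier_model(-2.136e12, 2.847e12, 4.534e10,
                           -7.115e11, -2.267e10, 2.09e-5),
    curve2 = fourier_model(216.4, 125.5, -40.1, 29.52, 4.189, 0.02373),
    curve3 = fourier_model(3.167e9, -2.394e9, 3.479e9,
                           -3.773e8, -9.861e8, -0.001086),
    curve4 = fourier_model(-1.942e13, 2.589e13, -3.502e11,
                           -6.47e12, 1.751e11, -1.774e-5)
  )
}

# family metadata -----------------------------------------------------------

fit_families <- c("gaussian2", "fourier2", "poly2", "poly3")

n_params <- function(family) {
  switch(family,
    fourier2 = 6L, gaussian2 = 6L, poly2 = 3L, poly3 = 4L,
    stop_claw("unknown family: ", family)
  )
}

# closed-form value and first two derivatives for each family ---------------

eval_family <- function(family, coefs, x) {
  switch(family,
    fourier2 = {
      w <- coefs[["w"]]
      y <- coefs[["a0"]] +
        coefs[["a1"]] * cos(x * w) + coefs[["b1"]] * sin(x * w) +
        coefs[["a2"]] * cos(2 * x * w) + coefs[["b2"]] * sin(2 * x * w)
      dy <- w * (-coefs[["a1"]] * sin(x * w) + coefs[["b1"]] * cos(x * w)) +
        2 * w * (-coefs[["a2"]] * sin(2 * x * w) + coefs[["b2"]] * cos(2 * x * w))
      d2y <- -w^2 * (coefs[["a1"]] * cos(x * w) + coefs[["b1"]] * sin(x * w)) -
        4 * w^2 * (coefs[["a2"]] * cos(2 * x * w) + coefs[["b2"]] * sin(2 * x * w))
      list(y = y, dy = dy, d2y = d2y)
    },
    gaussian2 = {
      u1 <- (x - coefs[["b1"]]) / coefs[["c1"]]
      u2 <- (x - coefs[["b2"]]) / coefs[["c2"]]
      g1 <- coefs[["a1"]] * exp(-u1^2)
      g2 <- coefs[["a2"]] * exp(-u2^2)
      y <- g1 + g2
      dy <- -2 * u1 / coefs[["c1"]] * g1 - 2 * u2 / coefs[["c2"]] * g2
      d2y <- (4 * u1^2 - 2) / coefs[["c1"]]^2 * g1 +
        (4 * u2^2 - 2) / coefs[["c2"]]^2 * g2
      list(y = y, dy = dy, d2y = d2y)
    },
    poly2 = {
      y <- coefs[["c0"]] + coefs[["c1"]] * x + coefs[["c2"]] * x^2
      list(y = y, dy = coefs[["c1"]] + 2 * coefs[["c2"]] * x,
           d2y = rep(2 * coefs[["c2"]], length(x)))
    },
    poly3 = {
      y <- coefs[["c0"]] + coefs[["c1"]] * x + coefs[["c2"]] * x^2 +
        coefs[["c3"]] * x^3
      list(y = y,
           dy = coefs[["c1"]] + 2 * coefs[["c2"]] * x + 3 * coefs[["c3"]] * x^2,
           d2y = 2 * coefs[["c2"]] + 6 * coefs[["c3"]] * x)
    },
    stop_claw("unknown family: ", family)
  )
}

#' Evaluate a boundary model and its analytic derivatives
#'
#' Derivatives are closed-form expressions of the fitted family; no numerical
#' differentiation is involved, so curvature downstream is exact for the
#' model.
#'
#' @param model a [fourier_model()] or a fitted [fit_curve()] result.
#' @param x numeric vector of positions (um).
#' @return tibble with columns `x`, `y`, `dy`, `d2y`.
#' @export
evaluate_model <- function(model, x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  fam <- model$family
  ev <- eval_family(fam, model$coefficients, x)
  tibble::tibble(x = x, y = ev$y, dy = ev$dy, d2y = ev$d2y)
}

# goodness of fit -----------------------------------------------------------

#' Least-squares goodness-of-fit summaries
#'
#' `SSE = sum (y - yhat)^2`, `SST = sum (y - mean(y))^2` and
#' `R^2 = 1 - SSE/SST`. A constant response has `SST = 0` and no defined
#' `R^2`; that is an error rather than an `NaN`.
#'
#' @param y observed values.
#' @param y_hat fitted values, same length.
#' @return tibble with columns `sse`, `sst`, `r_squared`.
#' @export
#' @examples
#' goodness(c(1, 2, 3), c(1, 2, 4))
goodness <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop_claw("y and y_hat lengths differ")
  sse <- sum((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_claw("SST is zero (constant response): R^2 undefined")
  tibble::tibble(sse = sse, sst = sst, r_squared = 1 - sse / sst)
}

# initialisation helpers ----------------------------------------------------

# dominant angular frequency of the detrended response, for seeding w
seed_frequency <- function(x, y) {
  n <- length(y)
  dx <- mean(diff(x))
  yd <- stats::residuals(stats::lm(y ~ x))
  sp <- Mod(stats::fft(yd))[2:floor(n / 2)]
  k <- unname(which.max(sp))
  2 * pi * k / (n * dx)
}

fourier_design <- function(x, w) {
  cbind(1, cos(x * w), sin(x * w), cos(2 * x * w), sin(2 * x * w))
}

# linear LS for the amplitudes at fixed w; returns list(coefs, sse)
fourier_linear_fit <- function(x, y, w) {
  X <- fourier_design(x, w)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(
    coefs = c(a0 = cf[[1]], a1 = cf[[2]], b1 = cf[[3]],
              a2 = cf[[4]], b2 = cf[[5]], w = w),
    sse = sum(fit$residuals^2)
  )
}

# twin local maxima of a lightly smoothed response, for gaussian2 centres
seed_gaussian2 <- function(x, y) {
  n <- length(y)
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  peaks <- which(diff(sign(diff(ys))) < 0) + 1L
  if (length(peaks) >= 2L) {
    peaks <- peaks[order(ys[peaks], decreasing = TRUE)][1:2]
  } else {
    peaks <- round(c(0.3, 0.7) * n)
    peaks[peaks < 1] <- 1L
  }
  span <- diff(range(x))
  c(a1 = max(y), b1 = x[peaks[1]], c1 = span / 4,
    a2 = max(y) / 2, b2 = x[peaks[2]], c2 = span / 4)
}

# fitting -------------------------------------------------------------------

#' Fit a boundary curve by least squares
#'
#' Fits one of four candidate families to an ordered set of boundary points:
#' a two-term Gaussian (`gaussian2`), a second-order Fourier series
#' (`fourier2`), and quadratic/cubic polynomials (`poly2`, `poly3`).
#' Polynomials are solved directly; the nonlinear families use
#' Levenberg-Marquardt with documented initialisation (the Fourier frequency
#' is seeded from the dominant discrete-Fourier peak of the detrended data,
#' Gaussian centres from the two largest local maxima). Non-convergence is
#' reported as a failure status, never silently.
#'
#' @param points data frame with columns `x_um`, `y_um` (or `x`, `y`);
#'   `x` strictly monotone.
#' @param family one of `"fourier2"`, `"gaussian2"`, `"poly2"`, `"poly3"`.
#' @return a `claw_fit` object: coefficients, fitted values, `sse`, `sst`,
#'   `r_squared`, standard errors when available, and a `converged` flag.
#' @export
#' @examples
#' m <- fourier_model(10, 4, -2, 1, 0.5, 0.05)
#' pts <- sample_boundary_points(m, c(0, 100), n = 80, noise_sd = 0)
#' fit <- fit_curve(pts, "fourier2")
#' glance(fit)
fit_curve <- function(points, family = fit_families) {
  family <- match.arg(family)
  xy <- boundary_xy(points)
  x <- xy$x
  y <- xy$y
  n <- length(x)
  if (n < n_params(family)) {
    stop_claw("need at least ", n_params(family), " points for ", family)
  }
  dxs <- diff(x)
  if (!(all(dxs > 0) || all(dxs < 0))) {
    stop_claw("x must be strictly monotone within a segment")
  }
  if (sum((y - mean(y))^2) == 0) {
    stop_claw("SST is zero (constant response): R^2 undefined")
  }

  coefs <- NULL
  se <- NULL
  converged <- TRUE

  if (family %in% c("poly2", "poly3")) {
    deg <- if (family == "poly2") 2L else 3L
    fit <- stats::lm(y ~ stats::poly(x, deg, raw = TRUE))
    cf <- unname(stats::coef(fit))
    coefs <- stats::setNames(cf, paste0("c", 0:deg))
    # vcov warns on interpolating fits; SEs are still well defined
    se <- suppressWarnings(
      stats::setNames(unname(sqrt(diag(stats::vcov(fit)))), names(coefs))
    )
  } else if (family == "fourier2") {
    w0 <- seed_frequency(x, y)
    lin <- fourier_linear_fit(x, y, w0)
    start <- as.list(lin$coefs)
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a0 + a1 * cos(x * w) + b1 * sin(x * w) +
          a2 * cos(2 * x * w) + b2 * sin(2 * x * w),
        data = data.frame(x = x, y = y), start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(nls_fit)) {
      # profile SSE over w on a bracket around the seed, amplitudes linear
      ws <- w0 * exp(seq(log(0.25), log(4), length.out = 60))
      prof <- vapply(ws, function(w) fourier_linear_fit(x, y, w)$sse, 0)
      best <- fourier_linear_fit(x, y, ws[which.min(prof)])
      coefs <- best$coefs
      converged <- FALSE
    } else {
      cf <- stats::coef(nls_fit)
      coefs <- cf[c("a0", "a1", "b1", "a2", "b2", "w")]
      se <- tryCatch(
        sqrt(diag(stats::vcov(nls_fit)))[names(coefs)],
        error = function(e) NULL
      )
    }
  } else { # gaussian2
    start <- as.list(seed_gaussian2(x, y))
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-((x - b1) / c1)^2) + a2 * exp(-((x - b2) / c2)^2),
        data = data.frame(x = x, y = y), start = start,
        lower = c(-Inf, -Inf, 1e-9, -Inf, -Inf, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(nls_fit)) {
      coefs <- unlist(start)
      converged <- FALSE
    } else {
      cf <- stats::coef(nls_fit)
      coefs <- cf[c("a1", "b1", "c1", "a2", "b2", "c2")]
      se <- tryCatch(
        sqrt(diag(stats::vcov(nls_fit)))[names(coefs)],
        error = function(e) NULL
      )
    }
  }

  y_hat <- eval_family(family, coefs, x)$y
  gof <- goodness(y, y_hat)
  structure(
    list(
      family = family,
      coefficients = coefs,
      std_errors = se,
      fitted = y_hat,
      data = tibble::tibble(x_um = x, y_um = y),
      sse = gof$sse,
      sst = gof$sst,
      r_squared = gof$r_squared,
      converged = converged,
      n = n
    ),
    class = c("claw_fit", "claw_model")
  )
}

# accept x_um/y_um or x/y columns
boundary_xy <- function(points, require_n = 1L) {
  if (!is.data.frame(points)) stop_claw("points must be a data frame")
  nx <- intersect(c("x_um", "x"), names(points))[1]
  ny <- intersect(c("y_um", "y"), names(points))[1]
  if (is.na(nx) || is.na(ny)) {
    stop_claw("points needs columns x_um/y_um (or x/y)")
  }
  if (nrow(points) < require_n) stop_claw("too few points")
  list(x = points[[nx]], y = points[[ny]])
}

#' @export
print.claw_fit <- function(x, ...) {
  cat("<claw_fit> family =", x$family,
      if (!x$converged) "(DID NOT CONVERGE)", "\n")
  cat("  n =", x$n, " SSE =", signif(x$sse, 5),
      " R^2 =", signif(x$r_squared, 5), "\n")
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
predict.claw_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x_um else boundary_xy(newdata)$x
  eval_family(object$family, object$coefficients, x)$y
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @export
tidy.claw_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = if (is.null(x$std_errors)) NA_real_ else unname(x$std_errors)
  )
}

#' @export
glance.claw_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family, r.squared = x$r_squared, sse = x$sse, sst = x$sst,
    nobs = x$n, converged = x$converged
  )
}

#' @export
augment.claw_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = .data$y_um - x$fitted)
}

#' Select the best fit among candidate families
#'
#' Picks the converged fit with the highest coefficient of determination;
#' ties go to the family with fewer parameters.
#'
#' @param fits list of [fit_curve()] results.
#' @return the winning `claw_fit`.
#' @export
select_model <- function(fits) {
  ok <- purrr::keep(fits, ~ .x$converged)
  if (length(ok) == 0) stop_claw("no fit converged")
  r2 <- purrr::map_dbl(ok, "r_squared")
  np <- purrr::map_int(ok, ~ n_params(.x$family))
  best <- order(-r2, np)[1]
  ok[[best]]
}

#' Fit all candidate families to one segment
#'
#' @inheritParams fit_curve
#' @param families character vector of families to try.
#' @return named list of `claw_fit` objects (failed setups dropped with a
#'   warning only when every family errors).
#' @export
fit_all_families <- function(points, families = fit_families) {
  fits <- purrr::map(
    stats::setNames(families, families),
    function(f) tryCatch(fit_curve(points, f), error = function(e) NULL)
  )
  fits <- purrr::compact(fits)
  if (length(fits) == 0) stop_claw("all families failed to fit")
  fits
}

# curvature -----------------------------------------------------------------

#' Curvature from first and second derivatives
#'
#' \deqn{K = |y''| / (1 + y'^2)^{3/2}} — the plane-curve curvature of a
#' graph `y(x)`, in 1/um when x and y are in um.
#'
#' @param dy,d2y first and second derivative values (vectorised).
#' @return non-negative curvature values.
#' @export
#' @examples
#' curvature_k(0, 2) # parabola y = x^2 at the vertex
curvature_k <- function(dy, d2y) {
  abs(d2y) / (1 + dy^2)^(3 / 2)
}

#' Curvature profile of a fitted boundary curve
#'
#' Computes \eqn{K = |y''| / (1 + y'^2)^{3/2}} on a grid from the analytic
#' derivatives of the model, and classifies each point as concave
#' (`y'' < 0`), convex (`y'' > 0`) or flat. The sign convention follows the
#' anatomical reading of the claw profiles: a negative second derivative is
#' a concave segment.
#'
#' @param model a [fourier_model()] or [fit_curve()] result.
#' @param x_range length-2 numeric range (um); for a `claw_fit` it defaults
#'   to the fitted data range.
#' @param n_grid number of grid points.
#' @return a tibble of class `curvature_profile` with columns
#'   `x`, `y`, `dy`, `d2y`, `curvature`, `shape`, plus attributes
#'   `max_curvature` and `x_at_max`.
#' @export
#' @examples
#' prof <- curvature_profile(fourier_model(0, 1, 0, 0, 0, 1), c(-1, 1))
#' attr(prof, "max_curvature")
curvature_profile <- function(model, x_range = NULL, n_grid = 512L) {
  if (is.null(x_range)) {
    if (inherits(model, "claw_fit")) {
      x_range <- range(model$data$x_um)
    } else {
      stop_claw("x_range must be given for a bare model")
    }
  }
  stopifnot(length(x_range) == 2L, x_range[2] > x_range[1], n_grid >= 2L)
  x <- seq(x_range[1], x_range[2], length.out = n_grid)
  ev <- evaluate_model(model, x)
  k <- curvature_k(ev$dy, ev$d2y)
  out <- dplyr::mutate(
    ev,
    curvature = k,
    shape = dplyr::case_when(
      .data$d2y < 0 ~ "concave",
      .data$d2y > 0 ~ "convex",
      TRUE ~ "flat"
    )
  )
  structure(
    out,
    max_curvature = max(k),
    x_at_max = x[which.max(k)],
    class = c("curvature_profile", class(out))
  )
}
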