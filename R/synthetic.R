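#' Specification of a claw phantom image
#'
#' A phantom stands in for a scanning electron micrograph of a claw: a
#' filled band between two smooth ground-truth contours (second-order
#' Fourier curves in pixel coordinates, Cartesian y measured up from the
#' bottom scan line), rendered at known intensities and optionally blurred.
#' Because the contours are known in closed form, every downstream stage
#' (denoising quality, edge localisation, boundary fitting) can be scored
#' against exact ground truth.
#'
#' The defaults draw a curved band spanning the frame, with foreground 200
#' and background 30 on the 8-bit scale and a light 1-px blur, emulating
#' the smooth high-contrast silhouette of a claw against the stub.
#'
#' @param width,height image size in pixels (>= 32).
#' @param outer_curve,inner_curve [fourier_model()] ground truths giving the
#'   upper and lower contour y(x) in pixels; the outer curve must stay
#'   strictly above the inner one across the window.
#' @param foreground,background intensities in `[0, 255]`.
#' @param smoothing_sd Gaussian blur SD in pixels (0 = none).
#' @return a `phantom_spec` list.
#' @export
#' @examples
#' ph <- generate_claw_phantom(phantom_spec(64, 64))
#' range(ph)
phantom_spec <- function(width = 128L, height = 128L,
                         outer_curve = NULL, inner_curve = NULL,
                         foreground = 200, background = 30,
                         smoothing_sd = 1) {
  check_number(width, "width", lower = 32)
  check_number(height, "height", lower = 32)
  check_number(foreground, "foreground", 0, 255)
  check_number(background, "background", 0, 255)
  check_number(smoothing_sd, "smoothing_sd", lower = 0)
  if (is.null(outer_curve)) {
    outer_curve <- fourier_model(0.60 * height, 0, 0.25 * height, 0, 0,
                                 pi / width)
  }
  if (is.null(inner_curve)) {
    inner_curve <- fourier_model(0.45 * height, 0, 0.30 * height, 0, 0,
                                 pi / width)
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      outer_curve = outer_curve, inner_curve = inner_curve,
      foreground = foreground, background = background,
      smoothing_sd = smoothing_sd
    ),
    class = "phantom_spec"
  )
}

#' Render a claw phantom image
#'
#' Scanline fill in pixel coordinates: for each pixel column the rows whose
#' Cartesian centre lies between the inner and outer contour are set to the
#' foreground intensity. The true contours are attached as the `truth`
#' attribute for oracle comparisons.
#'
#' @param spec a [phantom_spec()].
#' @return a [gray_image()] with attribute `truth`
#'   (list `outer`, `inner`, `area_px`: the analytic area between contours
#'   in pixel units).
#' @export
generate_claw_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width
  h <- spec$height
  xs <- seq_len(w) - 0.5
  y_out <- evaluate_model(spec$outer_curve, xs)$y
  y_in <- evaluate_model(spec$inner_curve, xs)$y
  if (all(abs(y_out - y_in) < 1e-9)) {
    stop_claw("outer and inner contours coincide: degenerate region")
  }
  if (any(y_out <= y_in)) {
    stop_claw(
      "contours cross within the window (outer <= inner at x = ",
      signif(xs[which(y_out <= y_in)[1]], 4), " px)"
    )
  }
  img <- matrix(spec$background, h, w)
  yc <- h - (seq_len(h) - 0.5) # Cartesian y of each row centre
  for (j in seq_len(w)) {
    inside <- yc > y_in[j] & yc < y_out[j]
    img[inside, j] <- spec$foreground
  }
  area <- sum(pmax(pmin(y_out, h) - pmax(y_in, 0), 0))
  if (spec$smoothing_sd > 0) {
    img <- conv2_sep_mirror(img, gaussian_kernel_1d(spec$smoothing_sd))
  }
  out <- gray_image(clip255(img))
  attr(out, "truth") <- list(
    outer = spec$outer_curve, inner = spec$inner_curve, area_px = area
  )
  out
}

#' Render a disk phantom
#'
#' A filled circle with known centre and radius; the workhorse target for
#' edge-localisation checks, since every true boundary point is at exact
#' distance `radius` from the centre.
#'
#' @param size image side in pixels.
#' @param radius disk radius in pixels.
#' @param center length-2 centre (x, y) in pixel coordinates; defaults to
#'   the image centre.
#' @inheritParams phantom_spec
#' @return a [gray_image()] with attribute `truth` (list `center`, `radius`).
#' @export
generate_disk_phantom <- function(size = 128L, radius = 40,
                                  center = NULL,
                                  foreground = 200, background = 30,
                                  smoothing_sd = 0) {
  check_number(size, "size", lower = 32)
  check_number(radius, "radius", lower = 1)
  if (is.null(center)) center <- c(size, size) / 2
  xs <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  ys <- matrix(seq_len(size) - 0.5, size, size)
  img <- ifelse((xs - center[1])^2 + (ys - center[2])^2 <= radius^2,
                foreground, background)
  if (smoothing_sd > 0) {
    img <- conv2_sep_mirror(img, gaussian_kernel_1d(smoothing_sd))
  }
  out <- gray_image(clip255(img))
  attr(out, "truth") <- list(center = center, radius = radius)
  out
}

#' Noise specification
#'
#' The speckled "snowflake" artefacts of SEM imaging are emulated as
#' salt-and-pepper impulse noise on a fraction of pixels plus additive
#' Gaussian noise; both are standard models and jointly reproduce the
#' blurred/speckled look of the originals.
#'
#' @param gaussian_sd additive noise SD in intensity units (>= 0).
#' @param impulse_fraction proportion of pixels replaced by 0 or 255.
#' @param seed integer seed; the injection is bit-reproducible given the
#'   seed and leaves the caller's RNG stream untouched.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(gaussian_sd = 10, impulse_fraction = 0.02,
                       seed = NULL) {
  check_number(gaussian_sd, "gaussian_sd", lower = 0)
  check_number(impulse_fraction, "impulse_fraction", 0, 1)
  structure(
    list(gaussian_sd = gaussian_sd, impulse_fraction = impulse_fraction,
         seed = seed),
    class = "noise_spec"
  )
}

#' Add synthetic noise to an image
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param noise a [noise_spec()].
#' @return a [gray_image()] of the same dimensions, clipped to `[0, 255]`.
#' @export
#' @examples
#' img <- gray_image(matrix(128, 32, 32))
#' noisy <- add_noise(img, noise_spec(gaussian_sd = 10, seed = 1))
#' sd(noisy - img)
add_noise <- function(image, noise = noise_spec()) {
  image <- as_gray_image(image)
  stopifnot(inherits(noise, "noise_spec"))
  px <- unclass(image)
  attributes(px) <- list(dim = dim(px))
  with_seed(noise$seed, {
    if (noise$gaussian_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, noise$gaussian_sd)
    }
    if (noise$impulse_fraction > 0) {
      n_imp <- round(noise$impulse_fraction * length(px))
      idx <- if (noise$impulse_fraction >= 1) {
        seq_along(px)
      } else {
        sample.int(length(px), n_imp)
      }
      px[idx] <- 255 * stats::rbinom(length(idx), 1, 0.5)
    }
  })
  gray_image(clip255(px), attr(image, "pixel_size"))
}

#' Sample noisy boundary points from a ground-truth model
#'
#' Points are equally spaced in x over `x_range`, with iid Gaussian noise on
#' y. At least six points are required, the parameter count of the
#' second-order Fourier family these sets are meant to exercise.
#'
#' @param model a [fourier_model()] (or any `claw_model`).
#' @param x_range length-2 range in um.
#' @param n number of points (>= 6).
#' @param noise_sd y-noise SD in um.
#' @param seed integer seed.
#' @return tibble with columns `x_um`, `y_um`.
#' @export
sample_boundary_points <- function(model, x_range, n = 100L, noise_sd = 0,
                                   seed = NULL) {
  stopifnot(length(x_range) == 2L, x_range[2] > x_range[1])
  check_number(noise_sd, "noise_sd", lower = 0)
  if (n < 6L) stop_claw("n must be >= 6 (second-order Fourier has 6 parameters)")
  x <- seq(x_range[1], x_range[2], length.out = n)
  y <- evaluate_model(model, x)$y
  eps <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  tibble::tibble(x_um = x, y_um = y + if (noise_sd > 0) eps else 0)
}

#' Trapezoidal nanoindentation protocol
#'
#' Defaults follow the standard claw testing protocol: peak load 3 mN,
#' loading rate 50 uN/s, 50 s hold; unloading at the loading rate.
#'
#' @param max_load_mN peak load (mN).
#' @param loading_rate_uN_s,unload_rate_uN_s ramp rates (uN/s).
#' @param hold_time_s hold at peak (s).
#' @param sampling_rate_hz sample rate (Hz).
#' @return an `indentation_protocol` list.
#' @export
indentation_protocol <- function(max_load_mN = 3, loading_rate_uN_s = 50,
                                 hold_time_s = 50, unload_rate_uN_s = 50,
                                 sampling_rate_hz = 20) {
  check_number(max_load_mN, "max_load_mN", lower = 0, strict_lower = TRUE)
  check_number(loading_rate_uN_s, "loading_rate_uN_s", 0, strict_lower = TRUE)
  check_number(hold_time_s, "hold_time_s", lower = 0)
  check_number(unload_rate_uN_s, "unload_rate_uN_s", 0, strict_lower = TRUE)
  check_number(sampling_rate_hz, "sampling_rate_hz", 0, strict_lower = TRUE)
  structure(
    list(max_load_mN = max_load_mN, loading_rate_uN_s = loading_rate_uN_s,
         hold_time_s = hold_time_s, unload_rate_uN_s = unload_rate_uN_s,
         sampling_rate_hz = sampling_rate_hz),
    class = "indentation_protocol"
  )
}

#' Generate a synthetic indentation load-displacement curve
#'
#' Builds a trapezoidal load history whose unloading branch follows the
#' power law \eqn{P = B\,(h - h_f)^m}, constructed so that Oliver-Pharr
#' analysis of the noiseless curve recovers the requested hardness and
#' reduced modulus: the projected contact area comes from
#' \eqn{A_c = P_{max}/H}, the unloading stiffness from
#' \eqn{S = 2\beta E_r \sqrt{A_c/\pi}}, the peak depth from
#' \eqn{h_{max} = h_c + \varepsilon P_{max}/S}, and the residual depth from
#' matching both \eqn{P(h_{max}) = P_{max}} and \eqn{P'(h_{max}) = S}.
#' Loading is Hertz-like (\eqn{P \propto h^2}); hold creep is a linear
#' drift, zero by default. Optional Gaussian noise applies to the load
#' channel only, so two seeds share an identical noiseless backbone.
#'
#' @param H_true target hardness (GPa).
#' @param Er_true target reduced modulus (GPa).
#' @param protocol an [indentation_protocol()].
#' @param config an [indentation_config()]; the same area function and
#'   geometry constants must be used for generation and analysis.
#' @param m unloading exponent in `[1.2, 2]`, or `NULL` (default) to pick
#'   the largest feasible exponent in that band: stiff, shallow-recovery
#'   pairs need a lower `m` for the residual depth to stay non-negative.
#' @param creep_nm total hold drift (nm).
#' @param noise_frac load noise SD as a fraction of peak load.
#' @param seed integer seed for the noise.
#' @param condition `"dry"` or `"wet"` tag carried into summaries.
#' @return tibble with columns `time_s`, `load_mN`, `displacement_nm`,
#'   `segment`, `condition`, plus a `truth` attribute (H, Er, S, depths).
#' @export
#' @examples
#' cur <- generate_indentation_curve(0.2, 1.2)
#' analyze_indentation(cur)$H_GPa
generate_indentation_curve <- function(H_true, Er_true,
                                       protocol = indentation_protocol(),
                                       config = indentation_config(),
                                       m = NULL, creep_nm = 0,
                                       noise_frac = 0, seed = NULL,
                                       condition = "dry") {
  check_number(H_true, "H_true", 0, strict_lower = TRUE)
  check_number(Er_true, "Er_true", 0, strict_lower = TRUE)
  stopifnot(inherits(protocol, "indentation_protocol"))

  P_max <- protocol$max_load_mN * 1e-3           # N
  H <- H_true * 1e9                              # Pa
  Er <- Er_true * 1e9
  A_c <- P_max / H                               # m^2
  h_c <- sqrt(A_c / config$area_coefficient)     # m
  S <- 2 * config$beta * Er * sqrt(A_c / pi)     # N/m
  # feasibility: h_f >= 0 requires m <= epsilon + h_c S / P_max
  m_max <- config$epsilon + h_c * S / P_max
  if (is.null(m)) {
    m <- max(1.2, min(2, 0.9 * m_max))
  } else {
    check_number(m, "m", 1.2, 2)
  }
  h_max <- h_c + config$epsilon * P_max / S
  h_f <- h_max - m * P_max / S
  if (h_f < 0) {
    stop_claw(
      "inconsistent (H, E_r) pair: residual depth is negative; ",
      "a stiffer modulus or lower hardness is required"
    )
  }
  B <- P_max / (h_max - h_f)^m

  fs <- protocol$sampling_rate_hz
  t_load <- P_max / (protocol$loading_rate_uN_s * 1e-6)
  t_unload <- P_max / (protocol$unload_rate_uN_s * 1e-6)
  t_hold <- protocol$hold_time_s

  tl <- seq(0, t_load, by = 1 / fs)
  th <- if (t_hold > 0) seq(0, t_hold, by = 1 / fs)[-1] else numeric()
  tu <- seq(0, t_unload, by = 1 / fs)[-1]

  P_l <- protocol$loading_rate_uN_s * 1e-6 * tl
  P_h <- rep(P_max, length(th))
  P_u <- pmax(P_max - protocol$unload_rate_uN_s * 1e-6 * tu, 0)

  h_l <- h_max * sqrt(P_l / P_max)
  h_h <- h_max + if (t_hold > 0) creep_nm * 1e-9 * th / t_hold else numeric()
  h_end <- h_max + creep_nm * 1e-9
  # unloading leaves from the post-hold depth along the power law
  h_u <- (h_f + (P_u / B)^(1 / m)) + (h_end - h_max)

  load_N <- c(P_l, P_h, P_u)
  if (noise_frac > 0) {
    load_N <- load_N +
      with_seed(seed, stats::rnorm(length(load_N), 0, noise_frac * P_max))
    load_N <- pmax(load_N, 0)
  }
  out <- tibble::tibble(
    time_s = c(tl, t_load + th, t_load + t_hold + tu),
    load_mN = load_N * 1e3,
    displacement_nm = c(h_l, h_h, h_u) * 1e9,
    segment = c(rep("loading", length(tl)), rep("hold", length(th)),
                rep("unloading", length(tu))),
    condition = condition
  )
  attr(out, "truth") <- list(
    H_GPa = H_true, Er_GPa = Er_true, S_N_per_m = S, h_max_nm = h_max * 1e9,
    h_f_nm = h_f * 1e9, h_c_nm = h_c * 1e9, m = m, B = B
  )
  out
}
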