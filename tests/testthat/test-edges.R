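test_that("classical operators behave on canonical targets", {
  flat <- gray_image(matrix(100, 32, 32))
  for (op in c("sobel", "roberts", "prewitt", "log", "canny")) {
    expect_equal(sum(classical_edges(flat, op)$edges), 0)
  }
  expect_error(classical_edges(flat, "scharr"))

  # vertical step: sobel responds only in the two columns flanking the step
  step <- matrix(0, 16, 16)
  step[, 9:16] <- 200
  em <- classical_edges(gray_image(step), "sobel")
  hit_cols <- sort(unique(which(em$edges == 1, arr.ind = TRUE)[, 2]))
  expect_identical(hit_cols, c(8L, 9L))
  # hand-convolved 3x3 magnitude at the step is 4 * 200
  expect_equal(max(em$modulus), 800)

  # 180-degree rotation commutes with detection
  set.seed(7)
  img <- matrix(round(runif(400, 0, 255)), 20, 20)
  rot180 <- function(m) m[nrow(m):1, ncol(m):1]
  for (op in c("sobel", "prewitt")) {
    a <- classical_edges(gray_image(img), op)$edges
    b <- classical_edges(gray_image(rot180(img)), op)$edges
    expect_identical(rot180(b), a)
  }
})

test_that("B-spline wavelet details act like smoothed gradients", {
  flat <- gray_image(matrix(55, 32, 32))
  d <- bspline_wavelet_decompose(flat, 1)
  expect_equal(max(abs(d$wt1)), 0)
  expect_equal(max(abs(d$wt2)), 0)

  # horizontal ramp: wt1 constant nonzero, wt2 zero (away from borders)
  ramp <- gray_image(matrix(rep(seq(0, 155, length.out = 32), each = 32),
                            32, 32))
  for (j in 1:2) {
    d <- bspline_wavelet_decompose(ramp, j)
    core <- 9:24
    expect_equal(diff(range(d$wt1[core, core])), 0, tolerance = 1e-9)
    expect_gt(abs(d$wt1[16, 16]), 0)
    expect_equal(max(abs(d$wt2[core, core])), 0, tolerance = 1e-9)
  }

  # transposition exchanges the two detail fields
  set.seed(8)
  img <- matrix(round(runif(1024, 0, 255)), 32, 32)
  d1 <- bspline_wavelet_decompose(gray_image(img), 2)
  d2 <- bspline_wavelet_decompose(gray_image(t(img)), 2)
  expect_equal(d2$wt1, t(d1$wt2), tolerance = 1e-12)
  expect_equal(d2$wt2, t(d1$wt1), tolerance = 1e-12)
})

test_that("modulus and angle follow the two-component definitions", {
  fake <- structure(list(wt1 = matrix(3, 2, 2), wt2 = matrix(4, 2, 2),
                         scale_index = 1L), class = "wavelet_detail")
  expect_equal(gradient_modulus(fake), matrix(5, 2, 2))
  swapped <- structure(list(wt1 = fake$wt2, wt2 = fake$wt1,
                            scale_index = 1L), class = "wavelet_detail")
  expect_equal(gradient_modulus(swapped), gradient_modulus(fake))

  zero <- structure(list(wt1 = matrix(0, 2, 2), wt2 = matrix(0, 2, 2),
                         scale_index = 1L), class = "wavelet_detail")
  expect_equal(gradient_modulus(zero), matrix(0, 2, 2))
  expect_equal(gradient_angle(zero), matrix(0, 2, 2))

  ang <- function(wt1, wt2) {
    d <- structure(list(wt1 = matrix(wt1, 1, 1), wt2 = matrix(wt2, 1, 1),
                        scale_index = 1L), class = "wavelet_detail")
    degrees(gradient_angle(d)[1, 1])
  }
  expect_equal(ang(1, 1), 45)
  expect_equal(ang(0, 1), 90)
  expect_equal(ang(-1, 0), 180)
})

test_that("direction quantization snaps to the four bins with lower-bin ties", {
  expect_equal(quantize_direction(30, degrees = TRUE), 45)
  expect_equal(quantize_direction(91, degrees = TRUE), 90)
  expect_equal(quantize_direction(157.5, degrees = TRUE), 135)
  expect_equal(quantize_direction(22.5, degrees = TRUE), 0)
  expect_equal(quantize_direction(67.5, degrees = TRUE), 45)
  expect_equal(quantize_direction(200, degrees = TRUE), 0) # mod 180
  expect_equal(quantize_direction(radians(-45)), 135)
})

test_that("non-maximum suppression keeps directional maxima only", {
  # single peak in a flat field survives alone
  mod <- matrix(1, 7, 7)
  mod[4, 4] <- 5
  bins <- matrix(0, 7, 7)
  out <- nonmax_suppress(mod, bins)
  expect_equal(which(out > 0), which(mod == 5))

  # output support is a subset of the input support
  set.seed(9)
  mod <- matrix(runif(81), 9, 9)
  bins <- matrix(sample(c(0, 45, 90, 135), 81, TRUE), 9, 9)
  out <- nonmax_suppress(mod, bins)
  expect_true(all(out[out > 0] == mod[out > 0]))

  # agrees with a brute-force loop applying the stated rule
  expect_equal(out, nms_oracle(mod, bins))

  # a flat two-pixel ridge keeps exactly one pixel (>= fwd, > bwd)
  ridge <- matrix(0, 5, 5)
  ridge[3, 3] <- ridge[3, 4] <- 2
  ridge[3, 2] <- ridge[3, 5] <- 1
  keep <- nonmax_suppress(ridge, matrix(0, 5, 5))
  expect_equal(sum(keep > 0), 1L)
  expect_equal(nms_oracle(ridge, matrix(0, 5, 5)), keep)

  expect_error(nonmax_suppress(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("thresholding keeps exactly the strong maxima", {
  supp <- matrix(0, 3, 5)
  supp[2, ] <- 1:5
  expect_equal(sum(threshold_edges(supp, 0)$edges), 5)
  expect_equal(sum(threshold_edges(supp, 3)$edges), 3)
  expect_equal(sum(threshold_edges(supp, 6)$edges), 0)
  expect_error(threshold_edges(supp, -1), ">= 0")
})

test_that("multiscale detection localizes the disk boundary to a pixel", {
  disk <- generate_disk_phantom(128, 40)
  tr <- attr(disk, "truth")
  maps <- multiscale_edge_detect(disk, scales = 1)
  idx <- which(maps$j1$edges == 1, arr.ind = TRUE)
  d <- sqrt((idx[, 2] - 0.5 - tr$center[1])^2 +
              (idx[, 1] - 0.5 - tr$center[2])^2)
  expect_gt(nrow(idx), 0)
  expect_lte(max(abs(d - tr$radius)), 1)
  # single-pixel ring: circumference within 15% of 2 pi r
  expect_lt(abs(nrow(idx) - 2 * pi * tr$radius) / (2 * pi * tr$radius),
            0.15)

  flat <- gray_image(matrix(128, 64, 64))
  expect_true(all(purrr::map_int(
    multiscale_edge_detect(flat, scales = c(1, 2)),
    ~ sum(.x$edges)
  ) == 0))
})

test_that("coarser scales suppress noise edges on the noisy phantom", {
  noisy <- add_noise(generate_claw_phantom(phantom_spec()),
                     noise_spec(seed = 3))
  maps <- multiscale_edge_detect(noisy, scales = c(1, 2))
  expect_lte(sum(maps$j2$edges), sum(maps$j1$edges))
})

test_that("the wavelet detector is no worse than LoG/Canny at matched recall", {
  ph <- generate_claw_phantom(phantom_spec())
  noisy <- add_noise(ph, noise_spec(gaussian_sd = 20,
                                    impulse_fraction = 0.05, seed = 1))
  bm <- edge_detector_benchmark(noisy, phantom_truth_xy(ph),
                                methods = c("wavelet", "log", "canny"),
                                scale_index = 2)
  sp <- setNames(bm$n_spurious, bm$method)
  expect_false(anyNA(sp))
  expect_lte(sp[["wavelet"]], sp[["log"]])
  expect_lte(sp[["wavelet"]], sp[["canny"]])
})
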