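#' Undecimated B-spline wavelet detail decomposition
#'
#' Computes the dyadic-scale horizontal and vertical detail fields of an
#' image in the a-trous (undecimated) scheme built on the cubic B-spline
#' smoothing filter `(1, 4, 6, 4, 1)/16`. At scale index `j` the image is
#' first smoothed by the filters dilated to steps `1, 2, ..., 2^(j-2)`,
#' then the detail fields are dilated central differences at step
#' `2^(j-1)`: `wt1` along x (columns), `wt2` along y (rows). This is the
#' standard modulus-maxima construction in which the detail coefficients
#' are proportional to the gradient of the image smoothed at scale
#' `a = 2^j`.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param scale_index dyadic scale index `j >= 1`.
#' @return a `wavelet_detail` object: list with `wt1`, `wt2` (matrices the
#'   size of the image) and `scale_index`.
#' @export
#' @examples
#' d <- bspline_wavelet_decompose(generate_disk_phantom(64, 20), 1)
#' dim(d$wt1)
bspline_wavelet_decompose <- function(image, scale_index = 1L) {
  image <- as_gray_image(image)
  if (scale_index < 1) stop_claw("scale_index must be >= 1")
  px <- unclass(image)
  attributes(px) <- list(dim = dim(px))
  h <- c(1, 4, 6, 4, 1) / 16
  sm <- px
  if (scale_index > 1) {
    for (jj in seq_len(scale_index - 1L)) {
      sm <- conv2_sep_mirror(sm, h, step = 2L^(jj - 1L))
    }
  }
  step <- 2L^(scale_index - 1L)
  dkernel <- matrix(c(-0.5, 0, 0.5), 1, 3) # central difference
  wt1 <- conv2_mirror(sm, dkernel, step = step)
  wt2 <- conv2_mirror(sm, t(dkernel), step = step)
  structure(
    list(wt1 = wt1, wt2 = wt2, scale_index = as.integer(scale_index)),
    class = "wavelet_detail"
  )
}

#' Gradient modulus of a wavelet detail pair
#'
#' Elementwise Euclidean norm `sqrt(wt1^2 + wt2^2)`.
#'
#' @param detail a `wavelet_detail` from [bspline_wavelet_decompose()].
#' @return non-negative matrix.
#' @export
gradient_modulus <- function(detail) {
  stopifnot(inherits(detail, "wavelet_detail"))
  sqrt(detail$wt1^2 + detail$wt2^2)
}

#' Gradient angle of a wavelet detail pair
#'
#' Full-circle angle via the two-argument arctangent `atan2(wt2, wt1)`,
#' in radians in `(-pi, pi]`. Pixels where both components vanish get
#' angle 0 (the direction is undefined there; the modulus is 0 so they
#' never survive suppression).
#'
#' @inheritParams gradient_modulus
#' @return matrix of angles (radians).
#' @export
gradient_angle <- function(detail) {
  stopifnot(inherits(detail, "wavelet_detail"))
  atan2(detail$wt2, detail$wt1)
}

#' Quantize gradient angles into four directions
#'
#' Angles are reduced modulo 180 degrees and snapped to the nearest of the
#' four orientations 0/180, 45/225, 90/270, 135/315. An exact tie at a bin
#' midpoint goes to the lower angle (e.g. 22.5 -> 0, 157.5 -> 135).
#'
#' @param angle angles in radians (vector or matrix).
#' @param degrees set `TRUE` if `angle` is already in degrees.
#' @return object shaped like `angle` with values in `{0, 45, 90, 135}`.
#' @export
#' @examples
#' quantize_direction(c(30, 91, 157.5), degrees = TRUE)
quantize_direction <- function(angle, degrees = FALSE) {
  deg <- if (degrees) angle else degrees(angle)
  a <- ((deg %% 180) + 180) %% 180
  b <- (45 * ceiling((a - 22.5) / 45)) %% 180
  out <- b
  attributes(out) <- attributes(angle)
  out
}

# offsets (dr, dc) along each quantized gradient direction;
# rows increase downward, so direction 45 deg steps (+1, +1)
bin_offsets <- list(
  `0` = c(0L, 1L), `45` = c(1L, 1L), `90` = c(1L, 0L), `135` = c(1L, -1L)
)

nms_raster <- function(modulus, bins) {
  nr <- nrow(modulus)
  nc <- ncol(modulus)
  keep <- matrix(FALSE, nr, nc)
  for (bv in c(0, 45, 90, 135)) {
    off <- bin_offsets[[as.character(bv)]]
    fwd <- shift_edge_inf(modulus, off[1], off[2])
    bwd <- shift_edge_inf(modulus, -off[1], -off[2])
    # >= forward, > backward: a two-pixel plateau keeps exactly one pixel
    keep <- keep | (bins == bv & modulus >= fwd & modulus > bwd)
  }
  # border pixels lack a full neighbourhood and are excluded
  keep[c(1, nr), ] <- FALSE
  keep[, c(1, nc)] <- FALSE
  out <- modulus
  out[!keep] <- 0
  out
}

# shift returning +Inf outside the image so borders never win comparisons
shift_edge_inf <- function(x, dr, dc) {
  out <- matrix(Inf, nrow(x), ncol(x))
  sr <- seq_len(nrow(x))
  sc <- seq_len(ncol(x))
  rr <- sr + dr
  cc <- sc + dc
  ok_r <- rr >= 1 & rr <= nrow(x)
  ok_c <- cc >= 1 & cc <= ncol(x)
  out[sr[ok_r], sc[ok_c]] <- x[rr[ok_r], cc[ok_c]]
  out
}

#' Non-maximum suppression along quantized gradient directions
#'
#' A pixel survives if its modulus is a local maximum along its direction
#' bin: at least its forward neighbour and strictly greater than its
#' backward neighbour (so a flat two-pixel ridge keeps exactly one pixel).
#' Border pixels, lacking a full neighbourhood, are excluded. The output
#' support is always a subset of the input's nonzero support.
#'
#' @param modulus gradient magnitude matrix.
#' @param bins direction-bin matrix from [quantize_direction()].
#' @return matrix with non-maxima zeroed.
#' @export
nonmax_suppress <- function(modulus, bins) {
  if (!identical(dim(modulus), dim(bins))) stop_claw("shape mismatch")
  nms_raster(modulus, bins)
}

#' Threshold a suppressed modulus raster into an edge map
#'
#' Pixels whose suppressed modulus is below `lambda` are dropped; survivors
#' (modulus `>= lambda` and nonzero) become edge pixels.
#'
#' @param suppressed output of [nonmax_suppress()].
#' @param lambda non-negative threshold on the modulus scale.
#' @return an [edge_map()].
#' @export
threshold_edges <- function(suppressed, lambda) {
  check_number(lambda, "lambda", lower = 0)
  edge_map((suppressed > 0 & suppressed >= lambda) * 1L,
           modulus = suppressed, operator = "wavelet")
}

#' Multiscale B-spline wavelet edge detection
#'
#' Full modulus-maxima pipeline at each requested dyadic scale: B-spline
#' detail decomposition, gradient modulus and angle, direction
#' quantization, non-maximum suppression, and thresholding. The default
#' threshold rule is per-scale, `lambda = lambda_frac * max(modulus)` at
#' that scale.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param scales integer vector of scale indices `j`.
#' @param lambda fixed threshold(s) on the modulus scale (recycled across
#'   scales), or `NULL` to use the per-scale rule.
#' @param lambda_frac fraction of the per-scale maximum modulus used when
#'   `lambda` is `NULL`.
#' @return named list of [edge_map()]s, one per scale (`j1`, `j2`, ...).
#' @export
#' @examples
#' maps <- multiscale_edge_detect(generate_disk_phantom(64, 20), scales = 1)
#' sum(maps$j1$edges) > 0
multiscale_edge_detect <- function(image, scales = c(1L, 2L), lambda = NULL,
                                   lambda_frac = 0.2) {
  if (length(scales) == 0) stop_claw("scales must be non-empty")
  if (!is.null(lambda)) lambda <- rep_len(lambda, length(scales))
  out <- purrr::imap(stats::setNames(as.list(scales), paste0("j", scales)),
    function(j, nm) {
      detail <- bspline_wavelet_decompose(image, j)
      mod <- gradient_modulus(detail)
      bins <- quantize_direction(gradient_angle(detail))
      supp <- nonmax_suppress(mod, bins)
      lam <- if (is.null(lambda)) {
        lambda_frac * max(mod)
      } else {
        lambda[[match(nm, paste0("j", scales))]]
      }
      em <- threshold_edges(supp, lam)
      em$scale_index <- as.integer(j)
      em
    }
  )
  out
}
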