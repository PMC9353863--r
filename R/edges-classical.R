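#' Binary edge map container
#'
#' @param edges 0/1 integer matrix of edge pixels.
#' @param modulus optional gradient-magnitude raster retained for
#'   re-thresholding.
#' @param operator name of the producing detector.
#' @param scale_index dyadic scale (wavelet detector only).
#' @return an `edge_map` object.
#' @export
edge_map <- function(edges, modulus = NULL, operator = "unknown",
                     scale_index = NA_integer_) {
  storage.mode(edges) <- "integer"
  if (!all(edges %in% c(0L, 1L))) stop_claw("edges must be binary")
  structure(
    list(edges = edges, modulus = modulus, operator = operator,
         scale_index = scale_index),
    class = "edge_map"
  )
}

#' @export
print.edge_map <- function(x, ...) {
  cat("<edge_map> ", x$operator,
      if (!is.na(x$scale_index)) paste0(" (j=", x$scale_index, ")"),
      ": ", sum(x$edges), " edge pixels in ",
      nrow(x$edges), "x", ncol(x$edges), "\n", sep = "")
  invisible(x)
}

# named 3x3 derivative kernel pairs (gx = d/dx i.e. across columns)
sobel_kx <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
prewitt_kx <- function() matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3)

shift_mirror <- function(x, dr, dc) {
  r <- max(abs(dr), abs(dc))
  xp <- mirror_pad(x, r)
  xp[r + seq_len(nrow(x)) + dr, r + seq_len(ncol(x)) + dc, drop = FALSE]
}

gradient_pair <- function(px, operator) {
  switch(operator,
    sobel = list(gx = conv2_mirror(px, sobel_kx()),
                 gy = conv2_mirror(px, t(sobel_kx()))),
    prewitt = list(gx = conv2_mirror(px, prewitt_kx()),
                   gy = conv2_mirror(px, t(prewitt_kx()))),
    roberts = list(gx = px - shift_mirror(px, 1, 1),
                   gy = shift_mirror(px, 0, 1) - shift_mirror(px, 1, 0)),
    stop_claw("no gradient pair for operator ", operator)
  )
}

#' Classical edge detectors
#'
#' The five classical baselines: Sobel, Roberts and Prewitt as explicit
#' convolutions thresholded on gradient magnitude; Laplacian-of-Gaussian
#' as zero crossings of the LoG response with a slope threshold; and Canny
#' with Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' double-threshold hysteresis. Thresholds are fractions of the maximum
#' response so behaviour is contrast-invariant.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param operator one of `"sobel"`, `"roberts"`, `"prewitt"`, `"log"`,
#'   `"canny"`.
#' @param threshold magnitude threshold as a fraction of the maximum
#'   response (gradient operators and LoG slope). For Canny, the *high*
#'   threshold; the low one is `low_ratio` times it.
#' @param sigma Gaussian SD for LoG and Canny smoothing (pixels).
#' @param low_ratio Canny low/high threshold ratio.
#' @return an [edge_map()].
#' @export
#' @examples
#' img <- generate_disk_phantom(64, 20)
#' sum(classical_edges(img, "sobel")$edges) > 0
classical_edges <- function(image,
                            operator = c("sobel", "roberts", "prewitt",
                                         "log", "canny"),
                            threshold = 0.2, sigma = 2, low_ratio = 0.4) {
  operator <- match.arg(operator)
  image <- as_gray_image(image)
  px <- unclass(image)
  attributes(px) <- list(dim = dim(px))

  if (operator %in% c("sobel", "roberts", "prewitt")) {
    g <- gradient_pair(px, operator)
    mod <- sqrt(g$gx^2 + g$gy^2)
    thr <- threshold * max(mod)
    edges <- (mod > thr) * 1L
    return(edge_map(edges, mod, operator))
  }

  if (operator == "log") {
    k <- gaussian_kernel_1d(sigma)
    sm <- conv2_sep_mirror(px, k)
    lap <- conv2_mirror(sm, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
    # zero crossing with slope above threshold * max slope
    right <- shift_mirror(lap, 0, 1)
    down <- shift_mirror(lap, 1, 0)
    slope <- pmax(abs(lap - right), abs(lap - down))
    zc <- (lap * right < 0) | (lap * down < 0)
    edges <- (zc & slope > threshold * max(slope)) * 1L
    return(edge_map(edges, abs(lap), operator))
  }

  # canny
  k <- gaussian_kernel_1d(sigma)
  sm <- conv2_sep_mirror(px, k)
  g <- gradient_pair(sm, "sobel")
  mod <- sqrt(g$gx^2 + g$gy^2)
  ang <- atan2(g$gy, g$gx)
  bins <- quantize_direction(ang)
  supp <- nms_raster(mod, bins)
  hi <- threshold * max(mod)
  lo <- low_ratio * hi
  strong <- supp >= hi
  weak <- supp >= lo & !strong
  edges <- hysteresis_link(strong, weak)
  edge_map(edges * 1L, mod, operator)
}

# grow strong edges into connected weak pixels (8-connected dilation loop)
hysteresis_link <- function(strong, weak) {
  repeat {
    grown <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift_logical(strong, dr, dc)
    }
    new_strong <- strong | (weak & grown)
    if (identical(new_strong, strong)) break
    strong <- new_strong
  }
  strong
}

shift_logical <- function(x, dr, dc) {
  out <- matrix(FALSE, nrow(x), ncol(x))
  sr <- seq_len(nrow(x))
  sc <- seq_len(ncol(x))
  rr <- sr - dr
  cc <- sc - dc
  ok_r <- rr >= 1 & rr <= nrow(x)
  ok_c <- cc >= 1 & cc <= ncol(x)
  out[sr[ok_r], sc[ok_c]] <- x[rr[ok_r], cc[ok_c]]
  out
}
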