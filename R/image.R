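#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix of 8-bit intensities (0-255)
#' with rows running down the image (row 1 is the top scan line) and an
#' optional physical pixel size in micrometres. It is the unit of the
#' denoising and edge-detection steps.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param pixel_size physical edge length of one pixel in micrometres,
#'   or `NA` when the scale is unknown.
#' @return a `gray_image` (numeric matrix with class and `pixel_size`
#'   attributes).
#' @export
#' @examples
#' img <- gray_image(matrix(128, 8, 8))
#' dim(img)
gray_image <- function(pixels, pixel_size = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_claw("pixels must be a numeric matrix")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_claw("intensities must lie in [0, 255] with no missing values")
  }
  structure(pixels,
    pixel_size = pixel_size,
    class = c("gray_image", class(pixels))
  )
}

#' @rdname gray_image
#' @param x object to test or coerce.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' @rdname gray_image
#' @export
as_gray_image <- function(x, pixel_size = NA_real_) {
  if (is_gray_image(x)) return(x)
  if (is.array(x) && length(dim(x)) == 3L) x <- luma(x)
  gray_image(clip255(as.matrix(x)), pixel_size)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

# ITU-R BT.601 luma conversion for colour arrays (h x w x channels)
luma <- function(arr) {
  if (dim(arr)[3] >= 3) {
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  } else {
    arr[, , 1]
  }
}

#' @export
print.gray_image <- function(x, ...) {
  cat(
    "<gray_image> ", nrow(x), "x", ncol(x),
    " intensities [", round(min(x), 1), ", ", round(max(x), 1), "]",
    if (!is.na(attr(x, "pixel_size"))) {
      paste0(" @ ", attr(x, "pixel_size"), " um/px")
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Read and write grayscale images
#'
#' PNG and TIFF round trips are lossless for 8-bit data. Colour inputs are
#' converted to grayscale with ITU-R BT.601 luma weights. Images are stored
#' on disk on the usual 0-1 scale and exposed in R on the 0-255 scale.
#'
#' @param path file path; format chosen from the extension
#'   (`.png`, `.tif`, `.tiff`).
#' @param pixel_size micrometres per pixel recorded on the returned image.
#' @return `read_image()` returns a [gray_image()]; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path, pixel_size = NA_real_) {
  if (!file.exists(path)) stop_claw("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_claw("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3L) arr <- luma(arr)
  gray_image(clip255(round(arr * 255)), pixel_size)
}

#' @rdname read_image
#' @param image a [gray_image()] or numeric matrix in `[0, 255]`.
#' @export
write_image <- function(image, path) {
  image <- as_gray_image(image)
  ext <- tolower(tools::file_ext(path))
  norm <- unclass(image) / 255
  attributes(norm) <- list(dim = dim(image))
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    stop_claw("unsupported image format: .", ext)
  )
  invisible(path)
}
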