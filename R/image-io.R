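# Internal pixel conventions used throughout the package:
#   - an RGB image is a numeric array [H, W, 3] with values in [0, 1];
#     row index = y (top to bottom), column index = x (left to right)
#   - a mask is a logical matrix [H, W] in the same frame
#   - all user-facing pixel coordinates are 0-based, x = column, y = row,
#     origin at the top-left pixel center; distances are between pixel centers

#' Validate an RGB image array
#'
#' Checks that `img` is a numeric `H x W x 3` array with finite values in
#' `[0, 1]`.
#'
#' @param img object to validate.
#' @return The validated image, invisibly.
#' @keywords internal
validate_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("image must have at least one pixel", call. = FALSE)
  if (!is.numeric(img) || anyNA(img) || any(!is.finite(img)))
    stop("image values must be finite numbers", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop("image values must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

#' Validate a binary mask
#'
#' @param mask logical matrix to validate.
#' @param img optional paired image; if given, dimensions must agree.
#' @return The mask as a logical matrix, invisibly.
#' @keywords internal
validate_mask <- function(mask, img = NULL) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!is.null(img) && !identical(dim(mask), dim(img)[1:2]))
    stop("mask and image dimensions differ", call. = FALSE)
  invisible(mask)
}

#' Clip values into the unit interval
#'
#' @param x numeric array.
#' @return `x` with every value clipped into `[0, 1]`.
#' @keywords internal
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Read an RGB image from PNG or JPEG
#'
#' 8-bit PNG or JPEG files are read into the package's internal
#' representation: a numeric `H x W x 3` array in `[0, 1]`, red-green-blue
#' channel order. Grayscale files are expanded to three channels and an
#' alpha channel, if present, is dropped.
#'
#' @param path file path ending in `.png`, `.jpg` or `.jpeg`.
#' @return Numeric `H x W x 3` array in `[0, 1]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    eb <- EBImage::readImage(path)
    px <- eb_to_array(eb)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  img <- clip01(px)
  validate_image(img)
  img
}

#' Write an RGB image to PNG or JPEG
#'
#' @param img numeric `H x W x 3` array in `[0, 1]`.
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_image(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    EBImage::writeImage(array_to_eb(img), path, quality = 98)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

# EBImage stores images x-major (dim = W, H, C); convert to/from [H, W, C].
eb_to_array <- function(eb) {
  px <- EBImage::imageData(eb)
  if (length(dim(px)) == 2L) t(px) else aperm(px, c(2L, 1L, 3L))
}

array_to_eb <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)), colormode = "Color")
}

#' Read a binary mask from an 8-bit PNG
#'
#' Any nonzero pixel is foreground. Multi-channel files are reduced with a
#' channel maximum.
#'
#' @param path PNG file path.
#' @return Logical `H x W` matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), max)
  px > 0
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask logical matrix; foreground written as 255, background as 0.
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Convert an RGB image to luminance grayscale
#'
#' Uses the BT.601 luma weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param img numeric `H x W x 3` array in `[0, 1]`.
#' @return Numeric `H x W` matrix in `[0, 1]`.
#' @export
to_gray <- function(img) {
  validate_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# n x 3 RGB rows in [0,1] -> n x 3 HSV rows (H in degrees [0, 360), S, V in [0,1])
rgb_rows_to_hsv <- function(rgb) {
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  hsv[, 1] <- hsv[, 1] * 360
  hsv[hsv[, 1] >= 360, 1] <- 0
  colnames(hsv) <- c("h", "s", "v")
  hsv
}

# HSV (H in degrees) -> RGB in [0,1], vectorized over rows
hsv_rows_to_rgb <- function(hsv) {
  cols <- grDevices::hsv(hsv[, 1] %% 360 / 360, hsv[, 2], hsv[, 3])
  t(grDevices::col2rgb(cols)) / 255
}

# Gaussian blur that tolerates small images (kernel never exceeds image size).
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  size <- min(size, 2L * (min(dim(mat)) %/% 2L) - 1L)
  if (size < 3L) return(mat)
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  EBImage::filter2(mat, brush, boundary = "replicate")
}
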