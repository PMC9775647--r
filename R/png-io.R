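#' Read an 8-bit PNG image
#'
#' Reads a plain (non-interlaced) 8-bit grayscale, RGB or RGBA PNG into an
#' integer array with values in 0..255. The package carries its own minimal
#' PNG codec (zlib-backed); pyramidal or 16-bit formats are out of scope.
#'
#' @param path path to a PNG file.
#' @return For grayscale input an integer matrix `height x width`; otherwise
#'   an integer array `height x width x channels`, indexed `[row, col,
#'   channel]` with 1-based coordinates, origin at the top-left, and channel
#'   order red, green, blue (, alpha).
#' @export
read_png <- function(path) {
  if (!file.exists(path)) abort_data("image file '%s' does not exist", path)
  res <- read_png_cpp(path.expand(path))
  v <- as.integer(res$data)
  if (res$channels == 1L) {
    # scanline order is row-major: fill a W x H matrix then transpose
    t(matrix(v, nrow = res$width, ncol = res$height))
  } else {
    a <- array(v, dim = c(res$channels, res$width, res$height))
    aperm(a, c(3L, 2L, 1L))
  }
}

#' Write an 8-bit PNG image
#'
#' @param image integer matrix (grayscale) or `height x width x channels`
#'   array (RGB/RGBA) with values in 0..255.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  d <- dim(image)
  if (length(d) != 3L || !d[3] %in% c(1L, 3L, 4L))
    abort_config("image must be a matrix or an H x W x {1,3,4} array")
  v <- as.integer(image)
  if (anyNA(v) || any(v < 0L) || any(v > 255L))
    abort_config("pixel values must be integers in 0..255")
  raw_data <- as.raw(aperm(image, c(3L, 2L, 1L)))  # scanline order
  write_png_cpp(path.expand(path), raw_data, d[2], d[1], d[3])
  invisible(path)
}

#' @rdname write_png
#' @param mask logical or 0/1 matrix; stored as 0/255 grayscale PNG.
#' @export
write_mask_png <- function(mask, path) {
  write_png(matrix(as.integer(mask) * 255L, nrow(mask), ncol(mask)), path)
}

#' @rdname read_png
#' @export
read_mask_png <- function(path) {
  m <- read_png(path)
  if (!is.matrix(m)) abort_data("mask PNG '%s' is not single-channel", path)
  m > 127L
}
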