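#' Color image container
#'
#' A light wrapper around an `H x W x 3` integer array in `[0, 255]` that
#' tracks channel semantics: `"rgb"` for ordinary micrographs,
#' `"reconstructed"` for multispace images whose channels are the gradient,
#' GLCM and LBP maps.
#'
#' @param pixels numeric `H x W x 3` array with integral values in
#'   `[0, 255]`; `H >= 3` and `W >= 3` (the texture operators need a
#'   neighborhood).
#' @param color_space `"rgb"` or `"reconstructed"`.
#' @return An object of class `color_image` (the pixel array with a
#'   `color_space` attribute).
#' @examples
#' img <- color_image(array(128, dim = c(8, 8, 3)))
#' color_space(img)
#' @export
color_image <- function(pixels, color_space = c("rgb", "reconstructed")) {
  color_space <- match.arg(color_space)
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("'pixels' must be an H x W x 3 array")
  if (d[1] < 3L || d[2] < 3L)
    stop("image must be at least 3 x 3 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  pixels <- round(pixels)
  structure(pixels, color_space = color_space,
            class = c("color_image", class(array())))
}

#' @rdname color_image
#' @param img a `color_image`.
#' @export
color_space <- function(img) {
  cs <- attr(img, "color_space")
  if (is.null(cs)) stop("not a color_image: missing color_space")
  cs
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image> %d x %d px, %s, range [%d, %d]\n",
              d[2], d[1], color_space(x), min(x), max(x)))
  invisible(x)
}

is_color_image <- function(x) inherits(x, "color_image")

assert_rgb <- function(img) {
  if (!is_color_image(img)) stop("expected a color_image")
  if (color_space(img) != "rgb")
    stop("operation requires an RGB image, got '", color_space(img), "'")
  invisible(img)
}

#' Read an image file as a `color_image`
#'
#' Supports 8-bit RGB PNG and TIFF (and JPEG when the optional jpeg package
#' is installed). Grayscale files are replicated to three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return A `color_image` in the `"rgb"` color space.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: '", ext, "' (use png or tiff)")
  )
  if (length(dim(raw)) == 2L) raw <- array(raw, dim = c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3] == 1L) raw <- array(raw, dim = c(dim(raw)[1:2], 3L))
  color_image(round(raw * 255))
}

#' Write a `color_image` to a PNG file
#'
#' PNG is used for all output because it is lossless; LBP codes in
#' reconstructed images would be corrupted by JPEG compression.
#'
#' @param img a `color_image`.
#' @param path output path (a `.png` file).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (!is_color_image(img)) stop("expected a color_image")
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}
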