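#' Parameters of the texture space operators
#'
#' Free parameters of the GLCM and LBP maps used in multispace
#' reconstruction. The GLCM map is computed per pixel from the symmetric,
#' normalized cooccurrence matrix of a sliding window; the LBP map is the
#' classic 8-neighbor, radius-1 code.
#'
#' @param glcm_levels number of gray-level quantization bins (>= 2, <= 256).
#' @param glcm_window odd window side length in pixels (>= 3).
#' @param glcm_offset integer `(row, col)` displacement of cooccurring pairs;
#'   must be nonzero.
#' @param glcm_statistic summary statistic of the window cooccurrence
#'   matrix: `"contrast"` (sum of `P(i,j) (i-j)^2`), `"energy"`
#'   (sum of `P(i,j)^2`) or `"homogeneity"` (sum of `P(i,j)/(1+|i-j|)`).
#' @param lbp_radius,lbp_points LBP geometry; only the classic 8-point,
#'   radius-1 code is implemented.
#' @return An object of class `space_params`.
#' @export
space_params <- function(glcm_levels = 8L, glcm_window = 7L,
                         glcm_offset = c(0L, 1L),
                         glcm_statistic = c("contrast", "energy", "homogeneity"),
                         lbp_radius = 1L, lbp_points = 8L) {
  glcm_statistic <- match.arg(glcm_statistic)
  glcm_levels <- as.integer(glcm_levels)
  glcm_window <- as.integer(glcm_window)
  glcm_offset <- as.integer(glcm_offset)
  if (glcm_levels < 2L || glcm_levels > 256L)
    stop("glcm_levels must be in [2, 256]")
  if (glcm_window < 3L || glcm_window %% 2L == 0L)
    stop("glcm_window must be odd and >= 3")
  if (length(glcm_offset) != 2L || all(glcm_offset == 0L))
    stop("glcm_offset must be a nonzero (row, col) pair")
  if (lbp_radius != 1L || lbp_points != 8L)
    stop("only the 8-point, radius-1 LBP is implemented")
  structure(list(glcm_levels = glcm_levels, glcm_window = glcm_window,
                 glcm_offset = glcm_offset, glcm_statistic = glcm_statistic,
                 lbp_radius = 1L, lbp_points = 8L),
            class = "space_params")
}

#' Gray-world white balance
#'
#' Scales each channel so its mean equals the mean of the three channel
#' means, alleviating the stain/scanner color casts typical of H&E slides.
#' Output is clipped to `[0, 255]` and rounded.
#'
#' @param img an RGB `color_image`.
#' @return A white-balanced RGB `color_image` of the same size.
#' @export
white_balance <- function(img) {
  assert_rgb(img)
  x <- unclass(img)
  m <- apply(x, 3, mean)
  if (any(m == 0))
    stop("degenerate input: channel with zero mean cannot be white-balanced")
  g <- mean(m)
  for (k in 1:3) x[, , k] <- x[, , k] * (g / m[k])
  color_image(pmin(pmax(round(x), 0), 255))
}

#' Luminance grayscale conversion
#'
#' Standard luminance combination `0.299 R + 0.587 G + 0.114 B`, rounded.
#'
#' @param img an RGB `color_image`.
#' @return An integer matrix (`H x W`) with values in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  assert_rgb(img)
  x <- unclass(img)
  g <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  round(g)
}

assert_gray <- function(gray, min_side = 3L) {
  if (!is.matrix(gray)) stop("expected a grayscale matrix")
  if (nrow(gray) < min_side || ncol(gray) < min_side)
    stop("grayscale image must be at least ", min_side, " x ", min_side)
  if (min(gray) < 0 || max(gray) > 255)
    stop("grayscale values must lie in [0, 255]")
  invisible(gray)
}

# replicate-pad a matrix by one pixel on every side
pad_replicate1 <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

# linear rescale so the maximum maps to 255; an all-zero map stays zero
rescale_255 <- function(m) {
  mx <- max(m)
  if (mx > 0) m <- m / mx * 255
  round(m)
}

#' Sobel gradient magnitude map
#'
#' 3x3 Sobel magnitude `sqrt(Gx^2 + Gy^2)` with replicate border padding,
#' rescaled so the image maximum maps to 255. Emphasizes boundaries, in
#' particular nucleus contours in H&E tissue.
#'
#' @param gray integer matrix in `[0, 255]`, at least 3 x 3.
#' @return An integer matrix of the same size with values in `[0, 255]`.
#' @export
gradient_image <- function(gray) {
  assert_gray(gray)
  p <- pad_replicate1(gray)
  H <- nrow(gray); W <- ncol(gray)
  sh <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  # Sobel kernels: Gx responds to horizontal change, Gy to vertical
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  rescale_255(sqrt(gx^2 + gy^2))
}

#' Sliding-window GLCM statistic map
#'
#' The gray-level cooccurrence matrix is natively a whole-image summary; to
#' obtain an image-shaped "GLCM space", each pixel is assigned the chosen
#' statistic of the symmetric, normalized cooccurrence matrix of its
#' quantized window neighborhood (replicate padding at the border). The
#' statistic map is rescaled so its maximum maps to 255. Responds to the
#' textured interior of nuclei.
#'
#' @param gray integer matrix in `[0, 255]`.
#' @param params a [space_params()] object.
#' @return An integer matrix of the same size with values in `[0, 255]`.
#' @export
glcm_image <- function(gray, params = space_params()) {
  assert_gray(gray)
  if (nrow(gray) < params$glcm_window || ncol(gray) < params$glcm_window)
    stop("GLCM window (", params$glcm_window, ") larger than the image")
  q <- matrix(as.integer(floor(gray * params$glcm_levels / 256)),
              nrow(gray), ncol(gray))
  stat <- match(params$glcm_statistic, c("contrast", "energy", "homogeneity")) - 1L
  m <- cpp_glcm_map(q, params$glcm_levels, params$glcm_window,
                    params$glcm_offset[1], params$glcm_offset[2], stat)
  rescale_255(m)
}

#' Local binary pattern map
#'
#' Classic 8-neighbor, radius-1 LBP: bit `b` of the code is set when the
#' corresponding neighbor is `>=` the center pixel, bits ordered clockwise
#' from the top-left neighbor (most significant bit first). Codes already
#' span `[0, 255]`, so no rescaling is applied; replicate padding at the
#' border. Highlights locally extremal structures such as nucleus centers.
#'
#' @param gray integer matrix in `[0, 255]`, at least 3 x 3.
#' @return An integer matrix of LBP codes in `[0, 255]`.
#' @export
lbp_image <- function(gray) {
  assert_gray(gray)
  cpp_lbp(matrix(as.integer(gray), nrow(gray), ncol(gray)))
}

#' Multispace image reconstruction
#'
#' Builds the reconstructed image: white balance, grayscale conversion, then
#' the gradient, GLCM-statistic and LBP maps stacked as the R, G and B
#' channels. The result is a `color_image` tagged `"reconstructed"` with the
#' same pixel geometry as the input.
#'
#' @param img an RGB `color_image`.
#' @param params a [space_params()] object.
#' @return A `color_image` with `color_space = "reconstructed"`.
#' @examples
#' img <- color_image(array(rep(c(200, 150, 180), each = 64),
#'                          dim = c(8, 8, 3)))
#' rec <- reconstruct(img)
#' color_space(rec)
#' @export
reconstruct <- function(img, params = space_params()) {
  assert_rgb(img)
  gray <- to_grayscale(white_balance(img))
  out <- array(0, dim = dim(img))
  out[, , 1] <- gradient_image(gray)
  out[, , 2] <- glcm_image(gray, params)
  out[, , 3] <- lbp_image(gray)
  color_image(out, color_space = "reconstructed")
}
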