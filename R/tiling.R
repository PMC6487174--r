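#' Cut an image into non-overlapping patches
#'
#' Tiles row-major from the top-left pixel; right and bottom remainders
#' (`W %% patch_size`, `H %% patch_size`) are discarded. A 1388 x 1040
#' micrograph at the default patch size yields the canonical 21 x 16 grid
#' of 336 patches.
#'
#' @param img a `color_image` (either color space).
#' @param patch_size patch side length in pixels (default 64).
#' @return An object of class `patch_grid`: list with `patch_size`,
#'   `n_rows`, `n_cols`, `patches` (row-major list of
#'   `patch_size x patch_size x 3` arrays) and `origins` (integer matrix of
#'   0-based `(row_px, col_px)` top-left corners).
#' @examples
#' img <- color_image(array(100, dim = c(70, 130, 3)))
#' tile_image(img)$n_cols  # floor(130 / 64) = 2
#' @export
tile_image <- function(img, patch_size = 64L) {
  if (!is_color_image(img)) stop("expected a color_image")
  patch_size <- as.integer(patch_size)
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H < patch_size || W < patch_size)
    stop("image (", W, " x ", H, ") smaller than one ", patch_size, " px patch")
  n_rows <- H %/% patch_size
  n_cols <- W %/% patch_size
  patches <- vector("list", n_rows * n_cols)
  origins <- matrix(0L, n_rows * n_cols, 2,
                    dimnames = list(NULL, c("row_px", "col_px")))
  x <- unclass(img)
  k <- 0L
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      k <- k + 1L
      r0 <- (r - 1L) * patch_size
      c0 <- (cc - 1L) * patch_size
      patches[[k]] <- x[(r0 + 1L):(r0 + patch_size),
                        (c0 + 1L):(c0 + patch_size), , drop = FALSE]
      origins[k, ] <- c(r0, c0)
    }
  }
  structure(list(patch_size = patch_size, n_rows = n_rows, n_cols = n_cols,
                 patches = patches, origins = origins,
                 color_space = color_space(img)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d grid of %d px patches (%d total, %s)\n",
              x$n_cols, x$n_rows, x$patch_size,
              length(x$patches), x$color_space))
  invisible(x)
}

#' Majority vote over patch labels
#'
#' Returns the modal label; ties are broken deterministically by the
#' smallest class id.
#'
#' @param patch_labels non-empty vector of integer class ids.
#' @return The winning class id.
#' @examples
#' majority_vote(c(0, 0, 1))  # 0
#' majority_vote(c(0, 1))     # tie -> smallest id
#' @export
majority_vote <- function(patch_labels) {
  if (length(patch_labels) == 0) stop("empty label list")
  counts <- table(patch_labels)
  ids <- as.integer(names(counts))
  winners <- ids[counts == max(counts)]
  min(winners)
}

#' Per-patch probability atlas
#'
#' The atlas holds, at each grid cell, the predicted probability of the
#' image-level class for the patch at that position — a spatial map of
#' prediction confidence across the slide.
#'
#' @param grid a [tile_image()] `patch_grid`.
#' @param probs numeric matrix, one row per patch (row-major grid order),
#'   one column per class in increasing class-id order.
#' @param image_class integer class id (0-based column into `probs`).
#' @return A `n_rows x n_cols` matrix of probabilities in `[0, 1]`.
#' @export
probability_atlas <- function(grid, probs, image_class) {
  if (!inherits(grid, "patch_grid")) stop("expected a patch_grid")
  probs <- as.matrix(probs)
  n <- length(grid$patches)
  if (nrow(probs) != n)
    stop("probs has ", nrow(probs), " rows for ", n, " patches")
  cl <- as.integer(image_class) + 1L
  if (cl < 1L || cl > ncol(probs)) stop("image_class out of range")
  p <- probs[, cl]
  if (min(p) < 0 || max(p) > 1) stop("probabilities must lie in [0, 1]")
  matrix(p, grid$n_rows, grid$n_cols, byrow = TRUE)
}
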