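#' Backbone configuration
#'
#' VGG-16-style convolutional feature extractor: five blocks of
#' (2, 2, 3, 3, 3) convolution layers with (64, 128, 256, 512, 512) filters,
#' all 3x3 kernels with stride 1 and same-padding, each block followed by a
#' 2x2 max-pool. On a 64x64 input the spatial size after five pools is 2x2,
#' so the flattened feature dimension is 2 * 2 * 512 = 2048.
#'
#' @param input_size input patch side length (64).
#' @param weights_source `"seeded_random"` (deterministic He-style random
#'   weights, usable offline) or `"imagenet_pretrained"`.
#' @param seed integer seed for `"seeded_random"` weights.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(input_size = 64L,
                            weights_source = c("seeded_random",
                                               "imagenet_pretrained"),
                            seed = 1L) {
  weights_source <- match.arg(weights_source)
  input_size <- as.integer(input_size)
  if (input_size != 64L)
    stop("the architecture is fixed to 64 px inputs (five 2x2 pools -> 2x2)")
  structure(list(input_size = input_size,
                 conv_layers_per_block = c(2L, 2L, 3L, 3L, 3L),
                 filters_per_block = c(64L, 128L, 256L, 512L, 512L),
                 weights_source = weights_source,
                 seed = as.integer(seed)),
            class = "backbone_config")
}

#' Build the convolutional backbone
#'
#' Instantiates the feature extractor of [backbone_config()]. With
#' `weights_source = "seeded_random"` the weights are He-initialized from a
#' fixed seed, so two builds with the same seed are bit-identical. The
#' fully connected layers of stock VGG-16 are dropped: features are the
#' flattened output of the last max-pool. Pretrained ImageNet weights are
#' not bundled; requesting them raises an error pointing at the seeded
#' alternative.
#'
#' @param cfg a [backbone_config()].
#' @return An object of class `vgg_backbone`.
#' @examples
#' b <- build_backbone(backbone_config(seed = 7))
#' f <- extract_features(b, array(128, dim = c(64, 64, 3)))
#' dim(f)  # 1 x 2048
#' @export
build_backbone <- function(cfg = backbone_config()) {
  if (!inherits(cfg, "backbone_config")) stop("expected a backbone_config")
  if (cfg$weights_source == "imagenet_pretrained")
    stop("ImageNet-pretrained weights are not bundled; build with ",
         "weights_source = \"seeded_random\" for offline use")
  layers <- list()
  in_ch <- 3L
  set.seed(cfg$seed)
  for (blk in seq_along(cfg$conv_layers_per_block)) {
    out_ch <- cfg$filters_per_block[blk]
    for (l in seq_len(cfg$conv_layers_per_block[blk])) {
      fan_in <- 9L * in_ch
      W <- matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                  fan_in, out_ch)
      layers[[length(layers) + 1L]] <-
        list(W = W, b = numeric(out_ch), block = blk)
      in_ch <- out_ch
    }
  }
  structure(list(config = cfg, layers = layers, out_dim = 2048L),
            class = "vgg_backbone")
}

#' @export
print.vgg_backbone <- function(x, ...) {
  cat(sprintf("<vgg_backbone> %d conv layers, %s weights (seed %d), %d-dim features\n",
              length(x$layers), x$config$weights_source, x$config$seed,
              x$out_dim))
  invisible(x)
}

#' Per-layer shape trace of the backbone
#'
#' @param backbone a [build_backbone()] object.
#' @return A data frame with one row per layer (`layer`, `filters`,
#'   `height`, `width`, `channels`), the architecture audit of the network.
#' @export
architecture_trace <- function(backbone) {
  cfg <- backbone$config
  rows <- list(data.frame(layer = "Input", filters = NA_integer_,
                          height = cfg$input_size, width = cfg$input_size,
                          channels = 3L))
  s <- cfg$input_size
  conv_i <- 0L
  for (blk in seq_along(cfg$conv_layers_per_block)) {
    ch <- cfg$filters_per_block[blk]
    for (l in seq_len(cfg$conv_layers_per_block[blk])) {
      conv_i <- conv_i + 1L
      rows[[length(rows) + 1L]] <-
        data.frame(layer = paste0("Conv", conv_i), filters = ch,
                   height = s, width = s, channels = ch)
    }
    s <- s %/% 2L
    rows[[length(rows) + 1L]] <-
      data.frame(layer = paste0("Max-Pool", blk), filters = NA_integer_,
                 height = s, width = s, channels = ch)
  }
  do.call(rbind, rows)
}

# forward pass of one 64 x 64 x 3 patch already scaled to [0, 1]
backbone_forward <- function(backbone, x) {
  cfg <- backbone$config
  li <- 0L
  for (blk in seq_along(cfg$conv_layers_per_block)) {
    for (l in seq_len(cfg$conv_layers_per_block[blk])) {
      li <- li + 1L
      layer <- backbone$layers[[li]]
      m <- cpp_im2col(x)
      z <- m %*% layer$W
      z <- sweep(z, 2, layer$b, "+")
      z[z < 0] <- 0
      dim(z) <- c(dim(x)[1], dim(x)[2], ncol(layer$W))
      x <- z
    }
    x <- cpp_maxpool2(x)
  }
  as.vector(x)
}

#' Extract deep features from patches
#'
#' Runs each 64x64x3 patch through the backbone and flattens the final
#' pooled maps to a 2048-dimensional feature vector. Patches are processed
#' independently, so a patch's features never depend on its batch
#' neighbors. Pixel values in `[0, 255]` are scaled to `[0, 1]` before the
#' first convolution.
#'
#' @param backbone a [build_backbone()] object.
#' @param patches a single `64 x 64 x 3` array, a list of such arrays, or a
#'   [tile_image()] `patch_grid`.
#' @return A numeric `N x 2048` matrix, one row per patch.
#' @export
extract_features <- function(backbone, patches) {
  if (!inherits(backbone, "vgg_backbone")) stop("expected a vgg_backbone")
  if (inherits(patches, "patch_grid")) patches <- patches$patches
  if (is.array(patches) && length(dim(patches)) == 3L) patches <- list(patches)
  sz <- backbone$config$input_size
  out <- matrix(0, length(patches), backbone$out_dim)
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    if (!identical(dim(p), c(sz, sz, 3L)) &&
        !identical(dim(p), as.integer(c(sz, sz, 3))))
      stop("patch ", i, " is not ", sz, " x ", sz, " x 3")
    out[i, ] <- backbone_forward(backbone, unclass(p) / 255)
  }
  out
}

#' Concatenate the two feature streams
#'
#' Joins the 2048-dimensional RGB-stream and reconstructed-stream features
#' into the 4096-dimensional combination, RGB half first.
#'
#' @param rgb,rec numeric vectors of length 2048 (or matrices with 2048
#'   columns and matching row counts).
#' @return A length-4096 vector (or `N x 4096` matrix).
#' @export
concat_features <- function(rgb, rec) {
  if (is.matrix(rgb) || is.matrix(rec)) {
    rgb <- as.matrix(rgb); rec <- as.matrix(rec)
    if (ncol(rgb) != 2048L || ncol(rec) != 2048L || nrow(rgb) != nrow(rec))
      stop("expected matching N x 2048 matrices")
    return(cbind(rgb, rec))
  }
  if (length(rgb) != 2048L || length(rec) != 2048L)
    stop("expected two length-2048 vectors")
  c(rgb, rec)
}
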