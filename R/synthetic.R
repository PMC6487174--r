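#' Default class profiles for the synthetic generator
#'
#' Three morphology profiles mimicking the qualitative contrast between the
#' lymphoma subtypes on H&E slides: CLL-like (many small nuclei), FL-like
#' (fewer, larger follicular nuclei) and MCL-like (intermediate density and
#' size). Densities are nucleus counts per full-size 1388 x 1040 image;
#' pass proportionally smaller counts for smaller image geometries.
#'
#' @return A named list of profiles, each with `density`, `radius_range`
#'   (px), `texture_amplitude` (gray levels) and `graininess` (px scale of
#'   intra-nucleus chromatin noise).
#' @export
default_class_profiles <- function() {
  list(
    CLL = list(density = 400L, radius_range = c(6, 11),
               texture_amplitude = 10, graininess = 2L),
    FL  = list(density = 140L, radius_range = c(14, 22),
               texture_amplitude = 18, graininess = 4L),
    MCL = list(density = 250L, radius_range = c(9, 15),
               texture_amplitude = 14, graininess = 3L)
  )
}

#' Synthetic dataset configuration
#'
#' @param image_size `(W, H)` in pixels; default the 1388 x 1040 geometry
#'   of bright-field lymphoma micrographs.
#' @param n_per_class images per class.
#' @param profiles list of class profiles as in [default_class_profiles()];
#'   profiles must differ in at least one of density / radius / texture.
#' @param background pink-ish background: list with RGB `mean` and pixel
#'   `jitter` (sd in gray levels).
#' @param nucleus purple-ish nucleus color: list with `mean` and per-nucleus
#'   `jitter`.
#' @param color_cast half-range of the random per-image multiplicative
#'   channel cast (exercises the white-balance step).
#' @param seed integer seed; fully determines the dataset.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(image_size = c(1388L, 1040L), n_per_class = 4L,
                         profiles = default_class_profiles(),
                         background = list(mean = c(228, 180, 200), jitter = 6),
                         nucleus = list(mean = c(110, 70, 150), jitter = 12),
                         color_cast = 0.08, seed = 1L) {
  if (length(profiles) < 2L) stop("need at least two class profiles")
  key <- vapply(profiles, function(p)
    paste(p$density, paste(p$radius_range, collapse = ","),
          p$texture_amplitude), character(1))
  if (anyDuplicated(key))
    stop("class profiles must be pairwise distinct")
  structure(list(image_size = as.integer(image_size),
                 n_per_class = as.integer(n_per_class),
                 profiles = profiles, background = background,
                 nucleus = nucleus, color_cast = color_cast,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# coarse gaussian noise field expanded to (h, w): chromatin-like graininess
grain_noise <- function(h, w, scale) {
  scale <- max(1L, as.integer(scale))
  ch <- ceiling(h / scale); cw <- ceiling(w / scale)
  coarse <- matrix(rnorm(ch * cw), ch, cw)
  big <- coarse[rep(seq_len(ch), each = scale), rep(seq_len(cw), each = scale),
                drop = FALSE]
  big[seq_len(h), seq_len(w), drop = FALSE]
}

# place non-overlapping ellipses by rejection sampling
place_nuclei <- function(W, H, profile, max_tries_per = 200L) {
  n <- profile$density
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0),
                                 a = numeric(0), b = numeric(0),
                                 theta = numeric(0)))
  rr <- profile$radius_range
  x <- y <- a <- b <- theta <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- max_tries_per * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("nucleus density too high: placed ", placed, " of ", n,
           " non-overlapping nuclei after ", max_tries, " tries")
    ca <- runif(1, rr[1], rr[2]); cb <- runif(1, rr[1], rr[2])
    m <- max(ca, cb)
    cx <- runif(1, m + 1, W - m - 1); cy <- runif(1, m + 1, H - m - 1)
    if (placed > 0L) {
      d2 <- (x[seq_len(placed)] - cx)^2 + (y[seq_len(placed)] - cy)^2
      lim <- (pmax(a[seq_len(placed)], b[seq_len(placed)]) + m)^2
      if (any(d2 < lim)) next
    }
    placed <- placed + 1L
    x[placed] <- cx; y[placed] <- cy; a[placed] <- ca; b[placed] <- cb
    theta[placed] <- runif(1, 0, pi)
  }
  data.frame(x = x, y = y, a = a, b = b, theta = theta)
}

render_image <- function(cfg, profile) {
  W <- cfg$image_size[1]; H <- cfg$image_size[2]
  img <- array(0, dim = c(H, W, 3))
  for (k in 1:3)
    img[, , k] <- cfg$background$mean[k] +
      matrix(rnorm(H * W, sd = cfg$background$jitter), H, W)
  nuclei <- place_nuclei(W, H, profile)
  for (i in seq_len(nrow(nuclei))) {
    nc <- nuclei[i, ]
    m <- ceiling(max(nc$a, nc$b))
    r0 <- max(1L, floor(nc$y - m)); r1 <- min(H, ceiling(nc$y + m))
    c0 <- max(1L, floor(nc$x - m)); c1 <- min(W, ceiling(nc$x + m))
    rows <- r0:r1; cols <- c0:c1
    dy <- outer(rows - nc$y, rep(1, length(cols)))
    dx <- outer(rep(1, length(rows)), cols - nc$x)
    u <- dx * cos(nc$theta) + dy * sin(nc$theta)
    v <- -dx * sin(nc$theta) + dy * cos(nc$theta)
    mask <- (u / nc$a)^2 + (v / nc$b)^2 <= 1
    col_jit <- rnorm(3, sd = cfg$nucleus$jitter)
    tex <- profile$texture_amplitude *
      grain_noise(length(rows), length(cols), profile$graininess)
    for (k in 1:3) {
      plane <- img[rows, cols, k]
      plane[mask] <- cfg$nucleus$mean[k] + col_jit[k] + tex[mask]
      img[rows, cols, k] <- plane
    }
  }
  cast <- 1 + runif(3, -cfg$color_cast, cfg$color_cast)
  for (k in 1:3) img[, , k] <- img[, , k] * cast[k]
  list(image = color_image(pmin(pmax(round(img), 0), 255)),
       nuclei = nuclei)
}

#' Generate a seeded synthetic H&E-like dataset
#'
#' Renders, per class profile, images of a pink background field with
#' non-overlapping purple elliptical nuclei carrying additive chromatin
#' texture, under a random per-image color cast. The seed fully determines
#' the output.
#'
#' @param cfg a [synth_config()].
#' @param out_dir optional directory; when given, images are written as
#'   PNGs alongside a `manifest.csv`.
#' @return A list with `images` (list of `color_image`), `labels` (integer
#'   class ids, 0-based in profile order), `manifest` (data frame
#'   `image_id`, `class`, `class_name`, `seed`) and `placements` (per-image
#'   nucleus placement logs).
#' @export
generate_dataset <- function(cfg = synth_config(), out_dir = NULL) {
  set.seed(cfg$seed)
  class_names <- names(cfg$profiles)
  if (is.null(class_names))
    class_names <- paste0("class", seq_along(cfg$profiles) - 1L)
  images <- list(); labels <- integer(0)
  placements <- list()
  ids <- character(0)
  for (ci in seq_along(cfg$profiles)) {
    for (j in seq_len(cfg$n_per_class)) {
      r <- render_image(cfg, cfg$profiles[[ci]])
      id <- sprintf("%s_%02d", class_names[ci], j)
      images[[id]] <- r$image
      placements[[id]] <- r$nuclei
      labels <- c(labels, ci - 1L)
      ids <- c(ids, id)
    }
  }
  manifest <- data.frame(image_id = ids, class = labels,
                         class_name = class_names[labels + 1L],
                         seed = cfg$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in ids)
      write_image(images[[id]], file.path(out_dir, paste0(id, ".png")))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(images = images, labels = labels, manifest = manifest,
       placements = placements)
}

#' Generate a paired two-stream feature fixture
#'
#' Class-conditional Gaussian feature vectors emulating the statistical
#' structure the selector assumes: unit-variance noise with a mean offset
#' of `separation` on a class-specific coordinate block. The RGB and
#' reconstructed streams carry their signal on disjoint coordinate blocks,
#' encoding the complementarity that makes stream fusion genuinely
#' informative. Blocks are placed in the tail coordinates (the last
#' timesteps of the selector's row-major sequence), where a recurrent
#' reader's terminal state retains them; the reconstruction stream's blocks
#' sit earlier than the RGB stream's, so it is the intrinsically harder
#' stream.
#'
#' @param n_per_class samples per class.
#' @param separation mean offset of the informative block (effect size);
#'   `0` produces a null fixture with no class signal.
#' @param dim feature dimension (default 2048).
#' @param seed integer seed.
#' @param n_classes number of classes.
#' @param block_size informative block width per class.
#' @param patches_per_image group consecutive same-class samples into
#'   pseudo-images of this many patches (for image-level protocols); must
#'   divide `n_per_class`.
#' @return A list with `rgb`, `rec` (`N x dim` matrices), `labels` (0-based
#'   ids) and `image_id`.
#' @export
generate_feature_fixture <- function(n_per_class = 100L, separation = 5,
                                     dim = 2048L, seed = 1L,
                                     n_classes = 3L, block_size = 64L,
                                     patches_per_image = 1L) {
  if (separation < 0) stop("separation must be >= 0")
  if (n_per_class %% patches_per_image != 0)
    stop("patches_per_image must divide n_per_class")
  if (2L * n_classes * block_size > dim)
    stop("dim too small for disjoint informative blocks")
  set.seed(seed)
  N <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
  rgb <- matrix(rnorm(N * dim), N, dim)
  rec <- matrix(rnorm(N * dim), N, dim)
  K <- n_classes
  for (k in seq_len(K) - 1L) {
    rows <- labels == k
    cols_rgb <- dim - (K - k) * block_size + seq_len(block_size)
    cols_rec <- dim - K * block_size - (K - k) * block_size +
      seq_len(block_size)
    rgb[rows, cols_rgb] <- rgb[rows, cols_rgb] + separation
    rec[rows, cols_rec] <- rec[rows, cols_rec] + separation
  }
  image_id <- paste0("img_", labels, "_",
                     rep(rep(seq_len(n_per_class %/% patches_per_image),
                             each = patches_per_image), n_classes))
  list(rgb = rgb, rec = rec, labels = labels, image_id = image_id)
}
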