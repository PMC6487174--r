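const_rgb <- function(vals, h = 4, w = 4) {
  color_image(array(rep(vals, each = h * w), dim = c(h, w, 3)))
}

test_that("gray-world white balance equalizes channel means", {
  # channels constant at (100, 200, 100): global mean 400/3, scaling
  # (4/3, 2/3, 4/3) -> all channels 133 after rounding
  wb <- white_balance(const_rgb(c(100, 200, 100)))
  expect_equal(unique(as.vector(unclass(wb))), 133)

  # image with equal channel means is a fixed point (up to rounding)
  set.seed(5)
  base <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
  img <- color_image(array(rep(base, 3), dim = c(6, 6, 3)))
  expect_equal(unclass(white_balance(img)), unclass(img),
               ignore_attr = TRUE)
})

test_that("white balance rejects an all-black channel", {
  img <- array(100, dim = c(4, 4, 3)); img[, , 1] <- 0
  expect_error(white_balance(color_image(img)), "degenerate")
})

test_that("grayscale conversion is the standard luminance combination", {
  expect_equal(to_grayscale(const_rgb(c(255, 255, 255)))[1, 1], 255)
  expect_equal(to_grayscale(const_rgb(c(255, 0, 0)))[1, 1], 76)
  for (g in c(0, 17, 128, 255))
    expect_equal(to_grayscale(const_rgb(c(g, g, g)))[1, 1], g)
})

test_that("gradient map is zero on constants and localizes a step edge", {
  expect_true(all(gradient_image(matrix(137, 5, 5)) == 0))

  step <- cbind(matrix(0, 5, 3), matrix(200, 5, 2))
  out <- gradient_image(step)
  expect_true(all(out[, c(1, 2, 5)] == 0))   # flat regions stay zero
  expect_true(all(out[, 3:4] > 0))           # response flanks the step
})

test_that("transposing the input transposes the gradient map", {
  g <- random_gray(7, seed = 21)
  expect_equal(gradient_image(t(g)), t(gradient_image(g)))
})

test_that("gradient map matches the brute-force Sobel oracle", {
  for (s in 1:5) {
    g <- random_gray(9, seed = s)
    expect_equal(gradient_image(g), oracle_rescale(oracle_sobel(g)))
  }
})

test_that("GLCM map of a constant image is degenerate as expected", {
  g <- matrix(99, 9, 9)
  # single cooccurring pair with i = j: contrast 0
  expect_true(all(glcm_image(g, space_params(glcm_statistic = "contrast")) == 0))
  # P has one cell equal to 1: energy 1 everywhere -> 255 after rescale
  expect_true(all(glcm_image(g, space_params(glcm_statistic = "energy")) == 255))
})

test_that("checkerboard GLCM contrast puts all mass on adjacent levels", {
  cb <- matrix(0, 7, 7)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 255
  raw <- oracle_glcm(cb, levels = 2, window = 7, offset = c(0, 1),
                     statistic = "contrast")
  expect_equal(raw[4, 4], 1)  # all mass on (0,1)/(1,0): contrast = 1
  # border replicate padding dilutes the off-center windows, so the center
  # attains the maximum and maps to 255
  out <- glcm_image(cb, space_params(glcm_levels = 2))
  expect_equal(out[4, 4], 255)
  expect_equal(out, oracle_rescale(raw))
})

test_that("GLCM map matches the brute-force pair-counting oracle", {
  for (s in 1:3) {
    g <- random_gray(9, seed = 100 + s)
    for (stat in c("contrast", "energy", "homogeneity")) {
      p <- space_params(glcm_window = 5L, glcm_statistic = stat)
      raw_pkg <- histopatch:::cpp_glcm_map(
        matrix(as.integer(floor(g * 8 / 256)), 9, 9), 8L, 5L, 0L, 1L,
        match(stat, c("contrast", "energy", "homogeneity")) - 1L)
      raw_orc <- oracle_glcm(g, 8, 5, c(0, 1), stat)
      expect_equal(raw_pkg, raw_orc, tolerance = 1e-6)
      expect_equal(glcm_image(g, p), oracle_rescale(raw_orc))
    }
  }
  # non-axial offset as well
  g <- random_gray(9, seed = 77)
  raw_pkg <- histopatch:::cpp_glcm_map(
    matrix(as.integer(floor(g * 4 / 256)), 9, 9), 4L, 5L, 1L, 1L, 0L)
  expect_equal(raw_pkg, oracle_glcm(g, 4, 5, c(1, 1), "contrast"),
               tolerance = 1e-6)
})

test_that("GLCM window larger than the image is rejected", {
  expect_error(glcm_image(matrix(1, 5, 5), space_params(glcm_window = 7L)),
               "window")
})

test_that("LBP codes follow the stated comparison and bit order", {
  # every neighbor >= center on a constant image: all-ones code
  expect_true(all(lbp_image(matrix(42, 5, 5)) == 255))
  # a strict maximum has no neighbor >= it
  z <- matrix(0, 5, 5); z[3, 3] <- 255
  expect_equal(lbp_image(z)[3, 3], 0)
  # hand-evaluated toy: neighbors clockwise from top-left of the center 5
  # are (1,2,3,6,9,8,7,4) -> bits 00011110 -> 30
  toy <- matrix(1:9, 3, 3, byrow = TRUE)
  expect_equal(lbp_image(toy)[2, 2], 30)
})

test_that("LBP map matches the brute-force oracle exactly", {
  for (s in 1:5) {
    g <- random_gray(9, seed = 200 + s)
    expect_identical(lbp_image(g), oracle_lbp(g))
  }
})

test_that("reconstruction stacks the component maps channel-wise", {
  set.seed(31)
  img <- color_image(array(sample(0:255, 12 * 12 * 3, TRUE),
                           dim = c(12, 12, 3)))
  p <- space_params()
  rec <- reconstruct(img, p)
  expect_equal(color_space(rec), "reconstructed")
  expect_equal(dim(rec), dim(img))
  gray <- to_grayscale(white_balance(img))
  expect_equal(rec[, , 1], gradient_image(gray), ignore_attr = TRUE)
  expect_equal(rec[, , 2], glcm_image(gray, p), ignore_attr = TRUE)
  expect_equal(rec[, , 3], lbp_image(gray), ignore_attr = TRUE)
})

test_that("reconstruction of a constant image hits the component extremes", {
  rec <- reconstruct(const_rgb(c(120, 120, 120), 8, 8))
  expect_true(all(rec[, , 1] == 0))    # no gradient
  expect_true(all(rec[, , 3] == 255))  # all-true LBP code
})

test_that("space operators preserve shape and range, deterministically", {
  for (s in 1:4) {
    set.seed(400 + s)
    h <- sample(7:15, 1); w <- sample(7:15, 1)
    img <- color_image(array(sample(0:255, h * w * 3, TRUE), dim = c(h, w, 3)))
    r1 <- reconstruct(img)
    r2 <- reconstruct(img)
    expect_identical(unclass(r1), unclass(r2))
    expect_equal(dim(r1), c(h, w, 3L))
    expect_true(min(r1) >= 0 && max(r1) <= 255)
  }
})

test_that("gradient channel peaks on the boundary ring of a nucleus", {
  # synthetic 64x64 patch: dark disk (nucleus) on a bright background
  h <- 64
  d <- sqrt(outer((1:h) - 32.5, rep(1, h))^2 +
            outer(rep(1, h), (1:h) - 32.5)^2)
  img <- array(210, dim = c(h, h, 3))
  for (k in 1:3) {
    plane <- img[, , k]
    plane[d <= 15] <- c(110, 70, 150)[k]
    img[, , k] <- plane
  }
  rec <- reconstruct(color_image(img))
  peak <- which(rec[, , 1] == max(rec[, , 1]), arr.ind = TRUE)
  ring_dist <- sqrt((peak[, 1] - 32.5)^2 + (peak[, 2] - 32.5)^2)
  expect_true(all(abs(ring_dist - 15) <= 2))
  # oracle agreement on the same patch
  gray <- to_grayscale(white_balance(color_image(img)))
  expect_equal(rec[, , 1], oracle_rescale(oracle_sobel(gray)),
               ignore_attr = TRUE)
})

test_that("reconstructed images round-trip through PNG losslessly", {
  set.seed(9)
  img <- color_image(array(sample(0:255, 192, TRUE), dim = c(8, 8, 3)))
  rec <- reconstruct(img)
  path <- tempfile(fileext = ".png")
  write_image(rec, path)
  back <- read_image(path)
  expect_equal(unclass(back), unclass(rec), ignore_attr = TRUE)
})
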