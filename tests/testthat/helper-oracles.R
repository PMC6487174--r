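# Independent brute-force oracles used to validate the package's
# vectorized / compiled implementations. All are explicit double loops and
# share no code with the implementation paths they check.

clamp_idx <- function(i, n) pmin(pmax(i, 1L), n)

oracle_rescale <- function(m) {
  mx <- max(m)
  if (mx > 0) m <- m / mx * 255
  round(m)
}

# 3x3 Sobel magnitude with replicate padding, explicit per-pixel loops
oracle_sobel <- function(gray) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)   # d/dcol
  ky <- t(kx)                                            # d/drow
  H <- nrow(gray); W <- ncol(gray)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      gx <- 0; gy <- 0
      for (dr in -1:1) {
        for (dc in -1:1) {
          v <- gray[clamp_idx(r + dr, H), clamp_idx(cc + dc, W)]
          gx <- gx + v * kx[dr + 2, dc + 2]
          gy <- gy + v * ky[dr + 2, dc + 2]
        }
      }
      out[r, cc] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# per-pixel sliding-window symmetric normalized GLCM statistic, raw scale
oracle_glcm <- function(gray, levels, window, offset, statistic) {
  q <- floor(gray * levels / 256)
  H <- nrow(gray); W <- ncol(gray)
  h <- window %/% 2
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      P <- matrix(0, levels, levels)
      for (wr in -h:h) {
        for (wc in -h:h) {
          pr <- wr + offset[1]; pc <- wc + offset[2]
          if (pr < -h || pr > h || pc < -h || pc > h) next
          a <- q[clamp_idx(r + wr, H), clamp_idx(cc + wc, W)]
          b <- q[clamp_idx(r + pr, H), clamp_idx(cc + pc, W)]
          P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
          P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
        }
      }
      P <- P / sum(P)
      s <- 0
      for (i in seq_len(levels)) {
        for (j in seq_len(levels)) {
          s <- s + switch(statistic,
                          contrast = P[i, j] * (i - j)^2,
                          energy = P[i, j]^2,
                          homogeneity = P[i, j] / (1 + abs(i - j)))
        }
      }
      out[r, cc] <- s
    }
  }
  out
}

# 8-neighbor radius-1 LBP, bits clockwise from top-left (MSB first)
oracle_lbp <- function(gray) {
  H <- nrow(gray); W <- ncol(gray)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0L, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      code <- 0L
      for (k in 1:8) {
        v <- gray[clamp_idx(r + offs[[k]][1], H),
                  clamp_idx(cc + offs[[k]][2], W)]
        bit <- as.integer(v >= gray[r, cc])
        code <- code + bit * 2L^(8L - k)
      }
      out[r, cc] <- code
    }
  }
  storage.mode(out) <- "integer"
  out
}

# scalar step-by-step LSTM recurrence from the gate equations; params is a
# list(W, U, b) with gate column blocks ordered input/forget/cell/output
oracle_lstm <- function(seq_mat, params) {
  Hn <- ncol(params$U) / 4
  sg <- function(x) 1 / (1 + exp(-x))
  h <- numeric(Hn); cc <- numeric(Hn)
  for (t in seq_len(nrow(seq_mat))) {
    x <- seq_mat[t, ]
    z <- numeric(4 * Hn)
    for (j in seq_len(4 * Hn)) {
      acc <- params$b[j]
      for (d in seq_along(x)) acc <- acc + x[d] * params$W[d, j]
      for (m in seq_len(Hn)) acc <- acc + h[m] * params$U[m, j]
      z[j] <- acc
    }
    i <- sg(z[1:Hn])
    f <- sg(z[(Hn + 1):(2 * Hn)])
    g <- tanh(z[(2 * Hn + 1):(3 * Hn)])
    o <- sg(z[(3 * Hn + 1):(4 * Hn)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  h
}

# confusion-matrix-derived metrics
oracle_confusion_metrics <- function(pred, truth, classes) {
  cm <- matrix(0, length(classes), length(classes),
               dimnames = list(as.character(classes), as.character(classes)))
  for (i in seq_along(pred))
    cm[as.character(truth[i]), as.character(pred[i])] <-
      cm[as.character(truth[i]), as.character(pred[i])] + 1
  acc <- sum(diag(cm)) / sum(cm)
  sen <- diag(cm) / rowSums(cm)
  spe <- vapply(seq_along(classes), function(k) {
    tn <- sum(cm[-k, -k]); fp <- sum(cm[-k, k])
    tn / (tn + fp)
  }, numeric(1))
  list(acc = acc, sen = sen, spe = setNames(spe, as.character(classes)))
}

# nearest-class-mean classifier (oracle for the feature fixture)
oracle_nearest_centroid <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  centroids <- t(vapply(classes, function(cl)
    colMeans(train_x[train_y == cl, , drop = FALSE]),
    numeric(ncol(train_x))))
  pred <- apply(test_x, 1, function(v) {
    d <- rowSums(sweep(centroids, 2, v)^2)
    classes[which.min(d)]
  })
  pred
}

random_gray <- function(n = 9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

tiny_selector_config <- function(...) {
  selector_config(feature_dim = 12L, seq_len = 4L, step_dim = 3L,
                  hidden = 2L, iterations = 1L, batch_size = 4L, ...)
}
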