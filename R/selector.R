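#' Selector configuration
#'
#' Configuration of the dual-stream LSTM feature selector. Each stream's
#' 2048-dimensional backbone feature vector is reshaped row-major into a
#' `seq_len x step_dim` matrix and consumed one row per timestep by a
#' stream-specific LSTM whose final hidden state (32 dims) is the selected
#' feature vector; the two selections are cascaded into a 64-dim vector for
#' the fused softmax head.
#'
#' @param feature_dim length of each stream's input feature vector (2048).
#' @param seq_len number of LSTM timesteps `T` (default 64).
#' @param step_dim per-timestep input dimension `D`; `T * D` must equal
#'   `feature_dim`.
#' @param hidden LSTM state size = selected feature size (default 32).
#' @param n_classes number of classes (default 3: CLL / FL / MCL).
#' @param learning_rate SGD learning rate.
#' @param iterations training iterations, counted as full passes (epochs)
#'   over the training set; default 250.
#' @param batch_size minibatch size.
#' @param seed integer seed controlling initialization and batch order.
#' @return An object of class `selector_config`.
#' @export
selector_config <- function(feature_dim = 2048L, seq_len = 64L,
                            step_dim = 32L, hidden = 32L, n_classes = 3L,
                            learning_rate = 0.3, iterations = 250L,
                            batch_size = 16L, seed = 1L) {
  cfg <- list(feature_dim = as.integer(feature_dim),
              seq_len = as.integer(seq_len),
              step_dim = as.integer(step_dim),
              hidden = as.integer(hidden),
              n_classes = as.integer(n_classes),
              learning_rate = learning_rate,
              iterations = as.integer(iterations),
              batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  if (cfg$seq_len * cfg$step_dim != cfg$feature_dim)
    stop("seq_len * step_dim (", cfg$seq_len * cfg$step_dim,
         ") must equal feature_dim (", cfg$feature_dim, ")")
  if (cfg$seq_len < 1L || cfg$step_dim < 1L || cfg$hidden < 1L)
    stop("seq_len, step_dim and hidden must be positive")
  if (cfg$n_classes < 2L) stop("need at least 2 classes")
  structure(cfg, class = "selector_config")
}

#' Reshape a feature vector into an LSTM input sequence
#'
#' Row-major reshape: row `t` of the result holds entries
#' `v[(t-1) * D + 1] ... v[t * D]` and is consumed at timestep `t`.
#'
#' @param v numeric vector of length `seq_len * step_dim`.
#' @param cfg a [selector_config()].
#' @return A `seq_len x step_dim` matrix.
#' @export
to_sequence <- function(v, cfg = selector_config()) {
  if (length(v) != cfg$seq_len * cfg$step_dim)
    stop("feature length ", length(v), " does not match seq_len * step_dim = ",
         cfg$seq_len * cfg$step_dim)
  matrix(v, cfg$seq_len, cfg$step_dim, byrow = TRUE)
}

#' Numerically stable softmax
#'
#' @param z numeric vector of logits, or a matrix with one logit vector per
#'   row.
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    return(e / rowSums(e))
  }
  e <- exp(z - max(z))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Combined two-stream cross-entropy loss
#'
#' The training loss of the dual-stream selector: the sum of the
#' cross-entropies of the RGB-stream (`a`) and reconstruction-stream (`b`)
#' softmax outputs against the same one-hot label, `-sum(y * log a) -
#' sum(y * log b)`. Probabilities are floored at `1e-12` inside the logs.
#'
#' @param a,b probability vectors on the class simplex.
#' @param y one-hot label vector of the same length.
#' @return A nonnegative scalar; zero iff both streams put probability 1 on
#'   the true class.
#' @examples
#' combined_loss(rep(1 / 3, 3), rep(1 / 3, 3), c(1, 0, 0))  # 2 * log(3)
#' @export
combined_loss <- function(a, b, y) {
  for (v in list(a, b)) {
    if (any(v < -1e-9) || abs(sum(v) - 1) > 1e-6)
      stop("probabilities must lie on the simplex")
  }
  if (!all(y %in% c(0, 1)) || sum(y) != 1)
    stop("y must be a one-hot vector")
  -sum(y * log(pmax(a, 1e-12))) - sum(y * log(pmax(b, 1e-12)))
}

# ---- LSTM internals -------------------------------------------------------

# gate columns in W/U/b: input, forget, cell candidate, output
init_lstm_params <- function(input_dim, hidden) {
  r <- 1 / sqrt(hidden)
  W <- matrix(runif(input_dim * 4 * hidden, -r, r), input_dim, 4 * hidden)
  U <- matrix(runif(hidden * 4 * hidden, -r, r), hidden, 4 * hidden)
  b <- numeric(4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1  # forget-gate bias, standard init
  list(W = W, U = U, b = b)
}

init_head_params <- function(input_dim, n_classes) {
  r <- 1 / sqrt(input_dim)
  list(W = matrix(runif(input_dim * n_classes, -r, r), input_dim, n_classes),
       b = numeric(n_classes))
}

# batched LSTM forward; X is N x (T*D), row-major sequences.
# Returns the final hidden state and, optionally, per-timestep caches
# needed for backpropagation through time.
lstm_forward <- function(X, p, Tn, D, keep_cache = FALSE) {
  N <- nrow(X)
  Hn <- ncol(p$U)/4L
  h <- matrix(0, N, Hn)
  cc <- matrix(0, N, Hn)
  cache <- if (keep_cache) vector("list", Tn) else NULL
  idx_i <- 1:Hn; idx_f <- Hn + idx_i; idx_g <- 2 * Hn + idx_i
  idx_o <- 3 * Hn + idx_i
  for (t in seq_len(Tn)) {
    xt <- X[, ((t - 1) * D + 1):(t * D), drop = FALSE]
    Z <- xt %*% p$W + h %*% p$U
    Z <- sweep(Z, 2, p$b, "+")
    i <- sigmoid(Z[, idx_i, drop = FALSE])
    f <- sigmoid(Z[, idx_f, drop = FALSE])
    g <- tanh(Z[, idx_g, drop = FALSE])
    o <- sigmoid(Z[, idx_o, drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache)
      cache[[t]] <- list(i = i, f = f, g = g, o = o,
                         c_prev = cc, h_prev = h, tc = tc)
    cc <- c_new
    h <- h_new
  }
  list(h = h, cache = cache)
}

# backpropagation through time; dh_T is the gradient at the final hidden
# state. Returns gradients for W, U, b.
lstm_backward <- function(X, p, fw, dh_T, Tn, D) {
  Hn <- ncol(dh_T)
  dW <- matrix(0, nrow(p$W), ncol(p$W))
  dU <- matrix(0, Hn, 4 * Hn)
  db <- numeric(4 * Hn)
  dh <- dh_T
  dc <- matrix(0, nrow(dh_T), Hn)
  for (t in rev(seq_len(Tn))) {
    cv <- fw$cache[[t]]
    do_ <- dh * cv$tc
    dc <- dc + dh * cv$o * (1 - cv$tc^2)
    di <- dc * cv$g
    dg <- dc * cv$i
    df <- dc * cv$c_prev
    dc_prev <- dc * cv$f
    dZ <- cbind(di * cv$i * (1 - cv$i),
                df * cv$f * (1 - cv$f),
                dg * (1 - cv$g^2),
                do_ * cv$o * (1 - cv$o))
    xt <- X[, ((t - 1) * D + 1):(t * D), drop = FALSE]
    dW <- dW + crossprod(xt, dZ)
    dU <- dU + crossprod(cv$h_prev, dZ)
    db <- db + colSums(dZ)
    dh <- dZ %*% t(p$U)
    dc <- dc_prev
  }
  list(W = dW, U = dU, b = db)
}

# mean combined loss (two stream cross-entropies + fused-head
# cross-entropy) and its gradients for one batch. Y is N x K one-hot.
selector_loss_grad <- function(params, Xr, Xc, Y, cfg, grads = TRUE) {
  N <- nrow(Xr)
  Tn <- cfg$seq_len; D <- cfg$step_dim
  fa <- lstm_forward(Xr, params$lstm_rgb, Tn, D, keep_cache = grads)
  fb <- lstm_forward(Xc, params$lstm_rec, Tn, D, keep_cache = grads)
  hA <- fa$h; hB <- fb$h
  Hf <- cbind(hA, hB)
  la <- sweep(hA %*% params$head_rgb$W, 2, params$head_rgb$b, "+")
  lb <- sweep(hB %*% params$head_rec$W, 2, params$head_rec$b, "+")
  lf <- sweep(Hf %*% params$head_fused$W, 2, params$head_fused$b, "+")
  pa <- softmax(la); pb <- softmax(lb); pf <- softmax(lf)
  ce <- function(p) -sum(Y * log(pmax(p, 1e-12))) / N
  loss <- ce(pa) + ce(pb) + ce(pf)
  if (!grads)
    return(list(loss = loss, prob_rgb = pa, prob_rec = pb, prob_fused = pf,
                h_rgb = hA, h_rec = hB))
  dla <- (pa - Y) / N
  dlb <- (pb - Y) / N
  dlf <- (pf - Y) / N
  Hn <- cfg$hidden
  dHf <- dlf %*% t(params$head_fused$W)
  dhA <- dla %*% t(params$head_rgb$W) + dHf[, 1:Hn, drop = FALSE]
  dhB <- dlb %*% t(params$head_rec$W) + dHf[, (Hn + 1):(2 * Hn), drop = FALSE]
  g <- list(
    head_rgb = list(W = crossprod(hA, dla), b = colSums(dla)),
    head_rec = list(W = crossprod(hB, dlb), b = colSums(dlb)),
    head_fused = list(W = crossprod(Hf, dlf), b = colSums(dlf)),
    lstm_rgb = lstm_backward(Xr, params$lstm_rgb, fa, dhA, Tn, D),
    lstm_rec = lstm_backward(Xc, params$lstm_rec, fb, dhB, Tn, D)
  )
  list(loss = loss, grads = g)
}

sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    for (w in names(grads[[nm]])) {
      params[[nm]][[w]] <- params[[nm]][[w]] - lr * grads[[nm]][[w]]
    }
  }
  params
}

# ---- fitting --------------------------------------------------------------

#' Train the dual-stream LSTM feature selector
#'
#' Fits the selector: one LSTM per feature stream (RGB and reconstructed),
#' a linear + softmax head on each stream's 32-dim final state, and a fused
#' head on the 64-dim cascade. Training minimizes, by minibatch stochastic
#' gradient descent, the combined loss — the sum of the two per-stream
#' cross-entropies plus the fused-head cross-entropy. The seed fixes
#' initialization and batch order, so identical calls yield identical fits.
#'
#' @param rgb,rec numeric `N x feature_dim` matrices of backbone features
#'   for the RGB and reconstructed streams (paired rows).
#' @param labels integer class ids, one per row; every class in `classes`
#'   must be present.
#' @param config a [selector_config()].
#' @param classes the full set of class ids (default `0:(n_classes - 1)`).
#' @return An object of class `lstm_selector` with components `params`
#'   (stream LSTMs and softmax heads), `config`, `classes`, `loss_trace`
#'   (mean combined loss per epoch) and `n_train`.
#' @seealso [predict.lstm_selector()], [lstm_select()], [classify()]
#' @export
train_selector <- function(rgb, rec, labels, config = selector_config(),
                           classes = seq_len(config$n_classes) - 1L) {
  rgb <- as.matrix(rgb); rec <- as.matrix(rec)
  if (!all(dim(rgb) == dim(rec)))
    stop("rgb and rec feature matrices must have identical shape")
  if (ncol(rgb) != config$feature_dim)
    stop("feature dimension ", ncol(rgb), " does not match config (",
         config$feature_dim, ")")
  N <- nrow(rgb)
  if (length(labels) != N) stop("one label per feature row required")
  missing_cl <- setdiff(classes, labels)
  if (length(missing_cl) > 0)
    stop("class absent from training set: ",
         paste(missing_cl, collapse = ", "))
  if (length(classes) != config$n_classes)
    stop("length(classes) must equal n_classes")
  Y <- matrix(0, N, config$n_classes)
  Y[cbind(seq_len(N), match(labels, classes))] <- 1

  set.seed(config$seed)
  params <- list(
    lstm_rgb = init_lstm_params(config$step_dim, config$hidden),
    lstm_rec = init_lstm_params(config$step_dim, config$hidden),
    head_rgb = init_head_params(config$hidden, config$n_classes),
    head_rec = init_head_params(config$hidden, config$n_classes),
    head_fused = init_head_params(2L * config$hidden, config$n_classes)
  )
  loss_trace <- numeric(config$iterations)
  for (ep in seq_len(config$iterations)) {
    perm <- sample.int(N)
    starts <- seq(1L, N, by = config$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, N)]
      lg <- selector_loss_grad(params,
                               rgb[idx, , drop = FALSE],
                               rec[idx, , drop = FALSE],
                               Y[idx, , drop = FALSE], config)
      params <- sgd_step(params, lg$grads, config$learning_rate)
      ep_loss <- ep_loss + lg$loss * length(idx)
    }
    loss_trace[ep] <- ep_loss / N
  }
  structure(list(params = params, config = config,
                 classes = as.integer(classes),
                 loss_trace = loss_trace, n_train = N,
                 call = match.call()),
            class = "lstm_selector")
}

#' Run one stream's LSTM selection
#'
#' Consumes a feature vector (or its `T x D` sequence form) through the
#' chosen stream's LSTM and returns the final hidden state — the selected
#' 32-dimensional feature vector. Deterministic given the fitted weights.
#'
#' @param model a fitted [train_selector()] object.
#' @param v a length-`feature_dim` vector or a `seq_len x step_dim` matrix.
#' @param stream `"rgb"` or `"reconstructed"`.
#' @return A numeric vector of length `hidden` (32 by default).
#' @export
lstm_select <- function(model, v, stream = c("rgb", "reconstructed")) {
  stream <- match.arg(stream)
  if (!inherits(model, "lstm_selector")) stop("model is not a fitted selector")
  cfg <- model$config
  if (is.matrix(v)) {
    if (!all(dim(v) == c(cfg$seq_len, cfg$step_dim)))
      stop("sequence must be seq_len x step_dim")
    v <- as.vector(t(v))
  }
  if (length(v) != cfg$feature_dim) stop("feature length mismatch")
  p <- if (stream == "rgb") model$params$lstm_rgb else model$params$lstm_rec
  fw <- lstm_forward(matrix(v, 1), p, cfg$seq_len, cfg$step_dim)
  as.vector(fw$h)
}

#' Selected features for a batch
#'
#' @param model a fitted [train_selector()] object.
#' @param rgb,rec `N x feature_dim` feature matrices.
#' @return A list with `rgb32`, `rec32` (`N x hidden`) and `fused64`
#'   (`N x 2*hidden`, the exact column concatenation of the two).
#' @export
selected_features <- function(model, rgb, rec) {
  cfg <- model$config
  rgb <- as.matrix(rgb); rec <- as.matrix(rec)
  a <- lstm_forward(rgb, model$params$lstm_rgb, cfg$seq_len, cfg$step_dim)$h
  b <- lstm_forward(rec, model$params$lstm_rec, cfg$seq_len, cfg$step_dim)$h
  list(rgb32 = a, rec32 = b, fused64 = cbind(a, b))
}

#' Classify selected features
#'
#' Applies the three linear + softmax heads to already-selected features:
#' the RGB head on `rgb32`, the reconstruction head on `rec32` and the
#' fused head on their 64-dim cascade.
#'
#' @param model a fitted [train_selector()] object.
#' @param features a [selected_features()] list (fields `rgb32`, `rec32`).
#' @return A list of probability matrices `a`, `b`, `fused` (each row a
#'   simplex vector).
#' @export
classify <- function(model, features) {
  a32 <- as.matrix(features$rgb32); b32 <- as.matrix(features$rec32)
  if (ncol(a32) == 1L && model$config$hidden > 1L) { a32 <- t(a32); b32 <- t(b32) }
  hp <- model$params
  a <- softmax(sweep(a32 %*% hp$head_rgb$W, 2, hp$head_rgb$b, "+"))
  b <- softmax(sweep(b32 %*% hp$head_rec$W, 2, hp$head_rec$b, "+"))
  fused <- softmax(sweep(cbind(a32, b32) %*% hp$head_fused$W, 2,
                         hp$head_fused$b, "+"))
  list(a = a, b = b, fused = fused)
}

#' Per-patch class probabilities and hard labels
#'
#' Runs both streams through the fitted selector and returns the three
#' probability tables and the hard labels (argmax of the fused
#' probabilities; exact ties go to the smallest class id).
#'
#' @param model a fitted [train_selector()] object.
#' @param rgb,rec `N x feature_dim` feature matrices (paired rows).
#' @return A list with `prob_rgb`, `prob_rec`, `prob_fused` (`N x K`
#'   matrices, columns named by class id) and `labels` (integer vector).
#' @export
predict_patches <- function(model, rgb, rec) {
  if (!inherits(model, "lstm_selector")) stop("model is not a fitted selector")
  cfg <- model$config
  rgb <- as.matrix(rgb); rec <- as.matrix(rec)
  if (ncol(rgb) != cfg$feature_dim || ncol(rec) != cfg$feature_dim)
    stop("feature dimension mismatch: expected ", cfg$feature_dim)
  sf <- selected_features(model, rgb, rec)
  pr <- classify(model, sf)
  for (nm in names(pr)) colnames(pr[[nm]]) <- as.character(model$classes)
  labels <- model$classes[apply(pr$fused, 1, which.max)]
  list(prob_rgb = pr$a, prob_rec = pr$b, prob_fused = pr$fused,
       labels = labels)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.lstm_selector <- function(x, ...) {
  cfg <- x$config
  cat("Dual-stream LSTM feature selector\n")
  cat(sprintf("  streams: 2 x LSTM(%d steps x %d dims -> %d), fused head on %d dims\n",
              cfg$seq_len, cfg$step_dim, cfg$hidden, 2 * cfg$hidden))
  cat(sprintf("  classes: %s; trained on %d samples, %d epochs (final loss %.4f)\n",
              paste(x$classes, collapse = "/"), x$n_train,
              cfg$iterations, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
summary.lstm_selector <- function(object, ...) {
  out <- list(config = object$config, classes = object$classes,
              n_train = object$n_train,
              n_parameters = sum(vapply(unlist(object$params,
                                               recursive = FALSE),
                                        length, integer(1))),
              initial_loss = object$loss_trace[1],
              final_loss = object$loss_trace[length(object$loss_trace)])
  class(out) <- "summary.lstm_selector"
  out
}

#' @export
print.summary.lstm_selector <- function(x, ...) {
  cat("Dual-stream LSTM feature selector\n")
  cat(sprintf("  %d trainable parameters, %d training samples\n",
              x$n_parameters, x$n_train))
  cat(sprintf("  combined loss: %.4f (epoch 1) -> %.4f (epoch %d)\n",
              x$initial_loss, x$final_loss, x$config$iterations))
  invisible(x)
}

#' @export
coef.lstm_selector <- function(object, ...) object$params

#' @param x a fitted `lstm_selector`.
#' @param ... passed to [graphics::plot()].
#' @describeIn train_selector plot the per-epoch training loss trace.
#' @export
plot.lstm_selector <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "mean combined loss", ...)
  invisible(x)
}

#' Predict method for the LSTM selector
#'
#' @param object a fitted [train_selector()] model.
#' @param rgb,rec `N x feature_dim` feature matrices.
#' @param type `"class"` for hard labels, `"prob"` for the fused
#'   probability matrix, `"all"` for the full [predict_patches()] list.
#' @param ... unused.
#' @return Labels, a probability matrix, or the full prediction list.
#' @export
predict.lstm_selector <- function(object, rgb, rec,
                                  type = c("class", "prob", "all"), ...) {
  type <- match.arg(type)
  pr <- predict_patches(object, rgb, rec)
  switch(type, class = pr$labels, prob = pr$prob_fused, all = pr)
}
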