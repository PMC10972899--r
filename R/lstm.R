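#' @name lstm
#' @title From-scratch LSTM primitives
#' @description
#' The bidirectional LSTM classifier is implemented directly in R. An LSTM
#' unit at time t combines the input `x_t`, previous hidden state `h_(t-1)`
#' and previous cell state `c_(t-1)` through three logistic gates (forget,
#' update, output) and a tanh candidate cell:
#' \deqn{f = \sigma(W_{fh} h_{t-1} + W_{fx} x_t + b_f)}
#' \deqn{u = \sigma(W_{uh} h_{t-1} + W_{ux} x_t + b_u)}
#' \deqn{o = \sigma(W_{oh} h_{t-1} + W_{ox} x_t + b_o)}
#' \deqn{\bar c = \tanh(W_{ch} h_{t-1} + W_{cx} x_t + b_c)}
#' \deqn{c_t = f \cdot c_{t-1} + u \cdot \bar c, \quad h_t = o \cdot \tanh(c_t)}
#' Training is full backpropagation through time with the Adam optimizer.
NULL

sigm <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM unit parameters
#'
#' Weights are drawn uniformly in `(-s, s)` with `s = 1/sqrt(hidden)`
#' (a standard small-uniform recurrent initialization); biases start at zero.
#' Uses the current RNG stream.
#'
#' @param input_dim Input dimension per time step.
#' @param hidden Hidden units.
#' @return A list of class `lstm_params` with weight matrices `W_fx`,
#'   `W_fh`, ..., `W_cx`, `W_ch` (hidden x input / hidden x hidden) and
#'   biases `b_f`, `b_u`, `b_o`, `b_c`.
#' @export
lstm_params <- function(input_dim, hidden) {
  s <- 1 / sqrt(hidden)
  rmat <- function(r, c) matrix(stats::runif(r * c, -s, s), r, c)
  p <- list()
  for (g in c("f", "u", "o", "c")) {
    p[[paste0("W_", g, "x")]] <- rmat(hidden, input_dim)
    p[[paste0("W_", g, "h")]] <- rmat(hidden, hidden)
    p[[paste0("b_", g)]] <- numeric(hidden)
  }
  structure(p, class = "lstm_params")
}

#' One LSTM unit step
#'
#' Applies the gate equations (see [lstm]) to a single time step. All gate
#' values lie in (0, 1) and `|h| < 1` elementwise.
#'
#' @param params An `lstm_params` list (see [lstm_params()]).
#' @param x Input vector (length `input_dim`).
#' @param h_prev Previous hidden state vector (length `hidden`).
#' @param c_prev Previous cell state vector (length `hidden`).
#' @return A list with elements `h`, `c` and the gate activations `f`, `u`,
#'   `o`, `cbar`.
#' @examples
#' p <- lstm_params(1, 1)
#' for (nm in names(p)) p[[nm]][] <- 0
#' p$W_cx[] <- 1
#' lstm_unit_step(p, 1, 0, 0) # h = 0.5 * tanh(0.5 * tanh(1))
#' @export
lstm_unit_step <- function(params, x, h_prev, c_prev) {
  x <- as.numeric(x)
  h_prev <- as.numeric(h_prev)
  c_prev <- as.numeric(c_prev)
  if (length(x) != ncol(params$W_fx) || length(h_prev) != ncol(params$W_fh) ||
    length(c_prev) != length(h_prev)) {
    stop("shape mismatch between parameters and states", call. = FALSE)
  }
  if (any(!is.finite(c(x, h_prev, c_prev)))) stop("non-finite inputs", call. = FALSE)
  f <- sigm(drop(params$W_fh %*% h_prev + params$W_fx %*% x) + params$b_f)
  u <- sigm(drop(params$W_uh %*% h_prev + params$W_ux %*% x) + params$b_u)
  o <- sigm(drop(params$W_oh %*% h_prev + params$W_ox %*% x) + params$b_o)
  cbar <- tanh(drop(params$W_ch %*% h_prev + params$W_cx %*% x) + params$b_c)
  c_new <- f * c_prev + u * cbar
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, f = f, u = u, o = o, cbar = cbar)
}

# Batched forward pass over a sequence. X: B x T x d array. Returns final
# hidden state and (optionally) the cache needed for BPTT.
lstm_forward_seq <- function(p, X, keep_cache = FALSE) {
  B <- dim(X)[1]
  Tn <- dim(X)[2]
  h <- length(p$b_f)
  tW <- lapply(p[grep("^W_", names(p))], t)
  H <- matrix(0, B, h)
  C <- matrix(0, B, h)
  cache <- if (keep_cache) vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- matrix(X[, t, ], nrow = B)
    f <- sigm(H %*% tW$W_fh + x %*% tW$W_fx + rep(p$b_f, each = B))
    u <- sigm(H %*% tW$W_uh + x %*% tW$W_ux + rep(p$b_u, each = B))
    o <- sigm(H %*% tW$W_oh + x %*% tW$W_ox + rep(p$b_o, each = B))
    cb <- tanh(H %*% tW$W_ch + x %*% tW$W_cx + rep(p$b_c, each = B))
    C_new <- f * C + u * cb
    H_new <- o * tanh(C_new)
    if (keep_cache) {
      cache[[t]] <- list(f = f, u = u, o = o, cb = cb, c = C_new, h = H_new,
                         h_prev = H, c_prev = C)
    }
    H <- H_new
    C <- C_new
  }
  list(h = H, cache = cache)
}

# BPTT for a sequence whose loss depends only on the final hidden state.
# dH: B x h gradient of the loss w.r.t. the final hidden state.
lstm_backward_seq <- function(p, X, cache, dH) {
  B <- dim(X)[1]
  Tn <- dim(X)[2]
  g <- lapply(p, function(x) x * 0)
  dC <- dH * 0
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    x <- matrix(X[, t, ], nrow = B)
    tc <- tanh(cc$c)
    do <- dH * tc
    dC <- dC + dH * cc$o * (1 - tc^2)
    df <- dC * cc$c_prev
    du <- dC * cc$cb
    dcb <- dC * cc$u
    pre_f <- df * cc$f * (1 - cc$f)
    pre_u <- du * cc$u * (1 - cc$u)
    pre_o <- do * cc$o * (1 - cc$o)
    pre_c <- dcb * (1 - cc$cb^2)
    g$W_fx <- g$W_fx + crossprod(pre_f, x)
    g$W_ux <- g$W_ux + crossprod(pre_u, x)
    g$W_ox <- g$W_ox + crossprod(pre_o, x)
    g$W_cx <- g$W_cx + crossprod(pre_c, x)
    g$W_fh <- g$W_fh + crossprod(pre_f, cc$h_prev)
    g$W_uh <- g$W_uh + crossprod(pre_u, cc$h_prev)
    g$W_oh <- g$W_oh + crossprod(pre_o, cc$h_prev)
    g$W_ch <- g$W_ch + crossprod(pre_c, cc$h_prev)
    g$b_f <- g$b_f + colSums(pre_f)
    g$b_u <- g$b_u + colSums(pre_u)
    g$b_o <- g$b_o + colSums(pre_o)
    g$b_c <- g$b_c + colSums(pre_c)
    dH <- pre_f %*% p$W_fh + pre_u %*% p$W_uh +
      pre_o %*% p$W_oh + pre_c %*% p$W_ch
    dC <- dC * cc$f
  }
  g
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

dense_init <- function(sizes, seed_stream = NULL) {
  purrr::map(seq_len(length(sizes) - 1), function(i) {
    fan_in <- sizes[i]
    s <- sqrt(2 / fan_in)
    list(
      W = matrix(stats::rnorm(sizes[i + 1] * fan_in, 0, s), sizes[i + 1], fan_in),
      b = numeric(sizes[i + 1])
    )
  })
}

# Forward through the dense head; ReLU between layers, softmax at the end.
dense_forward <- function(layers, A0, keep_cache = FALSE) {
  A <- A0
  acts <- list(A0)
  n <- length(layers)
  for (i in seq_len(n)) {
    Z <- A %*% t(layers[[i]]$W) + rep(layers[[i]]$b, each = nrow(A))
    A <- if (i < n) relu(Z) else Z
    if (keep_cache) acts[[i + 1]] <- A
  }
  list(probs = softmax_rows(A), acts = acts)
}

dense_backward <- function(layers, acts, dZ_last) {
  n <- length(layers)
  g <- vector("list", n)
  dZ <- dZ_last
  for (i in rev(seq_len(n))) {
    g[[i]] <- list(
      W = crossprod(dZ, acts[[i]]),
      b = colSums(dZ)
    )
    if (i > 1) {
      dA <- dZ %*% layers[[i]]$W
      dZ <- dA * (acts[[i]] > 0) # ReLU mask
    }
  }
  list(grads = g, dA0 = dZ %*% layers[[1]]$W)
}

# Recursively apply f to matching numeric leaves of two parameter trees.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- purrr::map2(a, b, tree_map2, f = f)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) {
    out <- purrr::map(a, tree_zero)
    attributes(out) <- attributes(a)
    out
  } else {
    a * 0
  }
}

adam_new <- function(theta) list(m = tree_zero(theta), v = tree_zero(theta), t = 0)

adam_step <- function(theta, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- tree_map2(state$m, state$m, function(m, ...) m / bc1)
  vhat <- tree_map2(state$v, state$v, function(v, ...) v / bc2)
  upd <- tree_map2(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(theta = tree_map2(theta, upd, `-`), state = state)
}

# Full BiLSTM forward on a batch array X (B x T x d): forward pass on X,
# backward pass on the time-reversed X, concatenated final hidden states
# through the dense head.
bilstm_batch_forward <- function(theta, X, keep_cache = FALSE) {
  Xr <- X[, rev(seq_len(dim(X)[2])), , drop = FALSE]
  fw <- lstm_forward_seq(theta$fwd, X, keep_cache)
  bw <- lstm_forward_seq(theta$bwd, Xr, keep_cache)
  A0 <- cbind(fw$h, bw$h)
  dn <- dense_forward(theta$dense, A0, keep_cache)
  list(probs = dn$probs, fw = fw, bw = bw, Xr = Xr, dense = dn, A0 = A0)
}

#' Train a bidirectional LSTM sequence classifier
#'
#' A single BiLSTM layer (forward pass plus a pass over the time-reversed
#' sequence, final hidden states concatenated) followed by four dense layers
#' with rectifier nonlinearities and a softmax output; trained by full
#' backpropagation through time with Adam on the mean cross-entropy.
#' Defaults follow the reference recipe: 128 hidden units, learning rate
#' 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8, 60 epochs, batch size
#' one-tenth of the training samples.
#'
#' @param X Numeric array `n x T x d` of input sequences.
#' @param y Factor (or coercible) of class labels, length `n`.
#' @param hidden LSTM hidden units per direction.
#' @param dense_sizes Sizes of the first three dense layers (the fourth is
#'   the class layer).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size; default `ceiling(n / 10)`.
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @return A list of class `bilstm_model` with the parameters, class
#'   `levels`, and a `history` record (epochs run, final training accuracy).
#' @export
train_bilstm <- function(X, y, hidden = 128, dense_sizes = c(256, 128, 64),
                         lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         epochs = 60, batch_size = NULL, seed = 1) {
  stopifnot(length(dim(X)) == 3)
  y <- factor(y)
  n <- dim(X)[1]
  if (n != length(y)) stop("X and y lengths differ", call. = FALSE)
  if (nlevels(y) < 2) stop("training set must contain at least 2 classes", call. = FALSE)
  if (is.null(batch_size)) batch_size <- ceiling(n / 10)
  d <- dim(X)[3]
  K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  with_local_seed(seed, {
    theta <- list(
      fwd = lstm_params(d, hidden),
      bwd = lstm_params(d, hidden),
      dense = dense_init(c(2 * hidden, dense_sizes, K))
    )
    opt <- adam_new(theta)
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / batch_size))
      for (bidx in batches) {
        Xb <- X[bidx, , , drop = FALSE]
        Yb <- Y[bidx, , drop = FALSE]
        fwd <- bilstm_batch_forward(theta, Xb, keep_cache = TRUE)
        dZ <- (fwd$probs - Yb) / length(bidx)
        dn <- dense_backward(theta$dense, fwd$dense$acts, dZ)
        h <- ncol(fwd$fw$h)
        g <- list(
          fwd = lstm_backward_seq(theta$fwd, Xb, fwd$fw$cache,
                                  dn$dA0[, seq_len(h), drop = FALSE]),
          bwd = lstm_backward_seq(theta$bwd, fwd$Xr, fwd$bw$cache,
                                  dn$dA0[, h + seq_len(h), drop = FALSE]),
          dense = dn$grads
        )
        st <- adam_step(theta, g, opt, lr, beta1, beta2, eps)
        theta <- st$theta
        opt <- st$state
      }
    }
    final <- bilstm_batch_forward(theta, X)
    acc <- mean(max.col(final$probs) == as.integer(y)) * 100
    structure(
      list(
        theta = theta, levels = levels(y), hidden = hidden,
        history = list(epochs = epochs, batch_size = batch_size,
                       final_train_accuracy = acc)
      ),
      class = "bilstm_model"
    )
  })
}

#' Class scores of a trained BiLSTM for one sample
#'
#' Runs the forward and time-reversed passes, concatenates the final hidden
#' states and applies the dense head; scores are a softmax distribution over
#' the trained classes (nonnegative, summing to one).
#'
#' @param model A `bilstm_model` from [train_bilstm()].
#' @param sample A `T x d` numeric matrix (one sequence).
#' @return Named numeric vector of class scores.
#' @export
bilstm_forward <- function(model, sample) {
  if (!inherits(model, "bilstm_model")) stop("model is not a trained BiLSTM", call. = FALSE)
  sample <- as.matrix(sample)
  if (ncol(sample) != ncol(model$theta$fwd$W_fx)) {
    stop("input has wrong channel count", call. = FALSE)
  }
  X <- array(sample, dim = c(1, nrow(sample), ncol(sample)))
  probs <- bilstm_batch_forward(model$theta, X)$probs
  stats::setNames(drop(probs), model$levels)
}

#' @export
print.bilstm_model <- function(x, ...) {
  cat(sprintf(
    "<bilstm_model: %d hidden units/direction, %d classes, %d epochs, train acc %.1f%%>\n",
    x$hidden, length(x$levels), x$history$epochs, x$history$final_train_accuracy
  ))
  invisible(x)
}
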