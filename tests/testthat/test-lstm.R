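# Independent scalar oracle: evaluates the gate equations literally with
# base-R arithmetic, no matrix code shared with the implementation.
oracle_step <- function(p, x, h, c) {
  lin <- function(Wh, Wx, b, i) {
    sum(Wh[i, ] * h) + sum(Wx[i, ] * x) + b[i]
  }
  nh <- length(p$b_f)
  f <- u <- o <- cb <- numeric(nh)
  for (i in seq_len(nh)) {
    f[i] <- stats::plogis(lin(p$W_fh, p$W_fx, p$b_f, i))
    u[i] <- stats::plogis(lin(p$W_uh, p$W_ux, p$b_u, i))
    o[i] <- stats::plogis(lin(p$W_oh, p$W_ox, p$b_o, i))
    cb[i] <- tanh(lin(p$W_ch, p$W_cx, p$b_c, i))
  }
  cn <- f * c + u * cb
  list(h = o * tanh(cn), c = cn)
}

test_that("the LSTM unit reproduces hand-evaluated gate arithmetic", {
  p0 <- lstm_params(2, 3)
  for (nm in names(p0)) p0[[nm]][] <- 0
  s <- lstm_unit_step(p0, c(1, -2), numeric(3), numeric(3))
  expect_equal(s$h, rep(0, 3)) # sigma(0) = 0.5, tanh(0) = 0
  expect_equal(s$c, rep(0, 3))
  expect_equal(s$f, rep(0.5, 3))

  # 1-dim worked case: only W_cx = 1, x = 1, zero states
  p1 <- lstm_params(1, 1)
  for (nm in names(p1)) p1[[nm]][] <- 0
  p1$W_cx[] <- 1
  s1 <- lstm_unit_step(p1, 1, 0, 0)
  expect_equal(s1$cbar, tanh(1), tolerance = 1e-7)
  expect_equal(s1$c, 0.5 * tanh(1), tolerance = 1e-7)
  expect_equal(s1$h, 0.18170, tolerance = 1e-5) # 0.5 * tanh(0.5 * tanh(1))

  expect_error(lstm_unit_step(p1, c(1, 2), 0, 0), "shape")
  expect_error(lstm_unit_step(p1, NaN, 0, 0), "non-finite")
})

test_that("unit step matches the independent scalar oracle on random instances", {
  withr::with_seed(7, {
    for (rep in 1:5) {
      d <- sample(1:4, 1)
      nh <- sample(1:5, 1)
      p <- lstm_params(d, nh)
      x <- rnorm(d)
      h <- rnorm(nh) * 0.5
      c <- rnorm(nh)
      got <- lstm_unit_step(p, x, h, c)
      ref <- oracle_step(p, x, h, c)
      expect_equal(got$h, ref$h, tolerance = 1e-12)
      expect_equal(got$c, ref$c, tolerance = 1e-12)
      expect_true(all(got$f > 0 & got$f < 1))
      expect_true(all(got$u > 0 & got$u < 1))
      expect_true(all(got$o > 0 & got$o < 1))
      expect_true(all(abs(got$h) < 1))
      # cell state growth bound: |c_t| <= |c_(t-1)| + 1
      expect_true(all(abs(got$c) <= abs(c) + 1))
    }
  })
})

test_that("the batched sequence pass equals repeated unit steps", {
  withr::with_seed(8, {
    d <- 3
    nh <- 4
    Tn <- 6
    B <- 2
    p <- lstm_params(d, nh)
    X <- array(rnorm(B * Tn * d), c(B, Tn, d))
    got <- crawlr:::lstm_forward_seq(p, X)$h
    for (b in 1:B) {
      h <- numeric(nh)
      c <- numeric(nh)
      for (t in 1:Tn) {
        s <- lstm_unit_step(p, X[b, t, ], h, c)
        h <- s$h
        c <- s$c
      }
      expect_equal(got[b, ], h, tolerance = 1e-12)
    }
  })
})

test_that("analytic BPTT gradients match numerical differentiation", {
  withr::with_seed(9, {
    d <- 3
    nh <- 4
    Tn <- 5
    B <- 2
    K <- 3
    X <- array(rnorm(B * Tn * d), c(B, Tn, d))
    y <- c(1L, 3L)
    Y <- diag(K)[y, , drop = FALSE]
    theta <- list(
      fwd = lstm_params(d, nh), bwd = lstm_params(d, nh),
      dense = crawlr:::dense_init(c(2 * nh, 6, 5, 4, K))
    )
    loss <- function(th) {
      pr <- crawlr:::bilstm_batch_forward(th, X)$probs
      -mean(log(pr[cbind(seq_len(B), y)]))
    }
    fwd <- crawlr:::bilstm_batch_forward(theta, X, keep_cache = TRUE)
    dZ <- (fwd$probs - Y) / B
    dn <- crawlr:::dense_backward(theta$dense, fwd$dense$acts, dZ)
    g <- list(
      fwd = crawlr:::lstm_backward_seq(
        theta$fwd, X, fwd$fw$cache, dn$dA0[, 1:nh, drop = FALSE]
      ),
      bwd = crawlr:::lstm_backward_seq(
        theta$bwd, fwd$Xr, fwd$bw$cache, dn$dA0[, nh + 1:nh, drop = FALSE]
      ),
      dense = dn$grads
    )
    eps <- 1e-6
    check <- function(get, set, analytic) {
      th <- theta
      tp <- set(th, get(th) + eps)
      tm <- set(th, get(th) - eps)
      expect_equal((loss(tp) - loss(tm)) / (2 * eps), analytic, tolerance = 1e-5)
    }
    for (blk in c("fwd", "bwd")) {
      for (nm in c("W_fx", "W_uh", "W_cx", "b_o")) {
        i <- 2
        check(
          function(th) th[[blk]][[nm]][i],
          function(th, v) {
            th[[blk]][[nm]][i] <- v
            th
          },
          g[[blk]][[nm]][i]
        )
      }
    }
    for (li in c(1, 4)) {
      check(
        function(th) th$dense[[li]]$W[1, 2],
        function(th, v) {
          th$dense[[li]]$W[1, 2] <- v
          th
        },
        g$dense[[li]]$W[1, 2]
      )
    }
  })
})

test_that("BiLSTM scores are a distribution with the stated symmetries", {
  ds <- toy_envelopes()
  spec <- classifier_spec("bilstm",
    hidden = 8, epochs = 5, seq_points = 20,
    dense_sizes = c(16, 8, 4)
  )
  m <- train_classifier(spec, ds, seed = 5)
  s <- bilstm_forward(m$fit, crawlr:::envelope_sequence(ds$envelope[[1]], 20))
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_true(all(s >= 0))
  expect_named(s, c("A", "B"))

  # tied weights: reversing the input swaps the forward/backward passes
  theta <- m$fit$theta
  theta$bwd <- theta$fwd
  X <- crawlr:::envelope_sequence(ds$envelope[[2]], 20)
  Xa <- array(X, c(1, dim(X)))
  Xr <- array(X[rev(seq_len(nrow(X))), ], c(1, dim(X)))
  fa <- crawlr:::bilstm_batch_forward(theta, Xa)
  fr <- crawlr:::bilstm_batch_forward(theta, Xr)
  expect_equal(fa$fw$h, fr$bw$h, tolerance = 1e-12)
  expect_equal(fa$bw$h, fr$fw$h, tolerance = 1e-12)

  # palindromic input: scores invariant to time reversal
  pal <- X
  pal[] <- rep(colMeans(X), each = nrow(X))
  sp1 <- bilstm_forward(m$fit, pal)
  sp2 <- bilstm_forward(m$fit, pal[rev(seq_len(nrow(pal))), ])
  expect_equal(sp1, sp2, tolerance = 1e-12)

  expect_error(bilstm_forward(m$fit, X[, 1:3]), "channel")
})
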