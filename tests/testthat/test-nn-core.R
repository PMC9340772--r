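# Finite-difference gradient checks of the hand-written layers: if these
# hold, every model built from them optimizes the loss it claims to.

num_grad <- function(f, a, eps = 1e-6) {
  out <- a * 0
  for (i in seq_along(a)) {
    a1 <- a; a2 <- a
    a1[i] <- a1[i] + eps; a2[i] <- a2[i] - eps
    out[i] <- (f(a1) - f(a2)) / (2 * eps)
  }
  out
}

test_that("convolution backward matches finite differences", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  p <- thermoshock:::conv_param(3, 3, 2, 3)
  y <- thermoshock:::conv_fwd(x, p)
  dy <- array(rnorm(length(y)), dim(y))
  g <- thermoshock:::conv_bwd(x, p, dy)
  fX <- function(a) sum(thermoshock:::conv_fwd(array(a, dim(x)), p) * dy)
  fW <- function(a) sum(thermoshock:::conv2d_fwd(x, array(a, dim(p$W)),
                                                 p$b, 1L) * dy)
  fb <- function(a) sum(thermoshock:::conv2d_fwd(x, p$W, a, 1L) * dy)
  expect_lt(max(abs(num_grad(fX, x) - g$dX)), 1e-6)
  expect_lt(max(abs(num_grad(fW, p$W) - g$dW)), 1e-6)
  expect_lt(max(abs(num_grad(fb, p$b) - g$db)), 1e-6)
})

test_that("max pooling selects block maxima and routes gradient to them", {
  set.seed(2)
  x <- array(rnorm(4 * 6 * 2 * 3), c(4, 6, 2, 3))
  mp <- thermoshock:::maxpool2_fwd(x)
  ref <- pmax(x[c(1, 3), c(1, 3, 5), , ], x[c(2, 4), c(1, 3, 5), , ],
              x[c(1, 3), c(2, 4, 6), , ], x[c(2, 4), c(2, 4, 6), , ])
  expect_equal(as.vector(mp$Y), as.vector(ref))
  dy <- array(rnorm(length(mp$Y)), dim(mp$Y))
  dx <- thermoshock:::maxpool2_bwd(mp$idx, dy, dim(x))
  expect_equal(sum(dx != 0), length(dy))   # one route per output
  expect_equal(sum(dx), sum(dy))
})

test_that("upsample2 backward is the exact adjoint of the forward", {
  set.seed(3)
  x <- array(rnorm(3 * 4 * 2 * 2), c(3, 4, 2, 2))
  y <- thermoshock:::upsample2_fwd(x)
  dy <- array(rnorm(length(y)), dim(y))
  # adjoint identity: <up(x), dy> == <x, up^T(dy)>
  expect_equal(sum(y * dy), sum(x * thermoshock:::upsample2_bwd(dy)))
})

test_that("U-shaped segmenter gradient matches finite differences", {
  set.seed(4)
  cfg <- utils::modifyList(thermoshock:::segmenter_config_default(),
                           list(levels = 2L, base_filters = 2L))
  params <- thermoshock:::unet_init(cfg)
  x <- array(rnorm(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(0, c(8, 8, 3, 2))
  cls <- array(sample(0:2, 8 * 8 * 2, replace = TRUE), c(8, 8, 2))
  for (c in 1:3) y[, , c, ] <- (cls == c - 1) * 1
  loss_of <- function(pp) {
    fw <- thermoshock:::unet_forward(pp, x)
    thermoshock:::seg_loss_grad(fw$probs, y, cfg)$loss
  }
  fw <- thermoshock:::unet_forward(params, x, keep_cache = TRUE)
  lg <- thermoshock:::seg_loss_grad(fw$probs, y, cfg)
  grads <- thermoshock:::unet_backward(params, fw$cache, lg$dz)
  # spot-check a handful of parameters across the network
  for (pick in list(c("enc", 1, "conv1"), c("bott", NA, "conv2"),
                    c("dec", 2, "proj"), c("head", NA, NA))) {
    p2 <- params
    target <- if (pick[1] == "head") params$head$W
      else if (pick[1] == "bott") params$bott[[pick[3]]]$W
      else params[[pick[1]]][[as.integer(pick[2])]][[pick[3]]]$W
    g <- if (pick[1] == "head") grads$head$W
      else if (pick[1] == "bott") grads$bott[[pick[3]]]$W
      else grads[[pick[1]]][[as.integer(pick[2])]][[pick[3]]]$W
    idx <- seq_len(min(5, length(target)))
    for (i in idx) {
      eps <- 1e-5
      t1 <- target; t1[i] <- t1[i] + eps
      t2 <- target; t2[i] <- t2[i] - eps
      set_w <- function(v) {
        q <- params
        if (pick[1] == "head") q$head$W <- v
        else if (pick[1] == "bott") q$bott[[pick[3]]]$W <- v
        else q[[pick[1]]][[as.integer(pick[2])]][[pick[3]]]$W <- v
        q
      }
      fd <- (loss_of(set_w(t1)) - loss_of(set_w(t2))) / (2 * eps)
      expect_lt(abs(fd - g[i]), 1e-5)
    }
  }
})

test_that("LSTM layer gradient matches finite differences", {
  set.seed(5)
  N <- 3; Tn <- 4; D <- 2; H <- 3
  p <- list(W = matrix(rnorm((D + H) * 4 * H, sd = 0.3), D + H, 4 * H),
            b = rnorm(4 * H, sd = 0.1))
  xs <- lapply(1:Tn, function(t) matrix(rnorm(N * D), N, D))
  mask <- matrix(TRUE, N, Tn)
  mask[1, 1:2] <- FALSE                     # padded prefix for one sequence
  v <- matrix(rnorm(N * H), N, H)
  loss_of <- function(pp, xss) {
    fw <- thermoshock:::lstm_layer_fwd(pp, xss, mask * 1)
    sum(fw$h_last * v)
  }
  fw <- thermoshock:::lstm_layer_fwd(p, xs, mask * 1, keep_cache = TRUE)
  bw <- thermoshock:::lstm_layer_bwd(p, fw$cache, vector("list", Tn), v)
  fW <- function(a) loss_of(list(W = matrix(a, D + H, 4 * H), b = p$b), xs)
  expect_lt(max(abs(num_grad(fW, p$W) - bw$dW)), 1e-6)
  fx <- function(a) {
    xs2 <- xs; xs2[[2]] <- matrix(a, N, D)
    loss_of(p, xs2)
  }
  expect_lt(max(abs(num_grad(fx, xs[[2]]) - bw$dxs[[2]])), 1e-6)
})

test_that("Adam decreases a simple quadratic", {
  params <- list(w = c(5, -3))
  grads_of <- function(p) list(w = 2 * p$w)
  st <- thermoshock:::adam_init(params)
  for (i in 1:200) {
    s <- thermoshock:::adam_step(params, grads_of(params), st, lr = 0.1)
    params <- s$params; st <- s$state
  }
  expect_lt(sum(params$w^2), 1e-2)
})
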