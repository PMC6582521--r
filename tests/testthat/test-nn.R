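# The neural-network engine: forward shapes, exact gradients against
# numerical differentiation, pooling against naive references, and the
# optimizer.

naive_conv <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; C <- d[3]
  oh <- (H + 2 * pad - k) %/% stride + 1
  ow <- (Wd + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(H + 2 * pad, Wd + 2 * pad, C))
  xp[pad + seq_len(H), pad + seq_len(Wd), ] <- x
  oc <- ncol(W)
  y <- array(0, c(oh, ow, oc))
  for (o in seq_len(oc)) for (j in seq_len(ow)) for (i in seq_len(oh)) {
    patch <- xp[(i - 1) * stride + seq_len(k),
                (j - 1) * stride + seq_len(k), , drop = FALSE]
    # patch entries in (ki, kj, c) order match the weight row layout
    y[i, j, o] <- sum(as.vector(patch) * W[, o]) + b[o]
  }
  y
}

test_that("conv2d via im2col agrees with a naive direct convolution", {
  set.seed(1)
  l <- molimage:::nn_conv2d(2, 3, 3, stride = 2, pad = 1)
  x <- array(rnorm(7 * 5 * 2), c(7, 5, 2))
  y <- molimage:::layer_forward(l, x)
  expect_equal(y, naive_conv(x, l$W, l$b, 3, 2, 1), tolerance = 1e-12)
})

test_that("max and average pooling agree with naive references", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  mp <- molimage:::layer_forward(molimage:::nn_maxpool2d(2, 2), x)
  ap <- molimage:::layer_forward(molimage:::nn_avgpool2d(2, 2), x)
  for (c in 1:2) for (i in 1:3) for (j in 1:3) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c]
    expect_equal(mp[i, j, c], max(blk))
    expect_equal(ap[i, j, c], mean(blk))
  }
})

check_gradients <- function(net, head, x, target, n_probe = 5, tol = 1e-5) {
  loss_fn <- function() {
    f <- molimage:::layer_forward(net, x, training = TRUE)
    p <- molimage:::layer_forward(head, matrix(f, 1), training = TRUE)
    sum((p - target)^2)
  }
  molimage:::nn_zero_grad(net)
  molimage:::nn_zero_grad(head)
  f <- molimage:::layer_forward(net, x, training = TRUE)
  p <- molimage:::layer_forward(head, matrix(f, 1), training = TRUE)
  d <- molimage:::layer_backward(head, matrix(2 * (p - target), 1))
  molimage:::layer_backward(net, as.vector(d))
  for (l in molimage:::collect_layers(net)) {
    pn <- molimage:::PARAM_NAMES[[l$type]]
    gn <- molimage:::GRAD_NAMES[[l$type]]
    for (k in seq_along(pn)) {
      par <- l[[pn[k]]]
      for (i in sample(length(par), min(n_probe, length(par)))) {
        orig <- par[i]
        l[[pn[k]]][i] <- orig + 1e-6
        lp <- loss_fn()
        l[[pn[k]]][i] <- orig - 1e-6
        lm <- loss_fn()
        l[[pn[k]]][i] <- orig
        num <- (lp - lm) / 2e-6
        ana <- l[[gn[k]]][i]
        expect_equal(ana, num, tolerance = tol,
                     label = paste("analytic grad", l$type, pn[k]))
      }
    }
  }
}

test_that("backprop through the plain conv stack matches numeric gradients", {
  set.seed(42)
  net <- molimage:::nn_sequential(
    molimage:::nn_conv2d(2, 3, 3, stride = 1, pad = 1),
    molimage:::nn_batchnorm2d(3), molimage:::nn_relu(),
    molimage:::nn_maxpool2d(2, 2),
    molimage:::nn_conv2d(3, 4, 3, pad = 1), molimage:::nn_relu(),
    molimage:::nn_avgpool2d(2, 2),
    molimage:::nn_adaptive_avgpool2d(2), molimage:::nn_flatten())
  head <- molimage:::nn_sequential(molimage:::nn_linear(16, 2))
  check_gradients(net, head, array(rnorm(8 * 8 * 2), c(8, 8, 2)),
                  c(0.3, -0.7))
})

test_that("backprop through residual and dense blocks matches numerics", {
  set.seed(7)
  net <- molimage:::nn_sequential(
    molimage:::resnet_bottleneck(2, 2, 2),
    molimage:::densenet_layer(8, 4),
    molimage:::nn_adaptive_avgpool2d(1), molimage:::nn_flatten())
  head <- molimage:::nn_sequential(molimage:::nn_linear(12, 1))
  check_gradients(net, head, array(rnorm(6 * 6 * 2), c(6, 6, 2)), 1)
})

test_that("checkpoint save/restore round-trips parameters exactly", {
  set.seed(3)
  net <- molimage:::nn_sequential(molimage:::nn_linear(4, 3),
                                  molimage:::nn_relu(),
                                  molimage:::nn_linear(3, 1))
  saved <- molimage:::nn_get_params(net)
  for (l in molimage:::collect_layers(net)) l$W <- l$W * 2 + 1
  molimage:::nn_set_params(net, saved)
  expect_identical(molimage:::nn_get_params(net), saved)
})

test_that("SGD with Nesterov momentum follows the v = mu v + g recursion", {
  # single scalar weight, no bias gradient: w' = w - lr (g + mu (mu v + g))
  l <- molimage:::nn_linear(1, 1)
  l$W[1, 1] <- 2
  net <- molimage:::nn_sequential(l)
  opt <- molimage:::sgd_optimizer(momentum = 0.9)
  # loss = (w x - y)^2 with x = 1, y = 0 -> g = 2 w
  step_once <- function() {
    molimage:::nn_zero_grad(net)
    p <- molimage:::layer_forward(net, matrix(1, 1, 1), training = TRUE)
    molimage:::layer_backward(net, matrix(2 * p, 1, 1))
    opt$step(net, 0.1)
  }
  w0 <- 2
  b0 <- l$b
  vw <- vb <- 0
  for (i in 1:3) {
    p <- w0 + b0             # x = 1, so both parameters see gradient 2p
    gw <- 2 * p
    gb <- 2 * p
    vw <- 0.9 * vw + gw
    vb <- 0.9 * vb + gb
    w0 <- w0 - 0.1 * (gw + 0.9 * vw)
    b0 <- b0 - 0.1 * (gb + 0.9 * vb)
    step_once()
    expect_equal(l$W[1, 1], w0, tolerance = 1e-12)
    expect_equal(l$b, b0, tolerance = 1e-12)
  }
})

test_that("dropout is identity in eval mode and unbiased in training", {
  set.seed(5)
  l <- molimage:::nn_dropout(0.5)
  x <- matrix(1, 100, 50)
  expect_identical(molimage:::layer_forward(l, x, training = FALSE), x)
  y <- molimage:::layer_forward(l, x, training = TRUE)
  expect_true(all(y %in% c(0, 2)))
  expect_equal(mean(y), 1, tolerance = 0.05)
})
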