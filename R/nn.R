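# A compact neural-network engine with explicit forward/backward passes.
#
# Layers are mutable environments carrying parameters, gradients and the
# activations cached by the forward pass. Convolutional layers operate on
# single images in (H, W, C) column-major layout via im2col so each
# convolution is one BLAS matrix product; fully-connected layers operate
# on (batch, features) matrices. Networks used here are a convolutional
# feature extractor followed by a fully-connected regression head, so the
# two conventions meet at a flatten boundary.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

he_init <- function(fan_in, n, gain = sqrt(2)) {
  stats::rnorm(n, 0, gain / sqrt(fan_in))
}

#' @rdname nn_layers
#' @param in_features,out_features Input/output width of a linear layer.
#' @export
nn_linear <- function(in_features, out_features) {
  new_layer("linear",
            W = matrix(he_init(in_features, in_features * out_features),
                       in_features, out_features),
            b = rep(0, out_features),
            dW = NULL, db = NULL)
}

#' Neural-network layer constructors
#'
#' Building blocks of the regression networks: linear, rectified-linear,
#' dropout, 2D convolution, max/average pooling, adaptive average
#' pooling, per-channel batch normalization, flatten, and the residual /
#' densely-connected composite blocks used by the deeper backbones.
#' Parameters are He-initialized from the RNG state current at
#' construction time.
#'
#' @name nn_layers
#' @return A layer object (mutable environment) usable in
#'   [nn_sequential()].
NULL

#' @rdname nn_layers
#' @export
nn_relu <- function() new_layer("relu")

#' @rdname nn_layers
#' @param p Dropout probability.
#' @export
nn_dropout <- function(p) new_layer("dropout", p = p)

#' @rdname nn_layers
#' @param in_ch,out_ch Channel counts.
#' @param k Square kernel size.
#' @param stride,pad Stride and zero padding.
#' @export
nn_conv2d <- function(in_ch, out_ch, k, stride = 1, pad = 0) {
  fan_in <- k * k * in_ch
  new_layer("conv2d",
            W = matrix(he_init(fan_in, fan_in * out_ch), fan_in, out_ch),
            b = rep(0, out_ch),
            k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad), in_ch = as.integer(in_ch),
            out_ch = as.integer(out_ch))
}

#' @rdname nn_layers
#' @export
nn_maxpool2d <- function(k, stride = k, pad = 0) {
  new_layer("maxpool2d", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}

#' @rdname nn_layers
#' @export
nn_avgpool2d <- function(k, stride = k) {
  new_layer("avgpool2d", k = as.integer(k), stride = as.integer(stride))
}

#' @rdname nn_layers
#' @param oh,ow Output spatial size of adaptive average pooling.
#' @export
nn_adaptive_avgpool2d <- function(oh, ow = oh) {
  new_layer("adaptive_avgpool2d", oh = as.integer(oh), ow = as.integer(ow))
}

#' @rdname nn_layers
#' @param ch Number of channels normalized.
#' @param eps Numerical stabilizer added to the variance.
#' @param momentum Running-statistics update rate.
#' @export
nn_batchnorm2d <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("batchnorm2d",
            gamma = rep(1, ch), beta = rep(0, ch),
            running_mean = rep(0, ch), running_var = rep(1, ch),
            eps = eps, momentum = momentum, ch = as.integer(ch))
}

#' @rdname nn_layers
#' @export
nn_flatten <- function() new_layer("flatten")

#' @rdname nn_layers
#' @param layers List of layers applied in order.
#' @export
nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) {
    layers <- layers[[1]]
  }
  new_layer("sequential", layers = layers)
}

#' @rdname nn_layers
#' @param main,shortcut Sequential branches of a residual block
#'   (`shortcut = NULL` is the identity); the block output is
#'   `relu(main(x) + shortcut(x))`.
#' @export
nn_residual <- function(main, shortcut = NULL) {
  new_layer("residual", main = main, shortcut = shortcut)
}

#' @rdname nn_layers
#' @param branch Sequential branch of a densely-connected layer; the
#'   block output concatenates the input and `branch(x)` along channels.
#' @export
nn_dense_block_layer <- function(branch) {
  new_layer("denselayer", branch = branch)
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }

# ---- forward ----------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    linear = {
      if (training) layer$x <- x
      sweep(x %*% layer$W, 2, layer$b, "+")
    },
    relu = {
      y <- relu_fwd(x)
      if (training) layer$mask <- y > 0
      y
    },
    dropout = {
      if (!training || layer$p <= 0) return(x)
      keep <- array(stats::runif(length(x)) >= layer$p, dim = dim(x) %||% length(x))
      layer$keep <- keep
      x * keep / (1 - layer$p)
    },
    conv2d = {
      d <- dim(x)
      cols <- im2col_hwc(x, d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      y <- cols %*% layer$W
      y <- sweep(y, 2, layer$b, "+")
      oh <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1
      ow <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1
      if (training) { layer$cols <- cols; layer$in_dim <- d }
      array(y, c(oh, ow, layer$out_ch))
    },
    maxpool2d = {
      d <- dim(x)
      r <- maxpool_fwd(x, d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
      if (training) { layer$argmax <- r$argmax; layer$in_dim <- d }
      r$y
    },
    avgpool2d = {
      d <- dim(x)
      if (training) layer$in_dim <- d
      avgpool_fwd(x, d[1], d[2], d[3], layer$k, layer$stride)
    },
    adaptive_avgpool2d = adaptive_avgpool_fwd(layer, x, training),
    batchnorm2d = batchnorm_fwd(layer, x, training),
    flatten = {
      if (training) layer$in_dim <- dim(x)
      as.vector(x)
    },
    sequential = {
      for (l in layer$layers) x <- layer_forward(l, x, training)
      x
    },
    residual = {
      a <- layer_forward(layer$main, x, training)
      s <- if (is.null(layer$shortcut)) x else
        layer_forward(layer$shortcut, x, training)
      y <- relu_fwd(a + s)
      if (training) layer$mask <- y > 0
      y
    },
    denselayer = {
      b <- layer_forward(layer$branch, x, training)
      if (training) layer$in_ch <- dim(x)[3]
      abind_channels(x, b)
    },
    stop("unknown layer type: ", layer$type)
  )
}

abind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

adaptive_avgpool_fwd <- function(layer, x, training) {
  d <- dim(x)
  oh <- layer$oh; ow <- layer$ow
  hs <- floor((seq_len(oh) - 1) * d[1] / oh) + 1
  he <- ceiling(seq_len(oh) * d[1] / oh)
  ws <- floor((seq_len(ow) - 1) * d[2] / ow) + 1
  we <- ceiling(seq_len(ow) * d[2] / ow)
  y <- array(0, c(oh, ow, d[3]))
  for (j in seq_len(ow)) for (i in seq_len(oh)) {
    block <- x[hs[i]:he[i], ws[j]:we[j], , drop = FALSE]
    y[i, j, ] <- colMeans(matrix(block, ncol = d[3]))
  }
  if (training) {
    layer$in_dim <- d
    layer$bins <- list(hs = hs, he = he, ws = ws, we = we)
  }
  y
}

batchnorm_fwd <- function(layer, x, training) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  if (training) {
    m <- colMeans(xm)
    v <- colMeans(xm^2) - m^2
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * m
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v * n / max(n - 1, 1)
    inv <- 1 / sqrt(v + layer$eps)
    xhat <- sweep(sweep(xm, 2, m), 2, inv, "*")
    layer$xhat <- xhat; layer$inv <- inv; layer$in_dim <- d
    y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  } else {
    inv <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- sweep(sweep(xm, 2, layer$running_mean), 2, inv, "*")
    y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  }
  array(y, d)
}

# ---- backward ---------------------------------------------------------------

acc_grad <- function(layer, name, g) {
  cur <- layer[[name]]
  layer[[name]] <- if (is.null(cur)) g else cur + g
}

layer_backward <- function(layer, dy) {
  switch(layer$type,
    linear = {
      acc_grad(layer, "dW", crossprod(layer$x, dy))
      acc_grad(layer, "db", colSums(dy))
      dy %*% t(layer$W)
    },
    relu = dy * layer$mask,
    dropout = {
      if (is.null(layer$keep)) return(dy)
      dy * layer$keep / (1 - layer$p)
    },
    conv2d = {
      d <- layer$in_dim
      oc <- layer$out_ch
      dym <- matrix(dy, ncol = oc)
      acc_grad(layer, "dW", crossprod(layer$cols, dym))
      acc_grad(layer, "db", colSums(dym))
      dcols <- dym %*% t(layer$W)
      col2im_hwc(dcols, d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
    },
    maxpool2d = {
      d <- layer$in_dim
      maxpool_bwd(dy, layer$argmax, d[1], d[2], d[3])
    },
    avgpool2d = {
      d <- layer$in_dim
      avgpool_bwd(dy, d[1], d[2], d[3], layer$k, layer$stride)
    },
    adaptive_avgpool2d = {
      d <- layer$in_dim
      b <- layer$bins
      dx <- array(0, d)
      for (j in seq_along(b$ws)) for (i in seq_along(b$hs)) {
        hr <- b$hs[i]:b$he[i]; wr <- b$ws[j]:b$we[j]
        g <- dy[i, j, ] / (length(hr) * length(wr))
        dx[hr, wr, ] <- dx[hr, wr, ] +
          rep(g, each = length(hr) * length(wr))
      }
      dx
    },
    batchnorm2d = {
      d <- layer$in_dim
      n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      acc_grad(layer, "dgamma", colSums(dym * layer$xhat))
      acc_grad(layer, "dbeta", colSums(dym))
      dxhat <- sweep(dym, 2, layer$gamma, "*")
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * layer$xhat)
      dx <- sweep(
        dxhat - matrix(s1 / n, n, d[3], byrow = TRUE) -
          layer$xhat * matrix(s2 / n, n, d[3], byrow = TRUE),
        2, layer$inv, "*")
      array(dx, d)
    },
    flatten = array(dy, layer$in_dim),
    sequential = {
      for (l in rev(layer$layers)) dy <- layer_backward(l, dy)
      dy
    },
    residual = {
      dy <- dy * layer$mask
      dx <- layer_backward(layer$main, dy)
      dx + if (is.null(layer$shortcut)) dy else
        layer_backward(layer$shortcut, dy)
    },
    denselayer = {
      ci <- layer$in_ch
      d <- dim(dy)
      dx1 <- dy[, , seq_len(ci), drop = FALSE]
      db <- dy[, , (ci + 1):d[3], drop = FALSE]
      dx1 + layer_backward(layer$branch, db)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- parameter plumbing -----------------------------------------------------

PARAM_NAMES <- list(linear = c("W", "b"), conv2d = c("W", "b"),
                    batchnorm2d = c("gamma", "beta"))
GRAD_NAMES <- list(linear = c("dW", "db"), conv2d = c("dW", "db"),
                   batchnorm2d = c("dgamma", "dbeta"))

# Depth-first list of all parameterized leaf layers.
collect_layers <- function(layer) {
  switch(layer$type,
    sequential = do.call(c, lapply(layer$layers, collect_layers)),
    residual = c(collect_layers(layer$main),
                 if (!is.null(layer$shortcut)) collect_layers(layer$shortcut)),
    denselayer = collect_layers(layer$branch),
    if (layer$type %in% names(PARAM_NAMES)) list(layer) else list()
  )
}

nn_zero_grad <- function(layer) {
  for (l in collect_layers(layer)) {
    for (g in GRAD_NAMES[[l$type]]) l[[g]] <- NULL
  }
  invisible(layer)
}

nn_get_params <- function(layer) {
  lapply(collect_layers(layer), function(l) {
    stats::setNames(lapply(PARAM_NAMES[[l$type]], function(p) l[[p]]),
                    PARAM_NAMES[[l$type]])
  })
}

nn_set_params <- function(layer, params) {
  ls <- collect_layers(layer)
  assert_that(length(ls) == length(params), "parameter shape mismatch")
  for (i in seq_along(ls)) {
    for (p in names(params[[i]])) ls[[i]][[p]] <- params[[i]][[p]]
  }
  invisible(layer)
}

#' Count trainable parameters of a network
#'
#' @param layer A layer or container built with the `nn_*` constructors,
#'   or a model from [build_convnet()] / [build_dnn()].
#' @return Integer count of trainable scalars.
#' @export
nn_n_params <- function(layer) {
  if (inherits(layer, "convnet_model") || inherits(layer, "dnn_model")) {
    return(sum(vapply(Filter(Negate(is.null),
                             list(layer$features, layer$head)),
                      nn_n_params, numeric(1))))
  }
  sum(vapply(nn_get_params(layer), function(p) {
    sum(vapply(p, length, numeric(1)))
  }, numeric(1)))
}

# Stochastic gradient descent with Nesterov momentum:
# v <- mu v + g ; w <- w - lr (g + mu v)
sgd_optimizer <- function(momentum = 0.9) {
  e <- new.env(parent = emptyenv())
  e$momentum <- momentum
  e$velocity <- list()
  e$step <- function(net, lr) {
    key <- rlang::obj_address(net)
    layers <- collect_layers(net)
    if (is.null(e$velocity[[key]])) {
      e$velocity[[key]] <- lapply(layers, function(l) {
        lapply(stats::setNames(PARAM_NAMES[[l$type]], PARAM_NAMES[[l$type]]),
               function(p) {
                 d <- dim(l[[p]])
                 if (is.null(d)) numeric(length(l[[p]])) else array(0, d)
               })
      })
    }
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      pn <- PARAM_NAMES[[l$type]]
      gn <- GRAD_NAMES[[l$type]]
      for (j in seq_along(pn)) {
        g <- l[[gn[j]]]
        if (is.null(g)) next
        p <- l[[pn[j]]]
        # align gradient shape with the parameter (drop stray names/dims)
        g <- unname(as.vector(g))
        if (!is.null(dim(p))) dim(g) <- dim(p)
        v <- e$momentum * e$velocity[[key]][[i]][[pn[j]]] + g
        e$velocity[[key]][[i]][[pn[j]]] <- v
        l[[pn[j]]] <- p - lr * (g + e$momentum * v)
      }
    }
  }
  e
}
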