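# Convolutional feature extractors replicating the layer layouts of four
# classic image-classification architectures. Only the feature-extraction
# stages are defined here; regression heads are attached by
# build_convnet(). Weights are He-initialized at construction; ImageNet
# weight files are not bundled.

BACKBONES <- c("alexnet", "vgg19bn", "resnet152", "densenet201")

backbone_alexnet <- function() {
  feats <- nn_sequential(
    nn_conv2d(3, 64, 11, stride = 4, pad = 2), nn_relu(),
    nn_maxpool2d(3, 2),
    nn_conv2d(64, 192, 5, pad = 2), nn_relu(),
    nn_maxpool2d(3, 2),
    nn_conv2d(192, 384, 3, pad = 1), nn_relu(),
    nn_conv2d(384, 256, 3, pad = 1), nn_relu(),
    nn_conv2d(256, 256, 3, pad = 1), nn_relu(),
    nn_maxpool2d(3, 2),
    nn_adaptive_avgpool2d(6), nn_flatten()
  )
  list(features = feats, feature_dim = 256L * 6L * 6L)
}

backbone_vgg19bn <- function() {
  cfg <- c(64, 64, "M", 128, 128, "M", 256, 256, 256, 256, "M",
           512, 512, 512, 512, "M", 512, 512, 512, 512, "M")
  layers <- list()
  in_ch <- 3L
  for (v in cfg) {
    if (v == "M") {
      layers <- c(layers, list(nn_maxpool2d(2, 2)))
    } else {
      ch <- as.integer(v)
      layers <- c(layers, list(nn_conv2d(in_ch, ch, 3, pad = 1),
                               nn_batchnorm2d(ch), nn_relu()))
      in_ch <- ch
    }
  }
  layers <- c(layers, list(nn_adaptive_avgpool2d(7), nn_flatten()))
  list(features = nn_sequential(layers), feature_dim = 512L * 7L * 7L)
}

# Bottleneck residual unit: 1x1 reduce, 3x3, 1x1 expand (x4).
resnet_bottleneck <- function(in_ch, mid_ch, stride) {
  out_ch <- mid_ch * 4L
  main <- nn_sequential(
    nn_conv2d(in_ch, mid_ch, 1), nn_batchnorm2d(mid_ch), nn_relu(),
    nn_conv2d(mid_ch, mid_ch, 3, stride = stride, pad = 1),
    nn_batchnorm2d(mid_ch), nn_relu(),
    nn_conv2d(mid_ch, out_ch, 1), nn_batchnorm2d(out_ch)
  )
  shortcut <- if (stride != 1 || in_ch != out_ch) {
    nn_sequential(nn_conv2d(in_ch, out_ch, 1, stride = stride),
                  nn_batchnorm2d(out_ch))
  } else NULL
  nn_residual(main, shortcut)
}

backbone_resnet152 <- function() {
  stage_sizes <- c(3L, 8L, 36L, 3L)
  mid <- c(64L, 128L, 256L, 512L)
  layers <- list(nn_conv2d(3, 64, 7, stride = 2, pad = 3),
                 nn_batchnorm2d(64), nn_relu(),
                 nn_maxpool2d(3, 2, pad = 1))
  in_ch <- 64L
  for (s in seq_along(stage_sizes)) {
    for (b in seq_len(stage_sizes[s])) {
      stride <- if (b == 1 && s > 1) 2L else 1L
      layers <- c(layers, list(resnet_bottleneck(in_ch, mid[s], stride)))
      in_ch <- mid[s] * 4L
    }
  }
  layers <- c(layers, list(nn_adaptive_avgpool2d(1), nn_flatten()))
  list(features = nn_sequential(layers), feature_dim = 2048L)
}

densenet_layer <- function(in_ch, growth) {
  nn_dense_block_layer(nn_sequential(
    nn_batchnorm2d(in_ch), nn_relu(), nn_conv2d(in_ch, 4L * growth, 1),
    nn_batchnorm2d(4L * growth), nn_relu(),
    nn_conv2d(4L * growth, growth, 3, pad = 1)
  ))
}

backbone_densenet201 <- function() {
  growth <- 32L
  block_sizes <- c(6L, 12L, 48L, 32L)
  layers <- list(nn_conv2d(3, 64, 7, stride = 2, pad = 3),
                 nn_batchnorm2d(64), nn_relu(),
                 nn_maxpool2d(3, 2, pad = 1))
  ch <- 64L
  for (b in seq_along(block_sizes)) {
    for (i in seq_len(block_sizes[b])) {
      layers <- c(layers, list(densenet_layer(ch, growth)))
      ch <- ch + growth
    }
    if (b < length(block_sizes)) {
      half <- ch %/% 2L
      layers <- c(layers, list(nn_batchnorm2d(ch), nn_relu(),
                               nn_conv2d(ch, half, 1), nn_avgpool2d(2, 2)))
      ch <- half
    }
  }
  layers <- c(layers, list(nn_batchnorm2d(ch), nn_relu(),
                           nn_adaptive_avgpool2d(1), nn_flatten()))
  list(features = nn_sequential(layers), feature_dim = ch)
}

# Construct a named backbone; RNG state at call time seeds the weights.
build_backbone <- function(backbone_id) {
  switch(backbone_id,
    alexnet = backbone_alexnet(),
    vgg19bn = backbone_vgg19bn(),
    resnet152 = backbone_resnet152(),
    densenet201 = backbone_densenet201(),
    stop("unknown backbone_id: '", backbone_id, "' (expected one of ",
         paste(BACKBONES, collapse = ", "), ")", call. = FALSE)
  )
}
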