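# Model families: ConvNet regressors on image backbones, fully-connected
# networks on fingerprints, and Random Forest baselines.

#' ConvNet regressor specification
#'
#' Describes a convolutional regression network: a feature-extraction
#' backbone and either a `standard` head (one linear layer straight to
#' the task outputs) or an `extended` head appending four hidden
#' fully-connected layers of 4096, 1000, 200 and 100 units (rectified
#' linear, 50% dropout) before the linear output layer — five
#' fully-connected layers in total. Neither head applies an output
#' nonlinearity: predictions live on the open pIC50 scale.
#'
#' @param backbone_id One of `"alexnet"`, `"vgg19bn"`, `"resnet152"`,
#'   `"densenet201"`.
#' @param head `"standard"` or `"extended"`.
#' @param n_tasks Number of regression outputs (>= 2 for multi-task).
#' @param head_widths Hidden widths of the extended head.
#' @param head_dropout Dropout rate in the extended head.
#' @param pretrained If `TRUE`, requires backbone weight files, which
#'   this package does not bundle; the offline default `FALSE` draws
#'   He-initialized weights.
#' @param freeze_backbone If `TRUE`, backbone parameters receive no
#'   updates; only the head is trained.
#' @return An object of class `convnet_spec`.
#' @export
convnet_spec <- function(backbone_id = "alexnet",
                         head = c("standard", "extended"),
                         n_tasks = 1L,
                         head_widths = c(4096L, 1000L, 200L, 100L),
                         head_dropout = 0.5,
                         pretrained = FALSE,
                         freeze_backbone = FALSE) {
  head <- match.arg(head)
  assert_that(backbone_id %in% BACKBONES,
              paste0("unknown backbone_id: '", backbone_id, "'"))
  assert_that(is.numeric(n_tasks) && n_tasks >= 1, "n_tasks must be >= 1")
  structure(list(backbone_id = backbone_id, head = head,
                 n_tasks = as.integer(n_tasks),
                 head_widths = as.integer(head_widths),
                 head_dropout = head_dropout, pretrained = pretrained,
                 freeze_backbone = freeze_backbone),
            class = "convnet_spec")
}

build_head <- function(feature_dim, spec) {
  if (spec$head == "standard") {
    return(nn_sequential(nn_linear(feature_dim, spec$n_tasks)))
  }
  widths <- c(feature_dim, spec$head_widths)
  layers <- list()
  for (i in seq_len(length(widths) - 1)) {
    layers <- c(layers, list(nn_linear(widths[i], widths[i + 1]),
                             nn_relu(), nn_dropout(spec$head_dropout)))
  }
  layers <- c(layers, list(nn_linear(widths[length(widths)], spec$n_tasks)))
  nn_sequential(layers)
}

#' Closed-form parameter count of a regression head
#'
#' Weights plus biases summed over consecutive layer widths.
#'
#' @param feature_dim Backbone feature dimension.
#' @param spec A [convnet_spec()].
#' @return Integer parameter count.
#' @export
head_param_count <- function(feature_dim, spec) {
  widths <- if (spec$head == "standard") {
    c(feature_dim, spec$n_tasks)
  } else {
    c(feature_dim, spec$head_widths, spec$n_tasks)
  }
  sum(widths[-length(widths)] * widths[-1] + widths[-1])
}

#' Build a ConvNet regressor
#'
#' Constructs the backbone feature extractor and attaches the requested
#' regression head. Weights are drawn from the RNG state current at the
#' call (wrap in a seeded context for reproducibility).
#'
#' @param spec A [convnet_spec()].
#' @return An object of class `convnet_model` with elements `features`,
#'   `head`, `feature_dim`, `spec`.
#' @export
build_convnet <- function(spec) {
  assert_that(inherits(spec, "convnet_spec"), "`spec` must be a convnet_spec")
  if (isTRUE(spec$pretrained)) {
    stop("pretrained backbone weights are not bundled with this package; ",
         "use pretrained = FALSE for randomly initialized backbones",
         call. = FALSE)
  }
  bb <- build_backbone(spec$backbone_id)
  head <- build_head(bb$feature_dim, spec)
  structure(list(features = bb$features, head = head,
                 feature_dim = bb$feature_dim, spec = spec),
            class = "convnet_model")
}

# Features of one normalized channel-first (C, H, W) tensor.
convnet_features <- function(model, x, training = FALSE) {
  layer_forward(model$features, aperm(x, c(2, 3, 1)), training)
}

#' Predict with a ConvNet model
#'
#' @param object A `convnet_model`.
#' @param images List of normalized channel-first tensors (see
#'   [normalize_for_backbone()]).
#' @param ... Unused.
#' @return Matrix of predictions, one row per image, `n_tasks` columns.
#' @export
predict.convnet_model <- function(object, images, ...) {
  feats <- t(vapply(images, function(x) convnet_features(object, x),
                    numeric(object$feature_dim)))
  layer_forward(object$head, feats, training = FALSE)
}

#' Fully-connected network specification
#'
#' Three hidden layers of 60, 20 and 10 rectified-linear units with 10%
#' dropout, then a single linear output — the fingerprint-based baseline
#' network.
#'
#' @param input_dim Fingerprint length; one of 128, 256, 512, 1024, 2048.
#' @param hidden_widths Hidden layer widths.
#' @param dropout Dropout rate on the hidden layers.
#' @return An object of class `dnn_spec`.
#' @export
dnn_spec <- function(input_dim, hidden_widths = c(60L, 20L, 10L),
                     dropout = 0.1) {
  assert_that(input_dim %in% c(128, 256, 512, 1024, 2048),
              "input_dim must be one of 128, 256, 512, 1024, 2048")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = as.integer(hidden_widths),
                 dropout = dropout),
            class = "dnn_spec")
}

#' Build a fully-connected regression network
#'
#' @param spec A [dnn_spec()].
#' @return An object of class `dnn_model` (single task).
#' @export
build_dnn <- function(spec) {
  assert_that(inherits(spec, "dnn_spec"), "`spec` must be a dnn_spec")
  widths <- c(spec$input_dim, spec$hidden_widths)
  layers <- list()
  for (i in seq_len(length(widths) - 1)) {
    layers <- c(layers, list(nn_linear(widths[i], widths[i + 1]),
                             nn_relu(), nn_dropout(spec$dropout)))
  }
  layers <- c(layers, list(nn_linear(widths[length(widths)], 1L)))
  structure(list(features = NULL, head = nn_sequential(layers), spec = spec),
            class = "dnn_model")
}

#' @export
predict.dnn_model <- function(object, x, ...) {
  drop(layer_forward(object$head, x, training = FALSE))
}

#' Random Forest specification and construction
#'
#' A regression forest with 100 trees and library defaults otherwise.
#'
#' @param n_trees Number of trees (default 100).
#' @return An object of class `rf_spec`.
#' @export
rf_spec <- function(n_trees = 100L) {
  assert_that(n_trees >= 1, "n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees)), class = "rf_spec")
}

#' @rdname rf_spec
#' @param spec An `rf_spec`.
#' @param seed Integer seed fixing the forest's randomness.
#' @return `build_rf` returns an unfitted `rf_model` handle.
#' @export
build_rf <- function(spec = rf_spec(), seed = 1L) {
  structure(list(spec = spec, seed = as.integer(seed), fit = NULL),
            class = "rf_model")
}

#' @rdname rf_spec
#' @param model An `rf_model`.
#' @param x Covariate matrix (e.g. fingerprints).
#' @param y Numeric response.
#' @return `rf_fit` returns the fitted `rf_model`.
#' @export
rf_fit <- function(model, x, y) {
  assert_that(inherits(model, "rf_model"), "`model` must come from build_rf()")
  model$fit <- with_seed(model$seed, {
    randomForest::randomForest(x, y, ntree = model$spec$n_trees)
  })
  model
}

#' @export
predict.rf_model <- function(object, x, ...) {
  assert_that(!is.null(object$fit), "model has not been fitted; call rf_fit()")
  unname(stats::predict(object$fit, x))
}
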