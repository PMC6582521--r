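# Optimization schedule, training loops for the three model families,
# and grid search over the tuning table.

#' Optimization schedule specification
#'
#' Stochastic gradient descent with Nesterov momentum under a cyclic
#' step-decay learning-rate schedule: within each cycle of
#' `cycle_length` epochs the rate is `lr0 * decay_rate^floor(e / anneal_step)`
#' (e counted from the cycle start), and it resets to `lr0` at every
#' cycle boundary. Early stopping tracks the globally best validation
#' RMSE regardless of cycle boundaries, and the returned model is the
#' best-validation checkpoint.
#'
#' @param lr0 Initial learning rate.
#' @param decay_rate Multiplicative decay per annealing step (in (0, 1)).
#' @param anneal_step Epochs between decays.
#' @param cycle_length Epochs per annealing cycle (default 200).
#' @param momentum Nesterov momentum coefficient, constant (default 0.9).
#' @param batch_size Mini-batch size.
#' @param max_epochs Training horizon (default 600).
#' @param early_stop_patience Epochs without validation improvement
#'   before stopping (default 250).
#' @param augmentation Apply stochastic image augmentation each epoch.
#' @return An object of class `optim_spec`.
#' @export
optim_spec <- function(lr0 = 0.01, decay_rate = 0.1, anneal_step = 10L,
                       cycle_length = 200L, momentum = 0.9,
                       batch_size = 16L, max_epochs = 600L,
                       early_stop_patience = 250L, augmentation = FALSE) {
  assert_that(lr0 >= 0, "lr0 must be >= 0")
  assert_that(decay_rate > 0 && decay_rate < 1,
              "decay_rate must lie in (0, 1)")
  assert_that(anneal_step < cycle_length,
              "anneal_step must be smaller than cycle_length")
  assert_that(early_stop_patience <= max_epochs,
              "early_stop_patience must not exceed max_epochs")
  structure(list(lr0 = lr0, decay_rate = decay_rate,
                 anneal_step = as.integer(anneal_step),
                 cycle_length = as.integer(cycle_length),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 augmentation = isTRUE(augmentation)),
            class = "optim_spec")
}

#' Learning rate at a given epoch
#'
#' Closed form of the cyclic step-decay schedule:
#' `lr0 * decay_rate^floor((epoch %% cycle_length) / anneal_step)`,
#' with `epoch` counted from 0.
#'
#' @param epoch Non-negative integer epoch (0-based); vectorized.
#' @param spec An [optim_spec()].
#' @return Numeric learning rate(s).
#' @export
lr_at <- function(epoch, spec) {
  assert_that(all(epoch >= 0), "epoch must be >= 0")
  spec$lr0 * spec$decay_rate ^
    floor((epoch %% spec$cycle_length) / spec$anneal_step)
}

masked_rmse <- function(pred, obs) {
  m <- is.finite(obs)
  sqrt(sum((pred[m] - obs[m])^2) / sum(m))
}

# Generic SGD loop with validation-based checkpointing and early
# stopping. `train_step(idx, lr)` performs one optimizer update and
# returns the batch loss; `validate()` returns validation RMSE in eval
# mode; `nets` are the containers whose parameters are checkpointed.
run_sgd <- function(nets, train_step, validate, n_train, optim) {
  # The initial state is a checkpoint candidate too: training that never
  # improves validation RMSE returns the starting model.
  best_val <- validate()
  best_epoch <- 0L
  best_params <- lapply(nets, nn_get_params)
  history <- numeric(0)
  epochs_run <- 0L
  for (e in seq_len(optim$max_epochs) - 1L) {
    lr <- lr_at(e, optim)
    idx <- sample(n_train)
    starts <- seq(1, n_train, by = optim$batch_size)
    for (s in starts) {
      batch <- idx[s:min(s + optim$batch_size - 1, n_train)]
      loss <- train_step(batch, lr)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", e, " (lr = ", lr, ")",
             call. = FALSE)
      }
    }
    v <- validate()
    history <- c(history, v)
    epochs_run <- e + 1L
    if (v < best_val - 1e-12) {
      best_val <- v
      best_epoch <- e
      best_params <- lapply(nets, nn_get_params)
    } else if (e - best_epoch >= optim$early_stop_patience) {
      break
    }
  }
  if (!is.null(best_params)) {
    for (i in seq_along(nets)) nn_set_params(nets[[i]], best_params[[i]])
  }
  list(epochs_run = epochs_run, best_val = best_val,
       best_epoch = best_epoch, history = history)
}

# Assemble the common result object from test-split predictions.
new_run_result <- function(dataset, pred, obs, split, target_ids,
                           rmse_val, epochs_run, seed, model_id,
                           batch_size = NA, augmentation = NA) {
  test_ids <- names(split)[split == "test"]
  pred_df <- data.frame(
    compound_id = rep(rownames(pred), ncol(pred)),
    target_id = rep(target_ids, each = nrow(pred)),
    observed = as.vector(obs),
    predicted = as.vector(pred),
    split = rep(split[rownames(pred)], ncol(pred)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  pred_df <- pred_df[is.finite(pred_df$observed), , drop = FALSE]
  te <- pred_df[pred_df$split == "test", , drop = FALSE]
  rmse_by_task <- vapply(split(te, te$target_id), function(d) {
    rmse(d$observed, d$predicted)
  }, numeric(1))
  cor_safe <- function(f) tryCatch(f(te$observed, te$predicted),
                                   error = function(e) NA_real_)
  structure(list(
    dataset_id = dataset$dataset_id, model_id = model_id,
    batch_size = batch_size, augmentation = augmentation,
    predictions = pred_df,
    rmse_test = rmse(te$observed, te$predicted),
    rmse_test_by_task = rmse_by_task,
    rmse_val = rmse_val,
    r2 = cor_safe(r_squared), pearson_r = cor_safe(pearson_r),
    residuals = stats::setNames(te$observed - te$predicted,
                                paste(te$compound_id, te$target_id, sep = ":")),
    epochs_run = epochs_run, seed = seed
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("Run [", x$model_id, "] on '", x$dataset_id, "': test RMSE ",
      round(x$rmse_test, 4), ", val RMSE ",
      if (is.na(x$rmse_val)) "NA" else round(x$rmse_val, 4),
      ", epochs ", x$epochs_run, "\n", sep = "")
  invisible(x)
}

check_images <- function(images, compounds) {
  if (is.data.frame(images)) images <- load_rendered(images)
  missing <- setdiff(compounds, names(images))
  assert_that(length(missing) == 0,
              paste("no rendered image for compound(s):",
                    paste(utils::head(missing, 5), collapse = ", ")))
  images[compounds]
}

#' Train a ConvNet regressor
#'
#' Minimizes mean squared error over the training split with SGD and
#' Nesterov momentum under the cyclic learning-rate schedule, monitors
#' validation RMSE each epoch, keeps the best-validation checkpoint and
#' stops early when validation has not improved for
#' `optim$early_stop_patience` epochs. With a frozen backbone, features
#' are extracted once (for all eight dihedral image variants when
#' augmentation is on) and only the head is optimized; otherwise all
#' layers are updated. Multi-task labels may be partially missing:
#' unobserved (compound, task) pairs contribute exactly zero loss and
#' gradient.
#'
#' @param dataset A split [bioactivity_dataset()].
#' @param images Named list of 8-bit `(H, W, 3)` pixel arrays keyed by
#'   compound id, or a manifest data frame from [render_library()].
#' @param conv_spec A [convnet_spec()]; `n_tasks` must equal the number
#'   of targets in `dataset`.
#' @param optim An [optim_spec()].
#' @param seed Integer seed covering weight init, batching, dropout and
#'   augmentation.
#' @param model_id Label recorded in the result.
#' @return A `run_result` with test-split predictions from the
#'   best-validation checkpoint.
#' @export
train_convnet <- function(dataset, images, conv_spec = convnet_spec(),
                          optim = optim_spec(), seed = 1L,
                          model_id = NULL) {
  split <- split_of(dataset)
  assert_that(all(c("train", "validation", "test") %in% split),
              "split has an empty part")
  y <- labels_matrix(dataset)
  assert_that(ncol(y) == conv_spec$n_tasks,
              "conv_spec$n_tasks must match the number of targets")
  for (t in dataset$target_ids) {
    if (!any(is.finite(y[split == "train", t]))) {
      stop("task '", t, "' has no observed training labels", call. = FALSE)
    }
  }
  images <- check_images(images, dataset$compounds)
  model_id <- model_id %||% paste0(conv_spec$backbone_id,
                                   if (conv_spec$head == "extended") "-ext")
  model <- with_seed(derive_seed(seed, "weights"), build_convnet(conv_spec))

  tr <- which(split == "train")
  va <- which(split == "validation")
  te <- which(split == "test")

  fit <- with_seed(derive_seed(seed, "train"), {
    if (conv_spec$freeze_backbone) {
      train_convnet_frozen(model, images, y, tr, va, optim)
    } else {
      train_convnet_full(model, images, y, tr, va, optim)
    }
  })

  pred <- if (conv_spec$freeze_backbone) {
    layer_forward(model$head, fit$eval_feats, training = FALSE)
  } else {
    stats::predict(model, lapply(images, normalize_for_backbone))
  }
  rownames(pred) <- dataset$compounds
  new_run_result(dataset, pred, y, split, dataset$target_ids,
                 rmse_val = fit$best_val, epochs_run = fit$epochs_run,
                 seed = seed, model_id = model_id,
                 batch_size = optim$batch_size,
                 augmentation = optim$augmentation)
}

# Frozen-backbone path: extract features once, train the head on them.
# Features are standardized with training-split statistics — with a
# fixed backbone the head is a plain regression on random features, and
# SGD needs the conditioning.
train_convnet_frozen <- function(model, images, y, tr, va, optim) {
  standardize <- NULL
  feats_of <- function(imgs) {
    f <- t(vapply(imgs, function(px) {
      convnet_features(model, normalize_for_backbone(px))
    }, numeric(model$feature_dim)))
    if (is.null(standardize)) {
      mu <- colMeans(f[tr, , drop = FALSE])
      sdv <- apply(f[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv < 1e-8] <- 1
      standardize <<- function(m) sweep(sweep(m, 2, mu), 2, sdv, "/")
    }
    standardize(f)
  }
  if (optim$augmentation) {
    variants <- dihedral_transforms()
    feat_bank <- lapply(variants, function(f) feats_of(lapply(images, f)))
    feats <- feat_bank[["identity"]]
    policy <- augmentation_policy()
    sample_feats <- function(idx) {
      rows <- vapply(idx, function(i) {
        d <- draw_augmentation(policy)
        key <- dihedral_key(function(x) apply_augmentation(x, d))
        keyi <- which(vapply(names(variants), function(nm) {
          dihedral_key(variants[[nm]]) == key
        }, logical(1)))
        keyi[1]
      }, numeric(1))
      m <- matrix(0, length(idx), model$feature_dim)
      for (j in seq_along(idx)) m[j, ] <- feat_bank[[rows[j]]][idx[j], ]
      m
    }
  } else {
    feats <- feats_of(images)
    sample_feats <- function(idx) feats[idx, , drop = FALSE]
  }
  res <- train_head_on_features(model$head, sample_feats, feats, y, tr, va,
                                optim)
  res$eval_feats <- feats
  res
}

# Shared head/MLP optimization on (possibly epoch-resampled) features.
# The output layer's bias is warm-started at the training-mean label per
# task, so optimization starts from the null (mean-predictor) model and
# validation-based checkpointing can only improve on it.
train_head_on_features <- function(head, sample_feats, eval_feats, y,
                                   tr, va, optim) {
  leaves <- collect_layers(head)
  out_layer <- leaves[[length(leaves)]]
  out_layer$W[] <- 0
  out_layer$b <- colMeans(y[tr, , drop = FALSE], na.rm = TRUE)
  opt <- sgd_optimizer(optim$momentum)
  train_step <- function(idx, lr) {
    X <- sample_feats(tr[idx])
    yb <- y[tr[idx], , drop = FALSE]
    mask <- is.finite(yb)
    nn_zero_grad(head)
    pred <- layer_forward(head, X, training = TRUE)
    err <- pred - yb
    err[!mask] <- 0
    loss <- sum(err^2) / sum(mask)
    layer_backward(head, 2 * err / sum(mask))
    opt$step(head, lr)
    loss
  }
  validate <- function() {
    pv <- layer_forward(head, eval_feats[va, , drop = FALSE],
                        training = FALSE)
    masked_rmse(pv, y[va, , drop = FALSE])
  }
  run_sgd(list(head), train_step, validate, length(tr), optim)
}

# Full path: every layer updated; images stream through one at a time
# (gradients over a mini-batch are accumulated, so the update equals the
# batched one).
train_convnet_full <- function(model, images, y, tr, va, optim) {
  policy <- augmentation_policy(enabled = optim$augmentation)
  leaves <- collect_layers(model$head)
  leaves[[length(leaves)]]$W[] <- 0
  leaves[[length(leaves)]]$b <- colMeans(y[tr, , drop = FALSE], na.rm = TRUE)
  opt <- sgd_optimizer(optim$momentum)
  nets <- list(model$features, model$head)
  train_step <- function(idx, lr) {
    gi <- tr[idx]
    yb <- y[gi, , drop = FALSE]
    mask <- is.finite(yb)
    n_obs <- sum(mask)
    for (n in nets) nn_zero_grad(n)
    loss <- 0
    for (j in seq_along(gi)) {
      px <- images[[gi[j]]]
      if (optim$augmentation) px <- augment_image(px, policy)
      f <- convnet_features(model, normalize_for_backbone(px),
                            training = TRUE)
      pred <- layer_forward(model$head, matrix(f, 1), training = TRUE)
      err <- pred - yb[j, ]
      err[!mask[j, ]] <- 0
      loss <- loss + sum(err^2)
      dfeat <- layer_backward(model$head, 2 * err / n_obs)
      layer_backward(model$features, as.vector(dfeat))
    }
    for (n in nets) opt$step(n, lr)
    loss / n_obs
  }
  validate <- function() {
    pv <- stats::predict(model,
                         lapply(images[va], normalize_for_backbone))
    masked_rmse(pv, y[va, , drop = FALSE])
  }
  run_sgd(nets, train_step, validate, length(tr), optim)
}

#' Train the fingerprint-based fully-connected network
#'
#' Same loop contract as [train_convnet()] with the baseline-network
#' defaults: 2000 epochs maximum, early-stopping patience 200, and
#' mini-batches of 15% of the training-set size (`ceiling(0.15 n)`).
#'
#' @param dataset A split [bioactivity_dataset()] with a single target.
#' @param spec A [dnn_spec()]; fingerprints are computed at
#'   `spec$input_dim` bits.
#' @param seed Integer seed.
#' @param optim Optional [optim_spec()] override; `batch_size` is always
#'   recomputed from the 15% rule.
#' @param radius Fingerprint radius.
#' @return A `run_result`.
#' @export
train_dnn <- function(dataset, spec = dnn_spec(2048), seed = 1L,
                      optim = optim_spec(max_epochs = 2000L,
                                         early_stop_patience = 200L),
                      radius = 2) {
  split <- split_of(dataset)
  assert_that(length(dataset$target_ids) == 1,
              "train_dnn expects a single-target dataset")
  y <- labels_matrix(dataset)
  smi <- compound_smiles(dataset)
  fp <- fingerprint_matrix(unname(smi), radius = radius,
                           n_bits = spec$input_dim)
  rownames(fp) <- names(smi)
  fp <- fp[dataset$compounds, , drop = FALSE]

  tr <- which(split == "train")
  va <- which(split == "validation")
  optim$batch_size <- as.integer(ceiling(0.15 * length(tr)))

  model <- with_seed(derive_seed(seed, "weights"), build_dnn(spec))
  fit <- with_seed(derive_seed(seed, "train"), {
    train_head_on_features(model$head,
                           function(idx) fp[idx, , drop = FALSE] * 1.0,
                           fp * 1.0, y, tr, va, optim)
  })
  pred <- matrix(stats::predict(model, fp * 1.0), ncol = 1,
                 dimnames = list(dataset$compounds, dataset$target_ids))
  new_run_result(dataset, pred, y, split, dataset$target_ids,
                 rmse_val = fit$best_val, epochs_run = fit$epochs_run,
                 seed = seed, model_id = paste0("dnn", spec$input_dim),
                 batch_size = optim$batch_size, augmentation = FALSE)
}

#' Train the Random Forest baseline
#'
#' Fits a 100-tree regression forest on training-split fingerprints and
#' predicts the test split. The validation split is deliberately unused
#' (the forest has no tuned parameters) but kept in the split so all
#' model families see identical test sets.
#'
#' @param dataset A split [bioactivity_dataset()] with a single target.
#' @param spec An [rf_spec()].
#' @param fp_bits Fingerprint length (default 2048).
#' @param seed Integer seed.
#' @param radius Fingerprint radius.
#' @return A `run_result` (with `rmse_val = NA`).
#' @export
train_rf <- function(dataset, spec = rf_spec(), fp_bits = 2048, seed = 1L,
                     radius = 2) {
  split <- split_of(dataset)
  assert_that(length(dataset$target_ids) == 1,
              "train_rf expects a single-target dataset")
  y <- labels_matrix(dataset)
  smi <- compound_smiles(dataset)
  fp <- fingerprint_matrix(unname(smi), radius = radius, n_bits = fp_bits)
  rownames(fp) <- names(smi)
  fp <- fp[dataset$compounds, , drop = FALSE]

  tr <- which(split == "train")
  model <- build_rf(spec, seed = derive_seed(seed, "rf"))
  model <- rf_fit(model, fp[tr, , drop = FALSE], y[tr, 1])
  pred <- matrix(stats::predict(model, fp), ncol = 1,
                 dimnames = list(dataset$compounds, dataset$target_ids))
  new_run_result(dataset, pred, y, split, dataset$target_ids,
                 rmse_val = NA_real_, epochs_run = NA_integer_,
                 seed = seed, model_id = paste0("rf", fp_bits),
                 batch_size = NA, augmentation = FALSE)
}

#' Train a multi-task ConvNet
#'
#' Wrapper over [train_convnet()] for datasets with two or more targets:
#' the loss averages squared errors over observed (compound, task) pairs
#' only, and per-task test RMSEs are reported in `rmse_test_by_task`.
#'
#' @inheritParams train_convnet
#' @return A `run_result` with per-task test RMSE.
#' @export
train_multitask <- function(dataset, images,
                            conv_spec = convnet_spec(n_tasks = 2),
                            optim = optim_spec(), seed = 1L,
                            model_id = NULL) {
  assert_that(length(dataset$target_ids) >= 2,
              "multi-task training needs >= 2 targets")
  train_convnet(dataset, images, conv_spec, optim, seed,
                model_id = model_id %||%
                  paste0(conv_spec$backbone_id, "-multitask"))
}

#' The tuning-table grid
#'
#' Full crossing of the tuned training parameters: learning rate
#' {0.1, 0.01, 0.005, 0.001, 0.0001}, decay rate {0.1, 0.6}, annealing
#' step {10, 25}, augmentation {no, yes}, batch size {4, 16, 32} — 120
#' configurations, enumerated with learning rate varying slowest and
#' batch size fastest.
#'
#' @param lr,decay,step,augmentation,batch Level sets to cross.
#' @return Data frame of configurations in enumeration order.
#' @export
tuning_grid <- function(lr = c(0.1, 0.01, 0.005, 0.001, 0.0001),
                        decay = c(0.1, 0.6),
                        step = c(10L, 25L),
                        augmentation = c(FALSE, TRUE),
                        batch = c(4L, 16L, 32L)) {
  g <- expand.grid(batch = batch, augmentation = augmentation, step = step,
                   decay = decay, lr = lr, KEEP.OUT.ATTRS = FALSE)
  g[, c("lr", "decay", "step", "augmentation", "batch")]
}

#' Grid search over training configurations
#'
#' Trains one model per grid row and selects the configuration with the
#' lowest validation RMSE; ties go to the earlier row in enumeration
#' order.
#'
#' @inheritParams train_convnet
#' @param grid Data frame with columns `lr`, `decay`, `step`,
#'   `augmentation`, `batch` (see [tuning_grid()]).
#' @param base_optim An [optim_spec()] providing the non-tuned fields.
#' @return A list with `best_optim`, `best_index`, and `results` (a list
#'   of `run_result`s parallel to the grid rows).
#' @export
grid_search <- function(dataset, images, conv_spec = convnet_spec(),
                        grid = tuning_grid(), seed = 1L,
                        base_optim = optim_spec()) {
  assert_that(nrow(grid) >= 1, "grid must be non-empty")
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    o <- base_optim
    o$lr0 <- grid$lr[i]
    o$decay_rate <- grid$decay[i]
    o$anneal_step <- as.integer(grid$step[i])
    o$augmentation <- isTRUE(grid$augmentation[i])
    o$batch_size <- as.integer(grid$batch[i])
    # one derived seed for every grid point: configurations differ only
    # by their tuned values, and exact-duplicate rows tie exactly
    results[[i]] <- train_convnet(dataset, images, conv_spec, o,
                                  seed = derive_seed(seed, "grid"))
  }
  vals <- vapply(results, `[[`, numeric(1), "rmse_val")
  best <- which.min(vals)  # which.min takes the first minimum: tie rule
  o <- base_optim
  o$lr0 <- grid$lr[best]
  o$decay_rate <- grid$decay[best]
  o$anneal_step <- as.integer(grid$step[best])
  o$augmentation <- isTRUE(grid$augmentation[best])
  o$batch_size <- as.integer(grid$batch[best])
  list(best_optim = o, best_index = best, grid = grid, results = results)
}
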