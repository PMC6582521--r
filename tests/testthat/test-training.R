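# Splitting, the learning-rate schedule, the training loops for the
# three model families, multi-task masking, and grid search.

test_that("splits follow the 70/15/15 rounding rule and are seeded", {
  recs <- function(n) data.frame(
    compound_id = sprintf("C%03d", 1:n), canonical_smiles = "CCO",
    target_id = "T1", pIC50 = 6, stringsAsFactors = FALSE)
  ds100 <- split_dataset(bioactivity_dataset(recs(100)), seed = 7)
  tb <- table(factor(ds100$split, c("train", "validation", "test")))
  expect_identical(as.integer(tb), c(70L, 15L, 15L))

  ds101 <- split_dataset(bioactivity_dataset(recs(101)), seed = 7)
  tb <- table(factor(ds101$split, c("train", "validation", "test")))
  expect_identical(as.integer(tb), c(70L, 15L, 16L))

  again <- split_dataset(bioactivity_dataset(recs(101)), seed = 7)
  expect_identical(again$split, ds101$split)
  other <- split_dataset(bioactivity_dataset(recs(101)), seed = 8)
  expect_false(identical(other$split, ds101$split))

  expect_error(split_dataset(bioactivity_dataset(recs(9)), 1),
               "at least 10")
})

test_that("lr_at has the closed form, the cycle reset, and monotone cycles", {
  s <- optim_spec(lr0 = 0.01, decay_rate = 0.1, anneal_step = 10L)
  expect_equal(lr_at(0, s), 0.01)
  expect_equal(lr_at(10, s), 0.001)
  expect_equal(lr_at(25, s), 1e-4)
  expect_equal(lr_at(199, s), 0.01 * 0.1^19)
  expect_equal(lr_at(200, s), 0.01)  # cycle boundary resets to lr0

  # periodic with period cycle_length; non-increasing within a cycle
  e <- 0:399
  expect_equal(lr_at(e, s), lr_at(e + 200, s))
  within <- lr_at(0:199, s)
  expect_true(all(diff(within) <= 0))
})

test_that("optim_spec enforces its invariants", {
  expect_error(optim_spec(decay_rate = 1.5), "decay_rate")
  expect_error(optim_spec(anneal_step = 300), "anneal_step")
  expect_error(optim_spec(max_epochs = 10, early_stop_patience = 20),
               "early_stop_patience")
})

test_that("zero learning rate with patience 1 stops after two epochs, unchanged", {
  fx <- tiny_imaged_dataset()
  o <- optim_spec(lr0 = 0, decay_rate = 0.1, anneal_step = 10,
                  batch_size = 8, max_epochs = 50, early_stop_patience = 1)
  r <- train_convnet(fx$ds, fx$images,
                     convnet_spec("alexnet", freeze_backbone = TRUE),
                     o, seed = 3)
  expect_equal(r$epochs_run, 2L)
  # warm-started null model: every prediction is the training-mean label
  split <- fx$ds$split[fx$ds$compounds]
  y <- molimage:::labels_matrix(fx$ds)
  expect_equal(unique(round(r$predictions$predicted, 10)),
               round(mean(y[split == "train", 1]), 10))
})

test_that("frozen backbones are bit-identical before and after training", {
  fx <- tiny_imaged_dataset()
  spec <- convnet_spec("alexnet", freeze_backbone = TRUE)
  model <- molimage:::with_seed(molimage:::derive_seed(5, "weights"),
                                build_convnet(spec))
  before <- molimage:::nn_get_params(model$features)
  o <- optim_spec(lr0 = 3e-5, batch_size = 8, max_epochs = 3,
                  early_stop_patience = 3)
  r <- train_convnet(fx$ds, fx$images, spec, o, seed = 5)
  model2 <- molimage:::with_seed(molimage:::derive_seed(5, "weights"),
                                 build_convnet(spec))
  expect_identical(molimage:::nn_get_params(model2$features), before)
})

test_that("full (unfrozen) training fits a constant-label dataset", {
  fx <- tiny_imaged_dataset()
  ds <- fx$ds
  ds$records$pIC50 <- 6.0
  o <- optim_spec(lr0 = 1e-4, batch_size = 8, max_epochs = 5,
                  early_stop_patience = 5)
  r <- train_convnet(ds, fx$images, convnet_spec("alexnet"), o, seed = 2)
  expect_lt(r$rmse_test, 0.2)
})

test_that("the fingerprint network uses the 15% batch rule and learns", {
  expect_equal(ceiling(0.15 * 700), 105)
  ds <- medium_dataset()
  o <- optim_spec(lr0 = 0.005, decay_rate = 0.1, anneal_step = 50,
                  cycle_length = 200, max_epochs = 300,
                  early_stop_patience = 100)
  r <- train_dnn(ds, dnn_spec(2048), seed = 4, optim = o)
  n_train <- sum(ds$split == "train")
  expect_equal(r$batch_size, as.integer(ceiling(0.15 * n_train)))
  expect_lt(r$rmse_test, mean_predictor_rmse(ds))
})

test_that("the random forest recovers the planted substructure signal", {
  ds <- medium_dataset()
  r <- train_rf(ds, seed = 9)
  mp <- mean_predictor_rmse(ds)
  expect_lt(r$rmse_test, 0.6 * mp)
  expect_true(is.na(r$rmse_val))  # validation deliberately unused
  # same seed/data reproduce the identical result
  r2 <- train_rf(ds, seed = 9)
  expect_identical(r$predictions, r2$predictions)
  # in-sample fit is at least as good as out-of-sample
  tr_pred <- r$predictions[r$predictions$split == "train", ]
  expect_lte(rmse(tr_pred$observed, tr_pred$predicted), r$rmse_test)
})

test_that("multi-task training masks missing labels and mirrors tasks", {
  fx <- tiny_imaged_dataset()
  rec <- fx$ds$records
  rec2 <- rec
  rec2$target_id <- "T2"
  # drop some T2 labels so the mask is exercised
  rec2 <- rec2[seq_len(nrow(rec2)) %% 4 != 0, , drop = FALSE]
  ds2 <- bioactivity_dataset(rbind(rec, rec2), split = fx$ds$split,
                             dataset_id = "twintask")
  o <- optim_spec(lr0 = 3e-5, batch_size = 8, max_epochs = 10,
                  early_stop_patience = 10)
  r <- train_multitask(ds2, fx$images,
                       convnet_spec("alexnet", n_tasks = 2,
                                    freeze_backbone = TRUE),
                       o, seed = 6)
  expect_named(r$rmse_test_by_task, c("T1", "T2"))
  # task 2 duplicates task 1: per-task errors agree closely
  expect_lt(abs(r$rmse_test_by_task[["T1"]] - r$rmse_test_by_task[["T2"]]),
            0.1)
  # a task with no training labels at all is an error
  rec3 <- rec2[fx$ds$split[rec2$compound_id] == "test", , drop = FALSE]
  ds3 <- bioactivity_dataset(rbind(rec, rec3), split = fx$ds$split)
  expect_error(train_multitask(ds3, fx$images,
                               convnet_spec("alexnet", n_tasks = 2,
                                            freeze_backbone = TRUE),
                               o, seed = 6),
               "no observed training labels")
})

test_that("the tuning grid enumerates 120 configurations in stated order", {
  g <- tuning_grid()
  expect_equal(nrow(g), 5 * 2 * 2 * 2 * 3)
  expect_equal(nrow(unique(g)), 120)
  # learning rate varies slowest, batch fastest
  expect_equal(g$lr[1:24], rep(0.1, 24))
  expect_equal(g$batch[1:3], c(4L, 16L, 32L))
})

test_that("grid search selects by validation RMSE with first-wins ties", {
  fx <- tiny_imaged_dataset()
  base <- optim_spec(max_epochs = 3, early_stop_patience = 3)
  one <- tuning_grid(lr = 3e-5, decay = 0.1, step = 10,
                     augmentation = FALSE, batch = 8)
  gs1 <- grid_search(fx$ds, fx$images,
                     convnet_spec("alexnet", freeze_backbone = TRUE),
                     grid = one, seed = 2, base_optim = base)
  expect_equal(gs1$best_index, 1L)
  expect_equal(gs1$best_optim$lr0, 3e-5)

  # two identical configurations tie exactly; the first wins
  two <- rbind(one, one)
  gs2 <- grid_search(fx$ds, fx$images,
                     convnet_spec("alexnet", freeze_backbone = TRUE),
                     grid = two, seed = 2, base_optim = base)
  expect_equal(gs2$results[[1]]$rmse_val, gs2$results[[2]]$rmse_val)
  expect_equal(gs2$best_index, 1L)
})

test_that("augmented frozen training draws features from the dihedral bank", {
  fx <- tiny_imaged_dataset()
  o <- optim_spec(lr0 = 3e-5, batch_size = 8, max_epochs = 3,
                  early_stop_patience = 3, augmentation = TRUE)
  r <- train_convnet(fx$ds, fx$images,
                     convnet_spec("alexnet", freeze_backbone = TRUE),
                     o, seed = 12)
  expect_true(is.finite(r$rmse_test))
  # reproducible under the same seed
  r2 <- train_convnet(fx$ds, fx$images,
                      convnet_spec("alexnet", freeze_backbone = TRUE),
                      o, seed = 12)
  expect_equal(r$predictions$predicted, r2$predictions$predicted)
})
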