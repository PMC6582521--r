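# Presets and end-to-end orchestration of the modelling workflow:
# synthetic library -> curation -> rendering -> split -> models ->
# ensemble -> Y-scrambling -> factorial comparison.

#' Training presets
#'
#' `"full"` reproduces the benchmark-scale schedule (600 epochs,
#' patience 250, unfrozen backbone). `"ci"` is the desk-scale profile:
#' frozen backbone (features extracted once), 30 epochs, patience 10,
#' batch 16, no augmentation, so the whole pipeline runs on one CPU in
#' minutes.
#'
#' @param preset `"full"` or `"ci"`.
#' @return An [optim_spec()].
#' @export
preset_optim <- function(preset = c("ci", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    optim_spec(lr0 = 0.01, decay_rate = 0.1, anneal_step = 10L,
               batch_size = 16L, max_epochs = 600L,
               early_stop_patience = 250L)
  } else {
    optim_spec(lr0 = 3e-5, decay_rate = 0.1, anneal_step = 10L,
               batch_size = 16L, max_epochs = 30L,
               early_stop_patience = 10L)
  }
}

#' @rdname preset_optim
#' @param backbone_id Backbone for the ConvNet spec.
#' @return `preset_convnet` returns a [convnet_spec()] (frozen backbone
#'   under `"ci"`).
#' @export
preset_convnet <- function(preset = c("ci", "full"),
                           backbone_id = "alexnet") {
  preset <- match.arg(preset)
  convnet_spec(backbone_id = backbone_id,
               head = if (preset == "full") "extended" else "standard",
               freeze_backbone = preset == "ci")
}

#' Run the desk-scale end-to-end pipeline
#'
#' Generates a synthetic SAR library, curates it, renders the compound
#' images, assigns a 70/15/15 split, trains the Random Forest baseline
#' and a frozen-backbone ConvNet, ensembles the two, repeats the ConvNet
#' run on Y-scrambled labels, and fits a factorial model on a planted
#' synthetic run table. Every stage is seeded from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_compounds Library size (default 200).
#' @param dir Working directory for images (default: a temp dir).
#' @param backbone_id Backbone for the image model.
#' @return A list with the trained `run_result`s, the ensemble, the
#'   scrambled-run R-squared, the mean-predictor RMSE and the factorial
#'   fit.
#' @export
run_desk_pipeline <- function(seed = 1L, n_compounds = 200L,
                              dir = tempfile("molimage-"),
                              backbone_id = "alexnet") {
  cfg <- synthetic_sar_config(n_compounds = n_compounds,
                              seed = derive_seed(seed, "library"))
  lib <- generate_library(cfg)
  cur <- curate_activities(lib$activities)
  ds <- as_bioactivity_dataset(cur, dataset_id = "synthetic")
  ds <- split_dataset(ds, seed = derive_seed(seed, "split"))

  smi <- compound_smiles(ds)
  manifest <- render_library(smi, file.path(dir, "images"))
  images <- load_rendered(manifest)

  rf_run <- train_rf(ds, seed = derive_seed(seed, "rf"))
  conv_run <- train_convnet(ds, images,
                            conv_spec = preset_convnet("ci", backbone_id),
                            optim = preset_optim("ci"),
                            seed = derive_seed(seed, "conv"))

  test_pred <- function(run) {
    te <- run$predictions[run$predictions$split == "test", ]
    stats::setNames(te$predicted, te$compound_id)
  }
  te <- conv_run$predictions[conv_run$predictions$split == "test", ]
  obs <- stats::setNames(te$observed, te$compound_id)
  ens <- ensemble_average(test_pred(conv_run), test_pred(rf_run), obs)

  scr_ds <- y_scramble(ds, seed = derive_seed(seed, "scramble"))
  scr_run <- train_convnet(scr_ds, images,
                           conv_spec = preset_convnet("ci", backbone_id),
                           optim = preset_optim("ci"),
                           seed = derive_seed(seed, "conv"))

  rt <- generate_run_table(
    levels = list(dataset = paste0("D", 1:4),
                  model = c("alexnet", "alexnet-ext", "vgg19bn",
                            "vgg19bn-ext"),
                  batch = c("4", "16", "32"),
                  augmentation = c("0", "1")),
    effects = list(model = c("alexnet-ext" = -0.05, "vgg19bn" = -0.03,
                             "vgg19bn-ext" = -0.08),
                   augmentation = c("1" = -0.04),
                   dataset = c(D2 = 0.1, D3 = -0.05, D4 = 0.2)),
    mu0 = 0.9, noise_sd = 0.05, replicates = 3,
    seed = derive_seed(seed, "runtable")
  )
  fact <- fit_main_effects(rt$table,
                           ref_levels = list(dataset = "D1",
                                             model = "alexnet",
                                             batch = "4",
                                             augmentation = "0"))

  # Scrambled training may return an exactly constant predictor (the
  # warm-start null model survives early stopping); squared correlation
  # is then undefined, and a constant predictor has zero association
  # with the observations, so the collapse statistic is 0.
  list(dataset = ds, rf = rf_run, convnet = conv_run, ensemble = ens,
       scrambled = scr_run,
       scrambled_r2 = if (is.na(scr_run$r2)) 0 else scr_run$r2,
       mean_predictor_rmse = mean_predictor_rmse(ds),
       factorial = fact, run_table = rt, manifest = manifest)
}

#' Write a run result to disk
#'
#' Predictions as TSV (`compound_id`, `target_id`, `observed`,
#' `predicted`, `split`) and summary metrics as JSON.
#'
#' @param run A `run_result`.
#' @param dir Output directory.
#' @param prefix File name prefix (default: the run's model id).
#' @return Invisibly, the paths written.
#' @export
write_run_result <- function(run, dir, prefix = run$model_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pred_path <- file.path(dir, paste0(prefix, "_predictions.tsv"))
  utils::write.table(run$predictions, pred_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  metrics <- list(dataset_id = run$dataset_id, model_id = run$model_id,
                  rmse_test = run$rmse_test,
                  rmse_test_by_task = as.list(run$rmse_test_by_task),
                  rmse_val = run$rmse_val, r2 = run$r2,
                  pearson_r = run$pearson_r, epochs_run = run$epochs_run,
                  seed = run$seed)
  met_path <- file.path(dir, paste0(prefix, "_metrics.json"))
  jsonlite::write_json(metrics, met_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(pred_path, met_path))
}

#' Reassemble a dataset from curated CSV and split CSV files
#'
#' @param curated_csv CSV written by [write_curated()].
#' @param split_csv Optional CSV with columns `compound_id`, `split`.
#' @param dataset_id Dataset label.
#' @return A [bioactivity_dataset()].
#' @export
read_dataset <- function(curated_csv, split_csv = NULL,
                         dataset_id = "dataset") {
  rec <- utils::read.csv(curated_csv, stringsAsFactors = FALSE)
  split <- NULL
  if (!is.null(split_csv)) {
    s <- utils::read.csv(split_csv, stringsAsFactors = FALSE)
    split <- stats::setNames(s$split, s$compound_id)
  }
  bioactivity_dataset(rec, split = split, dataset_id = dataset_id)
}

#' @rdname read_dataset
#' @param dataset A split dataset to serialize.
#' @param path Output CSV path.
#' @export
write_split <- function(dataset, path) {
  s <- split_of(dataset)
  utils::write.csv(data.frame(compound_id = names(s), split = unname(s)),
                   path, row.names = FALSE)
  invisible(path)
}
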