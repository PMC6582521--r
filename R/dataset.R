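# The modelling unit: curated records plus a train/validation/test split.

#' Bioactivity dataset
#'
#' Bundles curated records (one row per compound/target pair) with an
#' optional train/validation/test split assignment over compounds.
#'
#' @param records Data frame with columns `compound_id`,
#'   `canonical_smiles`, `target_id`, `pIC50`.
#' @param split Optional named character vector mapping every compound id
#'   to `"train"`, `"validation"` or `"test"`.
#' @param dataset_id Label carried into run results.
#' @return An object of class `bioactivity_dataset`.
#' @export
bioactivity_dataset <- function(records, split = NULL, dataset_id = "dataset") {
  required <- c("compound_id", "canonical_smiles", "target_id", "pIC50")
  missing <- setdiff(required, names(records))
  assert_that(length(missing) == 0,
              paste("records are missing column(s):",
                    paste(missing, collapse = ", ")))
  assert_that(!anyDuplicated(records[c("compound_id", "target_id")]),
              "duplicate (compound_id, target_id) pairs; curate first")
  assert_that(all(is.finite(records$pIC50)), "pIC50 values must be finite")
  compounds <- unique(records$compound_id)
  if (!is.null(split)) {
    assert_that(setequal(names(split), compounds),
                "split must cover exactly the compounds in `records`")
    assert_that(all(split %in% c("train", "validation", "test")),
                "split labels must be train/validation/test")
  }
  structure(list(records = records,
                 target_ids = sort(unique(records$target_id)),
                 compounds = compounds, split = split,
                 dataset_id = dataset_id),
            class = "bioactivity_dataset")
}

#' @export
print.bioactivity_dataset <- function(x, ...) {
  cat("Bioactivity dataset '", x$dataset_id, "': ",
      length(x$compounds), " compounds, ",
      length(x$target_ids), " target(s)", sep = "")
  if (!is.null(x$split)) {
    tb <- table(factor(x$split, c("train", "validation", "test")))
    cat(" | split ", paste(tb, collapse = "/"), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Convert curated activities to a dataset
#'
#' @param curated A `curated_activities` object from [curate_activities()].
#' @param dataset_id Label for the dataset.
#' @return A [bioactivity_dataset()].
#' @export
as_bioactivity_dataset <- function(curated, dataset_id = "dataset") {
  bioactivity_dataset(curated$records, dataset_id = dataset_id)
}

#' Assign a random 70/15/15 split
#'
#' Compounds are partitioned uniformly at random into training (70%),
#' validation (15%) and test (15%) sets, with sizes
#' `floor(0.7 n)` / `floor(0.15 n)` / remainder. The same split is meant
#' to be reused across every model family compared on the dataset.
#'
#' @param dataset A [bioactivity_dataset()].
#' @param seed Integer seed; identical seeds give identical membership.
#' @return The dataset with its `split` field assigned.
#' @export
split_dataset <- function(dataset, seed = 1L) {
  assert_that(inherits(dataset, "bioactivity_dataset"),
              "`dataset` must be a bioactivity_dataset")
  n <- length(dataset$compounds)
  if (n < 10) stop("need at least 10 compounds to split, got ", n,
                   call. = FALSE)
  n_train <- floor(0.70 * n)
  n_val <- floor(0.15 * n)
  with_seed(seed, {
    perm <- sample(dataset$compounds)
    split <- stats::setNames(
      rep(c("train", "validation", "test"),
          c(n_train, n_val, n - n_train - n_val)),
      perm
    )
  })
  dataset$split <- split[dataset$compounds]
  names(dataset$split) <- dataset$compounds
  dataset
}

# Compound x target label matrix (NA = unobserved), plus split lookup.
labels_matrix <- function(dataset) {
  m <- matrix(NA_real_, length(dataset$compounds), length(dataset$target_ids),
              dimnames = list(dataset$compounds, dataset$target_ids))
  r <- dataset$records
  m[cbind(match(r$compound_id, dataset$compounds),
          match(r$target_id, dataset$target_ids))] <- r$pIC50
  m
}

#' Canonical SMILES lookup by compound id
#'
#' @param dataset A [bioactivity_dataset()].
#' @return Named character vector of canonical SMILES, one per compound.
#' @export
compound_smiles <- function(dataset) {
  r <- dataset$records
  s <- r$canonical_smiles[!duplicated(r$compound_id)]
  stats::setNames(s, r$compound_id[!duplicated(r$compound_id)])
}

split_of <- function(dataset) {
  assert_that(!is.null(dataset$split),
              "dataset has no split; call split_dataset() first")
  dataset$split[dataset$compounds]
}
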