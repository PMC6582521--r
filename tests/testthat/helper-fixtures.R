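# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Ten-row toy activity table exercising every curation rule:
# unit filter, relation filter, salt stripping, inorganic rejection,
# parse failure, and replicate averaging.
toy_activity_rows <- function() {
  data.frame(
    compound_id = c("C1", "C2", "C3", "C4", "C5",
                    "C6", "C1", "C8", "C9", "C10"),
    structure = c("CCO", "c1ccccc1", "CCN.Cl", "[Fe+2]", "CCC",
                  "CCCC", "CCO", "CC(=O)O", "not_a_smiles", "CCS"),
    standard_value = c(1000, 100, 10, 50, 1,
                       100, 100, 10000, 100, 200),
    standard_units = c("nM", "nM", "nM", "nM", "ug.mL-1",
                       "nM", "nM", "nM", "nM", "nM"),
    standard_relation = c("=", "=", "=", "=", "=",
                          ">", "=", "=", "=", "="),
    target_id = "T1",
    stringsAsFactors = FALSE
  )
}

# Hand-computed expectation for the toy table:
# C1 kept twice (1000 nM -> 6, 100 nM -> 7, mean 6.5), C2 7.0,
# C3 salt-stripped to CCN (10 nM -> 8), C4 inorganic, C5 unit, C6
# relation, C8 5.0, C9 parse error, C10 9 - log10(200).
toy_expected_records <- function() {
  data.frame(
    compound_id = c("C1", "C10", "C2", "C3", "C8"),
    canonical_smiles = c("CCO", "CCS", "c1ccccc1", "CCN", "CC(=O)O"),
    target_id = "T1",
    pIC50 = c(6.5, 9 - log10(200), 7.0, 8.0, 5.0),
    n_replicates = c(2L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

# A small curated-and-split dataset with rendered images, shared by the
# training tests. 40 compounds, 64-px images for speed.
tiny_imaged_dataset <- function() {
  memo("tiny_imaged", {
    lib <- generate_library(synthetic_sar_config(n_compounds = 40,
                                                 salt_prob = 0, seed = 11))
    ds <- as_bioactivity_dataset(curate_activities(lib$activities), "tiny")
    ds <- split_dataset(ds, seed = 11)
    smi <- stats::setNames(
      ds$records$canonical_smiles[!duplicated(ds$records$compound_id)],
      ds$records$compound_id[!duplicated(ds$records$compound_id)])
    images <- suppressWarnings(
      lapply(smi, function(s) render_kekule(s, size = 64L)$pixels))
    list(ds = ds, images = images)
  })
}

# Medium single-target library used by evaluation/RF tests.
medium_dataset <- function(seed = 21, n = 300) {
  memo(paste0("medium", seed, "_", n), {
    lib <- generate_library(synthetic_sar_config(n_compounds = n,
                                                 seed = seed))
    ds <- as_bioactivity_dataset(curate_activities(lib$activities), "medium")
    split_dataset(ds, seed = seed)
  })
}

# Minimal synthetic run_result for evaluation diagnostics.
fake_run_result <- function(observed, predicted, split = "test") {
  structure(list(
    dataset_id = "fake", model_id = "fake",
    predictions = data.frame(
      compound_id = paste0("X", seq_along(observed)),
      target_id = "T1", observed = observed, predicted = predicted,
      split = split, stringsAsFactors = FALSE),
    rmse_test = rmse(observed, predicted)
  ), class = "run_result")
}
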