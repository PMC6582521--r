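# Synthetic structure-activity data with known ground truth.
#
# The generator emulates the shape of public IC50 collections: an
# imbalanced pIC50 distribution with its mode in the 4-5 band and a long
# right tail of rarer potent compounds, replicate measurements, salt
# forms, and a latent additive substructure-driven activity signal that
# both fingerprint- and image-based models can in principle recover.

default_scaffolds <- function() {
  data.frame(
    name = c("benzene", "pyridine", "naphthalene", "benzamide-piperidine",
             "pyrimidine", "thiophene-phenyl"),
    template = c(
      "c1cc({R1})ccc1{R2}",
      "c1cc({R1})cnc1{R2}",
      "c1cc({R2})c2cc({R1})ccc2c1",
      "O=C(N1CCC({R1})CC1)c1ccc({R2})cc1",
      "c1nc({R1})ncc1{R2}",
      "c1csc({R1})c1-c1ccc({R2})cc1"
    ),
    offset = c(0, 0.15, -0.15, 0.3, 0.05, -0.05),
    weight = rep(1, 6),
    stringsAsFactors = FALSE
  )
}

default_substituents <- function() {
  data.frame(
    name = c("H", "fluoro", "chloro", "methyl", "methoxy", "hydroxy",
             "trifluoromethyl", "dimethylamino", "nitrile", "phenyl",
             "sulfonamide", "carboxamide"),
    fragment = c("", "F", "Cl", "C", "OC", "O",
                 "C(F)(F)F", "N(C)C", "C#N", "c9ccccc9",
                 "S(N)(=O)=O", "C(N)=O"),
    contribution = c(0, 0.05, 0.15, 0.1, 0.25, -0.1,
                     0.35, 0.3, 0.6, 1.3, 2.0, 1.1),
    weight = c(1.5, 1, 1, 1, 1, 1, 0.7, 0.7, 0.6, 0.5, 0.45, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic SAR generator
#'
#' Activity is planted additively on substituents: each generated molecule
#' is a scaffold decorated at two positions, and its noiseless pIC50 is
#' `base_activity + scaffold offset + sum of substituent contributions`.
#' Defaults place the mode of the activity distribution in the 4-5 pIC50
#' band with a right tail produced by a few rarer potent substituents.
#'
#' @param n_compounds Number of molecules to draw from the enumerable
#'   scaffold x substituent x substituent space.
#' @param scaffolds Data frame (`name`, `template`, `offset`, `weight`);
#'   templates carry `{R1}`/`{R2}` attachment markers.
#' @param substituents Data frame (`name`, `fragment`, `contribution`,
#'   `weight`); the empty fragment denotes hydrogen.
#' @param base_activity Baseline pIC50 (default 4.5).
#' @param noise_sd SD of i.i.d. normal measurement noise on pIC50
#'   (default 0.3, the order of inter-assay IC50 reproducibility).
#' @param replicate_prob Probability a compound receives a second,
#'   independently noisy measurement row.
#' @param salt_prob Probability the emitted SMILES carries a counterion
#'   fragment (stripped again by curation).
#' @param multitask `NULL`, or a list with `rho` (correlation knob in
#'   \[0, 1\] between the two tasks' substituent contributions),
#'   `base_activity` for task 2, and `label_prob` (per-task probability a
#'   compound is annotated; every compound keeps at least one task).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An object of class `synthetic_sar_config`.
#' @export
synthetic_sar_config <- function(n_compounds = 600,
                                 scaffolds = default_scaffolds(),
                                 substituents = default_substituents(),
                                 base_activity = 4.5,
                                 noise_sd = 0.3,
                                 replicate_prob = 0.2,
                                 salt_prob = 0.1,
                                 multitask = NULL,
                                 seed = 1L) {
  assert_that(all(c("name", "template", "offset", "weight") %in% names(scaffolds)),
              "scaffolds need columns name/template/offset/weight")
  assert_that(all(c("name", "fragment", "contribution", "weight") %in%
                    names(substituents)),
              "substituents need columns name/fragment/contribution/weight")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  for (p in c(replicate_prob, salt_prob)) {
    assert_that(p >= 0 && p <= 1, "probabilities must lie in [0, 1]")
  }
  if (!is.null(multitask)) {
    multitask$rho <- multitask$rho %||% 0.7
    multitask$base_activity <- multitask$base_activity %||% base_activity
    multitask$label_prob <- multitask$label_prob %||% 0.8
  }
  structure(list(
    n_compounds = as.integer(n_compounds), scaffolds = scaffolds,
    substituents = substituents, base_activity = base_activity,
    noise_sd = noise_sd, replicate_prob = replicate_prob,
    salt_prob = salt_prob, multitask = multitask, seed = as.integer(seed)
  ), class = "synthetic_sar_config")
}

# Splice substituent fragments into a scaffold template.
splice_substituents <- function(template, r1, r2) {
  s <- template
  s <- sub("({R1})", if (nzchar(r1)) paste0("(", r1, ")") else "", s, fixed = TRUE)
  s <- sub("({R2})", if (nzchar(r2)) paste0("(", r2, ")") else "", s, fixed = TRUE)
  s <- sub("{R1}", r1, s, fixed = TRUE)
  s <- sub("{R2}", r2, s, fixed = TRUE)
  s
}

COUNTERIONS <- c("Cl", "[Na+]", "Br")

#' Generate a synthetic ChEMBL-like activity table
#'
#' Draws molecules from the scaffold/substituent space (weighted, without
#' replacement), plants an additive activity signal, adds measurement
#' noise, and emits rows in the raw activity schema consumed by
#' [curate_activities()]: IC50 in nM (3 significant figures, so pIC50
#' round-trips to within 0.01), unit `"nM"`, relation `"="`. Some rows
#' carry counterion fragments and some compounds replicate measurements,
#' exercising the curation pipeline end to end.
#'
#' @param config A [synthetic_sar_config()].
#' @return A list with `activities` (raw rows), `ground_truth`
#'   (`compound_id`, `smiles`, one `true_pIC50` column per task) and
#'   `config`.
#' @export
generate_library <- function(config = synthetic_sar_config()) {
  sc <- config$scaffolds
  su <- config$substituents
  n_space <- nrow(sc) * nrow(su)^2
  if (config$n_compounds > n_space) {
    stop("n_compounds (", config$n_compounds,
         ") exceeds the enumerable space (", n_space, ")", call. = FALSE)
  }
  with_seed(config$seed, {
    combos <- expand.grid(scaffold = seq_len(nrow(sc)),
                          r1 = seq_len(nrow(su)), r2 = seq_len(nrow(su)))
    w <- sc$weight[combos$scaffold] * su$weight[combos$r1] * su$weight[combos$r2]
    pick <- sample(nrow(combos), config$n_compounds, prob = w)
    combos <- combos[pick, , drop = FALSE]

    smiles <- mapply(function(s, a, b) {
      splice_substituents(sc$template[s], su$fragment[a], su$fragment[b])
    }, combos$scaffold, combos$r1, combos$r2)
    ids <- sprintf("SYN%04d", seq_len(config$n_compounds))
    truth1 <- config$base_activity + sc$offset[combos$scaffold] +
      su$contribution[combos$r1] + su$contribution[combos$r2]

    tasks <- list(T1 = truth1)
    if (!is.null(config$multitask)) {
      rho <- config$multitask$rho
      c2 <- rho * su$contribution + (1 - rho) * rev(su$contribution)
      tasks$T2 <- config$multitask$base_activity +
        sc$offset[combos$scaffold] + c2[combos$r1] + c2[combos$r2]
    }

    ground_truth <- data.frame(compound_id = ids, smiles = smiles,
                               stringsAsFactors = FALSE, row.names = NULL)
    for (tn in names(tasks)) {
      ground_truth[[paste0("true_pIC50_", tn)]] <- tasks[[tn]]
    }

    # Which tasks each compound is annotated for (all, in single-task mode).
    label_mask <- matrix(TRUE, config$n_compounds, length(tasks))
    if (length(tasks) > 1) {
      lp <- config$multitask$label_prob
      label_mask[] <- stats::runif(length(label_mask)) < lp
      none <- rowSums(label_mask) == 0
      label_mask[cbind(which(none),
                       sample(length(tasks), sum(none), replace = TRUE))] <- TRUE
    }

    salted <- stats::runif(config$n_compounds) < config$salt_prob
    ion <- sample(COUNTERIONS, config$n_compounds, replace = TRUE)
    emitted_smiles <- ifelse(salted, paste0(smiles, ".", ion), smiles)

    rows <- list()
    for (ti in seq_along(tasks)) {
      tn <- names(tasks)[ti]
      ann <- which(label_mask[, ti])
      n_rep <- 1L + (stats::runif(length(ann)) < config$replicate_prob)
      idx <- rep(ann, n_rep)
      noisy <- tasks[[tn]][idx] + stats::rnorm(length(idx), 0, config$noise_sd)
      rows[[tn]] <- data.frame(
        compound_id = ids[idx],
        structure = emitted_smiles[idx],
        standard_value = signif(10^(9 - noisy), 3),
        standard_units = "nM",
        standard_relation = "=",
        target_id = tn,
        stringsAsFactors = FALSE
      )
    }
    activities <- do.call(rbind, rows)
    activities <- activities[order(activities$target_id,
                                   activities$compound_id), , drop = FALSE]
    row.names(activities) <- NULL
    list(activities = activities, ground_truth = ground_truth, config = config)
  })
}

#' Generate a balanced factorial run table with planted effects
#'
#' Builds the full crossing of the supplied factor levels with `replicates`
#' rows per cell; the response is `mu0` plus planted additive level
#' effects (reference level of each factor contributes 0), optional
#' planted interaction offsets, and i.i.d. normal noise.
#'
#' @param levels Named list of character level vectors, e.g.
#'   `list(dataset = ..., model = ..., batch = ..., augmentation = ...)`.
#' @param effects Named list (by factor) of named numeric vectors giving
#'   each non-reference level's additive effect. Missing levels get 0.
#' @param mu0 Intercept (reference-cell mean response).
#' @param noise_sd SD of the noise added to every row.
#' @param replicates Rows per design cell.
#' @param interactions Optional data frame with one column per interacting
#'   factor plus `effect`, each row an offset added to the matching cells.
#' @param seed Integer seed.
#' @return A list with `table` (factors as character columns plus
#'   `replicate` and `response`) and `truth` (mu0, effects, interactions).
#' @export
generate_run_table <- function(levels, effects = list(), mu0 = 1,
                               noise_sd = 0, replicates = 1,
                               interactions = NULL, seed = 1L) {
  assert_that(length(levels) >= 1 && all(lengths(levels) >= 2),
              "every factor needs at least 2 levels")
  grid <- expand.grid(c(levels, list(replicate = seq_len(replicates))),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  resp <- rep(mu0, nrow(grid))
  for (f in names(effects)) {
    e <- effects[[f]]
    hit <- match(grid[[f]], names(e))
    resp <- resp + ifelse(is.na(hit), 0, e[hit])
  }
  if (!is.null(interactions)) {
    fcols <- setdiff(names(interactions), "effect")
    for (i in seq_len(nrow(interactions))) {
      sel <- rep(TRUE, nrow(grid))
      for (f in fcols) sel <- sel & grid[[f]] == interactions[[f]][i]
      resp[sel] <- resp[sel] + interactions$effect[i]
    }
  }
  with_seed(seed, {
    resp <- resp + stats::rnorm(length(resp), 0, noise_sd)
  })
  grid$response <- resp
  list(table = grid,
       truth = list(mu0 = mu0, effects = effects, interactions = interactions))
}
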