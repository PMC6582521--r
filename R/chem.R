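# Curation of ChEMBL-style bioactivity tables and circular fingerprints.
#
# The curation contract mirrors standard medicinal-chemistry practice for
# IC50 data: keep only exact ("=") measurements reported in nM, strip
# counterions/solvents by retaining the largest organic fragment, reject
# inorganic species, convert to pIC50 = -log10(IC50 [M]) and average
# replicate measurements per compound/target pair on the log scale.

# Conventional organic-chemistry element whitelist.
ORGANIC_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I"
)

# ---- OpenBabel helpers ------------------------------------------------------

# Canonical SMILES of one molecule, or NA on parse failure.
ob_canonical <- function(smiles) {
  out <- suppressWarnings(tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  ))
  out <- sub("[ \t].*$", "", trimws(out))
  if (!nzchar(out)) return(NA_character_)
  out
}

# Molecular properties of one SMILES fragment via OpenBabel.
ob_props <- function(smiles) {
  p <- suppressWarnings(tryCatch(
    ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"),
                           function(m) ChemmineOB::prop_OB(m)),
    error = function(e) NULL
  ))
  if (is.null(p) || length(p) == 0) return(NULL)
  p[[1]]
}

# Parse a molecular formula like "C9H8O4" into a named count vector.
parse_formula <- function(formula) {
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Z][a-z]?", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  stats::setNames(n, el)
}

is_molblock <- function(structure) {
  grepl("\n", structure, fixed = TRUE) && grepl("V2000", structure, fixed = TRUE)
}

# ---- Structure standardization ---------------------------------------------

#' Standardize a chemical structure
#'
#' Parses a SMILES string (or a V2000 molblock), removes counterions and
#' solvents by keeping the fragment with the most heavy atoms among those
#' composed solely of allowed organic elements, and returns a canonical
#' SMILES. Species with no organic fragment (e.g. bare metal ions) are
#' rejected rather than raising an error; unparseable input is also
#' reported as a rejection with reason `"parse error"`.
#'
#' Fragment ties are broken by molecular weight (heavier wins), then by the
#' lexicographically smallest canonical SMILES, so the choice is
#' deterministic. Charged organic species are kept as-is; no neutralization
#' or tautomer canonicalization is attempted.
#'
#' @param structure A single SMILES string or V2000 molblock text.
#' @param allowed_elements Character vector of permitted element symbols.
#' @return A list with elements `accepted` (logical), `canonical_smiles`
#'   (character or `NA`), and `reason` (`NA` when accepted).
#' @examples
#' standardize_structure("CCO.[Na+].[Cl-]")$canonical_smiles  # "CCO"
#' standardize_structure("[Fe+2]")$reason                     # rejection
#' @export
standardize_structure <- function(structure,
                                  allowed_elements = ORGANIC_ELEMENTS) {
  assert_that(is.character(structure) && length(structure) == 1 &&
                nzchar(trimws(structure)),
              "`structure` must be a single non-empty string")
  smi <- if (is_molblock(structure)) {
    out <- suppressWarnings(tryCatch(
      ChemmineOB::convertFormat("SDF", "CAN", structure),
      error = function(e) ""
    ))
    sub("[ \t].*$", "", trimws(out))
  } else {
    trimws(structure)
  }
  if (!nzchar(smi) || is.na(smi)) {
    return(list(accepted = FALSE, canonical_smiles = NA_character_,
                reason = "parse error"))
  }

  # '.' is the SMILES fragment separator and cannot occur inside brackets.
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  info <- lapply(frags, function(f) {
    p <- ob_props(f)
    if (is.null(p)) return(NULL)
    counts <- parse_formula(p$formula)
    heavy <- sum(counts[setdiff(names(counts), "H")])
    organic <- all(names(counts) %in% allowed_elements)
    can <- ob_canonical(f)
    if (is.na(can)) return(NULL)
    list(smiles = can, heavy = heavy, mw = p$MW, organic = organic)
  })
  if (any(vapply(info, is.null, logical(1)))) {
    return(list(accepted = FALSE, canonical_smiles = NA_character_,
                reason = "parse error"))
  }
  org <- Filter(function(x) x$organic, info)
  if (length(org) == 0) {
    return(list(accepted = FALSE, canonical_smiles = NA_character_,
                reason = "inorganic element"))
  }
  heavy <- vapply(org, `[[`, numeric(1), "heavy")
  mw <- vapply(org, `[[`, numeric(1), "mw")
  smis <- vapply(org, `[[`, character(1), "smiles")
  ord <- order(-heavy, -mw, smis)
  list(accepted = TRUE, canonical_smiles = smis[ord[1]], reason = NA_character_)
}

# ---- Activity filtering and transforms -------------------------------------

#' Filter raw activity rows on unit and relation annotations
#'
#' Keeps only rows measured in nM with an exact ("=") activity
#' relationship. Matching is exact string equality after trimming
#' whitespace; no unit conversion is attempted.
#'
#' @param rows Data frame with at least columns `standard_units` and
#'   `standard_relation`.
#' @return A list with `kept` (the surviving rows) and `audit`, a named
#'   list of counts: `n_input`, `dropped_unit` (unit not "nM"),
#'   `dropped_relation` (unit ok but relation not "="), and `kept`.
#' @export
filter_activities <- function(rows) {
  required <- c("standard_units", "standard_relation")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0) {
    stop("activity table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  units <- trimws(as.character(rows$standard_units))
  rel <- trimws(as.character(rows$standard_relation))
  unit_ok <- !is.na(units) & units == "nM"
  rel_ok <- !is.na(rel) & rel == "="
  keep <- unit_ok & rel_ok
  list(
    kept = rows[keep, , drop = FALSE],
    audit = list(
      n_input = nrow(rows),
      dropped_unit = sum(!unit_ok),
      dropped_relation = sum(unit_ok & !rel_ok),
      kept = sum(keep)
    )
  )
}

#' Convert IC50 in nM to pIC50
#'
#' `pIC50 = -log10(IC50 [M]) = 9 - log10(IC50 [nM])`.
#'
#' @param ic50_nM Positive numeric vector of IC50 values in nM.
#' @return Numeric vector of pIC50 values.
#' @examples
#' to_pic50(1000) # 6
#' to_pic50(1)    # 9
#' @export
to_pic50 <- function(ic50_nM) {
  assert_that(is.numeric(ic50_nM) && all(is.finite(ic50_nM)),
              "`ic50_nM` must be finite numeric")
  assert_that(all(ic50_nM > 0), "IC50 values must be positive")
  9 - log10(ic50_nM)
}

#' Average replicate pIC50 measurements
#'
#' The mean is taken on the log (pIC50) scale, not on the IC50 scale.
#'
#' @param pic50 Numeric vector of replicate pIC50 values (length >= 1).
#' @return A single averaged pIC50.
#' @export
aggregate_replicates <- function(pic50) {
  assert_that(length(pic50) >= 1 && all(is.finite(pic50)),
              "need at least one finite pIC50 value")
  mean(pic50)
}

# ---- Full curation pipeline ------------------------------------------------

#' Curate a raw ChEMBL-style activity table
#'
#' Runs the full curation pipeline: unit/relation filtering, structure
#' standardization (largest organic fragment, inorganic rejection),
#' pIC50 conversion, and replicate averaging per (compound, target) pair.
#' The pipeline is idempotent: re-curating its own output (re-expressed as
#' exact nM measurements) changes nothing.
#'
#' @param rows Data frame with columns `compound_id`, `structure` (SMILES
#'   or molblock), `standard_value` (IC50 in the stated unit),
#'   `standard_units`, `standard_relation`, `target_id`.
#' @return An object of class `curated_activities`: a list with
#'   `records` (data frame: `compound_id`, `canonical_smiles`,
#'   `target_id`, `pIC50`, `n_replicates`), `rejected` (data frame of
#'   rejected structures with reasons), and `audit` (named count list).
#' @export
curate_activities <- function(rows) {
  required <- c("compound_id", "structure", "standard_value",
                "standard_units", "standard_relation", "target_id")
  missing <- setdiff(required, names(rows))
  if (length(missing) > 0) {
    stop("activity table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  filt <- filter_activities(rows)
  kept <- filt$kept
  audit <- filt$audit

  # Standardize each distinct structure once.
  uniq <- unique(as.character(kept$structure))
  std <- lapply(uniq, standardize_structure)
  names(std) <- uniq
  acc <- vapply(std, `[[`, logical(1), "accepted")
  reasons <- vapply(std, `[[`, character(1), "reason")
  can <- vapply(std, `[[`, character(1), "canonical_smiles")

  row_acc <- acc[as.character(kept$structure)]
  rejected_rows <- kept[!row_acc, , drop = FALSE]
  rejected <- data.frame(
    compound_id = rejected_rows$compound_id,
    structure = rejected_rows$structure,
    reason = reasons[as.character(rejected_rows$structure)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  kept <- kept[row_acc, , drop = FALSE]
  audit$dropped_parse <- sum(rejected$reason == "parse error")
  audit$dropped_inorganic <- sum(rejected$reason == "inorganic element")

  if (nrow(kept) == 0) {
    records <- data.frame(compound_id = character(), canonical_smiles = character(),
                          target_id = character(), pIC50 = numeric(),
                          n_replicates = integer(), stringsAsFactors = FALSE)
  } else {
    kept$pIC50 <- to_pic50(as.numeric(kept$standard_value))
    kept$canonical_smiles <- unname(can[as.character(kept$structure)])
    key <- interaction(kept$compound_id, kept$target_id, drop = TRUE)
    agg <- lapply(split(kept, key), function(d) {
      data.frame(
        compound_id = d$compound_id[1],
        canonical_smiles = d$canonical_smiles[1],
        target_id = d$target_id[1],
        pIC50 = aggregate_replicates(d$pIC50),
        n_replicates = nrow(d),
        stringsAsFactors = FALSE
      )
    })
    records <- do.call(rbind, agg)
    records <- records[order(records$compound_id, records$target_id), ,
                       drop = FALSE]
    row.names(records) <- NULL
  }
  audit$n_records <- nrow(records)
  structure(list(records = records, rejected = rejected, audit = audit),
            class = "curated_activities")
}

#' @export
print.curated_activities <- function(x, ...) {
  cat("Curated bioactivity set:", nrow(x$records), "records (",
      length(unique(x$records$compound_id)), "compounds,",
      length(unique(x$records$target_id)), "targets )\n")
  cat("  input rows:       ", x$audit$n_input, "\n")
  cat("  dropped unit:     ", x$audit$dropped_unit, "\n")
  cat("  dropped relation: ", x$audit$dropped_relation, "\n")
  cat("  dropped parse:    ", x$audit$dropped_parse, "\n")
  cat("  dropped inorganic:", x$audit$dropped_inorganic, "\n")
  invisible(x)
}

#' Read a raw activity table from CSV/TSV
#'
#' The delimiter is inferred from the file extension (`.tsv`/`.tab` read
#' as tab-separated, anything else as comma-separated). A `smiles` column
#' is accepted as an alias for `structure`.
#'
#' @param path Path to the file.
#' @return A data frame of raw activity rows.
#' @export
read_activity_table <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (!"structure" %in% names(df) && "smiles" %in% names(df)) {
    names(df)[names(df) == "smiles"] <- "structure"
  }
  df
}

#' Read a raw activity table from an SDF file
#'
#' Each V2000 record's structure block becomes the `structure` field
#' (molblock text); activity annotations are taken from SD data tags
#' `standard_value`, `standard_units`, `standard_relation`, `target_id`
#' and `compound_id` (falling back to the molecule title, then to a
#' sequential id).
#'
#' @param path Path to an uncompressed V2000 SDF file.
#' @return A data frame of raw activity rows for [curate_activities()].
#' @export
read_activity_sdf <- function(path) {
  sdfstr <- ChemmineR::read.SDFstr(path)
  blocks <- methods::as(sdfstr, "list")
  rows <- lapply(seq_along(blocks), function(i) {
    lines <- blocks[[i]]
    end <- which(lines == "M  END")[1]
    if (is.na(end)) {
      stop("record ", i, " in ", path, " has no 'M  END' terminator",
           call. = FALSE)
    }
    molblock <- paste(lines[seq_len(end)], collapse = "\n")
    tag_lines <- grep("^> *<", lines)
    tags <- list()
    for (tl in tag_lines) {
      key <- sub("^> *<([^>]+)>.*$", "\\1", lines[tl])
      tags[[key]] <- trimws(lines[tl + 1])
    }
    data.frame(
      compound_id = tags$compound_id %||%
        (if (nzchar(trimws(lines[1]))) trimws(lines[1]) else
          sprintf("SDF%04d", i)),
      structure = molblock,
      standard_value = as.numeric(tags$standard_value %||% NA),
      standard_units = tags$standard_units %||% "",
      standard_relation = tags$standard_relation %||% "",
      target_id = tags$target_id %||% "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write curated records and audit log
#'
#' @param curated A `curated_activities` object.
#' @param csv_path Output CSV for records.
#' @param audit_path Optional output JSON for the audit counts.
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(curated, csv_path, audit_path = NULL) {
  utils::write.csv(curated$records, csv_path, row.names = FALSE)
  if (!is.null(audit_path)) {
    jsonlite::write_json(curated$audit, audit_path, auto_unbox = TRUE)
  }
  invisible(c(csv_path, audit_path))
}

# ---- Circular fingerprints -------------------------------------------------

fp_cache <- new.env(parent = emptyenv())

#' Hashed circular (Morgan-type) fingerprint
#'
#' Computes an extended-connectivity fingerprint of the given radius
#' (ECFP-style atom environments up to `2 * radius` bonds in diameter) and
#' folds it down to `n_bits` by OR-ing equal-sized blocks. Fingerprints
#' are deterministic, invariant to the atom ordering of the input SMILES,
#' and memoised per (structure, radius, n_bits).
#'
#' @param smiles A single valid SMILES string.
#' @param radius Environment radius in bonds (default 2, i.e. ECFP4).
#' @param n_bits Folded length; one of 128, 256, 512, 1024, 2048, 4096.
#' @return Integer vector of length `n_bits` with entries in {0, 1}.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  assert_that(radius %in% 0:5, "`radius` must be an integer in 0..5")
  assert_that(n_bits %in% c(128, 256, 512, 1024, 2048, 4096),
              "`n_bits` must be one of 128, 256, 512, 1024, 2048, 4096")
  key <- paste(smiles, radius, n_bits, sep = "|")
  hit <- fp_cache[[key]]
  if (!is.null(hit)) return(hit)
  type <- paste0("ECFP", 2L * radius)
  raw <- suppressWarnings(tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity), type),
    error = function(e) NULL
  ))
  v <- as.integer(raw)
  if (length(v) == 0 || length(v) %% n_bits != 0) {
    stop("cannot compute fingerprint: invalid structure '", smiles, "'",
         call. = FALSE)
  }
  out <- as.integer(rowSums(matrix(v, nrow = n_bits)) > 0)
  fp_cache[[key]] <- out
  out
}

#' Fingerprint matrix for a set of structures
#'
#' @param smiles Character vector of SMILES.
#' @param radius,n_bits As in [morgan_fingerprint()].
#' @return Integer matrix, one row per structure, `n_bits` columns, with
#'   `smiles` as row names.
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 2048) {
  m <- t(vapply(smiles, morgan_fingerprint, integer(n_bits),
                radius = radius, n_bits = n_bits))
  rownames(m) <- smiles
  m
}
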