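# Curation: structure standardization, activity filtering, pIC50
# transform, replicate aggregation, and circular fingerprints.

test_that("standardize_structure keeps the largest organic fragment", {
  r <- standardize_structure("CCO.[Na+].[Cl-]")
  expect_true(r$accepted)
  expect_identical(r$canonical_smiles, "CCO")

  # single organic fragment is a fixed point
  expect_identical(standardize_structure("c1ccccc1")$canonical_smiles,
                   "c1ccccc1")

  # standardization is idempotent on its own output
  r2 <- standardize_structure(r$canonical_smiles)
  expect_identical(r2$canonical_smiles, r$canonical_smiles)
})

test_that("inorganic and unparseable species are rejected, not thrown", {
  r <- standardize_structure("[Fe+2]")
  expect_false(r$accepted)
  expect_identical(r$reason, "inorganic element")

  r <- standardize_structure("qq[[")
  expect_false(r$accepted)
  expect_identical(r$reason, "parse error")

  # a single-fragment molecule carrying a disallowed element is rejected
  r <- standardize_structure("CC[Hg]CC")
  expect_false(r$accepted)
  expect_identical(r$reason, "inorganic element")
})

test_that("standardize_structure accepts molblock input", {
  mb <- ChemmineOB::convertFormat("SMI", "SDF", "CCO\n")
  r <- standardize_structure(mb)
  expect_true(r$accepted)
  expect_identical(r$canonical_smiles, "CCO")
})

test_that("filter_activities applies exact unit and relation predicates", {
  rows <- data.frame(
    standard_units = c("nM", "ug.mL-1", "nM", " nM ", "uM"),
    standard_relation = c(">", "=", "=", "=", "="),
    stringsAsFactors = FALSE
  )
  f <- filter_activities(rows)
  expect_equal(f$audit$n_input, 5)
  expect_equal(f$audit$dropped_unit, 2)     # ug.mL-1 and uM
  expect_equal(f$audit$dropped_relation, 1) # the nM / '>' row
  expect_equal(f$audit$kept, 2)             # exact row and whitespace-trim row
  expect_error(filter_activities(data.frame(standard_units = "nM")),
               "standard_relation")
})

test_that("to_pic50 matches the -log10 molar transform", {
  expect_equal(to_pic50(1000), 6.0)
  expect_equal(to_pic50(1), 9.0)
  expect_equal(to_pic50(50), 7.30103, tolerance = 1e-6)
  expect_error(to_pic50(-5), "positive")
  expect_error(to_pic50(0), "positive")

  # strictly decreasing; a decade of IC50 is one pIC50 unit
  x <- 10^runif(50, -2, 5)
  expect_true(all(diff(to_pic50(sort(x))) < 0))
  expect_equal(to_pic50(10 * x), to_pic50(x) - 1)
})

test_that("replicates average on the log scale, not the IC50 scale", {
  expect_equal(aggregate_replicates(c(6, 7)), 6.5)
  expect_equal(aggregate_replicates(8.2), 8.2)
  # IC50s 10 nM and 1000 nM: mean of pIC50s 8 and 6 is 7, whereas the
  # pIC50 of the mean IC50 (505 nM) would be ~6.3
  expect_equal(aggregate_replicates(to_pic50(c(10, 1000))), 7.0)
  expect_false(isTRUE(all.equal(to_pic50(mean(c(10, 1000))), 7.0)))
})

test_that("curation of the toy table reproduces hand-computed records", {
  cur <- curate_activities(toy_activity_rows())
  expect_equal(cur$records, toy_expected_records(), tolerance = 1e-12)
  expect_equal(cur$audit$dropped_unit, 1)
  expect_equal(cur$audit$dropped_relation, 1)
  expect_equal(cur$audit$dropped_parse, 1)
  expect_equal(cur$audit$dropped_inorganic, 1)
  expect_equal(cur$audit$n_records, 5)
  expect_setequal(cur$rejected$compound_id, c("C4", "C9"))
})

test_that("curation is idempotent", {
  cur <- curate_activities(toy_activity_rows())
  again <- data.frame(
    compound_id = cur$records$compound_id,
    structure = cur$records$canonical_smiles,
    standard_value = 10^(9 - cur$records$pIC50),
    standard_units = "nM", standard_relation = "=",
    target_id = cur$records$target_id,
    stringsAsFactors = FALSE
  )
  cur2 <- curate_activities(again)
  expect_equal(cur2$records$compound_id, cur$records$compound_id)
  expect_equal(cur2$records$canonical_smiles, cur$records$canonical_smiles)
  expect_equal(cur2$records$pIC50, cur$records$pIC50, tolerance = 1e-9)
})

test_that("fingerprints are deterministic, binary, and atom-order invariant", {
  a <- morgan_fingerprint("CCO", 2, 2048)
  expect_length(a, 2048)
  expect_true(all(a %in% c(0L, 1L)))
  expect_identical(a, morgan_fingerprint("CCO", 2, 2048))

  # same molecule written with permuted atom order
  expect_identical(morgan_fingerprint("OCC", 2, 2048), a)
  expect_identical(morgan_fingerprint("C(O)C", 2, 2048), a)

  # different environments must not collide to identical vectors
  expect_false(identical(morgan_fingerprint("CC", 2, 2048), a))

  # folding ORs fixed-length blocks: a 1024-bit fold of aspirin has the
  # bits of the 2048-bit fold collapsed pairwise
  f2048 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O", 2, 2048)
  f1024 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O", 2, 1024)
  expect_identical(f1024,
                   as.integer((f2048[1:1024] + f2048[1025:2048]) > 0))

  expect_error(morgan_fingerprint("CCO", 2, 100), "n_bits")
  expect_error(morgan_fingerprint("zz9z", 2, 2048), "invalid structure")
})

test_that("fingerprint_matrix stacks per-compound rows at stated lengths", {
  for (nb in c(128, 512, 2048)) {
    m <- fingerprint_matrix(c("CCO", "c1ccccc1"), 2, nb)
    expect_identical(dim(m), c(2L, as.integer(nb)))
    expect_true(all(m %in% c(0L, 1L)))
  }
})

test_that("activity tables round-trip through CSV and TSV readers", {
  rows <- toy_activity_rows()
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  expect_equal(read_activity_table(csv), rows)

  tsv <- tempfile(fileext = ".tsv")
  names(rows)[names(rows) == "structure"] <- "smiles"
  utils::write.table(rows, tsv, sep = "\t", row.names = FALSE)
  back <- read_activity_table(tsv)
  expect_true("structure" %in% names(back))  # smiles alias accepted
})

test_that("SDF activity tables are read with structures and SD tags", {
  sdf_mol <- ChemmineOB::convertFormat("SMI", "SDF", "CCO\n")
  sdf_mol <- sub("\\$\\$\\$\\$\\s*$", "", sdf_mol)
  record <- paste0(sdf_mol,
                   "> <compound_id>\nE1\n\n",
                   "> <standard_value>\n1000\n\n",
                   "> <standard_units>\nnM\n\n",
                   "> <standard_relation>\n=\n\n",
                   "> <target_id>\nT1\n\n$$$$\n")
  path <- tempfile(fileext = ".sdf")
  writeLines(c(record, record), path)
  rows <- read_activity_sdf(path)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$compound_id, c("E1", "E1"))
  expect_equal(rows$standard_value, c(1000, 1000))
  cur <- curate_activities(rows)
  expect_equal(cur$records$canonical_smiles, "CCO")
  expect_equal(cur$records$pIC50, 6)
})
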