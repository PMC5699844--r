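test_that("wash ionizes strong acids and bases, strips salts, and canonicalizes", {
  w <- wash_smiles(c("CC(=O)O", "c1ccccc1", "CCN.Cl"))
  expect_true(all(w$ok))
  # carboxylic acid deprotonated; equal to washing the ionized form directly
  expect_match(w$smiles_canonical[1], "O-", fixed = TRUE)
  expect_identical(w$smiles_canonical[1],
                   wash_smiles("CC(=O)[O-]")$smiles_canonical)
  # no ionizable groups: identity
  expect_identical(w$smiles_canonical[2], "c1ccccc1")
  # salt stripped (largest fragment), amine protonated
  expect_false(grepl(".", w$smiles_canonical[3], fixed = TRUE))
  expect_match(w$smiles_canonical[3], "NH3+", fixed = TRUE)
  # weak acids and bases stay neutral
  w2 <- wash_smiles(c("CCO", "c1ccncc1", "Nc1ccccc1"))
  expect_false(any(grepl("[+-]", w2$smiles_canonical)))
})

test_that("wash rejects bad input with reason codes and is idempotent on generated molecules", {
  w <- wash_smiles(c("not a smiles ((", "", NA))
  expect_false(any(w$ok))
  expect_identical(w$reason, c("unparsable", "empty", "empty"))

  smis <- grammar_smiles(25, seed = 42)
  # add salt forms to exercise fragment stripping
  raw <- c(smis, paste0(smis[1:5], ".Cl"), paste0(smis[6:8], ".[Na+]"))
  w1 <- wash_smiles(raw)
  expect_true(all(w1$ok))
  expect_false(any(grepl(".", w1$smiles_canonical, fixed = TRUE)))
  w2 <- wash_smiles(w1$smiles_canonical)
  expect_identical(w2$smiles_canonical, w1$smiles_canonical)
})

test_that("dedup collapses exact repeats and merges targets, order-insensitively", {
  r <- make_records(c("L1", "L2", "L3", "L4"),
                    c("CCO", "CCO", "CCO", "c1ccccc1"),
                    c("P1", "P1", "P2", "P1"))
  d <- dedup_ligands(r)
  expect_equal(nrow(d), 2L)
  eth <- d[d$smiles_canonical == "CCO", ]
  expect_identical(eth$ligand_id, "L1")
  expect_identical(eth$target_ids, "P1;P2")
  # idempotent and independent of row order
  expect_identical(dedup_ligands(d), d)
  perm <- r[c(3, 1, 4, 2), ]
  expect_identical(dedup_ligands(perm), d)
  # empty input passes through
  expect_equal(nrow(dedup_ligands(r[0, ])), 0L)
})

test_that("assay filtering applies keyword stem, HTS removal and blacklist", {
  assays <- data.frame(
    assay_id = c("a1", "a2", "a3", "a4", "a5"),
    description = c("Allosteric modulation of receptor X",
                    "allosteric HTS campaign",
                    "Binding affinity",
                    "competitive inhibition assay",
                    "ALLOSTERIC site probe"),
    is_hts = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    standard_value = c(12, 5, 3, 8, NA),
    ligand_ids = c("L1;L2", "L3", "L4", "L5", "L6"),
    stringsAsFactors = FALSE)
  kept <- filter_assays(assays, "allosteric")
  expect_setequal(kept$assay_id, c("a1", "a5"))  # case-insensitive, HTS out
  expect_identical(filter_assays(assays, "competitive")$assay_id, "a4")
  # output is a subset; blacklisting never enlarges the kept set
  bl <- filter_assays(assays, "allosteric", curation_blacklist = "a1")
  expect_true(all(bl$assay_id %in% kept$assay_id))
  expect_identical(bl$assay_id, "a5")
  # active-molecule rule: positive, present standard_value only
  expect_setequal(active_ligand_ids(kept), c("L1", "L2"))
})

test_that("panel artifacts are flagged by distinct-target count", {
  many <- paste(sprintf("P%03d", 1:250), collapse = ";")
  r <- make_records(c("Lpanel", "Lmono"), c("CCO", "CCN"),
                    c(many, "P001"))
  expect_identical(flag_panel_artifacts(r, 100), "Lpanel")
  expect_identical(flag_panel_artifacts(r, 300), character(0))
  expect_error(flag_panel_artifacts(r, 0))
})

test_that("table and FASTA readers handle well-formed and malformed input", {
  lf <- tempfile(fileext = ".csv")
  writeLines(c("ligand_id,smiles,set_label,target_ids",
               "L1,CCO,allosteric,P1",
               "L2,,allosteric,P1",
               "L3,c1ccccc1,competitive,P1;P2"), lf)
  expect_message(tab <- read_ligand_table(lf), "skipped 1")
  expect_equal(nrow(tab), 2L)
  expect_identical(tab$smiles_raw, c("CCO", "c1ccccc1"))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("ligand_id,smiles", "L1,CCO"), bad)
  expect_error(read_ligand_table(bad), "set_label")

  ff <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 alpha kinase", "MKTAYIAK", ">P2", "MVLSPADK"), ff)
  pr <- read_protein_fasta(ff)
  expect_equal(nrow(pr), 2L)
  expect_identical(pr$protein_id, c("P1", "P2"))
  expect_identical(pr$name, c("alpha kinase", "None"))
  expect_identical(pr$sequence, c("MKTAYIAK", "MVLSPADK"))

  af <- tempfile(fileext = ".tsv")
  writeLines(c("assay_id\tdescription\tis_hts\tstandard_value\tligand_ids",
               "a1\tallosteric assay\tFALSE\t5\tL1;L2"), af)
  aa <- read_assay_table(af)
  expect_identical(aa$ligand_ids, "L1;L2")
  expect_false(aa$is_hts)
})

test_that("curation pipeline washes, filters by assay activity, dedups and removes panels", {
  many <- paste(sprintf("PK%03d", 1:150), collapse = ";")
  lig <- data.frame(
    ligand_id = c("L1", "L2", "L3", "L4", "L5"),
    smiles_raw = c("CC(=O)O", "CC(=O)O", "bad((", "CCN.Cl", "c1ccccc1"),
    set_label = "allosteric",
    target_ids = c("P1", "P1", "P1", "P2", many),
    stringsAsFactors = FALSE)
  assays <- data.frame(assay_id = "a1",
                       description = "allosteric binding",
                       is_hts = FALSE, standard_value = 3,
                       ligand_ids = "L1;L2;L3;L4;L5",
                       stringsAsFactors = FALSE)
  cu <- quiet(curate_ligands(lig, assays, mode = "allosteric"))
  expect_identical(cu$rejected$ligand_id, "L3")
  expect_identical(cu$flagged, "L5")
  # L1/L2 same molecule+protein collapse to one
  expect_equal(nrow(cu$ligands), 2L)
  expect_true(all(cu$ligands$ligand_id %in% c("L1", "L4")))
})
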