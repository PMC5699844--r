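test_that("protein families hit their pairwise identity targets", {
  # exact identity at 100%
  f100 <- generate_protein_family(4, 100, 100, seed = 1)
  expect_equal(length(unique(f100$sequence)), 1L)
  # measured identity within +/- 3 points of the target
  for (tgt in c(70, 90)) {
    fam <- generate_protein_family(3, tgt, 150, seed = tgt)
    for (i in 1:2) for (j in (i + 1):3) {
      id <- pairwise_identity(fam$sequence[i], fam$sequence[j])
      expect_true(all(abs(id - tgt) <= 3),
                  info = sprintf("target %d pair %d-%d: %s", tgt, i, j,
                                 paste(round(id, 1), collapse = "/")))
    }
  }
  # deterministic given the seed
  expect_identical(generate_protein_family(3, 80, 120, seed = 5),
                   generate_protein_family(3, 80, 120, seed = 5))
  expect_error(generate_protein_family(40, 10, 50, seed = 1), "infeasible")
})

test_that("the fragment grammar only emits valid, washable molecules", {
  set.seed(17)
  raw <- replicate(150, generate_ligand())
  w <- wash_smiles(raw)
  expect_true(all(w$ok))  # zero rejects, by construction
  d <- compute_descriptors(unique(w$smiles_canonical))
  expect_true(all(is.finite(d$SlogP)))
  expect_true(all(d$a_heavy >= 1))
})

test_that("grammar weights steer composition as declared", {
  # aromatic-only segments: fully aromatic heavy atoms (H caps)
  w_aro <- c(seg_arom = 1, cap_h = 1)
  set.seed(2)
  smi <- replicate(10, generate_ligand(w_aro))
  d <- compute_descriptors(wash_smiles(smi)$smiles_canonical)
  expect_true(all(d$a_aro_per_HA == 1))
  # no donor-bearing fragments: zero H-bond donors
  w_nodon <- c(seg_arom = 0.5, seg_alk2 = 0.5, cap_h = 0.5, cap_me = 0.3,
               cap_cl = 0.2)
  set.seed(3)
  smi2 <- replicate(10, generate_ligand(w_nodon))
  d2 <- compute_descriptors(wash_smiles(smi2)$smiles_canonical)
  expect_true(all(d2$a_don == 0))
})

test_that("realized aromatic fraction tracks the count-level expectation", {
  exp_frac <- expected_grammar_fractions(seed = 5)[["aromatic_fraction"]]
  set.seed(19)
  raw <- replicate(1000, generate_ligand())
  d <- compute_descriptors(wash_smiles(raw)$smiles_canonical,
                           columns = "a_aro_per_HA")
  expect_lt(abs(mean(d$a_aro_per_HA) - exp_frac), 0.05)
})

test_that("studies are deterministic and carry their injected artifacts", {
  cfg <- synthetic_config(n_families_allo = 5, n_families_comp = 5,
                          mean_ligands_per_family = 6, duplicate_rate = 0.2,
                          panel_artifact = c(7, 220), seed = 23)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1$ligands, st2$ligands)
  expect_identical(st1$proteins, st2$proteins)

  # panel artifact: exactly the injected ligands are flagged at the default
  lg <- st1$ligands
  lg$smiles_raw <- lg$smiles
  comp <- lg[lg$set_label == "competitive", ]
  cu <- quiet(curate_ligands(comp, max_targets = 1e9))  # keep them to flag
  expect_setequal(flag_panel_artifacts(cu$ligands, 100),
                  st1$manifest$panel_ligand_ids)

  # the injected exact repeats are present as duplicated rows, and dedup
  # leaves no repeated (molecule, set) pair behind
  n_dup <- length(st1$manifest$duplicate_ligand_ids)
  expect_gt(n_dup, 0)
  expect_equal(sum(duplicated(lg[c("ligand_id", "target_ids", "set_label")])),
               n_dup)
  both <- lg[!(lg$ligand_id %in% st1$manifest$panel_ligand_ids), ]
  both$smiles_canonical <- wash_smiles(both$smiles_raw)$smiles_canonical
  dd <- dedup_ligands(both)
  expect_equal(anyDuplicated(paste(dd$smiles_canonical, dd$set_label)), 0L)
  expect_lte(nrow(dd), nrow(both) - n_dup)

  # configured shift moves the realized descriptor means the right way
  cfg_s <- synthetic_config(n_families_allo = 12, n_families_comp = 12,
                            mean_ligands_per_family = 8,
                            shift_spec = c("a_aro/HA" = 0.08), seed = 29)
  st3 <- generate_study(cfg_s)
  lg3 <- st3$ligands
  m <- vapply(c("allosteric", "competitive"), function(s) {
    w <- wash_smiles(lg3$smiles[lg3$set_label == s])
    mean(compute_descriptors(w$smiles_canonical,
                             columns = "a_aro_per_HA")$a_aro_per_HA)
  }, 1)
  expect_gt(m[["allosteric"]] - m[["competitive"]], 0.03)
})

test_that("written studies round-trip through the readers", {
  st <- generate_study(synthetic_config(n_families_allo = 3,
                                        n_families_comp = 3,
                                        mean_ligands_per_family = 4,
                                        seed = 37))
  dir <- tempfile()
  write_study(st, dir)
  lg <- read_ligand_table(file.path(dir, "ligands.csv"))
  expect_equal(nrow(lg), nrow(st$ligands))
  pr <- read_protein_fasta(file.path(dir, "proteins.fasta"))
  expect_setequal(pr$protein_id, st$proteins$protein_id)
  expect_identical(pr$sequence[match(st$proteins$protein_id, pr$protein_id)],
                   st$proteins$sequence)
  aa <- read_assay_table(file.path(dir, "assays.csv"))
  expect_equal(nrow(aa), nrow(st$assays))
})
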