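test_that("bidirectional identity uses each sequence's own length", {
  s <- random_seq(120, 1)
  expect_equal(unname(pairwise_identity(s, s)), c(100, 100))
  # prefix half: full match of the short one, half of the long one
  half <- substr(s, 1, 60)
  expect_equal(unname(pairwise_identity(half, s)), c(100, 50))
  # unrelated random sequences score low in both directions
  id <- pairwise_identity(random_seq(300, 2), random_seq(300, 3))
  expect_true(all(id < 30))
})

test_that("greedy families group by bidirectional identity with the canonical order", {
  s <- random_seq(120, 4)
  p3 <- data.frame(protein_id = c("pA", "pB", "pC"), sequence = s,
                   stringsAsFactors = FALSE)
  f100 <- greedy_protein_families(p3, 100)
  expect_equal(length(unique(f100$family_id)), 1L)
  expect_equal(sum(f100$is_representative), 1L)

  # two sequences at ~50% mutual identity split at a 60% threshold
  fam50 <- generate_protein_family(2, 50, 200, seed = 5)
  expect_equal(length(unique(
    greedy_protein_families(fam50, 60)$family_id)), 2L)

  # isoforms at ~70% identity: together at 60%, separate at 90%
  iso <- generate_protein_family(2, 70, 200, seed = 6)
  mid <- pairwise_identity(iso$sequence[1], iso$sequence[2])
  expect_true(all(mid >= 67 & mid <= 73))
  expect_equal(length(unique(greedy_protein_families(iso, 60)$family_id)), 1L)
  expect_equal(length(unique(greedy_protein_families(iso, 90)$family_id)), 2L)

  # partition: every protein in exactly one family
  cols <- c("protein_id", "sequence")
  mix <- rbind(iso[cols], fam50[cols], p3[cols])
  mix$protein_id <- sprintf("q%d", seq_len(nrow(mix)))
  for (lv in c(60, 90, 100)) {
    fm <- greedy_protein_families(mix, lv)
    expect_setequal(fm$protein_id, mix$protein_id)
    expect_equal(anyDuplicated(fm$protein_id), 0L)
  }
})

test_that("maximum-dissimilarity clustering respects its defining constraints", {
  smis <- grammar_smiles(30, seed = 21)
  fps <- ecfp6(smis)

  # n identical ligands: one cluster
  same <- ecfp6(rep("c1ccccc1C(=O)NCC", 5))
  cl <- max_dissimilarity_cluster(same, 0.6, sprintf("L%d", 1:5))
  expect_equal(length(unique(cl$cluster)), 1L)
  expect_equal(sum(cl$is_center), 1L)

  # two fully dissimilar ligands: two singletons
  f2 <- ecfp6(c("c1ccccc1", "CCCCCC"))
  stopifnot(tanimoto(f2[1, ], f2[2, ]) == 0)
  cl2 <- max_dissimilarity_cluster(f2, 0.6, c("a", "b"))
  expect_equal(length(unique(cl2$cluster)), 2L)

  # threshold 1: clusters are exactly the identical-fingerprint groups
  fps3 <- ecfp6(c(smis[1:6], smis[1:3]))
  cl3 <- max_dissimilarity_cluster(fps3, 1.0, sprintf("m%d", 1:9))
  key <- apply(fps3, 1, paste, collapse = "")
  expect_equal(length(unique(cl3$cluster)), length(unique(key)))
  expect_true(all(tapply(key, cl3$cluster,
                         function(k) length(unique(k))) == 1L))

  # defining constraints, against the raw similarity matrix
  S <- tanimoto_matrix(fps)
  for (tc in c(0.4, 0.6, 0.9)) {
    cl <- max_dissimilarity_cluster(fps, tc, as.character(seq_len(nrow(fps))))
    expect_setequal(cl$ligand_id, as.character(seq_len(nrow(fps))))
    seeds <- which(cl$is_seed)
    seed_of <- vapply(split(seeds, cl$cluster[seeds]), `[`, 1L, 1L)
    # seeds are pairwise below the threshold (sphere exclusion)
    if (length(seeds) > 1) {
      off <- S[seeds, seeds]; diag(off) <- 0
      expect_lt(max(off), tc)
    }
    # every ligand sits with its most similar seed, hence within the sphere
    for (i in seq_len(nrow(fps))) {
      own <- S[i, seed_of[[as.character(cl$cluster[i])]]]
      expect_equal(own, max(S[i, seeds]))
      expect_gte(own, min(tc, 1) - 1e-12)
    }
  }
})

test_that("cluster centers minimize the summed Tanimoto distance", {
  f <- ecfp6(c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1"))
  # enumeration oracle over the three members
  S <- tanimoto_matrix(f)
  sums <- rowSums(1 - S)
  expect_identical(cluster_center(f, c("m1", "m2", "m3")),
                   c("m1", "m2", "m3")[which.min(sums)])
  # singleton
  expect_identical(cluster_center(f[1, , drop = FALSE], "only"), "only")
  # all identical: first in canonical order wins the tie
  same <- ecfp6(rep("CCO", 4))
  expect_identical(cluster_center(same, c("a", "b", "c", "d")), "a")
})

test_that("two-level clusters pool family ligands and partition them", {
  # one protein, five identical ligands at 100/1.0: a single cluster
  prot <- data.frame(protein_id = "P1", sequence = random_seq(100, 31),
                     stringsAsFactors = FALSE)
  lig <- make_records(sprintf("L%d", 1:5), rep("CCOc1ccccc1", 5),
                      rep("P1", 5))
  cl <- build_protein_ligand_clusters(lig, prot, 100, 1.0)
  expect_equal(length(unique(cl$clusters$cluster_id)), 1L)
  # pool dedups by molecule: five copies collapse to one row
  expect_equal(nrow(cl$clusters), 1L)

  # two unrelated proteins, one distinct ligand each: two clusters
  prot2 <- data.frame(protein_id = c("P1", "P2"),
                      sequence = c(random_seq(100, 32), random_seq(100, 33)),
                      stringsAsFactors = FALSE)
  lig2 <- make_records(c("L1", "L2"), c("c1ccccc1", "CCCCCC"),
                       c("P1", "P2"))
  cl2 <- build_protein_ligand_clusters(lig2, prot2, 60, 0.6)
  expect_equal(length(unique(cl2$clusters$cluster_id)), 2L)

  # a ligand targeting two unrelated families contributes to both pools
  lig3 <- make_records(c("L1", "L2", "Lboth"),
                       c("c1ccccc1", "CCCCCC", "CCOc1ccccc1"),
                       c("P1", "P2", "P1;P2"))
  cl3 <- build_protein_ligand_clusters(lig3, prot2, 60, 0.6)
  expect_equal(sum(cl3$clusters$ligand_id == "Lboth"), 2L)
  # within each family pool, ligands appear exactly once
  per_fam <- split(cl3$clusters$ligand_id, cl3$clusters$family_id)
  expect_true(all(vapply(per_fam, anyDuplicated, 1L) == 0L))
})

test_that("cluster counts do not decrease from the loosest to the strictest level", {
  st <- generate_study(synthetic_config(seed = 41, n_families_allo = 6,
                                        n_families_comp = 6,
                                        mean_ligands_per_family = 6,
                                        near_duplicate_rate = 0.4))
  lg <- st$ligands
  lg$smiles_raw <- lg$smiles
  cu <- quiet(curate_ligands(lg[lg$set_label == "allosteric", ]))
  lv <- clustering_levels()
  n <- vapply(seq_len(nrow(lv)), function(i) {
    cl <- build_protein_ligand_clusters(cu$ligands, st$proteins,
                                        lv$seq_identity_pct[i],
                                        lv$tc_threshold[i])
    length(unique(cl$clusters$cluster_id))
  }, 1L)
  expect_true(all(diff(n) >= 0))
})

test_that("re-clustering centers at threshold 1 leaves singletons", {
  smis <- unique(grammar_smiles(25, seed = 22))
  fps <- ecfp6(smis)
  cl <- max_dissimilarity_cluster(fps, 1.0, smis)
  centers <- cl$ligand_id[cl$is_center]
  cl2 <- max_dissimilarity_cluster(ecfp6(centers), 1.0, centers)
  expect_equal(max(table(cl2$cluster)), 1L)
})
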