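# helper: clustered values -> (values, weights) with weight 1/|cluster|
clustered <- function(...) {
  cl <- list(...)
  list(values = unlist(cl),
       weights = unlist(lapply(cl, function(x) rep(1 / length(x), length(x)))))
}

test_that("cluster weights give every cluster unit mass", {
  df <- data.frame(cluster_id = c(rep("c1", 4), "c2", rep("c3", 2)))
  w <- cluster_weights(df)
  expect_equal(w, c(rep(0.25, 4), 1, 0.5, 0.5))
  expect_equal(sum(w), 3)  # one unit per cluster
  expect_error(cluster_weights(df[0, , drop = FALSE]), "empty")
})

test_that("weighted histograms bin by floor with cluster-normalized mass", {
  h <- weighted_histogram(c(1, 1, 3), rep(1 / 3, 3), bin_width = 1)
  expect_equal(h$value, c(1, 3))
  expect_equal(h$mass, c(2 / 3, 1 / 3))
  h2 <- weighted_histogram(c(1, 3), c(1, 1), bin_width = 1)
  expect_equal(h2$mass, c(1, 1))
  expect_equal(h2$total_mass, 2)
  # continuous code: width 0.001, floor rule
  h3 <- weighted_histogram(3.4214, 1, code = "SlogP")
  expect_equal(h3$bin_width, 0.001)
  expect_equal(h3$index, 3421L)
  # discrete codes use width 1
  expect_equal(weighted_histogram(5, 1, code = "a_don")$bin_width, 1)
  expect_message(weighted_histogram(c(1, NA, 2), rep(1, 3), bin_width = 1),
                 "non-finite")
})

test_that("the weighted median takes the lower edge at half mass", {
  expect_equal(weighted_median(c(1, 3), c(0.5, 0.5), bin_width = 1), 1)
  # equal weights, odd n: plain sample median
  for (s in 1:20) {
    set.seed(s)
    x <- sample.int(50, 11, replace = TRUE)
    expect_equal(weighted_median(x, rep(1, 11), bin_width = 1), median(x))
  }
  # a huge cluster cannot outvote its unit mass
  cl <- clustered(rep(7, 100), 9)
  expect_equal(weighted_median(cl$values, cl$weights, bin_width = 1), 7)
  cl10 <- clustered(rep(7, 1000), 9)
  expect_equal(weighted_median(cl10$values, cl10$weights, bin_width = 1), 7)
  # weighted mean of bin lower edges
  expect_equal(weighted_mean(c(1, 3), c(1, 1), bin_width = 1), 2)
  expect_error(weighted_median(numeric(0), numeric(0), bin_width = 1))
})

test_that("the weighted Wilcoxon reduces to the classical test and ignores duplication", {
  expect_equal(weighted_wilcoxon(c(1, 2, 3), rep(1, 3), c(1, 2, 3), rep(1, 3)), 1)
  # equal weights: identical to the large-sample rank-sum, ties included
  for (s in 1:25) {
    set.seed(s)
    x <- sample.int(12, 14, replace = TRUE)
    y <- sample.int(12, 9, replace = TRUE) + s %% 4
    p1 <- weighted_wilcoxon(x, rep(1, length(x)), y, rep(1, length(y)))
    p2 <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value)
    expect_lt(abs(p1 - p2), 1e-12)
  }
  # k-fold duplication of a cluster's members leaves the p-value unchanged
  a <- clustered(c(1, 2, 2), c(4, 5), 7)
  b <- clustered(c(2, 3), c(5, 6, 8))
  p_ref <- weighted_wilcoxon(a$values, a$weights, b$values, b$weights)
  a_dup <- clustered(rep(c(1, 2, 2), 50), c(4, 5), 7)
  p_dup <- weighted_wilcoxon(a_dup$values, a_dup$weights, b$values, b$weights)
  expect_lt(abs(p_ref - p_dup), 1e-12)
  expect_error(weighted_wilcoxon(1, 0, 2, 1))
})

test_that("bootstrap CIs are deterministic, correct against direct resampling, and widen with smaller replicates", {
  # degenerate distribution
  h1 <- weighted_histogram(rep(4, 3), rep(1, 3), bin_width = 1)
  expect_equal(bootstrap_ci(h1, "median", 1000, seed = 1), c(4, 4))
  # determinism
  h <- weighted_histogram(c(rep(2, 6), rep(5, 4), rep(9, 3)), rep(1, 13),
                          bin_width = 1)
  ci1 <- bootstrap_ci(h, "median", 4000, seed = 7)
  expect_identical(ci1, bootstrap_ci(h, "median", 4000, seed = 7))
  # oracle: brute-force resampling of the same histogram
  set.seed(123)
  m <- 13
  reps <- replicate(40000, median(sample(h$value, m, TRUE,
                                         prob = h$mass / h$total_mass)))
  brute <- unname(quantile(reps, c(0.025, 0.975), names = FALSE))
  expect_equal(bootstrap_ci(h, "median", 40000, seed = 11), brute,
               tolerance = 1e-8)
  # halving the replicate size cannot narrow the CI of the median
  wide <- bootstrap_ci(h, "median", 20000, sample_size = 6, seed = 5)
  narrow <- bootstrap_ci(h, "median", 20000, sample_size = 13, seed = 5)
  expect_gte(diff(wide), diff(narrow))
  # mean CI brackets the true histogram mean
  hm <- weighted_histogram(c(rep(1, 10), rep(3, 10)), rep(1, 20),
                           bin_width = 1)
  cim <- bootstrap_ci(hm, "mean", 3000, sample_size = 200, seed = 9)
  expect_lt(cim[1], 2)
  expect_gt(cim[2], 2)
})

test_that("descriptor comparison flags shifted sets and not identical ones", {
  mkdesc <- function(vals) data.frame(ligand_id = sprintf("L%d", seq_along(vals)),
                                      a_don = vals,
                                      stringsAsFactors = FALSE)
  mkcl <- function(n) data.frame(cluster_id = sprintf("c%d", seq_len(n)),
                                 ligand_id = sprintf("L%d", seq_len(n)),
                                 is_seed = TRUE, is_center = TRUE,
                                 stringsAsFactors = FALSE)
  set.seed(31)
  base <- rpois(200, 2)
  same <- compare_descriptor("a_don", mkcl(200), mkcl(200),
                             mkdesc(base), mkdesc(base), n_boot = 2000)
  expect_false(same$significant)
  expect_gt(same$p_value, 0.9)
  shifted <- compare_descriptor("a_don", mkcl(200), mkcl(200),
                                mkdesc(base + 1), mkdesc(base),
                                n_boot = 2000, seed = 3)
  expect_true(shifted$significant)
  expect_lt(shifted$p_value, 1e-4)
  expect_gt(shifted$median_a, shifted$median_b)
  # centers scheme agrees in direction on the same data
  cen <- compare_descriptor("a_don", mkcl(200), mkcl(200),
                            mkdesc(base + 1), mkdesc(base),
                            scheme = "centers", n_boot = 2000, seed = 3)
  expect_gt(cen$median_a, cen$median_b)
  expect_true(cen$significant)
})

test_that("the robustness verdict demands all four levels with one direction", {
  mk <- function(sig, dir) {
    data.frame(code = "a_don", tc_threshold = c(0.6, 0.75, 0.9, 1.0),
               significant = sig, median_a = 1 + dir, median_b = 1,
               stringsAsFactors = FALSE)
  }
  expect_true(robust_verdict(mk(rep(TRUE, 4), 1))$significant_all_levels)
  expect_equal(robust_verdict(mk(rep(TRUE, 4), 1))$direction, "a_higher")
  expect_false(robust_verdict(mk(c(TRUE, TRUE, TRUE, FALSE), 1))$significant_all_levels)
  mixed <- mk(rep(TRUE, 4), 1)
  mixed$median_a <- c(2, 2, 0.5, 0.5)
  expect_false(robust_verdict(mixed)$significant_all_levels)
  expect_error(robust_verdict(mk(rep(TRUE, 4), 1)[1:3, ]), "four")
})

test_that("single-level clustering agrees with two-level when every protein stands alone", {
  # distinct chemotypes, one unrelated protein each
  smis <- unique(grammar_smiles(14, seed = 61))
  n <- length(smis)
  lig <- make_records(sprintf("L%02d", seq_len(n)), smis,
                      sprintf("P%02d", seq_len(n)))
  prot <- data.frame(protein_id = sprintf("P%02d", seq_len(n)),
                     sequence = vapply(seq_len(n), function(i)
                       random_seq(90, 100 + i), ""),
                     stringsAsFactors = FALSE)
  desc <- cbind(ligand_id = lig$ligand_id,
                compute_descriptors(lig$smiles_canonical))
  two <- build_protein_ligand_clusters(lig, prot, 100, 1.0)
  one <- cluster_ligand_set(lig, 1.0)
  r2 <- compare_all_descriptors(two, two, desc, desc, codes = "a_aro/HA",
                                n_boot = 500)
  r1 <- compare_all_descriptors(one, one, desc, desc, codes = "a_aro/HA",
                                n_boot = 500)
  expect_equal(r1$median_a, r2$median_a)
  expect_equal(r1$p_value, r2$p_value)
  # identical sets are never significant
  sl <- single_level_analysis(lig, lig, desc, desc, tc_thresholds = c(0.6, 1.0),
                              codes = c("a_aro/HA", "a_don"), n_boot = 500)
  expect_false(any(sl$significant))
})
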