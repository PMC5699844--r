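# Two-level redundancy removal: greedy protein families by bidirectional
# sequence identity, then per-family ligand clustering by maximum
# dissimilarity on ECFP6/Tanimoto, with cluster-center selection.

#' The four paired clustering levels
#'
#' Sequence-identity / Tanimoto thresholds are varied in lockstep:
#' 60%/0.6, 75%/0.75, 90%/0.9, 100%/1.0. Trends must hold at every level to
#' be considered robust.
#'
#' @return Data.frame with columns `seq_identity_pct` and `tc_threshold`.
#' @export
clustering_levels <- function() {
  data.frame(seq_identity_pct = c(60, 75, 90, 100),
             tc_threshold = c(0.6, 0.75, 0.9, 1.0))
}

#' Bidirectional local-alignment sequence identity
#'
#' Aligns two amino-acid sequences locally (BLOSUM62, gap open 11, extend 1)
#' and reports the percentage of identical aligned positions relative to
#' each sequence's own length, giving the directional asymmetry used by
#' bidirectional greedy clustering: `identity_ab` uses `length(a)` as
#' denominator, `identity_ba` uses `length(b)`.
#'
#' @param a,b Amino-acid sequences (character strings).
#' @return Named numeric vector `c(identity_ab, identity_ba)`, both in
#'   `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
  nm <- Biostrings::nmatch(al)
  c(identity_ab = 100 * nm / nchar(a), identity_ba = 100 * nm / nchar(b))
}

#' Greedy protein families at a sequence-identity threshold
#'
#' Proteins are processed in canonical order (descending sequence length,
#' ties broken lexicographically by id). Each protein joins the first
#' existing family whose representative satisfies
#' `min(identity_ab, identity_ba) >= threshold`, otherwise it founds a new
#' family whose representative it becomes. The output partitions the input.
#'
#' @param proteins Data.frame with `protein_id` and `sequence` columns,
#'   unique by `protein_id`.
#' @param seq_identity_pct Identity threshold in percent (e.g. 60, 75, 90,
#'   100). At 100 the families are groups of identical sequences.
#' @return Data.frame `family_id`, `protein_id`, `is_representative`, with
#'   attribute `seq_identity_pct`.
#' @export
greedy_protein_families <- function(proteins, seq_identity_pct) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)),
            !anyDuplicated(proteins$protein_id))
  p <- proteins[order(-nchar(proteins$sequence), proteins$protein_id), ,
                drop = FALSE]
  n <- nrow(p)
  fam <- integer(n)
  if (seq_identity_pct >= 100) {
    fam <- match(p$sequence, unique(p$sequence))
    rep_idx <- match(seq_len(max(fam)), fam)
  } else {
    # identical sequences always co-cluster; align unique sequences only
    useq <- unique(p$sequence)
    m <- length(useq)
    ulen <- nchar(useq)
    # bidirectional identity = nmatch / max(len) for every unique pair,
    # computed in one vectorized elementwise alignment call
    idmat <- matrix(100, m, m)
    if (m > 1L) {
      pr <- t(combn(m, 2L))
      # nmatch is threshold-independent; cache per sequence pair so the four
      # clustering levels (and repeated runs) align each pair only once
      cache <- .cache_env("nmatch")
      keys <- paste(useq[pr[, 1L]], useq[pr[, 2L]], sep = "\r")
      nmv <- rep(NA_real_, nrow(pr))
      hit <- vapply(keys, function(k) !is.null(cache[[k]]), TRUE)
      nmv[hit] <- vapply(keys[hit], function(k) cache[[k]], 1)
      miss <- which(!hit)
      if (length(miss)) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(useq[pr[miss, 1L]]),
          Biostrings::AAStringSet(useq[pr[miss, 2L]]), type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
        nmv[miss] <- Biostrings::nmatch(al)
        for (j in miss) cache[[keys[j]]] <- nmv[j]
      }
      idv <- 100 * nmv / pmax(ulen[pr[, 1L]], ulen[pr[, 2L]])
      idmat[pr] <- idv
      idmat[pr[, 2:1, drop = FALSE]] <- idv
    }
    uidx <- match(p$sequence, useq)
    reps <- integer(0)       # row indices of representatives, founding order
    for (i in seq_len(n)) {
      okf <- which(idmat[uidx[reps], uidx[i]] >= seq_identity_pct)
      if (length(okf)) {
        fam[i] <- okf[1L]
      } else {
        reps <- c(reps, i)
        fam[i] <- length(reps)
      }
    }
    rep_idx <- reps
  }
  out <- data.frame(family_id = sprintf("fam%04d", fam),
                    protein_id = p$protein_id,
                    is_representative = seq_len(n) %in% rep_idx,
                    stringsAsFactors = FALSE)
  out <- out[order(out$family_id, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seq_identity_pct") <- seq_identity_pct
  out
}

#' Maximum-dissimilarity (sphere-exclusion) ligand clustering
#'
#' Seed selection by maximum dissimilarity: the first seed is the ligand
#' with minimal total similarity to all others; seeds are then added by
#' picking the ligand whose nearest-seed similarity is smallest, until every
#' non-seed ligand has nearest-seed Tanimoto >= `tc_threshold`. Every ligand
#' is finally assigned to its most similar seed (ties resolved toward the
#' seed earliest in the input/canonical order). At threshold 1 the clusters
#' are exactly the groups of identical fingerprints.
#'
#' @param fps Fingerprint matrix ([ecfp6()]), rows in canonical ligand order
#'   (descending heavy-atom count, ties lexicographic by id).
#' @param tc_threshold Tanimoto radius of a cluster.
#' @param ligand_ids Ids for the rows; defaults to rownames.
#' @return Data.frame `cluster` (integer, numbered by seed order in the
#'   input), `ligand_id`, `is_seed` (the sphere-exclusion seed that founded
#'   the cluster), and `is_center` (center = member minimizing the sum of
#'   `1 - Tc` distances to the other members).
#' @export
max_dissimilarity_cluster <- function(fps, tc_threshold,
                                      ligand_ids = rownames(fps)) {
  n <- nrow(fps)
  stopifnot(n >= 1)
  if (is.null(ligand_ids)) ligand_ids <- as.character(seq_len(n))
  if (n == 1L)
    return(data.frame(cluster = 1L, ligand_id = ligand_ids, is_seed = TRUE,
                      is_center = TRUE, stringsAsFactors = FALSE))
  S <- tanimoto_matrix(fps)
  seeds <- which.min(rowSums(S))  # minimal total similarity, first on ties
  repeat {
    non <- setdiff(seq_len(n), seeds)
    if (!length(non)) break
    nearest <- apply(S[non, seeds, drop = FALSE], 1L, max)
    if (all(nearest >= tc_threshold)) break
    seeds <- c(seeds, non[which.min(nearest)])
  }
  seeds <- sort(seeds)
  assign <- vapply(seq_len(n), function(i) {
    sims <- S[i, seeds]
    min(which(sims == max(sims)))  # earliest (canonical-order) seed on ties
  }, 1L)
  out <- data.frame(cluster = assign, ligand_id = ligand_ids,
                    is_seed = seq_len(n) %in% seeds,
                    is_center = FALSE, stringsAsFactors = FALSE)
  for (k in unique(assign)) {
    mem <- which(assign == k)
    out$is_center[mem[cluster_center_index(S[mem, mem, drop = FALSE])]] <- TRUE
  }
  out$cluster <- match(out$cluster, sort(unique(out$cluster)))
  out
}

# index of the center given a member similarity submatrix
cluster_center_index <- function(S) {
  d <- rowSums(1 - S)
  which.min(d)  # first index on ties = canonical order
}

#' Cluster center: member with smallest total Tanimoto distance
#'
#' The center of a cluster is the member minimizing the sum of `1 - Tc`
#' distances to the other members; ties go to the member earliest in the
#' canonical order. A singleton's center is its only member.
#'
#' @param fps Fingerprint matrix of the cluster members, canonical order.
#' @param ligand_ids Ids for the rows; defaults to rownames.
#' @return The center's ligand id.
#' @export
cluster_center <- function(fps, ligand_ids = rownames(fps)) {
  n <- nrow(fps)
  stopifnot(n >= 1)
  if (is.null(ligand_ids)) ligand_ids <- as.character(seq_len(n))
  if (n == 1L) return(ligand_ids)
  ligand_ids[cluster_center_index(tanimoto_matrix(fps))]
}

# heavy-atom counts with session cache (for canonical ligand ordering)
.heavy_count <- function(smiles) {
  cache <- .cache_env("ha")
  hit <- vapply(smiles, function(s) !is.null(cache[[s]]), TRUE)
  todo <- unique(smiles[!hit])
  if (length(todo)) {
    ha <- ob_smarts_count(ob_mols(todo), "[*]")
    for (i in seq_along(todo)) cache[[todo[i]]] <- ha[i]
  }
  vapply(smiles, function(s) cache[[s]], 1)
}

#' Two-level protein-ligand clusters at one clustering level
#'
#' For each greedy protein family, pools the ligands of all member proteins
#' (a ligand targeting proteins in k families appears in k pools), removes
#' within-pool duplicates by canonical SMILES, and clusters the pool by
#' maximum dissimilarity at the level's Tanimoto threshold. The resulting
#' protein-ligand clusters are the normalization unit for all downstream
#' statistics.
#'
#' @param ligands Curated ligand records (`ligand_id`, `smiles_canonical`,
#'   `target_ids`), e.g. one set from [curate_ligands()].
#' @param proteins Protein records (`protein_id`, `sequence`).
#' @param seq_identity_pct,tc_threshold The clustering level (see
#'   [clustering_levels()]).
#' @param n_bits Fingerprint width for [ecfp6()].
#' @return Object of class `allocomp_clusters`: list with `level`,
#'   `families` (from [greedy_protein_families()]) and `clusters`
#'   (data.frame `family_id`, `cluster_id`, `ligand_id`, `smiles_canonical`,
#'   `is_center`).
#' @export
build_protein_ligand_clusters <- function(ligands, proteins,
                                          seq_identity_pct, tc_threshold,
                                          n_bits = 2048) {
  stopifnot(all(c("ligand_id", "smiles_canonical", "target_ids")
                %in% names(ligands)))
  used <- unique(unlist(strsplit(ligands$target_ids, ";", fixed = TRUE)))
  prot <- proteins[proteins$protein_id %in% used, , drop = FALSE]
  fam <- greedy_protein_families(prot, seq_identity_pct)
  targ <- strsplit(ligands$target_ids, ";", fixed = TRUE)
  ha <- .heavy_count(ligands$smiles_canonical)

  res <- vector("list", length(unique(fam$family_id)))
  fam_ids <- unique(fam$family_id)
  for (fi in seq_along(fam_ids)) {
    members <- fam$protein_id[fam$family_id == fam_ids[fi]]
    inpool <- which(vapply(targ, function(t) any(t %in% members), TRUE))
    if (!length(inpool)) next
    pool <- ligands[inpool, c("ligand_id", "smiles_canonical"), drop = FALSE]
    pool$ha <- ha[inpool]
    # within-pool dedup by molecule, keep smallest ligand_id
    pool <- pool[order(pool$ligand_id), , drop = FALSE]
    pool <- pool[!duplicated(pool$smiles_canonical), , drop = FALSE]
    # canonical order: descending heavy atoms, ties lexicographic by id
    pool <- pool[order(-pool$ha, pool$ligand_id), , drop = FALSE]
    fps <- ecfp6(pool$smiles_canonical, n_bits)
    cl <- max_dissimilarity_cluster(fps, tc_threshold, pool$ligand_id)
    res[[fi]] <- data.frame(
      family_id = fam_ids[fi],
      cluster_id = sprintf("%s.c%04d", fam_ids[fi], cl$cluster),
      ligand_id = cl$ligand_id,
      smiles_canonical = pool$smiles_canonical[match(cl$ligand_id,
                                                     pool$ligand_id)],
      is_center = cl$is_center,
      stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  rownames(clusters) <- NULL
  structure(list(level = c(seq_identity_pct = seq_identity_pct,
                           tc_threshold = tc_threshold),
                 families = fam, clusters = clusters),
            class = "allocomp_clusters")
}

#' @export
print.allocomp_clusters <- function(x, ...) {
  cat(sprintf(
    "protein-ligand clusters at %g%%/%g: %d proteins in %d families, %d ligand instances in %d clusters\n",
    x$level[["seq_identity_pct"]], x$level[["tc_threshold"]],
    nrow(x$families), length(unique(x$families$family_id)),
    nrow(x$clusters), length(unique(x$clusters$cluster_id))))
  invisible(x)
}

#' Cluster one ligand set globally by chemistry (single-level scheme)
#'
#' Ignores protein families entirely: the whole set is clustered by maximum
#' dissimilarity at the given Tanimoto threshold. Used by the single-level
#' sanity-check analysis.
#'
#' @param ligands Curated ligand records.
#' @param tc_threshold Tanimoto threshold.
#' @param n_bits Fingerprint width.
#' @return `allocomp_clusters` object with a single pseudo-family `"all"`.
#' @export
cluster_ligand_set <- function(ligands, tc_threshold, n_bits = 2048) {
  pool <- ligands[order(ligands$ligand_id), , drop = FALSE]
  pool <- pool[!duplicated(pool$smiles_canonical), , drop = FALSE]
  pool$ha <- .heavy_count(pool$smiles_canonical)
  pool <- pool[order(-pool$ha, pool$ligand_id), , drop = FALSE]
  fps <- ecfp6(pool$smiles_canonical, n_bits)
  cl <- max_dissimilarity_cluster(fps, tc_threshold, pool$ligand_id)
  clusters <- data.frame(
    family_id = "all",
    cluster_id = sprintf("all.c%04d", cl$cluster),
    ligand_id = cl$ligand_id,
    smiles_canonical = pool$smiles_canonical[match(cl$ligand_id,
                                                   pool$ligand_id)],
    is_center = cl$is_center,
    stringsAsFactors = FALSE)
  structure(list(level = c(seq_identity_pct = NA, tc_threshold = tc_threshold),
                 families = data.frame(family_id = "all",
                                       protein_id = NA_character_,
                                       is_representative = NA),
                 clusters = clusters),
            class = "allocomp_clusters")
}
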