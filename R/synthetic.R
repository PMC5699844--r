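# Synthetic studies with known ground truth. Ligands come from a closed
# fragment grammar (every assembled SMILES is valid and survives washing),
# proteins from mutated scaffolds at controlled pairwise identity, so every
# pipeline stage can be exercised without any external data source.

# Fragment table. Segments have two attachment points and are concatenated
# left-to-right; caps terminate the chain. Per-fragment heavy-atom, aromatic
# and (post-wash) donor contributions are exact by construction; rotatable
# contributions are the approximate count model used for steering.
.fragments_build <- function() {
  seg <- data.frame(
    name  = c("arom", "pyr", "naph", "alk1", "alk2", "alk3", "alk4",
              "chx", "amide", "ether", "branch"),
    smi   = c("c1ccccc1", "c1ccncc1", "c1ccc2ccccc2c1", "C", "CC", "CCC",
              "CCCC", "C1CCCCC1", "C(=O)N", "O", "C(C)"),
    heavy = c(6, 6, 10, 1, 2, 3, 4, 6, 3, 1, 2),
    aro   = c(6, 6, 10, 0, 0, 0, 0, 0, 0, 0, 0),
    don   = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0),
    rot   = c(0, 0, 0, 0, 1, 2, 3, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  cap <- data.frame(
    name  = c("h", "me", "oh", "nh2", "cl", "cooh"),
    smi   = c("", "C", "O", "N", "Cl", "C(=O)O"),
    heavy = c(0, 1, 1, 1, 1, 3),
    aro   = 0,
    don   = c(0, 0, 1, 1, 0, 0),  # washed: COOH deprotonates, NH2 keeps H
    rot   = c(0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  list(seg = seg, cap = cap)
}

.fragments_const <- .fragments_build()
.fragments <- function() .fragments_const

#' Default fragment-grammar weights
#'
#' Relative draw weights for the ligand grammar of [generate_ligand()]:
#' `seg_*` entries weight the chain segments (aromatic and pyridine rings,
#' alkyl linkers of 1-3 carbons, amide, ether, methyl branch), `cap_*` the
#' terminal caps (H, methyl, hydroxyl, amine, chloro, carboxyl). The
#' defaults produce small drug-like molecules with roughly half-aromatic
#' heavy atoms.
#'
#' @return Named numeric vector of weights.
#' @export
default_grammar_weights <- function() {
  c(seg_arom = 0.24, seg_pyr = 0.07, seg_naph = 0.05, seg_alk1 = 0.12,
    seg_alk2 = 0.10, seg_alk3 = 0.07, seg_alk4 = 0.04, seg_chx = 0.06,
    seg_amide = 0.09, seg_ether = 0.08, seg_branch = 0.08,
    cap_h = 0.25, cap_me = 0.20, cap_oh = 0.18, cap_nh2 = 0.12,
    cap_cl = 0.15, cap_cooh = 0.10)
}

.split_weights <- function(weights) {
  fr <- .fragments()
  ws <- weights[paste0("seg_", fr$seg$name)]
  wc <- weights[paste0("cap_", fr$cap$name)]
  ws[is.na(ws)] <- 0; wc[is.na(wc)] <- 0
  if (sum(ws) <= 0) stop("segment weights must not all be zero")
  if (sum(wc) <= 0) { wc[] <- 0; wc[1L] <- 1 }  # fall back to H caps
  list(seg = as.numeric(ws) / sum(ws), cap = as.numeric(wc) / sum(wc))
}

# draw fragment index sequences for n molecules (count level, no chemistry).
# Segment types follow a two-state Markov chain over {aromatic, aliphatic}
# whose stationary aromatic share equals the weights' share: after an
# aromatic segment the aromatic group weight is damped by `alternation`
# (scaffold-linker alternation, as in real medicinal-chemistry series),
# which narrows the per-molecule aromatic-fraction spread without moving
# its mean.
.draw_structure <- function(n, w, length_lambda, alternation = 0.4) {
  fr <- .fragments()
  nseg <- 1L + rpois(n, length_lambda)
  aro_idx <- which(fr$seg$aro > 0)
  ali_idx <- which(fr$seg$aro == 0)
  wA <- sum(w$seg[aro_idx]); wN <- sum(w$seg[ali_idx])
  p0 <- wA / (wA + wN)
  pick <- function(active, idx) {
    # independent within-group draws for the active molecules
    pr <- w$seg[idx] / sum(w$seg[idx])
    idx[findInterval(runif(sum(active)), cumsum(pr), left.open = TRUE) + 1L]
  }
  if (p0 <= 0 || p0 >= 1) {
    segs <- lapply(nseg, function(k)
      sample.int(nrow(fr$seg), k, replace = TRUE, prob = w$seg))
  } else {
    a2 <- alternation * wA / (alternation * wA + wN)   # P(aro | prev aro)
    p1 <- min(1, p0 * (1 - a2) / (1 - p0))             # P(aro | prev ali)
    segmat <- matrix(NA_integer_, n, max(nseg))
    prev_aro <- runif(n) < p0
    for (t in seq_len(max(nseg))) {
      active <- nseg >= t
      p_t <- if (t == 1L) rep(p0, n) else ifelse(prev_aro, a2, p1)
      is_aro <- runif(n) < p_t
      ia <- active & is_aro; in_ <- active & !is_aro
      if (any(ia)) segmat[ia, t] <- pick(ia, aro_idx)
      if (any(in_)) segmat[in_, t] <- pick(in_, ali_idx)
      prev_aro <- is_aro
    }
    segs <- lapply(seq_len(n), function(i) segmat[i, seq_len(nseg[i])])
  }
  list(nseg = nseg,
       segs = segs,
       capl = sample.int(nrow(fr$cap), n, replace = TRUE, prob = w$cap),
       capr = sample.int(nrow(fr$cap), n, replace = TRUE, prob = w$cap))
}

.structure_smiles <- function(st) {
  fr <- .fragments()
  vapply(seq_along(st$nseg), function(i) {
    paste0(fr$cap$smi[st$capl[i]],
           paste(fr$seg$smi[st$segs[[i]]], collapse = ""),
           fr$cap$smi[st$capr[i]])
  }, "")
}

# exact aromatic/heavy and approximate donor/rotatable counts per structure
.structure_counts <- function(st) {
  fr <- .fragments()
  n <- length(st$nseg)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("heavy", "aro", "don", "rot")))
  for (i in seq_len(n)) {
    s <- st$segs[[i]]
    cl <- st$capl[i]; cr <- st$capr[i]
    out[i, "heavy"] <- sum(fr$seg$heavy[s]) + fr$cap$heavy[cl] + fr$cap$heavy[cr]
    out[i, "aro"] <- sum(fr$seg$aro[s])
    out[i, "don"] <- sum(fr$seg$don[s]) + fr$cap$don[cl] + fr$cap$don[cr]
    out[i, "rot"] <- sum(fr$seg$rot[s]) + (length(s) - 1L) +
      fr$cap$rot[cl] + fr$cap$rot[cr]
  }
  out
}

#' Expected descriptor fractions of the fragment grammar
#'
#' Count-level expectation of the per-heavy-atom aromatic, donor and
#' rotatable-bond fractions under given grammar weights, computed by
#' simulating fragment compositions only (no molecule is ever assembled, so
#' this is an oracle independent of the chemistry stack). Aromatic and heavy
#' counts are exact by construction; donor and rotatable contributions use
#' the grammar's count model.
#'
#' @param weights Grammar weights (see [default_grammar_weights()]).
#' @param length_lambda Mean extra segments; chain length is
#'   `1 + Poisson(length_lambda)`.
#' @param n Monte Carlo size.
#' @param seed RNG seed (caller's RNG state is preserved).
#' @return Named numeric: `aromatic_fraction`, `donor_fraction`,
#'   `rot_fraction` (means of the per-molecule ratios).
#' @export
expected_grammar_fractions <- function(weights = default_grammar_weights(),
                                       length_lambda = 6, n = 20000,
                                       seed = 99) {
  w <- .split_weights(weights)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  st <- .draw_structure(n, w, length_lambda)
  cnt <- .structure_counts(st)
  c(aromatic_fraction = mean(cnt[, "aro"] / cnt[, "heavy"]),
    donor_fraction = mean(cnt[, "don"] / cnt[, "heavy"]),
    rot_fraction = mean(cnt[, "rot"] / cnt[, "heavy"]))
}

#' Generate one ligand SMILES from the fragment grammar
#'
#' Assembles a chain of `1 + Poisson(length_lambda)` segments with two caps.
#' The grammar is closed under validity: every emitted SMILES parses, is a
#' single fragment, and survives [wash_smiles()].
#'
#' @param weights Grammar weights.
#' @param seed Optional seed for a reproducible single draw.
#' @param length_lambda Mean extra segments.
#' @return A SMILES string.
#' @export
generate_ligand <- function(weights = default_grammar_weights(), seed = NULL,
                            length_lambda = 6) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  w <- .split_weights(weights)
  .structure_smiles(.draw_structure(1L, w, length_lambda))
}

# steer grammar weights so the count-model expectation of a fraction moves
# by `delta`; knob = multiplicative factor on the named weight entries
.steer_one <- function(weights, knob_names, target_fun, delta, length_lambda) {
  base <- target_fun(weights)
  f <- function(logx) {
    w <- weights
    w[knob_names] <- w[knob_names] * exp(logx)
    target_fun(w) - (base + delta)
  }
  lo <- -4; hi <- 4
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop("requested shift ", delta, " is outside the grammar's reachable range")
  r <- uniroot(f, c(lo, hi), tol = 1e-4)
  weights[knob_names] <- weights[knob_names] * exp(r$root)
  weights
}

.steer_weights <- function(weights, shift_spec, length_lambda, mc_n = 20000,
                           mc_seed = 99) {
  if (!length(shift_spec)) return(weights)
  cache <- .cache_env("steer")
  key <- paste(c(weights, shift_spec, names(shift_spec), length_lambda),
               collapse = "|")
  if (!is.null(cache[[key]])) return(cache[[key]])
  frac <- function(which) function(w)
    expected_grammar_fractions(w, length_lambda, mc_n, mc_seed)[[which]]
  norm <- function(nm) {
    nm <- sub("/HA", "_per_HA", nm, fixed = TRUE)
    c(a_aro_per_HA = "aromatic", aromatic_fraction = "aromatic",
      a_don_per_HA = "donor", hbd_per_HA = "donor",
      b_1rotN_per_HA = "rot", rot_per_HA = "rot")[[nm]]
  }
  for (nm in names(shift_spec)) {
    kind <- norm(nm)
    if (is.null(kind)) stop("unsupported shift target: ", nm)
    knobs <- switch(kind,
                    aromatic = c("seg_arom", "seg_pyr", "seg_naph"),
                    donor = c("cap_oh", "cap_nh2", "seg_amide"),
                    rot = c("seg_alk1", "seg_alk2", "seg_alk3", "seg_alk4"))
    target <- switch(kind, aromatic = "aromatic_fraction",
                     donor = "donor_fraction", rot = "rot_fraction")
    weights <- .steer_one(weights, knobs, frac(target), shift_spec[[nm]],
                          length_lambda)
  }
  cache[[key]] <- weights
  weights
}

#' Synthetic-study configuration
#'
#' Defines the conditions of a generated two-set study: family counts,
#' ligand-per-family size skew (Zipf-like, so a few families hold a large
#' share of the ligands, mimicking over-studied drug targets), within-family
#' protein identity, descriptor shifts applied to the first (allosteric)
#' set, near-duplicate redundancy, exact duplicate rows, and an optional
#' panel artifact (a few ligands annotated against hundreds of targets).
#'
#' @param n_families_allo,n_families_comp Protein families per set.
#' @param proteins_per_family Sequences per family.
#' @param protein_length Scaffold length in residues.
#' @param identity_within_family Pairwise identity (%) within a family.
#' @param mean_ligands_per_family Mean family pool size (sizes follow a
#'   truncated power law).
#' @param size_skew Power-law exponent for family sizes (larger = more even).
#' @param near_duplicate_rate Fraction of ligands that are cap-variants of an
#'   earlier ligand of the same family (chemical redundancy).
#' @param duplicate_rate Fraction of rows duplicated verbatim (exact
#'   protein-ligand repeats, culled by [dedup_ligands()]).
#' @param shift_spec Named numeric; additive shifts of count-model
#'   expectations applied to the allosteric set's grammar. Supported names:
#'   `"a_aro/HA"`, `"a_don/HA"`, `"b_1rotN/HA"` (or `aromatic_fraction`,
#'   `hbd_per_HA`, `rot_per_HA`).
#' @param panel_artifact `NULL`, or `c(n_ligands, n_targets)`: extra ligands
#'   in the competitive set annotated against a large decoy target panel.
#' @param weights Base grammar weights for both sets.
#' @param length_lambda Grammar chain-length parameter.
#' @param seed Integer seed; the study is a pure function of the config.
#' @param protein_seed Optional separate seed for the protein sequences;
#'   lets a series of studies share one fixed target panel while the
#'   chemistry is resampled (`NULL` = derive everything from `seed`).
#' @return A list of class `allocomp_synth_config`.
#' @export
synthetic_config <- function(n_families_allo = 30, n_families_comp = 30,
                             proteins_per_family = 2, protein_length = 120,
                             identity_within_family = 92,
                             mean_ligands_per_family = 10, size_skew = 1,
                             near_duplicate_rate = 0.25, duplicate_rate = 0,
                             shift_spec = numeric(), panel_artifact = NULL,
                             weights = default_grammar_weights(),
                             length_lambda = 6, seed = 1,
                             protein_seed = NULL) {
  stopifnot(n_families_allo >= 1, n_families_comp >= 1,
            proteins_per_family >= 1, protein_length >= 30,
            identity_within_family > 0, identity_within_family <= 100,
            mean_ligands_per_family >= 1,
            near_duplicate_rate >= 0, near_duplicate_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  if (!is.null(panel_artifact)) stopifnot(length(panel_artifact) == 2,
                                          all(panel_artifact >= 1))
  structure(as.list(environment()), class = "allocomp_synth_config")
}

#' Generate a protein family at a target pairwise identity
#'
#' Draws one random scaffold and emits `n` members, each mutated at a
#' disjoint set of interior positions covering a fraction `(1 - t/100)/2` of
#' the sequence, so that every pair of members differs at twice that
#' fraction and all realized pairwise identities sit at the target (within
#' ~3 points after alignment). Terminal residues are never mutated so local
#' alignment spans the full sequence. At 100% identity all members are
#' identical.
#'
#' @param n Number of member sequences.
#' @param identity_target Pairwise identity in percent, `(0, 100]`.
#' @param length Sequence length in residues.
#' @param seed Optional seed.
#' @param prefix Protein id prefix.
#' @return Data.frame `protein_id`, `name`, `sequence`.
#' @export
generate_protein_family <- function(n, identity_target, length = 120,
                                    seed = NULL, prefix = "prot") {
  stopifnot(n >= 1, identity_target > 0)
  if (identity_target > 100) stop("identity_target above 100% is infeasible")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  scaffold <- sample(aa, length, replace = TRUE)
  k <- round((1 - identity_target / 100) / 2 * length)
  mutable <- seq(6L, length - 5L)
  if (n * k > base::length(mutable))
    stop("identity target ", identity_target,
         "% is infeasible for n = ", n, " at length ", length)
  pos <- if (k > 0) sample(mutable, n * k) else integer(0)
  seqs <- vapply(seq_len(n), function(i) {
    s <- scaffold
    if (k > 0) {
      p <- pos[((i - 1L) * k + 1L):(i * k)]
      s[p] <- vapply(s[p], function(r) sample(setdiff(aa, r), 1L), "")
    }
    paste(s, collapse = "")
  }, "")
  data.frame(protein_id = sprintf("%s_%02d", prefix, seq_len(n)),
             name = sprintf("synthetic protein %s_%02d", prefix, seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}

# Zipf-like family pool sizes: size_i proportional to i^-skew, scaled to the
# requested mean, minimum 1
.family_sizes <- function(n, mean_size, skew) {
  raw <- (seq_len(n))^(-skew)
  sizes <- pmax(1L, round(raw * n * mean_size / sum(raw)))
  sizes[sample.int(n)]  # shuffle so family index does not encode size
}

#' Generate a complete synthetic two-set study
#'
#' Emits a ligand table, protein sequences, an assay table and a
#' ground-truth manifest, all a deterministic function of the config seed.
#' The two sets share the base grammar; the allosteric set's grammar weights
#' are re-calibrated so its count-model descriptor expectations differ by
#' the configured `shift_spec`. Redundancy skew, exact duplicate rows and
#' panel artifacts are injected as configured and recorded in the manifest.
#'
#' @param config A [synthetic_config()].
#' @return List of class `allocomp_study`: `ligands` (raw ligand table with
#'   `smiles` as generated), `proteins`, `assays`, `manifest`.
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "allocomp_synth_config"))
  w_b <- config$weights
  w_a <- .steer_weights(w_b, config$shift_spec, config$length_lambda)

  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)

  sets <- list(
    list(label = "allosteric", tag = "A", weights = .split_weights(w_a),
         nfam = config$n_families_allo, stem = "Allosteric modulation"),
    list(label = "competitive", tag = "B", weights = .split_weights(w_b),
         nfam = config$n_families_comp, stem = "Competitive inhibition"))

  # proteins first, under their own seed when configured, so studies can
  # share a fixed target panel while the chemistry is resampled
  set.seed(if (is.null(config$protein_seed)) config$seed
           else config$protein_seed)
  fam_prots <- lapply(sets, function(s)
    lapply(seq_len(s$nfam), function(fi)
      generate_protein_family(config$proteins_per_family,
                              config$identity_within_family,
                              config$protein_length,
                              prefix = sprintf("%s_f%03d", s$tag, fi))))
  set.seed(config$seed)

  lig_rows <- list(); prot_rows <- list(); assay_rows <- list()
  fam_rows <- list(); lig_counter <- 0L

  for (si in seq_along(sets)) {
    s <- sets[[si]]
    sizes <- .family_sizes(s$nfam, config$mean_ligands_per_family,
                           config$size_skew)
    for (fi in seq_len(s$nfam)) {
      fam_tag <- sprintf("%s_f%03d", s$tag, fi)
      prots <- fam_prots[[si]][[fi]]
      prot_rows[[length(prot_rows) + 1L]] <- prots
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(set_label = s$label, family = fam_tag,
                   protein_id = prots$protein_id, stringsAsFactors = FALSE)
      n_l <- sizes[fi]
      structs <- vector("list", n_l)
      for (j in seq_len(n_l)) {
        if (j > 1L && runif(1) < config$near_duplicate_rate) {
          base_st <- structs[[sample.int(j - 1L, 1L)]]
          st <- base_st  # cap-variant of an earlier family member
          st$capl <- sample.int(nrow(.fragments()$cap), 1L, prob = s$weights$cap)
          st$capr <- sample.int(nrow(.fragments()$cap), 1L, prob = s$weights$cap)
          structs[[j]] <- st
        } else {
          structs[[j]] <- .draw_structure(1L, s$weights, config$length_lambda)
        }
      }
      smis <- vapply(structs, .structure_smiles, "")
      ids <- sprintf("L%s%05d", s$tag, lig_counter + seq_len(n_l))
      lig_counter <- lig_counter + n_l
      targets <- prots$protein_id[sample.int(nrow(prots), n_l, replace = TRUE)]
      lig_rows[[length(lig_rows) + 1L]] <-
        data.frame(ligand_id = ids, smiles = smis, set_label = s$label,
                   target_ids = targets, source = "synthetic",
                   assay_id = sprintf("assay_%s", fam_tag),
                   stringsAsFactors = FALSE)
      assay_rows[[length(assay_rows) + 1L]] <-
        data.frame(assay_id = sprintf("assay_%s", fam_tag),
                   description = sprintf("%s of target family %s", s$stem, fam_tag),
                   is_hts = FALSE,
                   standard_value = signif(rlnorm(1, log(100), 1), 3),
                   ligand_ids = paste(ids, collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }

  ligands <- do.call(rbind, lig_rows)
  dup_ids <- character(0)
  if (config$duplicate_rate > 0) {
    ndup <- round(config$duplicate_rate * nrow(ligands))
    if (ndup > 0) {
      di <- sample.int(nrow(ligands), ndup)
      dup_ids <- ligands$ligand_id[di]
      ligands <- rbind(ligands, ligands[di, , drop = FALSE])
    }
  }

  panel_ids <- character(0)
  if (!is.null(config$panel_artifact)) {
    n_pl <- as.integer(config$panel_artifact[[1]])
    n_pt <- as.integer(config$panel_artifact[[2]])
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    pseq <- vapply(seq_len(n_pt), function(i)
      paste(sample(aa, 100, replace = TRUE), collapse = ""), "")
    pprot <- data.frame(protein_id = sprintf("PANEL_%03d", seq_len(n_pt)),
                        name = "synthetic panel kinase",
                        sequence = pseq, stringsAsFactors = FALSE)
    prot_rows[[length(prot_rows) + 1L]] <- pprot
    panel_ids <- sprintf("LPANEL%03d", seq_len(n_pl))
    psmis <- vapply(seq_len(n_pl), function(i)
      .structure_smiles(.draw_structure(1L, sets[[2]]$weights,
                                        config$length_lambda)), "")
    ligands <- rbind(ligands, data.frame(
      ligand_id = panel_ids, smiles = psmis, set_label = "competitive",
      target_ids = paste(pprot$protein_id, collapse = ";"),
      source = "synthetic", assay_id = "assay_panel",
      stringsAsFactors = FALSE))
    assay_rows[[length(assay_rows) + 1L]] <-
      data.frame(assay_id = "assay_panel",
                 description = "Competitive inhibition panel profiling",
                 is_hts = FALSE, standard_value = 10,
                 ligand_ids = paste(panel_ids, collapse = ";"),
                 stringsAsFactors = FALSE)
  }

  rownames(ligands) <- NULL
  structure(list(
    ligands = ligands,
    proteins = do.call(rbind, prot_rows),
    assays = do.call(rbind, assay_rows),
    manifest = list(seed = config$seed, shift_spec = config$shift_spec,
                    weights_allosteric = w_a, weights_competitive = w_b,
                    families = do.call(rbind, fam_rows),
                    duplicate_ligand_ids = dup_ids,
                    panel_ligand_ids = panel_ids)),
    class = "allocomp_study")
}

#' @export
print.allocomp_study <- function(x, ...) {
  tb <- table(x$ligands$set_label)
  cat("synthetic study:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "ligand rows;", nrow(x$proteins), "proteins;",
      nrow(x$assays), "assays\n")
  if (length(x$manifest$shift_spec))
    cat("  true shifts:",
        paste(names(x$manifest$shift_spec), x$manifest$shift_spec,
              collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic study to disk in the ingest formats
#'
#' @param study An `allocomp_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`ligands.csv`, `proteins.fasta`,
#'   `assays.csv`, `manifest.json`).
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "allocomp_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, c("ligands.csv", "proteins.fasta", "assays.csv",
                        "manifest.json"))
  write.csv(study$ligands, p[1], row.names = FALSE)
  aa <- Biostrings::AAStringSet(setNames(study$proteins$sequence,
                                         paste(study$proteins$protein_id,
                                               study$proteins$name)))
  Biostrings::writeXStringSet(aa, p[2])
  write.csv(study$assays, p[3], row.names = FALSE)
  m <- study$manifest
  m$families <- NULL
  jsonlite::write_json(m, p[4], auto_unbox = TRUE, digits = NA)
  invisible(p)
}
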