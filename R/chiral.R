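# Tetrahedral stereocenter counting from the molecular graph.
#
# Database SMILES frequently omit stereo flags, so counting only assigned
# centers undercounts badly; instead we detect *potential* tetrahedral
# centers: an sp3 carbon whose (three or four) heavy substituent branches
# are pairwise non-equivalent. Branch equivalence is judged with
# Weisfeiler-Lehman color refinement of the molecular graph (elements +
# bond orders), run once over the whole batch as a disjoint union: two
# substituent branches are equivalent iff their root atoms share a final
# color. With at most one implicit hydrogen the H "branch" is always
# distinct from any heavy branch. Known approximations: neighbors that are
# automorphic only through a symmetry moving the candidate atom itself, and
# Kekule-writing-dependent aromatic branches, may be mis-judged; such cases
# are rare in drug-like molecules and the convention is applied identically
# to both ligand sets.

# Molecular graphs for a batch of valid SMILES: elements plus bond triples
# (atom1, atom2, order), extracted from OpenBabel's V2000 molfile output.
# (A fixed-width slice of the counts/atom/bond lines; the full-featured SDF
# readers in the R chemistry stack parse entire SDF objects and are two
# orders of magnitude too slow for per-molecule graph queries at this
# volume.)
.mol_graphs <- function(smiles) {
  # coordinate generation is skipped: it costs ~40 ms/molecule and is
  # irrelevant for connectivity. The CLI route also keeps OpenBabel's
  # per-molecule "no coordinates" warnings off the console.
  txt <- if (.obabel_available()) {
    paste0(paste(.obabel_run(smiles, "-osdf"), collapse = "\n"), "\n")
  } else {
    ChemmineOB::convertFormat("SMI", "SDF", paste(smiles, collapse = "\n"),
                              options = data.frame(names = "nothing",
                                                   args = ""))
  }
  recs <- strsplit(txt, "$$$$\n", fixed = TRUE)[[1]]
  recs <- recs[nzchar(trimws(recs))]
  if (length(recs) != length(smiles))
    stop("molfile conversion dropped molecules (got ", length(recs),
         " of ", length(smiles), ")")
  lapply(recs, function(r) {
    ln <- strsplit(r, "\n", fixed = TRUE)[[1]]
    na <- as.integer(substr(ln[4L], 1L, 3L))
    nb <- as.integer(substr(ln[4L], 4L, 6L))
    atoms <- ln[4L + seq_len(na)]
    elem <- trimws(substr(atoms, 32L, 34L))
    if (nb > 0L) {
      bl <- ln[4L + na + seq_len(nb)]
      bonds <- cbind(as.integer(substr(bl, 1L, 3L)),
                     as.integer(substr(bl, 4L, 6L)),
                     as.integer(substr(bl, 7L, 9L)))
    } else bonds <- matrix(integer(0), 0L, 3L)
    list(elem = elem, bonds = bonds)
  })
}

# Vectorized stereocenter count over a batch of molecular graphs.
.count_stereo_batch <- function(graphs) {
  nat <- vapply(graphs, function(g) length(g$elem), 1L)
  off <- cumsum(c(0L, nat[-length(nat)]))
  elem <- unlist(lapply(graphs, `[[`, "elem"))
  n <- length(elem)
  bl <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    b <- graphs[[i]]$bonds
    if (nrow(b)) b[, 1:2] <- b[, 1:2] + off[i]
    b
  }))
  # directed edge arrays
  ef <- c(bl[, 1L], bl[, 2L])
  et <- c(bl[, 2L], bl[, 1L])
  eo <- c(bl[, 3L], bl[, 3L])
  deg <- tabulate(ef, n)
  maxord <- integer(n)
  if (length(ef)) {
    mo <- vapply(split(eo, ef), max, 1L)
    maxord[as.integer(names(mo))] <- mo
  }

  # WL refinement over the disjoint union; colors never merge across
  # molecules because signatures include full neighborhoods
  col <- match(elem, unique(elem))
  k_prev <- length(unique(col))
  M <- matrix(0L, n, max(4L, if (length(deg)) max(deg) else 0L))
  repeat {
    code <- col[et] * 8L + eo
    o <- order(ef, code)
    efo <- ef[o]
    pos <- sequence(deg[sort(unique(efo))])
    M[] <- 0L
    M[cbind(efo, pos)] <- code[o]
    sig <- do.call(paste, c(list(col), lapply(seq_len(ncol(M)),
                                              function(j) M[, j])))
    col <- match(sig, unique(sig))
    k <- length(unique(col))
    if (k == k_prev) break
    k_prev <- k
  }

  # candidates: carbon, degree 3-4, all bonds single
  cand <- which(elem == "C" & deg >= 3L & deg <= 4L & maxord == 1L)
  res <- integer(length(graphs))
  if (length(cand)) {
    # sorted neighbor colors per atom from the last refinement round
    code <- col[et]
    o <- order(ef, code)
    efo <- ef[o]
    pos <- sequence(deg[sort(unique(efo))])
    M[] <- 0L
    M[cbind(efo, pos)] <- code[o]
    dup <- (M[cand, 1L] == M[cand, 2L]) |
      (M[cand, 2L] == M[cand, 3L] & M[cand, 3L] > 0L) |
      (M[cand, 3L] == M[cand, 4L] & M[cand, 4L] > 0L)
    good <- cand[!dup]
    if (length(good)) {
      mol <- findInterval(good, off + 1L)
      cnt <- table(mol)
      res[as.integer(names(cnt))] <- as.integer(cnt)
    }
  }
  res
}

# Vectorized over SMILES. Molecules with fewer than 4 heavy atoms cannot
# host a tetrahedral center and short-circuit to zero.
count_stereocenters <- function(smiles) {
  n <- length(smiles)
  if (!n) return(integer(0))
  out <- integer(n)
  big <- which(.heavy_count(smiles) >= 4)
  if (!length(big)) return(out)
  out[big] <- .count_stereo_batch(.mol_graphs(smiles[big]))
  out
}
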