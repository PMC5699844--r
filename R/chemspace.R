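#' ECFP6 circular fingerprints
#'
#' Hashed extended-connectivity fingerprints of diameter 6 (radius 3),
#' computed by OpenBabel and folded to `n_bits` (default 2048) by OR-ing
#' halves. Deterministic: any SMILES writing of the same molecule yields the
#' same bits. No count or chirality information is encoded.
#'
#' @param smiles Character vector of valid SMILES.
#' @param n_bits Fingerprint length; must divide OpenBabel's native 4096.
#' @return Integer 0/1 matrix, one row per molecule (`rownames` = input
#'   SMILES), `n_bits` columns.
#' @export
ecfp6 <- function(smiles, n_bits = 2048) {
  smiles <- as.character(smiles)
  stopifnot(!anyNA(smiles), all(nzchar(smiles)))
  native <- 4096L
  stopifnot(n_bits >= 1, native %% n_bits == 0L)
  cache <- .cache_env("fp")
  key <- paste0(n_bits, "|", smiles)
  hit <- vapply(key, function(k) !is.null(cache[[k]]), TRUE)
  todo <- which(!hit)
  if (length(todo)) {
    usmi <- unique(smiles[todo])
    fp <- ob_ecfp6(usmi)
    if (n_bits < native) {
      folds <- native %/% n_bits
      f2 <- matrix(0L, nrow(fp), n_bits)
      for (k in seq_len(folds))
        f2 <- f2 | fp[, ((k - 1L) * n_bits + 1L):(k * n_bits), drop = FALSE]
      fp <- f2
      storage.mode(fp) <- "integer"
    }
    for (i in seq_along(usmi))
      cache[[paste0(n_bits, "|", usmi[i])]] <- fp[i, ]
  }
  out <- matrix(0L, length(smiles), n_bits)
  for (i in seq_along(smiles)) out[i, ] <- cache[[key[i]]]
  rownames(out) <- smiles
  out
}

#' Tanimoto similarity of two fingerprints
#'
#' `Tc = |A & B| / (|A| + |B| - |A & B|)`; symmetric, 1 for identical
#' fingerprints. Two all-zero fingerprints are defined as identical (Tc 1).
#'
#' @param a,b 0/1 vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  inter <- sum(a & b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' All-pairs Tanimoto similarity matrix
#'
#' @param a 0/1 fingerprint matrix (rows = molecules).
#' @param b Optional second matrix; defaults to `a`.
#' @return `nrow(a)` x `nrow(b)` similarity matrix.
#' @export
tanimoto_matrix <- function(a, b = a) {
  if (ncol(a) != ncol(b)) stop("fingerprint length mismatch")
  storage.mode(a) <- "double"
  storage.mode(b) <- "double"
  inter <- tcrossprod(a, b)
  pa <- rowSums(a)
  pb <- rowSums(b)
  uni <- outer(pa, pb, "+") - inter
  tc <- ifelse(uni == 0, 1, inter / uni)
  tc
}

#' Cross-set chemical-overlap counts
#'
#' For two fingerprint sets, counts how many (unique) molecules of each set
#' lie within `tc_threshold` of *some* molecule of the other set -- the
#' quantitative summary of how much chemical space the two sets share.
#'
#' @param set_a,set_b Fingerprint matrices from [ecfp6()].
#' @param tc_threshold Tanimoto threshold (default 0.6).
#' @param chunk Internal row-block size controlling memory use.
#' @return List `count_a`, `total_a`, `count_b`, `total_b`: `count_a` is the
#'   number of A molecules within threshold of a B molecule, etc.
#' @export
cross_set_neighbor_count <- function(set_a, set_b, tc_threshold = 0.6,
                                     chunk = 1024L) {
  stopifnot(nrow(set_a) >= 1, nrow(set_b) >= 1)
  near <- function(a, b) {
    hits <- logical(nrow(a))
    for (s in seq(1L, nrow(a), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(a))
      tc <- tanimoto_matrix(a[s:e, , drop = FALSE], b)
      hits[s:e] <- apply(tc, 1L, max) >= tc_threshold
    }
    sum(hits)
  }
  list(count_a = near(set_a, set_b), total_a = nrow(set_a),
       count_b = near(set_b, set_a), total_b = nrow(set_b))
}
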