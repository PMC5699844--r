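# Internal OpenBabel (ChemmineOB) backend: batched SMILES parsing,
# canonicalization, the pH-7 protonation transform, and SMARTS counting.
# All entry points are vectorized over SMILES and realign output by an
# index title so that unparsable inputs come back as NA instead of
# silently shifting rows.

.ob_opts_ph7 <- function() data.frame(names = "p", args = "7")

# Canonical SMILES for a character vector; NA where OpenBabel cannot parse.
# ph7 = TRUE additionally applies OpenBabel's fixed pH-7 transform table
# (deprotonates strong acids, protonates strong bases) before writing.
ob_canonical <- function(smiles, ph7 = FALSE) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  todo <- which(!is.na(smiles) & nzchar(smiles) & !grepl("[ \t]", smiles))
  if (!length(todo)) return(out)
  src <- paste0(smiles[todo], " i", seq_along(todo))
  opts <- if (ph7) .ob_opts_ph7() else data.frame(names = "nothing", args = "")
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste(src, collapse = "\n"),
                              options = opts),
    error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, "", 1L)
    ttl <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
    idx <- suppressWarnings(as.integer(sub("^i", "", trimws(ttl))))
    keep <- !is.na(idx) & idx >= 1L & idx <= length(todo) & nzchar(smi)
    out[todo[idx[keep]]] <- smi[keep]
  }
  # OpenBabel stops a batch at the first unparsable entry; retry the
  # remainder one molecule at a time so a single bad SMILES cannot take
  # its successors down with it
  for (i in todo[is.na(out[todo])]) {
    res1 <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", smiles[i], options = opts),
      error = function(e) "")
    s1 <- strsplit(res1, "[\t\n]")[[1]]
    if (length(s1) && nzchar(s1[1L])) out[i] <- s1[1L]
  }
  out
}

# OBMol references for a vector of *valid* SMILES (caller guarantees
# parseability, e.g. output of ob_canonical); errors otherwise.
ob_mols <- function(smiles) {
  stopifnot(length(smiles) >= 1L, !anyNA(smiles))
  mols <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                 identity)
  if (length(mols) != length(smiles))
    stop("OpenBabel dropped ", length(smiles) - length(mols),
         " molecule(s) while parsing supposedly valid SMILES")
  mols
}

# Count unique SMARTS matches per molecule. `mols` from ob_mols().
ob_smarts_count <- function(mols, pattern) {
  as.numeric(ChemmineOB::smartsSearch_OB(mols, pattern, uniqueMatches = TRUE))
}

.obabel_available <- function() {
  av <- .cache[["obabel_available"]]
  if (is.null(av)) {
    av <- nzchar(Sys.which("obabel"))
    .cache[["obabel_available"]] <- av
  }
  av
}

# run obabel on a batch of valid SMILES, returning stdout lines
.obabel_run <- function(smiles, args) {
  inf <- tempfile(fileext = ".smi")
  on.exit(unlink(inf), add = TRUE)
  writeLines(paste(smiles, paste0("m", seq_along(smiles))), inf)
  system2("obabel", c("-ismi", inf, args), stdout = TRUE, stderr = FALSE)
}

# MW and logP (Wildman-Crippen-style atomic contributions) per molecule.
# The obabel CLI path avoids the per-molecule InChI overhead of prop_OB;
# both use the same underlying descriptor implementations.
ob_props <- function(mols, smiles = NULL) {
  if (!is.null(smiles) && .obabel_available()) {
    out <- .obabel_run(smiles, c("-osmi", "--append", "MW logP"))
    parts <- strsplit(out, "[ \t]+")
    ttl <- vapply(parts, function(p) p[min(2L, length(p))], "")
    idx <- suppressWarnings(as.integer(sub("^m", "", ttl)))
    if (!anyNA(idx) && length(idx) == length(smiles) &&
        identical(sort(idx), seq_along(smiles))) {
      mw <- lp <- numeric(length(smiles))
      mw[idx] <- vapply(parts, function(p) as.numeric(p[length(p) - 1L]), 1)
      lp[idx] <- vapply(parts, function(p) as.numeric(p[length(p)]), 1)
      if (!anyNA(mw) && !anyNA(lp))
        return(data.frame(MW = mw, logP = lp))
    }
  }
  p <- ChemmineOB::prop_OB(mols)
  data.frame(MW = as.numeric(p$MW), logP = as.numeric(p$logP))
}

# ECFP6 bit matrix (4096 native bits) for a batch of valid SMILES via the
# obabel CLI's FPS output; falls back to ChemmineOB when obabel is absent.
# Bit order is backend-internal but fixed within a session, which is all the
# Tanimoto machinery needs.
ob_ecfp6 <- function(smiles) {
  if (.obabel_available()) {
    out <- .obabel_run(smiles, c("-ofps", "-xfECFP6"))
    out <- out[!startsWith(out, "#")]
    parts <- strsplit(out, "\t", fixed = TRUE)
    hx <- vapply(parts, `[`, "", 1L)
    idx <- suppressWarnings(as.integer(sub("^m", "",
                                           vapply(parts, `[`, "", 2L))))
    if (!anyNA(idx) && length(idx) == length(smiles) &&
        identical(sort(idx), seq_along(smiles)) &&
        all(nchar(hx) == 1024L)) {
      lut <- t(vapply(0:15, function(i) as.integer(intToBits(i)[1:4]),
                      integer(4)))
      codes <- match(unlist(strsplit(tolower(hx), "", fixed = TRUE)),
                     c(0:9, letters[1:6]))
      fp <- matrix(as.vector(t(lut[codes, , drop = FALSE])),
                   ncol = 4096L, byrow = TRUE)
      fp[idx, ] <- fp
      return(fp)
    }
  }
  fp <- ChemmineOB::fingerprint_OB(ob_mols(smiles), "ECFP6")
  if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1L)
  storage.mode(fp) <- "integer"
  fp
}

# Split a canonical SMILES into fragments. Safe on canonical output:
# OpenBabel never spans ring-closure digits across a "." separator.
ob_fragments <- function(smiles_canonical) {
  strsplit(smiles_canonical, ".", fixed = TRUE)
}
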