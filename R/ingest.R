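#' Wash SMILES: strip salts, ionize at pH 7, canonicalize
#'
#' Reproduces the standard preparation applied to database SMILES before
#' property calculation: keep the largest fragment (by heavy-atom count),
#' ionize strong acids and strong bases as at physiological pH using
#' OpenBabel's fixed pH-7 transform table (carboxylic and sulfonic acids and
#' tetrazoles are deprotonated; aliphatic amines, amidines and guanidines are
#' protonated; weak acids and bases stay neutral), and write canonical
#' SMILES. The operation is idempotent: washing a washed SMILES returns it
#' unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A data.frame with one row per input: `smiles_raw`,
#'   `smiles_canonical` (NA when rejected), `ok` (logical), and `reason`
#'   (`""`, `"unparsable"`, or `"empty"`).
#' @examples
#' \donttest{
#' wash_smiles(c("CC(=O)O", "CCN.Cl", "c1ccccc1"))$smiles_canonical
#' }
#' @export
wash_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  n <- length(smiles)
  out <- data.frame(smiles_raw = smiles,
                    smiles_canonical = rep(NA_character_, n),
                    ok = rep(FALSE, n),
                    reason = rep("", n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)

  cache <- .cache_env("wash")
  key <- ifelse(is.na(smiles) | !nzchar(smiles), "<empty>", smiles)
  hit <- vapply(key, function(k) !is.null(cache[[k]]), TRUE)
  for (i in which(hit)) {
    v <- cache[[key[i]]]
    out$smiles_canonical[i] <- v[1L]
    out$reason[i] <- v[2L]
  }

  todo <- which(!hit)
  if (length(todo)) {
    raw <- smiles[todo]
    empty <- is.na(raw) | !nzchar(trimws(raw))
    can <- rep(NA_character_, length(todo))
    can[!empty] <- ob_canonical(raw[!empty])
    reason <- ifelse(empty, "empty", ifelse(is.na(can), "unparsable", ""))

    parsed <- which(!is.na(can))
    if (length(parsed)) {
      frags <- ob_fragments(can[parsed])
      largest <- vapply(seq_along(parsed), function(j) {
        fr <- frags[[j]]
        if (length(fr) == 1L) return(fr)
        ha <- ob_smarts_count(ob_mols(fr), "[*]")
        fr[which.max(ha)]  # ties: first fragment in canonical writing
      }, "")
      washed <- ob_canonical(largest, ph7 = TRUE)
      bad <- is.na(washed)
      reason[parsed[bad]] <- "unparsable"
      can[parsed] <- washed
    }
    for (j in seq_along(todo)) {
      i <- todo[j]
      out$smiles_canonical[i] <- can[j]
      out$reason[i] <- reason[j]
      cache[[key[i]]] <- c(can[j], reason[j])
    }
  }
  out$ok <- !is.na(out$smiles_canonical) & out$reason == ""
  out
}

#' Deduplicate curated ligand records
#'
#' Collapses exact repeats: at most one record per (canonical SMILES, target
#' protein, set label) triple. Records of the same molecule within a set are
#' merged into a single row whose `target_ids` is the sorted union of all
#' targets, so a ligand annotated against several proteins keeps all of its
#' links. The result is independent of input row order: rows are merged under
#' the lexicographically smallest `ligand_id`.
#'
#' @param records Data.frame with columns `ligand_id`, `smiles_canonical`,
#'   `set_label`, `target_ids` (`;`-separated protein ids) and optionally
#'   `source`, `smiles_raw`.
#' @return Data.frame with one row per (molecule, set), same columns.
#' @export
dedup_ligands <- function(records) {
  stopifnot(all(c("ligand_id", "smiles_canonical", "set_label", "target_ids")
                %in% names(records)))
  if (!nrow(records)) return(records)
  records <- records[order(records$ligand_id), , drop = FALSE]
  grp <- paste(records$smiles_canonical, records$set_label, sep = "\r")
  idx <- split(seq_len(nrow(records)), grp)
  rows <- lapply(idx, function(ii) {
    r <- records[ii[1L], , drop = FALSE]
    tg <- sort(unique(unlist(strsplit(records$target_ids[ii], ";", fixed = TRUE))))
    tg <- tg[nzchar(tg)]
    r$target_ids <- paste(tg, collapse = ";")
    r
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$ligand_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep assays matching a mechanism keyword, excluding HTS and blacklist
#'
#' Mirrors keyword curation of assay tables: the assay description must
#' contain the mechanism stem (`"alloster"` or `"compet"`, case-insensitive,
#' followed by anything, as in a trailing-wildcard search), the assay must
#' not be high-throughput screening (HTS data carry high error rates), and
#' must not be on the manual curation blacklist.
#'
#' @param assays Data.frame with columns `assay_id`, `description`, `is_hts`
#'   (logical) and optionally `standard_value`, `ligand_ids`.
#' @param mode `"allosteric"` or `"competitive"`.
#' @param curation_blacklist Character vector of assay ids to drop.
#' @return The kept subset of `assays` (possibly empty).
#' @export
filter_assays <- function(assays, mode = c("allosteric", "competitive"),
                          curation_blacklist = character()) {
  mode <- match.arg(mode)
  stopifnot(all(c("assay_id", "description", "is_hts") %in% names(assays)))
  stem <- c(allosteric = "alloster", competitive = "compet")[[mode]]
  keep <- grepl(stem, assays$description, ignore.case = TRUE) &
    !as.logical(assays$is_hts) &
    !(assays$assay_id %in% curation_blacklist)
  assays[which(keep), , drop = FALSE]
}

#' Ligands active in at least one kept assay
#'
#' After [filter_assays()], a ligand is retained only if it appears in some
#' kept assay reporting a present, strictly positive `standard_value`
#' (the "active molecules only" rule).
#'
#' @param assays Kept assays (rows of the assay table), with `ligand_ids`
#'   `;`-separated and `standard_value` numeric (NA = not reported).
#' @return Character vector of active ligand ids.
#' @export
active_ligand_ids <- function(assays) {
  if (!nrow(assays)) return(character(0))
  act <- !is.na(assays$standard_value) & assays$standard_value > 0
  ids <- unlist(strsplit(assays$ligand_ids[act], ";", fixed = TRUE))
  sort(unique(ids[nzchar(ids)]))
}

#' Flag panel-assay artifacts
#'
#' Single compounds annotated as active against very large target panels in
#' one study (e.g. standard compounds profiled against a panel of >200
#' kinases) distort set-level statistics and are flagged for removal. The
#' default threshold of 100 targets separates such artifacts from ordinary
#' polypharmacology.
#'
#' @param records Ligand records (see [dedup_ligands()]).
#' @param max_targets Maximum allowed number of distinct targets.
#' @return Character vector of flagged `ligand_id`s (possibly empty).
#' @export
flag_panel_artifacts <- function(records, max_targets = 100) {
  stopifnot(max_targets >= 1)
  if (!nrow(records)) return(character(0))
  ntarg <- vapply(strsplit(records$target_ids, ";", fixed = TRUE),
                  function(t) length(unique(t[nzchar(t)])), 1L)
  records$ligand_id[ntarg > max_targets]
}

.read_table_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading ", ext, " files requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = 1L))
  } else if (ext == "tsv") {
    read.delim(path, stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Read a ligand table (CSV/TSV/XLSX)
#'
#' Mandatory columns: `ligand_id`, `smiles`, `set_label`, `target_ids`
#' (`;`-separated). Optional: `source`, `assay_id`. Rows with an empty or
#' missing SMILES or ligand id are skipped with a message reporting the count.
#'
#' @param path File path; format chosen by extension (first sheet for xlsx).
#' @return Data.frame of raw ligand records (`smiles_raw` column holds the
#'   SMILES as read).
#' @export
read_ligand_table <- function(path) {
  tab <- .read_table_any(path)
  need <- c("ligand_id", "smiles", "set_label", "target_ids")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ligand table ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  tab$ligand_id <- as.character(tab$ligand_id)
  tab$smiles <- as.character(tab$smiles)
  tab$target_ids <- as.character(tab$target_ids)
  bad <- is.na(tab$smiles) | !nzchar(trimws(tab$smiles)) |
    is.na(tab$ligand_id) | !nzchar(trimws(tab$ligand_id))
  if (any(bad))
    message("read_ligand_table: skipped ", sum(bad), " malformed row(s)")
  tab <- tab[!bad, , drop = FALSE]
  out <- data.frame(ligand_id = tab$ligand_id,
                    smiles_raw = tab$smiles,
                    set_label = as.character(tab$set_label),
                    target_ids = tab$target_ids,
                    source = if ("source" %in% names(tab))
                      as.character(tab$source) else "other",
                    stringsAsFactors = FALSE)
  if ("assay_id" %in% names(tab)) out$assay_id <- as.character(tab$assay_id)
  rownames(out) <- NULL
  out
}

#' Read target protein sequences from a multi-FASTA file
#'
#' The record id up to the first whitespace becomes `protein_id`; the
#' remainder of the header (possibly the sentinel `"None"` when the source
#' database supplied a sequence without a name) becomes `name`.
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Data.frame with columns `protein_id`, `name`, `sequence`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  id <- sub("\\s.*$", "", hdr)
  nm <- trimws(sub("^\\S+\\s*", "", hdr))
  nm[!nzchar(nm)] <- "None"
  data.frame(protein_id = id, name = nm,
             sequence = as.character(aa), stringsAsFactors = FALSE)
}

#' Read an assay table (CSV/TSV/XLSX)
#'
#' Columns: `assay_id`, `description`, `is_hts`, `standard_value`,
#' `ligand_ids` (`;`-separated).
#'
#' @param path File path; format chosen by extension.
#' @return Data.frame of assay records.
#' @export
read_assay_table <- function(path) {
  tab <- .read_table_any(path)
  need <- c("assay_id", "description", "is_hts", "standard_value", "ligand_ids")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("assay table ", path, " is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  data.frame(assay_id = as.character(tab$assay_id),
             description = as.character(tab$description),
             is_hts = as.logical(tab$is_hts),
             standard_value = suppressWarnings(as.numeric(tab$standard_value)),
             ligand_ids = as.character(tab$ligand_ids),
             stringsAsFactors = FALSE)
}

#' Curate a raw ligand table into clean, washed, deduplicated records
#'
#' Applies, in order: optional assay-based filtering (keyword stem + HTS
#' removal + blacklist, then the active-molecule rule), SMILES washing
#' ([wash_smiles()]), removal of unparsable molecules, deduplication
#' ([dedup_ligands()]), and panel-artifact removal
#' ([flag_panel_artifacts()]).
#'
#' @param ligands Raw ligand records (see [read_ligand_table()]).
#' @param assays Optional assay table; if given, `mode` selects the keyword.
#' @param mode `"allosteric"` or `"competitive"`; required with `assays`.
#' @param curation_blacklist Assay ids removed by manual curation.
#' @param max_targets Panel-artifact threshold (see [flag_panel_artifacts()]).
#' @return List with `ligands` (clean records incl. `smiles_canonical`),
#'   `rejected` (rows dropped at the wash step, with `reason`), and
#'   `flagged` (panel-artifact ligand ids removed).
#' @export
curate_ligands <- function(ligands, assays = NULL, mode = NULL,
                           curation_blacklist = character(),
                           max_targets = 100) {
  if (!is.null(assays)) {
    stopifnot(!is.null(mode))
    kept <- filter_assays(assays, mode, curation_blacklist)
    act <- active_ligand_ids(kept)
    ligands <- ligands[ligands$ligand_id %in% act, , drop = FALSE]
  }
  w <- wash_smiles(ligands$smiles_raw)
  ligands$smiles_canonical <- w$smiles_canonical
  rejected <- cbind(ligands[!w$ok, , drop = FALSE],
                    reason = w$reason[!w$ok])
  clean <- ligands[w$ok, , drop = FALSE]
  clean <- dedup_ligands(clean)
  flagged <- flag_panel_artifacts(clean, max_targets)
  clean <- clean[!(clean$ligand_id %in% flagged), , drop = FALSE]
  rownames(clean) <- NULL
  list(ligands = clean, rejected = rejected, flagged = flagged)
}
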