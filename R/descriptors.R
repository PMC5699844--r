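# The 29 physicochemical descriptors: 18 base properties plus 11
# size-corrected (per-heavy-atom) ratios. Counts come from SMARTS matching
# on the washed structure; SlogP from Wildman-Crippen-style atomic
# contributions (OpenBabel); logS from the ESOL linear solubility model.

# SMARTS count table. Conventions (documented substitutions for the
# proprietary typer used by commercial descriptor software):
#  - acceptors: any O; pyridine-type aromatic N; nitrile/imine N; aliphatic
#    amine N excluding amide N and positively charged N.
#  - donors: N or O bearing at least one hydrogen.
#  - acidic atoms: the ionizable O/N of carboxylic, sulfonic,
#    phosphoric/phosphonic acids and tetrazoles (neutral or deprotonated).
#  - basic atoms: aliphatic amine N bonded only to C/H (not amide, aniline,
#    imine), protonated N, and amidinium/guanidinium =N+.
#  - rotatable bond: single, non-ring, both atoms non-terminal, neither atom
#    triple-bonded, minus amide C-N bonds.
.desc_smarts <- list(
  a_heavy = "[*]",
  a_aro   = "[a]",
  a_nC    = "[#6]",
  a_acc   = paste0("[$([#8]),$([nX2]),$([NX1]),$([NX2;!$([N+])]),",
                   "$([NX3;!$([N+]);!$([NX3][CX3]=[OX1])])]"),
  a_don   = "[$([#7;!H0]),$([#8;!H0])]",
  a_acid  = paste0("[$([OX2H1][CX3]=[OX1]),$([OX1-][CX3]=[OX1]),",
                   "$([OX2H1][SX4](=[OX1])=[OX1]),$([OX1-][SX4](=[OX1])=[OX1]),",
                   "$([OX2H1][PX4]=[OX1]),$([OX1-][PX4]=[OX1]),",
                   "$([nX3H1]1nnnc1),$([nX3-]1nnnc1),",
                   "$([NX3H1]1[NX2]=[NX2][NX2]=[CX3]1),",
                   "$([N-]1[NX2]=[NX2][NX2]=[CX3]1),",
                   "$([N-]1[CX3]=[NX2][NX2]=[NX2]1),",
                   "$([N-]1=[CX3][NX3][NX2]=[NX2]1)]"),
  a_base  = paste0("[$([NX3;!$([NX3]~[!#6;!#1]);!$([NX3][CX3]=[OX1]);",
                   "!$([NX3][CX3]=[NX2]);!$([NX3]a);!$([NX3]=*)]),",
                   "$([NX4+]),$([NX3+;!$([NX3+]a)]),$([NX2+]=[CX3])]"),
  b_count = "*~*",
  b_ar    = "a:a",
  rot_all = "[!$(*#*);!D1]-!@[!$(*#*);!D1]",
  rot_amide = "[CX3](=[OX1])-!@[NX3;!D1]",
  chg_p1  = "[*+]", chg_p2 = "[*++]", chg_n1 = "[*-]", chg_n2 = "[*--]")

#' The 29 descriptor codes and their binning class
#'
#' Returns the descriptor table used throughout the package: the printed
#' property code, the data-frame column name (`/HA` written `_per_HA`), and
#' whether the descriptor is discrete (integer-valued counts and flags,
#' histogram bin width 1) or continuous (bin width 0.001).
#'
#' @return Data.frame with columns `code`, `column`, `kind`, `bin_width`.
#' @export
descriptor_codes <- function() .desc_codes_const

.desc_codes_build <- function() {
  base_disc <- c("a_heavy", "a_aro", "a_acc", "a_don", "a_acid", "a_base",
                 "b_count", "b_ar", "b_1rotN", "FCharge", "chiral", "rings",
                 "lip_druglike", "lip_violation", "opr_leadlike",
                 "opr_violation")
  base_cont <- c("SlogP", "logS")
  ratios <- c("a_aro/HA", "a_acc/HA", "a_don/HA", "a_acid/HA", "a_base/HA",
              "b_count/HA", "b_ar/HA", "b_1rotN/HA", "FCharge/HA",
              "a_nC/HA", "chiral/HA")
  code <- c(base_disc, base_cont, ratios)
  kind <- c(rep("discrete", length(base_disc)),
            rep("continuous", length(base_cont) + length(ratios)))
  data.frame(code = code,
             column = sub("/HA", "_per_HA", code, fixed = TRUE),
             kind = kind,
             bin_width = ifelse(kind == "discrete", 1, 0.001),
             stringsAsFactors = FALSE)
}

.desc_codes_const <- .desc_codes_build()

#' Lipinski's Rule of Five violation count
#'
#' Violations counted over MW > 500, SlogP > 5, donors > 5, acceptors > 10;
#' a molecule is drug-like iff it has fewer than two violations.
#'
#' @param mol_weight,slogp,a_don,a_acc Numeric vectors (recycled).
#' @return Data.frame with `lip_violation` (0--4) and `lip_druglike` (0/1).
#' @export
lipinski <- function(mol_weight, slogp, a_don, a_acc) {
  v <- (mol_weight > 500) + (slogp > 5) + (a_don > 5) + (a_acc > 10)
  data.frame(lip_violation = as.integer(v),
             lip_druglike = as.integer(v < 2))
}

#' Oprea lead-likeness violation count
#'
#' Violations counted over MW <= 450, SlogP in \[-3.5, 4.5\], rings <= 4,
#' rotatable bonds <= 10, donors <= 5, acceptors <= 8; lead-like iff fewer
#' than two violations.
#'
#' @param mol_weight,slogp,rings,b_1rotN,a_don,a_acc Numeric vectors.
#' @return Data.frame with `opr_violation` (0--6) and `opr_leadlike` (0/1).
#' @export
oprea <- function(mol_weight, slogp, rings, b_1rotN, a_don, a_acc) {
  v <- (mol_weight > 450) + (slogp < -3.5 | slogp > 4.5) + (rings > 4) +
    (b_1rotN > 10) + (a_don > 5) + (a_acc > 8)
  data.frame(opr_violation = as.integer(v),
             opr_leadlike = as.integer(v < 2))
}

# ESOL (Delaney) aqueous solubility estimate, log10 mol/L.
.esol_logS <- function(slogp, mw, rotatable, aromatic_proportion) {
  0.16 - 0.63 * slogp - 0.0062 * mw + 0.066 * rotatable -
    0.74 * aromatic_proportion
}

# column layout of the full descriptor block (cache order)
.desc_columns <- function() {
  c("MW", "a_heavy", "a_aro", "a_acc", "a_don", "a_acid", "a_base", "a_nC",
    "b_count", "b_ar", "b_1rotN", "FCharge", "SlogP", "logS", "chiral",
    "rings", "lip_violation", "lip_druglike", "opr_violation",
    "opr_leadlike",
    paste0(c("a_aro", "a_acc", "a_don", "a_acid", "a_base", "b_count",
             "b_ar", "b_1rotN", "FCharge", "a_nC", "chiral"), "_per_HA"))
}

# primitives needed per output column (beyond a_heavy, always computed)
.desc_needs <- function(columns) {
  base <- sub("_per_HA$", "", columns)
  need <- unique(base)
  smarts <- intersect(need, c("a_aro", "a_acc", "a_don", "a_acid", "a_base",
                              "a_nC", "b_count", "b_ar"))
  if (any(need %in% c("b_1rotN", "logS", "opr_violation", "opr_leadlike")))
    smarts <- union(smarts, c("rot_all", "rot_amide"))
  if (any(need %in% c("rings", "opr_violation", "opr_leadlike")))
    smarts <- union(smarts, "b_count")
  if ("FCharge" %in% need)
    smarts <- union(smarts, c("chg_p1", "chg_p2", "chg_n1", "chg_n2"))
  if ("logS" %in% need) smarts <- union(smarts, "a_aro")
  if (any(need %in% c("lip_violation", "lip_druglike",
                      "opr_violation", "opr_leadlike")))
    smarts <- union(smarts, c("a_don", "a_acc"))
  list(smarts = smarts,
       props = any(need %in% c("MW", "SlogP", "logS", "lip_violation",
                               "lip_druglike", "opr_violation",
                               "opr_leadlike")),
       chiral = "chiral" %in% need)
}

#' Compute the 29 physicochemical descriptors for washed SMILES
#'
#' Counts are taken on the heavy-atom graph with implicit hydrogens; SlogP
#' uses Wildman-Crippen-style atomic contributions; logS uses the ESOL
#' linear model (a documented substitute for proprietary solubility models);
#' `chiral` counts tetrahedral stereocenters detected from the molecular
#' graph, including centers whose configuration is unassigned in the SMILES.
#' Every per-HA ratio equals the base count divided by `a_heavy` exactly.
#' Results are memoized per SMILES string (and column profile) for the
#' session.
#'
#' @param smiles_canonical Character vector of washed, valid SMILES
#'   (see [wash_smiles()]); invalid input is an error.
#' @param columns Optional subset of output columns to compute (descriptor
#'   column names as in [descriptor_codes()], plus `"MW"`); `NULL` computes
#'   everything. Only the primitives those columns need are evaluated.
#' @return Data.frame, one row per molecule, with `smiles` and the
#'   requested columns (default: `MW`, `a_nC`, and the 29 descriptors).
#' @examples
#' \donttest{
#' compute_descriptors("c1ccccc1")[, c("a_heavy", "a_aro", "b_ar", "rings")]
#' }
#' @export
compute_descriptors <- function(smiles_canonical, columns = NULL) {
  smiles_canonical <- as.character(smiles_canonical)
  stopifnot(!anyNA(smiles_canonical), all(nzchar(smiles_canonical)))
  full <- .desc_columns()
  if (is.null(columns)) columns <- full
  columns <- union("a_heavy", columns)
  bad <- setdiff(columns, full)
  if (length(bad)) stop("unknown descriptor column(s): ",
                        paste(bad, collapse = ", "))
  columns <- full[full %in% columns]  # canonical order
  cache <- .cache_env(paste0("desc|", paste(columns, collapse = ",")))
  hit <- vapply(smiles_canonical, function(s) !is.null(cache[[s]]), TRUE)

  todo <- unique(smiles_canonical[!hit])
  if (length(todo)) {
    need <- .desc_needs(columns)
    mols <- ob_mols(todo)
    cnt <- list(a_heavy = ob_smarts_count(mols, .desc_smarts$a_heavy))
    for (nm in need$smarts) cnt[[nm]] <- ob_smarts_count(mols, .desc_smarts[[nm]])
    if (any(cnt$a_heavy < 1))
      stop("molecule with no heavy atoms in descriptor computation")
    val <- list(a_heavy = cnt$a_heavy)
    for (nm in c("a_aro", "a_acc", "a_don", "a_acid", "a_base", "a_nC",
                 "b_count", "b_ar"))
      if (!is.null(cnt[[nm]])) val[[nm]] <- cnt[[nm]]
    if (!is.null(cnt$rot_all)) val$b_1rotN <- cnt$rot_all - cnt$rot_amide
    if (!is.null(cnt$chg_p1))
      val$FCharge <- cnt$chg_p1 + 2 * cnt$chg_p2 - cnt$chg_n1 - 2 * cnt$chg_n2
    if (!is.null(cnt$b_count))
      val$rings <- cnt$b_count - cnt$a_heavy + 1  # SSSR, single fragment
    if (need$props) {
      pr <- ob_props(mols, smiles = todo)
      val$MW <- pr$MW
      val$SlogP <- pr$logP
    }
    if (need$chiral) {
      # candidate prescreen: only sp3 carbons with >= 3 heavy neighbours
      # can be tetrahedral centers, so most molecules skip graph analysis
      cand <- ob_smarts_count(mols, "[CX4;H0,H1]")
      chiral <- integer(length(todo))
      if (any(cand > 0))
        chiral[cand > 0] <- count_stereocenters(todo[cand > 0])
      val$chiral <- chiral
    }
    if ("logS" %in% columns)
      val$logS <- .esol_logS(val$SlogP, val$MW, val$b_1rotN,
                             val$a_aro / val$a_heavy)
    if (any(c("lip_violation", "lip_druglike") %in% columns)) {
      lip <- lipinski(val$MW, val$SlogP, val$a_don, val$a_acc)
      val$lip_violation <- lip$lip_violation
      val$lip_druglike <- lip$lip_druglike
    }
    if (any(c("opr_violation", "opr_leadlike") %in% columns)) {
      opr <- oprea(val$MW, val$SlogP, val$rings, val$b_1rotN,
                   val$a_don, val$a_acc)
      val$opr_violation <- opr$opr_violation
      val$opr_leadlike <- opr$opr_leadlike
    }
    for (cl in grep("_per_HA$", columns, value = TRUE))
      val[[cl]] <- val[[sub("_per_HA$", "", cl)]] / val$a_heavy
    num <- do.call(cbind, val[columns])
    colnames(num) <- columns
    for (i in seq_along(todo)) cache[[todo[i]]] <- num[i, ]
  }

  mat <- do.call(rbind, lapply(smiles_canonical, function(s) cache[[s]]))
  out <- data.frame(smiles = smiles_canonical, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
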