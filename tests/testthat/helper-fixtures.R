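# Shared fixtures and small builders, all generated in code.

# 20 molecules whose count descriptors were verified by hand from the
# documented SMARTS conventions (washed forms: acids deprotonated, amines
# protonated). Columns are the expected post-wash counts.
fixture_descriptor_table <- function() {
  tab <- read.csv(text = "
smiles_raw,a_heavy,a_aro,a_acc,a_don,a_acid,a_base,a_nC,b_count,b_ar,b_1rotN,FCharge,chiral,rings
c1ccccc1,6,6,0,0,0,0,6,6,6,0,0,0,1
Cc1ccccc1,7,6,0,0,0,0,7,7,6,0,0,0,1
Oc1ccccc1,7,6,1,1,0,0,6,7,6,0,0,0,1
c1ccncc1,6,6,1,0,0,0,5,6,6,0,0,0,1
Nc1ccccc1,7,6,1,1,0,0,6,7,6,0,0,0,1
CC(=O)O,4,0,2,0,1,0,2,3,0,0,-1,0,0
CCN,3,0,0,1,0,1,2,2,0,0,1,0,0
CCO,3,0,1,1,0,0,2,2,0,0,0,0,0
CC(N)C(=O)O,6,0,2,1,1,1,3,5,0,1,0,1,0
CC(=O)NC,5,0,1,1,0,0,3,4,0,0,0,0,0
NC(=O)c1ccccc1,9,6,1,1,0,0,7,9,6,1,0,0,1
C=Cc1ccccc1,8,6,0,0,0,0,8,8,6,1,0,0,1
c1ccc(cc1)-c1ccccc1,12,12,0,0,0,0,12,13,12,1,0,0,2
C1CCCCC1,6,0,0,0,0,0,6,6,0,0,0,0,1
CC(O)C,4,0,1,1,0,0,3,3,0,0,0,0,0
CCC(C)O,5,0,1,1,0,0,4,4,0,1,0,1,0
NCC(=O)O,5,0,2,1,1,1,2,4,0,1,0,0,0
c1ccc2ccccc2c1,10,10,0,0,0,0,10,11,11,0,0,0,2
COc1ccccc1,8,6,1,0,0,0,7,8,6,1,0,0,1
OC(=O)c1ccc(Cl)cc1,10,6,2,0,1,0,7,10,6,1,-1,0,1
", stringsAsFactors = FALSE, strip.white = TRUE)
  tab
}

# minimal curated ligand records
make_records <- function(ids, smiles, targets, set = "allosteric") {
  data.frame(ligand_id = ids, smiles_canonical = smiles,
             set_label = set, target_ids = targets,
             stringsAsFactors = FALSE)
}

# constructed fingerprint row from bit positions
make_fp <- function(bits, n = 32) {
  v <- integer(n)
  v[bits] <- 1L
  v
}

# a small seeded ligand set as washed SMILES (distinct molecules)
grammar_smiles <- function(n, seed = 1, weights = default_grammar_weights(),
                          lambda = 6) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  raw <- replicate(n, generate_ligand(weights, length_lambda = lambda))
  wash_smiles(raw)$smiles_canonical
}

# brute-force Tanimoto between two 0/1 vectors (independent of tanimoto())
tc_brute <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 1 else inter / uni
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

random_seq <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}
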