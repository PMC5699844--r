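---
title: "Methods: cluster-normalized comparison of two ligand sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-normalized comparison of two ligand sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the statistical obstacle

Given two labeled sets of small molecules — canonically allosteric
modulators versus competitive (active-site) binders — do their
physicochemical property distributions differ? The obstacle is that
bioactivity databases are wildly redundant: a handful of heavily studied
targets (GPCRs, kinases) contribute thousands of near-identical ligands,
so naive two-sample tests measure the idiosyncrasies of popular drug
programs, not a property of allosteric binding. `allocomp` implements a
redundancy-aware comparison:

1. **Curation.** SMILES are washed (largest fragment, strong acids
   deprotonated and strong bases protonated as at pH 7, canonicalized);
   exact (ligand, target, set) repeats are culled with target lists merged;
   compounds annotated against implausibly many targets (default > 100) are
   removed as panel-assay artifacts; optional assay-table filtering keeps
   only non-HTS assays whose description matches the mechanism keyword stem
   (`alloster*` / `compet*`) and ligands with a positive reported standard
   value.
2. **29 descriptors.** Atom/bond counts, acid/base/donor/acceptor atom
   counts, formal charge, SlogP, logS, stereocenters, rings, Lipinski and
   lead-likeness violation counts, plus eleven of these divided by the
   heavy-atom count (HA) to remove the size correlation.
3. **Two-level redundancy clustering.** Proteins are grouped greedily into
   families by bidirectional local-alignment identity; within each family
   the pooled ligands are clustered by maximum dissimilarity (sphere
   exclusion) on ECFP6/Tanimoto similarity. Four paired levels are used:
   60%/0.6, 75%/0.75, 90%/0.9, 100%/1.0.
4. **Cluster-normalized inference.** Every protein–ligand cluster
   contributes total weight 1 (each member weighs `1/size`). Distributions
   are binned cluster-normalized histograms; location is compared with a
   weighted Wilcoxon rank-sum test and 95% bootstrap confidence intervals
   of the medians; a difference counts only if `p < 1e-4` *and* the CIs are
   disjoint, *at every one of the four levels*, with a consistent
   direction.

An alternative normalization (one center per cluster, the member with the
smallest summed Tanimoto distance, unit weights, plain Wilcoxon) is
provided as the `centers` scheme, and a chemistry-only `single-level`
clustering of each whole set serves as a sanity check.

## The weighted Wilcoxon construction

The test treats the *cluster*, not the ligand, as the unit of information.
With design weights $w_i$ (here $1/|\mathrm{cluster}|$, so group totals
$W_A, W_B$ equal cluster counts), pooled weighted mid-ranks are

$$R_v = \sum_{u < v} T_u + \tfrac{T_v + 1}{2}, \qquad
  T_v = \text{total weight tied at value } v,$$

and the Mann–Whitney statistic
$U = \sum_{i \in A} w_i R_{x_i} - W_A (W_A + 1)/2$ is referred to the
classical tie-corrected normal null,

$$E_0[U] = \tfrac{W_A W_B}{2}, \qquad
  V_0[U] = \tfrac{W_A W_B}{12}\Big[(W + 1) -
  \tfrac{\sum_v (T_v^3 - T_v)}{W (W - 1)}\Big].$$

Two properties motivate this exact construction (both are asserted by the
test suite):

* **Equal-weight reduction.** With unit weights it *is* the large-sample
  two-sided Wilcoxon rank-sum test (`wilcox.test(exact = FALSE,
  correct = FALSE)`), to machine precision.
* **Replication invariance.** Statistic and variance depend only on the
  total weight at each distinct value, so replicating a cluster's members
  $k$-fold (weights rescaled by $1/k$) changes nothing — the normalization
  is genuinely insensitive to database redundancy.

A survey-regression formulation with a sandwich variance would satisfy
neither exactly; treating the total weight as the effective sample size is
the conservative reading of "one cluster, one observation's worth".

## Histograms, medians and the bootstrap

Values are binned at width 1 (all counts and violation flags) or 0.001
(SlogP, logS and all per-HA ratios), index `floor(value/width + 1e-9)`;
the tiny forgiveness keeps ratios that sit a hair under a bin edge from
being mis-binned, including negative values. The weighted median is the
lower edge of the first bin whose cumulative mass reaches half the total
(with a relative tolerance of 1e-9, so a mass exactly at half counts as
reaching it regardless of floating-point summation order) —
a deterministic convention that yields integer medians for integer
descriptors and equals the plain sample median for odd-sized unweighted
samples. Degenerate inputs: an empty distribution is an error; a one-bin
distribution has CI `(v, v)`.

Bootstrap CIs of the median resample `sample_size` values (default: the
cluster count) from the histogram, 100,000 replicates by default, and take
the 2.5–97.5 percentile range. Rather than materializing every replicate
sample, the replicate median is simulated exactly through the order
statistics of uniforms: for odd $m$ the $(m{+}1)/2$-th order statistic is
$\mathrm{Beta}(\tfrac{m+1}{2}, \tfrac{m+1}{2})$, pushed through the
histogram's step quantile function; for even $m$ the two middle order
statistics are drawn jointly ($u_{(r)}$, then
$u_{(r+1)} = u_{(r)} + (1-u_{(r)})\,\mathrm{Beta}(1, m-r)$) and averaged.
This is equidistributed with naive resampling (the suite checks the CI
endpoints against a brute-force resampler) at a cost independent of
`sample_size`. Mean CIs use chunked multinomial draws. All bootstrap
draws are seeded and restore the caller's RNG state.

Interval disjointness is strict: intervals sharing an endpoint overlap.
No multiple-testing correction is applied beyond the deliberately strict
`p < 1e-4` threshold combined with the CI condition and the four-level
consistency requirement.

## Chemistry conventions

Proprietary descriptor software does not publish its atom typing, so the
package pins open, auditable conventions and applies them identically to
both sets (two-sample contrasts are robust to a consistent convention
shift):

* **Wash**: OpenBabel's fixed pH-7 transform table after largest-fragment
  selection. Carboxylic and sulfonic acids and tetrazoles deprotonate;
  aliphatic amines, amidines and guanidines protonate; phenols, alcohols,
  anilines, pyridines stay neutral. One deliberate quirk of that table:
  phosphoric/phosphonic acids remain neutral. The wash is idempotent.
* **Acceptors**: any O; pyridine-type aromatic N; nitrile/imine N;
  aliphatic amine N excluding amide and positively charged N. **Donors**:
  N or O with at least one H. **Acidic/basic atoms**: the ionizable atoms
  of the wash's strong-acid/strong-base classes, for internal consistency.
* **Rotatable bond**: single, non-ring, both atoms non-terminal, no
  triple-bond-adjacent atom, amide C–N excluded.
* **SlogP**: Wildman–Crippen-style atomic contributions (OpenBabel's
  logP). **logS**: the ESOL linear model
  $0.16 - 0.63\,\mathrm{SlogP} - 0.0062\,\mathrm{MW} +
  0.066\,\mathrm{RB} - 0.74\,\mathrm{AP}$ — an established open
  substitute for unpublished commercial solubility models.
* **Lead-likeness**: MW ≤ 450, SlogP ∈ [−3.5, 4.5], rings ≤ 4, rotatable
  bonds ≤ 10, donors ≤ 5, acceptors ≤ 8; like Lipinski, "passes" means
  fewer than two violations.
* **Stereocenters** count *potential* tetrahedral centers — sp3 carbons
  whose substituent branches are pairwise non-equivalent under
  Weisfeiler–Lehman refinement of the molecular graph — because database
  SMILES routinely omit stereo flags. Branches equivalent only under a
  symmetry that moves the candidate atom itself, and Kekulé-dependent
  aromatic cases, can be mis-judged; these are rare and affect both sets
  alike.
* **ECFP6**: OpenBabel's hashed circular fingerprint of diameter 6
  (4096 native bits, folded to 2048 by default, no counts or chirality).
  Commercial ECFP6 dialects hash differently, so absolute overlap counts
  against numbers produced with other toolkits carry a small dialect
  error; all within-run similarity structure is unaffected.
* **Sequence identity**: exact local alignment (BLOSUM62, gap open 11,
  extend 1), identical positions divided by each sequence's own length —
  the bidirectional criterion uses the worse of the two directions, which
  equals dividing by the longer length. Deterministic, unlike heuristic
  BLAST scores, and applied in a fixed canonical order (descending
  sequence length, then id) because greedy clustering is order-dependent.

Ligands are likewise processed in a canonical order (descending heavy-atom
count, then id); all clustering tie-breaks resolve toward that order. One
property of sphere exclusion worth knowing: cluster *seeds* are pairwise
below the Tanimoto threshold by construction, but cluster *centers* need
not be, so re-clustering centers at the same threshold can merge clusters
(it is singleton-stable at threshold 1).

## The synthetic-study generator

Real inputs for this analysis are curated database exports that cannot be
redistributed or regenerated at desk scale, so validation runs on fully
synthetic studies with known ground truth.

* **Ligands** come from a closed fragment grammar: a chain of
  `1 + Poisson(6)` segments (benzene, pyridine, naphthalene, alkyl
  linkers of 1–4 carbons, cyclohexyl, amide, ether, methyl branch) with
  two terminal caps (H, methyl, hydroxyl, amine, chloro, carboxyl). Every
  assembled string is valid SMILES and survives washing. The default
  chain length puts median heavy-atom counts near 25–30, the size range
  typical of curated bioactive ligands. Segment types follow a two-state
  aromatic/aliphatic Markov chain whose stationary aromatic share equals
  the weights' share but whose repeat probability is damped
  (`alternation = 0.4`): medicinal-chemistry series alternate scaffolds
  and linkers, and independent draws would make the per-molecule aromatic
  fraction unrealistically overdispersed.
* **Steering.** Per-fragment aromatic/heavy counts are exact, so the
  expected aromatic fraction of a weight setting can be computed from
  fragment compositions alone (`expected_grammar_fractions()`, a
  chemistry-free oracle the tests also use). Configured shifts
  (`a_aro/HA`, `a_don/HA`, `b_1rotN/HA`) are applied by solving for a
  multiplicative factor on the relevant weights; donor and rotatable
  contributions use an approximate count model (junction bonds plus
  internal alkyl bonds), so realized shifts for those two track the target
  with some model error, in direction always.
* **Proteins.** Each family is built from one hidden random scaffold; all
  `n` members mutate a disjoint interior position set covering
  `(1 - t/100)/2` of the length, so *every* pairwise identity lands on the
  target `t` (within ~3 points after alignment; terminal residues are
  never mutated so local alignment spans the full sequence). Emitting the
  unmutated scaffold as a member would make pairwise identities bimodal,
  which is why it is not.
* **Artifacts.** Family sizes follow a truncated power law (a few families
  hold a large ligand share); a configurable fraction of ligands are
  cap-variants of earlier family members (chemical redundancy);
  `duplicate_rate` injects verbatim row repeats; `panel_artifact = c(n, m)`
  adds `n` ligands annotated against `m` decoy targets. The manifest
  records every injection.

What the generator does **not** emulate: real medicinal-chemistry
diversity (ring assortments, charge distributions, synthesizability),
activity values with meaning, correlated annotation errors, or any
particular database's curation history. Passing tests therefore
demonstrate that the *pipeline machinery* is correct and calibrated — not
that any scientific conclusion about real allosteric ligands transfers.

## Validation experiments and sizes

The test suite runs, at sizes chosen to exercise the statistics without
waste: replication-invariance and classical-reduction checks on seeded
constructed data (100 datasets); brute-force verification of
sphere-exclusion constraints on families of up to 12 ligands; a type-I
experiment of 500 null studies (10 single-protein families and ~40
ligands per set, shared target panel, bootstrap 5,000) requiring a
four-level false-verdict fraction ≤ 0.001; a power experiment of 100
seeded studies with a +0.1 aromatic-fraction shift at ~300 clusters per
set (a fixed target panel across seeds, chemistry resampled) requiring
recovery with the correct direction in ≥ 95% of seeds; a 20-molecule
hand-verified descriptor fixture; and cluster-count monotonicity across
the four levels on every synthetic study. `scripts/acceptance.R`
re-runs the full pipeline (both schemes, 100,000 bootstrap replicates,
single-level check, duplicate and panel injections) on one seeded study
and reports its principal quantities as JSON.

## Known limitations

* All chemistry conventions are open substitutes for unpublished
  commercial typers; absolute descriptor values (especially acceptor
  counts, logS, lead-likeness) are convention-dependent even though
  two-set contrasts are stable.
* The weighted test assumes clusters are exchangeable information units;
  it does not model within-family correlation between clusters.
* Greedy families depend on the processing order (fixed canonically here);
  alternative orders give slightly different family counts, which is why
  trends are demanded at all four levels rather than at one.
* The bootstrap quantifies sampling variability of the cluster-weighted
  histogram, not curation uncertainty.
* Binned medians are reported at bin resolution (1 or 0.001); no
  within-bin interpolation is attempted.
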