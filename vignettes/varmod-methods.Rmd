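---
title: "Methods: sequence- and structure-based prediction of functional missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence- and structure-based prediction of functional missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmod)
```

# The problem and the model

Most single-nucleotide variants in coding regions are tolerated; a minority
change the protein's function. Functional missense variants are enriched at
conserved positions, at ligand-binding sites and at protein–protein
interfaces, and tend to be chemically drastic substitutions. `varmod`
operationalises exactly these signals: each variant is encoded as a fixed
23-feature vector (4 sequence features, 16 structural features, 3
missingness indicators) and scored by an accuracy-weighted ensemble of five
Platt-calibrated linear classifiers trained with protein-grouped
cross-validation.

The package deliberately takes its *inputs* as given: the multiple sequence
alignment, the structural model and the site annotations are supplied by
the user (or by the synthetic generator). Homologue search, alignment
construction, homology modelling and site prediction are upstream tools'
jobs and are out of scope here.

# Features

## Conservation (Jensen–Shannon divergence)

For the alignment column aligned to query position *i*, with residue
distribution $p$ and background $q$:

$$\mathrm{JSD}(p, q) = \tfrac12 \mathrm{KL}(p \,\|\, m) +
\tfrac12 \mathrm{KL}(q \,\|\, m), \qquad m = \tfrac12 (p + q),$$

with base-2 logarithms, so the score is bounded by 1, and the convention
$0 \log 0 = 0$. The reported score is $(1 - g_i)\,\mathrm{JSD}(p_i, q)$
where $g_i$ is the column's gap fraction; non-standard letters count as
gaps. Choices where the source method left room:

- **Background** $q$: BLOSUM62 amino-acid frequencies by default
  (`aa_background("blosum62")`), the standard choice for JSD conservation
  scoring; a uniform background is available. $q$ must be strictly
  positive, so the KL terms are always finite.
- **Gap handling**: multiplying by $(1 - g_i)$ penalises gappy columns; an
  all-gap column scores 0 and is flagged `no_data`.
- **No window averaging by default** (a 3-column window is available via
  `conservation_track(window = 3)`), and **no sequence weighting by
  default** — both keep the score exactly equal to the literal JSD formula,
  which is what the oracle tests verify to 1e-10.

## Amino-acid change features

Three features depend only on (wt, mut): the **mass ratio**
mass(mut)/mass(wt) over *average residue masses* (peptide-bonded residues,
i.e. free amino acid minus water — the in-chain convention; the direction
mut/wt is a flag), the **charge-group change** (positive {K,R,H}, negative
{D,E}, neutral = the rest; severity matrix 0 on the diagonal, 1 for
neutral↔charged, 2 for a sign flip), and the **functional-group change**
(0 within a side-chain chemical group, 1 across; groups: aliphatic
{A,V,L,I,G,P}, aromatic {F,W,Y}, hydroxyl {S,T}, sulfur {C,M}, amide
{N,Q}, acidic {D,E}, basic {K,R,H}).

The published method's exact grouping and severity tables were not
available; the tables above are declared *stand-ins* with the standard
partitions, shipped as explicit config (`aa_tables()`,
`read_aa_tables()`) so the published tables can be dropped in without code
changes. Histidine is grouped as positive (titratable side chain), the
usual coarse-grained choice.

## Structural features

- **Site distances**: minimum Euclidean distance between any heavy atom of
  the variant residue and any heavy atom of any site residue, computed
  separately for ligand and interface annotations; 0 (and `in_site`) when
  the variant position is listed in the site. Atom-level minimum rather
  than Cα–Cα because contact proximity is what makes binding-site variants
  biologically meaningful; `ca_only = TRUE` offers the alternative.
  Distances are used raw, in Å (no cap by default).
- **Binding-site extras**: when the variant lies in a ligand site, that
  site's two confidence values pass through as features (highest
  `confidence_a` site when several overlap). Their upstream meaning is
  opaque to this package; they are treated as real-valued evidence.
- **Secondary structure**: Kabsch–Sander backbone hydrogen bonds with the
  electrostatic energy
  $E = 0.084 \cdot 332 \, (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
  kcal/mol and threshold $E < -0.5$; amide hydrogens are reconstructed
  1.01 Å from N opposite the bisector of the previous residue's C and O
  directions (structures usually lack hydrogens); 4/3/5-turn pairs give
  H/G/I helices, bridge ladders give E with isolated bridges B, remaining
  turn residues T, bends (κ > 70°) S. Both the 8-state one-hot and the
  3-state reduction ({H,G,I}→helix, {E,B}→sheet, rest→coil) enter the
  feature vector. Residues missing backbone atoms are unassigned; chains
  shorter than 3 assigned residues are all '-'.
- **Solvent accessibility**: Shrake–Rupley sampling with a deterministic
  960-point Fibonacci sphere per heavy atom, probe 1.4 Å, van der Waals
  radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å (unknown elements fall back to
  1.70 with a warning). Relative SASA divides the residue sum by the
  residue type's theoretical maximum (Tien-style table), clamped to [0,1].
  Shrake–Rupley was chosen over re-implementing a legacy accessibility
  integration because it is verifiable against a closed form (isolated
  atom) and a high-resolution Monte Carlo oracle; at 960 points the
  isolated-atom error is ~5e-14 % and cluster totals sit within 3% of a
  100,000-point oracle. The deterministic grid is orientation-dependent at
  the ~1–2% per-residue level at 960 points, which is why the rigid-body
  invariance test samples at 3840 points (jitter ~0.8%, below the 1%
  tolerance being verified) while default resolution stays at 960.
- **Missingness**: structural features that cannot be computed take the
  sentinel −1 *plus* explicit 0/1 indicators (structure missing, ligand
  annotation missing, interface annotation missing), letting the
  classifier learn missingness instead of conflating it with "distance 0"
  or "buried".

# Classifier

## Margin classifier and cost factor

Each ensemble member minimises

$$\tfrac12 \lVert w \rVert^2 + C \sum_i c_i \, \max(0,\, 1 - y_i(w \cdot
x_i + b))^2, \qquad c_i = j \text{ for positives, } 1 \text{ for
negatives},$$

a primal L2-SVM solved by BFGS from a zero start — deterministic, with the
cost factor `j` making errors on positive (functional) examples outweigh
errors on negatives. The squared hinge (rather than SVMlight's hinge) was
an environment-driven substitution: no SVM library is available to the
package, and the smooth objective admits an exact, reproducible solve; the
(C, j) semantics, the grid search and the calibration contract are
unchanged. Features are standardised with training-fold statistics only
(features span Å, ratios and [0,1] scores; linear margins are
scale-sensitive).

## Platt calibration

Decision values $f$ from the *validation* fold (never the training fold,
per Platt's own recommendation) are fit with
$P(y = 1 \mid f) = 1/(1 + e^{Af + B})$ by maximum likelihood using the
smoothed targets $t_+ = (N_+ + 1)/(N_+ + 2)$, $t_- = 1/(N_- + 2)$. The fit
is quasi-Newton with analytic gradients; non-convergence falls back to
$A = -1, B = 0$ with a warning. When $A < 0$ the probability is strictly
increasing in the decision value. The implementation is verified against
an independent plain-gradient-descent fit of the same objective to 1e-4.

## Folds, grid search, ensemble

Folds are built by protein: proteins in descending variant count (ties
shuffled under the seed) go greedily to the currently smallest fold, so no
protein spans folds and fold sizes are balanced *by variant count* (this
stabilises the per-fold accuracies used as ensemble weights). For each of
the five rotations (train 3 folds / validate 1 / test 1), a grid over
C ∈ {0.01, 0.1, 1, 10, 100} and j ∈ {0.5, 1, 2, 4} is scored by validation
accuracy at the 0.5 probability threshold; ties break toward smaller C,
then j closer to 1. The deployed members are the validation-calibrated
classifiers at each rotation's best (C, j) — they are *not* refit on
train+validation, keeping the recorded validation accuracy an honest
weight. Ensemble weights are the validation accuracies normalised to sum
to 1, so the final probability $\sum_i w_i p_i$ is a convex combination of
member probabilities ("summed and normalised" read as weight-sum
normalisation). The call threshold defaults to 0.5 and is configurable.
Models persist as a single JSON artefact carrying members, scalers,
weights and the feature-schema version; prediction across schema versions
is refused.

# The synthetic world

`make_labelled_dataset()` emulates, at desk scale, the statistical
structure the method exploits. Defaults (chosen once, not tuned):
50 proteins × 10 variants, protein length 100, MSA depth 50 with 2% gaps,
30% of columns conserved (query letter at probability 0.95 per row), 80%
of proteins with a structure (an ideal-geometry helix built from the
query sequence), one 4-residue ligand site and one 4-residue interface
site per protein with uniform-random confidences. With effect size δ, a
variant is "informative" with probability $1 - e^{-\delta}$: informative
pathogenic variants land on conserved-or-site positions with a
charge-flipping substitution; informative neutral variants land on
unconserved off-site positions with a same-functional-group substitution;
uninformative variants of either class use one identical mechanism
(uniform position, uniform non-identical mutant), so δ = 0 makes the
classes exchangeable by construction. δ = 3 (informative with probability
0.95) is the "strong effect" world.

What a green end-to-end test establishes: the full stack — generator →
alignments/structures/sites on disk or in memory → conservation, change
features, DSSP-style assignment, SASA, distances → grouped folds → grid
search → calibration → fusion — recovers an injected class signal
(out-of-fold AUC ≥ 0.95 at δ = 3) and invents none where none exists
(mean out-of-fold AUC ≈ 0.5 at δ = 0). What it does **not** establish:
performance on real pathogenicity data, whose conservation structure,
fold composition, annotation quality and class imbalance the generator
does not emulate (notably: real benchmarks cluster at ≤30% sequence
identity; the generator's proteins are independent draws, which is
stronger). Structures are single ideal helices, so secondary-structure
one-hots carry little synthetic signal — discrimination flows through
conservation, site distances and the substitution chemistry.

The evaluation protocol for the recovery check is the method's own:
for each rotation, the member trained on three folds and calibrated on
the validation fold scores the untouched test fold; pooling the five
disjoint test folds gives one leak-free probability per variant. This
uses all 500 variants as test points; a 20% protein holdout
(`holdout_evaluation()`) is also provided but its ~100-variant test set
has null-AUC noise (sd ≈ 0.08) wider than the ±0.05 acceptance band, so
it is the wrong instrument for that check.

# Numerical choices and degenerate inputs

- JSD uses $0 \log 0 = 0$, requires a strictly positive background, and
  clamps to [0,1]; identical profile and background give exactly 0.
- Hydrogen-bond energies with any inter-atom distance < 0.5 Å are treated
  as clashes (fixed minimal energy), as in the original assignment scheme;
  peptide-bond continuity is checked (C–N < 2.5 Å) so chain breaks never
  fabricate turns; prolines donate no hydrogen bond.
- Variant parsing is case-insensitive, rejects the non-standard letters
  B/J/O/U/X/Z, rejects position 0, and *accepts* identity substitutions
  (flagged) — silently dropping them would hide user input errors.
- Alternate locations in PDB input resolve to highest occupancy, then
  first seen; residues lacking Cα or full backbones are retained but
  flagged and excluded from distance/assignment use respectively.
- Fold construction, the fixture generator and every stochastic test
  accept an explicit integer seed (default 17); the optimisers start from
  fixed zero/analytic initial points, so training is bitwise reproducible
  given data and seed.
- Undefined confusion-matrix ratios (zero denominators) are reported as
  `NA` with an explicit flag rather than silently coerced to 0 or 1.
- Tied scores share one ROC threshold (grouped sweep); the trapezoidal
  AUC then equals the pairwise concordance statistic with ties counted ½,
  which the tests assert to 1e-12.

# Known limitations

- The linear ensemble cannot express feature interactions beyond what the
  fixed encoding provides; the source method is equally linear, but its
  hinge loss may place boundaries slightly differently from this package's
  squared hinge on heavily overlapping classes.
- Structure-to-sequence mapping defaults to "PDB residue number = query
  position", correct for numbering-preserving models but wrong for many
  experimental PDB files; a two-column `residue_map` is the escape hatch.
- Single chain, single model: no complexes, no mmCIF, no altloc ensembles.
- The two binding-site confidence features are pass-throughs; their scale
  is whatever the annotation source used, and models do not transfer
  across annotation sources with different confidence conventions.
- Relative-SASA maxima and van der Waals radii are tables, not physics;
  exotic residues fall back to defaults with warnings.
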