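---
title: "Methods: template-based protein-RNA docking from 3D protein and 2D RNA structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based protein-RNA docking from 3D protein and 2D RNA structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

The package treats protein–RNA complex prediction as template transfer.
A template library holds solved complexes reduced to a *3D2D*
representation: the protein keeps its tertiary structure, the RNA is
reduced to its secondary structure. A target (protein 3D + RNA 2D) is
compared against every template by two alignments:

* **Protein:** a structural alignment scored by TM-score,
  `(1/L_target) * sum_i 1/(1 + (d_i/d0)^2)` with
  `d0 = max(0.5, 1.24 (L_target - 15)^(1/3) - 1.8)`, normalized by the
  target (query) length — the query is the molecule being modelled, so
  coverage of the query is what matters for transfer.
* **RNA:** a global sequence + secondary-structure alignment (below),
  summarized by SSI — the fraction of alignment columns in which both
  sides carry the same structural-alphabet character.

The template ranking score is the convex combination
`W * TM-score + (1 - W) * SSI`. The defaults `W = 0.8` and template
cutoff `0.45` are the calibrated operating point of the method: at this
weight the phase-transition analysis (see below) places the onset of
similar binding modes at a score of about 0.45, and
`reference_transitions()` ships the calibrated transition score for each
weight from 0.9 (transition 0.40) to 0.4 (transition 0.70) as reference
data rather than re-deriving it.

The central assumption is that structurally similar protein folds with
similar RNA secondary structures bind in similar ways, and that the
RNA's secondary structure is (approximately) unchanged by binding. Both
assumptions fail for some families — conformational selection on the RNA
side is the known weak spot — which is why template scores below the
transition are treated as uninformative rather than weak evidence.

## The RNA aligner and its substitution matrix

Each nucleotide is encoded as one character that records the secondary
structure element containing it and the element's length ("BEAR-style"
encoding). The published character table for the original encoding is
not reproduced here; the package ships a documented default
("BEAR-lite") with four element types — stem (helix, length = number of
stacked pairs), hairpin loop, internal loop/bulge (multiloop segments
included), and exterior — crossed with length classes 1..9 (longer
elements share the cap class), using disjoint character ranges
`a–i`, `j–r`, `A–I`, `J–R`. A user table can be supplied through
`read_bear_alphabet()` to reproduce any other encoding; every downstream
step is alphabet-agnostic.

Alignment is global Needleman–Wunsch/Gotoh with affine gaps. Per-column
score: `structure_matrix[bear_i, bear_j] + nucleotide_matrix[nt_i, nt_j]
* bonus` with the A/C/G/U NUC.4.4 submatrix (match 5 / mismatch −4) and
`bonus = 0.2` by default; `bonus = 0` gives pure-structure alignment.
Gap penalties are open 10, extend 2, with the *open + (L−1)·extend*
convention (the first gapped position pays the opening penalty) and
penalized terminal gaps; the alternative `open + L·extend` dialect can be
emulated by adjusting the constants (open − extend). Traceback ties are
broken deterministically, diagonal over up (gap in the second sequence)
over left.

The structure matrix is trained from gapless blocks (maximal runs of
indel-free columns, more than five columns wide) of seed alignments with
consensus structure annotations (Stockholm `#=GC SS_cons`). Construction
follows the classic blocks-substitution recipe: within each block, rows
are single-linkage clustered at x% structural identity (weight
1/cluster-size; `RNABLOSUMx` names the result), columns contribute
weighted character pairs between distinct clusters, and scores are
half-bit log-odds `round(2 * log2(q_ab / e_ab))` with rounding half away
from zero. Numerical choices the source recipe leaves open, decided
here:

* **Zero counts.** Frequencies are estimated from the raw weighted
  counts (so observed-pair scores are exactly the log-odds of the data);
  a pair of observed characters that never co-occurs is scored with a
  single pseudo-pair, count 1 against the augmented total `N + 1`, which
  keeps all scores finite. Characters absent from the training data
  score 0 against everything and are flagged in the matrix attributes.
* **Clustering identity 100** disables redundancy removal entirely
  (every row its own cluster), mirroring how a "BLOSUM100"-style matrix
  counts all pairs; at any lower threshold identical rows merge and
  their pairs are not counted.
* **Within-cluster pairs** are never counted; cluster members share
  their weight instead (1/cluster size).
* **Per-row encodings.** With only a consensus structure, all rows of a
  block share one encoding; the option `pair_filter = "canonical"`
  additionally keeps a consensus pair for a row only when that row's
  nucleotides can form AU/GC/GU, giving per-row encodings and hence
  informative off-diagonal counts from a consensus-only alignment. The
  default follows the stricter consensus-only reading; the command-line
  trainer defaults to `canonical` because consensus-only rows within a
  block are otherwise identical.

## Geometry

* **Interface**: a residue or nucleotide is an interface position iff
  any of its heavy atoms lies within 4.5 Å of the other chain
  (hydrogens and waters are dropped at parse time). The set is monotone
  in the cutoff.
* **Superposition** is least-squares Kabsch via SVD with the determinant
  correction (proper rotations only). Model building superposes target
  onto template over the aligned Cα pairs (protein) and C3′ pairs (RNA)
  of the respective alignments, each requiring at least three pairs.
* **Ligand RMSD** superposes the model protein onto the native protein
  over Cα, applies that frame to the model RNA, and reports the C3′
  RMSD; ≤ 10 Å is the conventional "acceptable" model.
* **Interface RMSD (iRMSD)** is this package's convention (the cited
  definitions vary): representative atoms of positions that are
  interface in *either* complex and aligned in both chain maps, jointly
  superposed by Kabsch; fewer than three usable positions yields a
  missing value. It is symmetric in the two complexes and zero for any
  rigid motion of a whole complex.
* **TM-score search** uses the standard iterative-fragment heuristic:
  Kabsch fits seeded on alignment fragments (full, half, quarter length,
  minimum 4), each refined by re-fitting on the residues within the
  inclusion distance `max(d0, 4.5)` Å until stable, keeping the best
  score. Self-alignments score exactly 1; parity with the TM-align
  binary is not claimed, and the TM-align/LocARNA executables are used
  through `run_external_aligner()` whenever they are on `PATH`.

## Evaluation machinery

* **Phase transition**: template-comparison scores are binned in [0, 1)
  with width 0.05 (1.0 joins the last bin); per bin, the fraction of
  pairs with iRMSD ≤ 5 Å. The transition point is the left edge of the
  lowest-score non-empty bin from which every non-empty bin upward has a
  positive fraction; with no pair under the cutoff it is undefined.
* **Success rate**: fraction of targets with at least one model of
  ligand RMSD ≤ 10 Å among the top n; a target without models is a
  failure.
* **Site metrics**: SN, SP, PRE, ACC, MCC, Strength, F from the 2×2
  counts, formulas as printed in the method's description; a metric with
  a zero denominator is reported as 0 and flagged, which keeps
  per-target macro-averaging total (the package averages per-target
  metric rows, not pooled counts). AUC is the rank statistic with
  midrank ties; the per-position confidence feeding it is the maximum
  3D2D score over templates predicting that position positive, 0
  otherwise — the transfer rule itself is binary, so this is the
  package's documented scoring convention, not a claim about the
  original implementation.
* **Top-n aggregation**: the evaluation convention reports, for each n,
  the single prediction among the top n maximizing MCC ("best model in
  top n"); a label-free union mode is provided for prospective use.
* **SSI denominator** defaults to the full alignment length (gap columns
  count against identity); normalization by the shorter sequence is
  exposed as an option. **SPS** normalizes by the reference alignment's
  aligned-pair count.

## Pseudoknots and degenerate inputs

Dot-bracket with one bracket layer cannot express crossing pairs. CT
input (and multi-layer bracket strings) are resolved greedily: while
crossings remain, the pair involved in the most crossings is dropped,
ties dropping the pair with the larger opening index; removed pairs are
reported. Empty sequences, unbalanced brackets (reported with the
offending position), inconsistent CT partners, fewer than three points
for a superposition, and single-class AUC input all raise typed errors
or documented missing values rather than silent results.

## What the synthetic fixtures do and do not show

`make_toy_complex()` builds a helical Cα trace with dummy side-chain
atoms and a straight C3′ trace whose planted nucleotides sit 3.5 Å from
chosen residues, under a consistent hairpin secondary structure;
`make_template_library()` derives rigid copies (similarity ≈ 1),
stem-unwound variants (intermediate SSI, protein unchanged), and
random-walk decoys (similarity near chance). Default sizes are 30
residues / 16 nucleotides with a three-nucleotide planted interface —
small solved protein–RNA interfaces are of this order, and the sizes
keep the whole suite fast. All generators are pure functions of their
seed.

These fixtures validate the *machinery* — alignment optimality,
superposition, interface logic, transfer bookkeeping, metric formulas —
under geometries where the correct answer is known by construction. They
do not emulate real backbone geometry, real fold variety, non-hairpin
RNA topologies, or the noisy relation between structural similarity and
binding-mode similarity in real complexes; passing them says nothing
about benchmark performance on curated complex sets, which requires
external data deliberately out of scope here.

## Known limitations

* Rigid-body transfer only: no flexibility, no refinement, no ensemble
  docking.
* The built-in protein aligner is sequence-guided (global sequence
  alignment scored structurally); for remote homologs a proper
  structural aligner (TM-align) should be installed and is picked up
  automatically.
* Consensus-only matrix training is degenerate without the canonical
  pair filter (identical rows per block); training on per-sequence
  structures is preferable when available.
* mmCIF input, base-pair probabilities, and secondary-structure
  prediction are out of scope; 2D-only targets skip model building and
  only transfer sites.
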