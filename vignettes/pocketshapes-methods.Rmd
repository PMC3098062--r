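---
title: "Modelling binding-pocket flexibility with volumetric shape fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling binding-pocket flexibility with volumetric shape fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Protein side chains move. Even with a rigid backbone, the residues lining a
ligand-binding pocket can adopt many combinations of rotamers — the
commonly observed low-energy side-chain conformations — and each
combination carves a differently shaped pocket. Exhaustively enumerating
those combinations is combinatorial (the classical side-chain packing
problem is NP-hard), and docking a ligand against every single conformer is
hopeless. The observation this package is built on is that *many distinct
conformers carve indistinguishable pockets* at any finite spatial
resolution: if each conformer's pocket shape is encoded as a bit string
over a fixed 3D lattice, identical strings can be pruned, near-identical
strings merged, and the survivors clustered by volume overlap, leaving a
handful of representative pocket shapes that cover the accessible
conformational space.

`pocketshapes` implements that workflow end to end:

1. **Binding-site recognition.** Holo (ligand-bound) structures are
   rigid-body superposed onto a template over matched C-alpha atoms
   (least-squares, Kabsch algorithm); their ligands pool into a *ligand
   ensemble*. *First-layer residues* (FLRs) are all residues with an atom
   within 5 Å of the ensemble.
2. **Pocket enlargement and mapping.** FLR side chains are shaved to
   alanine, exposing the volume maximally reachable by any side-chain
   motion on the fixed backbone. A cubic lattice (1.0 Å spacing) fills the
   cavity: points inside any van der Waals sphere are discarded, points
   failing a buriedness test are discarded (see below), and points more
   than 6 Å from the binding-site residues and ligand ensemble are trimmed.
3. **Second-layer residues** (SLRs) are residues within 3 Å of lattice
   points that touch the first layer — the set whose rotamers are actually
   enumerated. Glycine and alanine carry no chi angles and are never
   flexible.
4. **Rotamer combination.** Each SLR is rebuilt in every rotamer of a
   backbone-independent library by internal-coordinate construction; a
   rotamer whose side chain clashes with the fixed atoms is removed up
   front. Two atoms clash when `d < r1 + r2 - CTD` with the clash
   tolerance distance CTD = 1.0 Å softening the test against coordinate
   uncertainty. The surviving rotamers form an interaction graph (edge =
   at least one clashing rotamer pair); all pairwise-compatible complete
   assignments are enumerated by connected-component decomposition and
   backtracking with forward checking — pruning only provably dead
   branches, so the enumeration stays exhaustive.
5. **Shape encoding.** A lattice point contacts an atom when
   `d < r_vdw + CPD` with the contact padding distance CPD = 0.5 Å.
   Points touched by every conformer (always-contact) or by none
   (always-free) carry no information and are set aside; the remaining
   *conditional* points, in fixed lattice order, are the bit positions of
   the shape fingerprint. SLRs that touch at least one conditional point
   are the *conditional contact residues* (CCRs) — the residues able to
   modulate pocket shape.
6. **Pruning, merging, clustering.** Identical bit strings collapse into
   one (the conformer ids are kept, so nothing is lost); strings differing
   by fewer than 5 bits can be merged greedily. Pairwise dissimilarity is
   `1 - SFT`, where the shape-fingerprint Tanimoto
   `SFT = N_AB / (N_A + N_B - N_AB)` is the bit-level volume overlap.
   Classical multidimensional scaling embeds the strings; k-medoids (PAM)
   partitions them; each cluster is represented by its medoid — the member
   with minimal average dissimilarity to the rest.
7. **Ligand incompatibility.** A ligand's volume is encoded on the same
   lattice with the same contact rule; its incompatibility with a
   conformer is `|L \ P|`, the count of ligand points outside the
   conformer's open pocket (always-free points plus off-bit conditional
   points). Multiplying by spacing³ converts to Å³.
8. **Key residues.** Instead of visually colouring an interactive MDS
   plot by rotamer state, the package computes, per CCR, the
   between-rotamer-state variance fraction (eta squared) along each
   principal coordinate and the normalised mutual information between
   rotamer state and cluster label, and ranks residues by their best
   score.

## Parameters and defaults

| parameter | default | role |
|---|---|---|
| lattice spacing | 1.0 Å | shape resolution; coarser = more pruning |
| FLR cutoff | 5.0 Å | residue-to-ligand-ensemble distance |
| SLR cutoff | 3.0 Å | residue-to-contact-point distance |
| trim cutoff | 6.0 Å | lattice extent around the binding site |
| CTD | 1.0 Å | soft steric clash tolerance |
| CPD | 0.5 Å | point-contact padding |
| merge threshold | 5 bits | strict Hamming radius for merging |
| k | `"auto"` | PAM cluster count, silhouette-selected over 2..15 |
| buriedness | 4 of 7 directions | cavity membership (below) |
| scan range | 14 Å | how far each scan line looks for protein |
| outlier rmsd | 1.0 Å | drop mobile structures with distinct backbones |

Three of these deserve comment.

**The buriedness (cavity) test.** Grid-based pocket detectors of the
POCKET/LIGSITE family mark a point as buried when scan lines through it
hit protein on both sides ("protein–solvent–protein" events). We scan the
3 lattice axes and 4 body diagonals and require protein hits on *both*
sides along at least `cavity_min_dirs` (default 4) of the 7 directions,
within `cavity_range` (default 14 Å — generous enough that the scan
reaches the wall even in wide, shallow pockets; a shorter range makes the
test silently fail open for large sites). The scan walks the occupancy
grid itself, so the test is exact with respect to the vdW-carved lattice.

**Clash and contact rules.** Both are one-line criteria:
`d < r1 + r2 - CTD` (clash) and `d < r_vdw + CPD` (point contact, the
point being a zero-radius probe). The same contact rule is used for
point classification, conformer encoding and ligand volumes, which is
what makes `L \ P` a pure bit operation. Intra-residue pairs separated by
three or fewer covalent bonds (the side chain against its own backbone,
and C-beta against the peptide-bond neighbours) are exempt from the
clash test, as in any soft steric checker — without the exemption every
rotamer would clash with its own backbone. Van der Waals radii are
Bondi-style element radii shipped as a replaceable table.

**Merging.** "Strings differing by fewer than 5 bits are merged" does not
by itself define an algorithm: merging is order-dependent and
non-transitive. We fix a canonical order (descending conformer count,
ties by bit pattern) and merge greedily against group *founders*, which is
deterministic and keeps every group within the stated radius of its
representative. A transitive-closure (single-linkage) variant is
available behind a flag; it produces fewer, wider groups.

## Numerical and design choices

* **Bit order** is the lexicographic (i, j, k) order of the conditional
  lattice points, fixed at classification time — bit positions are
  reproducible across runs by construction.
* **Enumeration order** is deterministic: residues sorted by key,
  rotamers in library order, earlier components varying slowest; conformer
  ids are therefore stable run to run.
* **Conformer streaming.** Rather than holding per-conformer atom sets,
  the package precomputes, per (residue, rotamer), the set of lattice
  points that rotamer touches; a conformer's fingerprint is then a union
  of precomputed sets. Memory scales with rotamers, not conformers.
* **MDS** is classical principal-coordinate analysis
  (`stats::cmdscale`); axes with non-positive eigenvalues are
  zero-filled, and each axis sign is fixed so its largest-magnitude
  coordinate is positive, making the embedding deterministic. The
  two-point and three-point closed forms are reproduced to 1e-9.
* **Cluster-count selection.** The published workflow picks cluster
  counts by visual inspection of an interactive 3D MDS plot. A headless
  artifact cannot do that, so the default is PAM with the average
  silhouette width maximised over k = 2..15 (ties to the smaller k), with
  a manual `k` override. Silhouette-selected counts are not expected to
  reproduce visually chosen counts on real systems.
* **Medoid ties** break to the lowest string id; `find_medoid` agrees
  with exhaustive argmin on every cluster (tested exactly).
* **Empty-shape Tanimoto.** Two all-zero strings are defined as
  similarity 1 (identical empty shapes) with a warning; the dissimilarity
  matrix uses the same convention, keeping the diagonal exactly zero.
* **Apo-template mode.** With no holo structure the ligand ensemble is
  empty; first-layer residues must then be supplied manually
  (`run_config(flr_keys = ...)`), the pocket is not maximally expanded,
  and the rest of the pipeline is unchanged.
* **Proline** is substituted like any other residue during pocket
  enlargement (with a message) and is never flexible: its ring couples
  the side chain to the backbone, which the fixed-backbone assumption
  cannot honour.
* **Sub-pocket analysis** (splitting a large site into halves) is
  supported only through user-supplied point-id subsets; no automatic
  split criterion is implemented.

## The synthetic toy system

Every stage is testable offline via `make_toy_system()`: a rigid,
deterministic scaffold of alanine pseudo-residues — a floor plate and
stacked dense wall rings forming a deep cylindrical well (default radius
~11 Å, depth 8 Å) — with `n_flexible` leucine residues standing on their
own mid-height ring, C-beta pointing into the cavity, and small
carbon-cluster ligands inside the pocket delivered on rigidly displaced
holo copies (so the superposition stage does real work). With four or
more flexible residues they sit in close pairs 50° apart, which makes
some rotamer pairs genuinely clash and the interaction graph non-trivial.
The mini rotamer library holds the three staggered chi1 wells plus
sub-well variants (chi2 + 1°, chi1 + 3°); at 1 Å / 0.5 Å resolution the
1° variants produce bit-identical fingerprints, so deduplication performs
the same role it performs on real systems (the default toy run collapses
225 conformers to 64 unique strings, a 3.5-fold reduction).

What the toy system emulates: a concave, enclosed binding site; steric
interplay between neighbouring flexible residues; redundant rotamers;
ligands of different sizes and depths. What it does not emulate: real
protein packing density, irregular pocket topology, heteroatom chemistry,
crystallographic noise, or backbone variation between structures
(holo copies differ by exact rigid motions, so the backbone-outlier
filter is exercised only by perturbed copies in the tests). Passing tests
on the toy system therefore validate the algorithmic machinery, not any
biological claim about a particular protein.

Problem sizes used in the shipped tests and acceptance script — four
flexible residues, four rotamers each, ~1200 lattice points, ~225
conformers, 200 planted strings of 120 bits for clustering recovery —
were chosen so a full run completes in seconds on one CPU while still
exercising every code path, including a non-trivial interaction graph
and genuine pruning.

## Known limitations

* Residue correspondence between structures is by (chain, residue
  number, insertion code); the package superposes crystal structures of
  the *same* protein and does no sequence alignment.
* Only model 1 of multi-model files is read; hydrogens are discarded;
  no hydrogen placement or energy model exists anywhere in the package —
  shape is the only criterion, by design.
* Enumeration is exhaustive by contract. Pockets whose surviving-rotamer
  product is astronomically large must be split by the user into point
  subsets; the package refuses to materialise more than 5·10^7
  conformers.
* The incompatibility score counts protruding lattice points; it is a
  shape filter, not a docking score.
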