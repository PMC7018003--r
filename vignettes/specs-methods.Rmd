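---
title: "Methods: side-chain-orientation-aware model scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: side-chain-orientation-aware model scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specscore)
```

## The model and its assumptions

`specscore` evaluates a predicted protein model against a native structure
with a five-component superposition-based metric in the united-residue
representation: each residue is a Cα atom plus one side-chain characteristic
point (SC), the unweighted centroid of its side-chain heavy atoms. The
representation assumes side-chain identity between model and native (pairs
with mismatched residue names are dropped with a warning) and that a single
rigid-body frame relates the two structures locally — all side-chain terms
are computed under one reference superposition derived from the Cα atoms,
never refit on the side chains themselves. That choice is what makes the
side-chain terms measure *orientation error* rather than being absorbed into
the fit.

Given the reference transform, each aligned pair contributes the Cα distance
`d`, the SC–SC distance `r = |native_SC − model_SC|`, planar angles
`theta1`/`theta2` between that displacement and the two virtual Cα→SC bonds,
and the signed dihedral `phi` of the native bond about the displacement
direction relative to the model bond, mapped to [0°, 360°).

The Cα component is GDT-style: an iterative seed-and-extend search
(contiguous windows of 3/5/7 residues plus the full chain; at most 10
refine-reselect iterations per threshold) approximates, for each threshold
in {0.5, 1, 2, 4} Å, the largest residue subset simultaneously superimposable
within it. Exact maximal-subset search is NP-hard; this is the standard
community heuristic. The search necessarily dominates the single full-length
least-squares fit because that fit is one of its seeds.

The four side-chain components use cumulative bins with linearly decreasing
weights, `2 Σ (k−i+1) pᵢ / (k(k+1))`: ten 0.5 Å distance bins to 5 Å, four
planar bins to 120°, ten dihedral bins to 300°. The total weights the Cα
component by 4 and divides by 8, giving backbone and side chain equal
halves.

## Normalization and degenerate inputs

* The Cα component divides by the full native length; the side-chain
  components divide by the number of native residues bearing at least one
  side-chain heavy atom (glycine excluded — its virtual bond is undefined).
  Missing model residues, and model residues whose side-chain atoms are
  absent, therefore cost score rather than silently shrinking the
  denominator.
* Coincident SC points (`r < 1e-6` Å), glycine on either side, or a
  vanishing virtual bond make the angles undefined; such pairs enter the
  angle bins with value 0, i.e. full credit, because the degeneracy arises
  exactly when the side chains agree perfectly. The distance `r` itself is
  always scored.
* A native with no side-chain-bearing residues at all (polyglycine) leaves
  the side-chain components `NA` and the total equals the Cα component,
  flagged in the result.
* When both bond vectors are collinear with the SC displacement the torsion
  plane is undefined; `phi` degenerates to 0 (parallel bonds) or 180°
  (antiparallel). Separately, when the two bonds and the displacement are
  *coplanar* the signed dihedral is 0 or 180° up to floating-point noise,
  and a noise sign of −ε would otherwise wrap 0 to ≈360°, the worst bin; a
  `|sin| < 1e-9` guard snaps these cases to the exact value.

## Open design choices and their resolutions

* **Direction of the SC displacement.** The formulation never fixes whether
  the displacement points model→native or native→model. The package fixes
  `rvec = native_SC − model_SC` and uses it identically in both planar
  angles and in the dihedral, making results reproducible; the planar-angle
  pair is asymmetric under this convention (one angle is measured "with" the
  arrow, one "against"), which is inherent to any single-vector choice.
* **Signed vs. unsigned dihedral.** The printed arccos form alone cannot
  exceed 180°, which would make the bins above 180° vacuous; the package
  computes the signed dihedral mapped to [0°, 360°), whose magnitude part
  agrees with the arccos expression (property-tested). The unsigned reading
  remains available implicitly as `min(phi, 360° − phi)`.
* **Seventh dihedral bin.** The printed "≤ 201°" breaks the uniform 30°
  ladder and is treated as a typo for 210°; `specs_config(dihedral_bin7 =
  201)` and the CLI flag `--dihedral-bin7 201` restore the printed value.
* **Reference superposition.** Which of the multiple GDT superpositions
  anchors the side-chain terms is unspecified; the package selects the
  visited transform with the highest count at the largest threshold, ties
  broken at successively smaller thresholds, then by lowest fitted RMSD, and
  reports the choice (rotation, translation, counts) in the CLI output.
* **Residue correspondence** is by identifier (chain, number, insertion
  code), the convention for model/native pairs sharing target numbering; a
  sequence-alignment fallback is out of scope.

## What the synthetic generator emulates — and what it does not

`make_native()` builds an idealized chain: Cα atoms on a helical spiral or
extended zigzag with exact 3.8 Å spacing, backbone N/C/O placed in a local
frame with realistic bond lengths, and side chains from nine per-type
templates (ALA, SER, CYS, VAL, THR, LEU, ILE, ASP, ASN; 1–4 heavy atoms)
with a seeded rotamer drawn near {−60°, 60°, 180°}. A configurable fraction
of residues is glycine. Everything is deterministic in the seed, which is
recorded in a REMARK line on output.

`make_decoy()` perturbs a native with independent per-residue Gaussian Cα
noise (propagated rigidly to the whole residue), a rotation of the
side-chain atoms about the Cα–Cβ bond, an optional rigid side-chain
displacement, and an optional whole-domain shift. Defaults are zero; the
tests state their own magnitudes (noise grid 0.1–5 Å spanning
near-experimental to wrong-fold Cα error; rotations 30–170° spanning rotamer
wells).

The rotation axis deserves a note. Rotating the SC centroid about an
*arbitrary* axis through Cα makes the native planar angle `theta2 = 90° −
γ/2` shrink — i.e. improve — as the rotation γ grows, an artifact of the
isoceles geometry that sets in whenever model and native share the Cα and
the bond length exactly. The generator instead rotates the side-chain atoms
about the Cα–Cβ bond: the χ1-rotamer error that fixed-backbone side-chain
prediction actually makes. The centroid then moves on a narrow cone
(half-angle ≤ ~30° for the template palette), both planar angles stay within
one bin across all rotation magnitudes, and the side-chain distance term
decreases monotonically with the rotation — which is also why this
perturbation doubles as an exact χ1 offset for the torsion tests. This
choice was made from the geometric analysis above before the corresponding
tests were written.

What the generator does **not** emulate: real rotamer distributions,
stereochemical self-consistency (no clash relaxation, approximate peptide
geometry), missing density, alternate conformations in the wild, or
physically realistic decoy ensembles. A green test therefore establishes the
*metric's* contracts — exact self-identity, rigid-motion invariance,
oracle-verified binning, monotone response to the planted error — not
agreement with any external benchmark score.

## Numerical choices

* Angle cosines are clamped to [−1, 1] before arccos; angles are stored in
  radians, bin bounds converted from degrees once at configuration time.
* Degeneracy threshold `eps = 1e-6` Å for coincident points and vanishing
  bonds; `1e-9` for the collinear/coplanar sine guards.
* The Kabsch fit corrects the SVD reflection branch so the rotation
  determinant is +1; orthonormality of any user-supplied transform is
  verified to ~1e-4.5 before use.
* The χ1 dihedral sign follows the standard structural-biology toolkit
  convention; the angular RMSD wraps differences to [0, π], so the branch
  choice never affects it.
* PDB output carries the format's three decimals; round trips are exact to
  1e-3 Å and tests that pass structures through files use that tolerance.

## Known limitations

* The GDT search is a heuristic: it lower-bounds the true maximal counts
  (and is tested to dominate the global fit), but can in principle miss the
  optimum that an exhaustive search would find.
* The [0°, 360°) dihedral binning is asymmetric: a small clockwise torsion
  error lands near 360° and scores worse than the same counterclockwise
  error. This follows from taking the bins beyond 180° seriously.
* Identifier-based pairing cannot handle renumbered models; no mmCIF input;
  single conformer only (first MODEL, highest-occupancy alt-loc).
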