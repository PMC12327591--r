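---
title: "Detecting high-fluctuation 3D motifs in MD trajectories"
author: "sphereMotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-fluctuation 3D motifs in MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sphereMotif)
```

## The problem and the model

A molecular dynamics trajectory records the coordinates of every protein
atom over a sequence of frames. In a stable fold most of those coordinates
fluctuate mildly about an equilibrium; functionally interesting behavior —
loop rearrangements, terminal folding, hinge motion — is localized in both
space and time. `sphereMotif` detects such regions with a deliberately
simple, assumption-light heuristic:

1. On a **target frame** (by default the first), a sphere of radius $d$ is
   centered at every residue's C$\alpha$, fixing a spatial neighborhood per
   residue.
2. For every residue $i$ and every consecutive frame pair $t \to t+1$, the
   RMSD of sphere $i$'s member atoms between the two frames is computed.
3. The $R \times (F-1)$ cells are ranked and the top $p\%$ are reported as
   **high-fluctuation motifs**.

The underlying assumptions are that (a) one frame's geometry is
representative enough to define neighborhoods for the whole trajectory —
reasonable for equilibrated runs, questionable for large-scale unfolding,
where a late target frame can be chosen instead — and (b) frame-to-frame
deviation of a *neighborhood*, rather than a single atom, is the quantity
of interest, because it captures concerted local motion including
long-range spatial contacts that sequence-neighborhood measures miss.

This differs from RMSF, which averages each atom's deviation from its own
trajectory-mean position over *all* frames: RMSF tells you which residues
are mobile overall, the sphere score tells you where *and when* a
neighborhood moves. `rmsfBaseline()` implements the traditional measure so
both can be compared on the same trajectory.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `radius` ($d$) | 4 | Å | sphere radius; accepted range 2–8. Small $d$ isolates single residues, large $d$ blends neighborhoods. The package default 4 Å sits mid-range; the bound itself is part of the method contract and is enforced (`checkRadius()`). |
| `percent` ($p$) | 5 | % of $R(F-1)$ cells | how many motifs to keep; $\lceil p/100 \cdot R(F-1) \rceil$, so any $p > 0$ yields at least one motif. |
| `targetFrame` | 1 | frame (1-based) | the frame on which sphere membership is fixed. |
| `rmsdMode` | `superposed` | — | `superposed` removes each sphere's rigid-body motion (Kabsch SVD, reflection-corrected) before scoring; `raw` scores plain displacement. |
| `membershipMode` | `residueCA` | — | see below. |
| `includeHydrogens` | `FALSE` | — | hydrogens are excluded from spheres by default so trajectories with and without explicit hydrogens score comparably. |

The defaults for $d$ and $p$ are this package's own choices (a mid-range
radius and a small motif fraction suited to highlighting); the method
itself prescribes only the 2–8 Å range.

### Two sphere definitions

"Atoms in spatial contact within $d$" admits two readings, and they
genuinely differ: a residue-level one (residue $j$ is a member iff
$\lVert C\alpha_i - C\alpha_j\rVert \le d$, whole residues included) and an
atom-level one (any atom within $d$ of the center C$\alpha$). Both are
implemented. `residueCA` is the default because it keeps whole residues
together — spheres then have chemically meaningful membership and the
selection strings map cleanly to viewer selections — while `atomAny` is
available when strict geometric membership is wanted. In both modes the
center residue always belongs to its own sphere, and the boundary is
closed ($\le d$) so membership is a deterministic function of the
coordinates.

### Raw versus superposed scores

Raw MD output usually carries global rigid-body drift (translation and
tumbling of the whole molecule), which contributes to the raw RMSD of
*every* sphere identically and can dominate genuine local signal. The
default therefore superposes each sphere pair (Kabsch) before scoring, so
only internal deformation of the neighborhood counts, and
`superposed ≤ raw` holds cell-wise. `raw` mode remains the right choice
for trajectories that were already globally fitted by the MD
post-processing, and reproduces plain frame-to-frame displacement exactly
(a pure translation of norm $\lVert t\rVert$ gives raw scores exactly
$\lVert t\rVert$ and superposed scores 0 — this rigid-motion contract is a
test).

## Validation rules

Before any analysis the input structure (model 1 of the trajectory file)
is cleaned, and every action is logged:

* HETATM groups are removed and counted as **water** (by residue name),
  **ion** (known monatomic species, or any single-heavy-atom group) or
  **ligand** (everything else). Waters get their own category rather than
  being folded into "ligands" so the log stays informative.
* A chain is protein iff it contains at least one standard amino-acid ATOM
  residue; other chains are removed whole.
* Alternate locations collapse to the conformer with the highest total
  occupancy (ties: first in file) — the standard single-conformer
  convention.
* A residue missing any heavy atom of its standard composition (hydrogens
  never required, OXT tolerated as an extra) is rejected, as are
  duplicate residue identifiers and nonstandard residue names such as MSE
  (no modification chemistry is attempted).
* A multi-model file supplied as a single structure uses model 1, with a
  note. Later trajectory frames are *not* re-validated: they must match
  the cleaned topology atom-for-atom, and any discrepancy is an error
  naming the frame — silent atom drift across frames would corrupt every
  score after it.

Coordinates are never modified, and retained + rejected + removed
partitions the input records (tested as an invariant).

## The synthetic generator

`synthSpec()`/`makeTrajectory()` generate poly-alanine chains (helical or
extended C$\alpha$ trace; all five ALA heavy atoms, so missing-atom
validation stays exercised) with two controllable motions:

* a per-frame **rigid transform** (rotation about the base centroid plus
  translation), composed frame over frame — emulating global drift;
* **localized Gaussian noise** of standard deviation $\sigma$ per
  coordinate, applied to a residue window and redrawn independently each
  frame — emulating a flexible fragment. Independent redrawing (not a
  random walk) keeps the frame-to-frame displacement distribution
  stationary and analytically checkable: the per-atom displacement is
  $N(0, 2\sigma^2 I_3)$, so $E[\mathrm{RMSD}^2] = 6\sigma^2$, which the
  tests verify against a Monte-Carlo mean.

Everything is a deterministic function of the spec, including its seed.
What the generator does **not** emulate: bonded geometry constraints,
side-chain packing, correlated collective motion, solvent effects and
periodic-boundary artifacts. Passing tests on synthetic data therefore
demonstrate the *algorithmic* contracts (dimensions, rigid-motion
invariance, signal recovery, determinism), not biophysical realism of the
scores on real trajectories.

## Numerical and design choices

* **Neighbor search** uses a cell list (spatial hash with cell edge $=d$,
  27-cell stencil); tests assert exact agreement with a brute-force
  all-pairs scan, so results are independent of the index internals.
* **Kabsch RMSD** uses the closed-form SVD solution with determinant
  correction (reflections never used); degenerate cases (single atom,
  collinear sets) fall out of the SVD naturally, and a clamped
  `max(0, ...)` guards the final square root against tiny negative
  round-off.
* **Selection** uses a ceiling count and a total tie-break order (higher
  score, then earlier transition, then lower residue index), making the
  motif set byte-reproducible.
* **Transitions** compare frame $t+1$ against frame $t$; scores are
  attributed to the *later* frame in all outputs (CSV columns are
  labelled "2"…"F"), and annotation colors frame $t+1$ plus an overview
  on frame 1.
* **Output precision**: scores print at 4 decimals (beyond the 3-decimal
  PDB coordinate precision); the B-factor flag value is 99.99, the
  largest number the PDB 6.2 field holds.
* **Frame indexing** is 1-based everywhere a user sees it (reports, CSV
  labels, error messages), matching "the first frame" phrasing.

## Problem sizes in the test suite

The suite runs entirely on generated data: oracle comparisons use up to 50
residues over 20 random draws, recovery properties use 30 residues × 5
frames over 20 seeds, and the CSV dimension check builds a 93-residue ×
3000-transition matrix directly. These sizes were chosen to exercise every
code path and keep the full suite fast enough for routine development.

## Known limitations

* Only multi-model PDB trajectories are read; binary formats (XTC/TRR/DCD)
  must be converted upstream (e.g. `gmx trjconv -o traj.pdb`).
* Sphere membership is static by design; a residue that migrates *into* a
  flexible region after the target frame is seen only through the spheres
  it already belonged to.
* Scores are unweighted heavy-atom RMSDs: no mass weighting, no per-residue
  normalization by sphere size, so spheres of very different sizes are
  compared on a common but not size-adjusted scale.
* Whether the "top $p\%$" pool should be residue×transition cells or
  residues only is a genuine ambiguity; this package uses cells, matching
  the stated pool size $R(F-1)$, and documents rather than hides the
  choice.
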