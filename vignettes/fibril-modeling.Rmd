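---
title: "Symmetry scoring, assembly and measurement of amyloid fibril models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetry scoring, assembly and measurement of amyloid fibril models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilkit)
```

## The modelling problem

Short amyloidogenic peptides aggregate into fibrils built from many
copies of the same monomer stacked with quasi-translational screw
symmetry: each chain is (approximately) the previous chain rotated by a
small twist angle about the fibril axis and translated by a rise of
roughly one β-strand spacing. A common prediction strategy samples many
small protofilament models (e.g. five interacting monomers), selects
those that already look fibril-like, and propagates the best candidate
into a long fibril whose observables — length, twist, helical pitch,
β-sheet content — can be compared with IR and AFM experiments.

`fibrilkit` implements the selection, propagation and measurement
stages. It assumes rigid-body geometry throughout: chains are compared
and propagated as rigid bodies, which is appropriate after the
candidates have been relaxed by whatever upstream refinement produced
them, and is exactly what makes the assembled fibril's symmetry
inherited rather than re-estimated.

## pcaRMSD: scoring translational symmetry

For a model of $M$ chains with $N$ C$\alpha$ atoms each,

$$\mathrm{pcaRMSD} \;=\; \frac{1}{M^2 - M}\sum_{i=1}^{M}\sum_{j=1}^{M}
\sqrt{\tfrac{1}{N}\sum_{k=1}^{N}\lvert X_k^{(i)} - Y_k^{(j)}\rvert^2},$$

where the deviation for each ordered pair $(i,j)$, $i \ne j$, is taken
*after* optimally superposing chain $i$ onto chain $j$. Because the
diagonal terms vanish and RMSD is symmetric, the ordered double sum
with its $1/(M^2-M)$ prefactor is identical to the arithmetic mean over
the $M(M-1)/2$ unordered pairs; the implementation computes the
unordered mean and the tests assert the equivalence to $10^{-10}$ Å.

All $N$ C$\alpha$ atoms enter each pairwise fit — no core selection is
applied, since for 13-residue peptides every residue participates in
the stack. Pairwise fitting uses the closed-form Kabsch solution with
the sign of the smallest singular value corrected, so a reflection can
never be returned even for near-planar chains; peptide chirality is
preserved by construction. Degenerate inputs (fewer than 3 atoms, or
collinear sets with relative singular-value spread below $10^{-12}$)
are rejected rather than silently fitted.

Low scores mean high translational symmetry; ranking is ascending with
ties kept in input order, so repeated runs are deterministic.

## Fibril assembly by iterated overlap superposition

Given an $M$-chain protofilament, a fresh copy is fitted so that its
chains $1..M-1$ superpose jointly onto chains $2..M$ of the fixed
model (all C$\alpha$ atoms of the overlap window in one Kabsch fit).
That single transform is then composed $t-1$ times to place iteration
$t$'s copy, and the central chain (index $\lceil M/2\rceil$ by
default) of each placed copy is collected into the fibril.

Two conventions deserve a note:

* **Iteration 1 contributes the untransformed copy.** The base case is
  chosen so that $n$ iterations yield exactly $n$ chains; with the
  default 30 iterations this gives the 30-chain fibril.
* **Compose, don't re-fit.** Because every copy is the identical rigid
  protofilament, re-fitting each new copy against the growing assembly
  is mathematically identical to composing the one overlap transform;
  composition is used because it cannot accumulate floating-point
  refit drift. For an exactly helical input the assembled fibril is
  then exactly helical with the same rise and twist — the tests verify
  agreement with the closed-form screw construction to $10^{-6}$ Å
  over 30 chains.

Backbone atoms ride along with the C$\alpha$ trace, so an assembled
fibril can be scored for hydrogen bonding without reconstruction.

## Measured observables

* **Fibril axis**: first principal direction of the per-chain
  C$\alpha$ centers of mass (equal weights — C$\alpha$-trace models
  carry no masses), anchored at their centroid, with the sign fixed so
  chain order increases along it. One global axis is used for all
  interfaces rather than per-interface local axes.
* **Length $d$** (Å): distance between the centers of mass of the
  first and last chains after ordering along the axis.
* **Twist angle $\alpha$** (degrees): in each chain a marker segment
  joins the C$\alpha$ atoms of two residues in the extended strand
  (defaults 3 and 9 for the built-in 13-residue monomer); segments are
  projected onto the plane perpendicular to the axis and the unsigned
  angle in $[0°, 180°]$ between adjacent chains' projections is
  reported. Handedness is reported separately as the sign of the axis
  component of the cross product, since magnitudes alone do not fix
  chirality. A segment parallel to the axis (projection below
  $10^{-6}$ Å) is an error naming the chain. Both the per-interface
  values and their mean ± sd are returned, so either pooling
  convention can be applied downstream.
* **Rise and pitch**: chains per turn $= 360/\alpha$; rise
  $= d/n$ by default, giving pitch $= (360/\alpha)\,(d/n)$. The $d/n$
  convention is the default because it treats $d$ as $n$ chains' worth
  of axial extent, which is how the pitch of a measured fibril of $n$
  chains is conventionally quoted; the construction-exact alternative
  $d/(n-1)$ (an ideal helix of $n$ chains spans $n-1$ rises) is
  exposed via `convention = "n-1"` and is what the parameter-recovery
  tests use against the generator. For $d = 134.13$ Å, $n = 30$,
  $\alpha = 9.0°$ the default yields 40 chains per turn and a pitch of
  178.8 Å ≈ 17.9 nm. Zero twist is reported as a distinguished
  untwisted result (infinite pitch), not an error.

## Secondary structure

Backbone H-bonds use the Kabsch–Sander electrostatic model:
amide hydrogens are placed 1.0 Å from N opposite the preceding
carbonyl (first residues and prolines carry none), and
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol with a bond when $E < -0.5$. Overlapping atoms (any distance
below 0.1 Å) clamp to the −9.9 kcal/mol minimum with a warning. Within
a chain, pairs closer than $|i-j| = 2$ are never counted, and bridge
partners in the same chain must satisfy $|i-j| \ge 3$.

Residues are assigned to β via the DSSP bridge patterns (parallel and
antiparallel), with bridges that repeat along the chain forming
ladders (state E) and lone bridges isolated β-bridges (state B). The
reported "residues involved in H-bonded β-sheets" counts E and B by
default — helical or turn H-bonds never count — and
`include_isolated_bridges = FALSE` restricts to E, since reported
β-residue counts in the literature are ambiguous on isolated bridges.
C$\alpha$-only models are refused explicitly: the energy needs N, C
and O positions.

`band_correction()` is the one spectroscopy-side operation: amide-I
component intensity fractions $I_c$ are converted to structure
fractions $(I_c/w_c)/\sum_k I_k/w_k$ using relative extinction weights
$w$; with β absorbing twice as strongly as turns, a 74% β intensity
share corrects to ≈ 58.7% β structure.

## The synthetic generator: what it does and does not emulate

`make_hairpin_monomer()` builds an idealized 13-residue β-arch: two
extended strand arms (consecutive C$\alpha$–C$\alpha$ ≈ 3.8 Å,
carbonyls alternating out of the strand plane) joined by a two-residue
U-turn on a circular arc, with the default sequence carrying the
landmarks used elsewhere in the package (Val3 marker, Cys6/Cys11
disulfide positions, Ala8–Ser9 turn). `make_fibril()` stacks screw
copies of it — rotation `twist`, translation `rise` per chain — and
optionally adds isotropic per-atom Gaussian noise after the screw
motion, seeded for bit-for-bit reproducibility.

Defaults are the study conditions of the modelled system: 30 chains,
rise 4.625 Å (a 30-chain fibril of length ≈ 134 Å under the
construction convention), twist 9°, noise 0. The out-of-plane carbonyl
alternation is what makes stacked copies satisfy the parallel
β-bridge patterns, so the generator provides ground truth for the
secondary-structure module as well as for geometry.

What it does **not** emulate: side chains and their packing,
sequence-specific conformational preferences, MD-scale backbone
disorder (its noise is isotropic and uncorrelated), polymorphism, or
multi-protofilament superstructures. Passing parameter-recovery tests
on these fixtures therefore validates the measurement arithmetic, not
the realism of any particular experimental fibril.

`cabsdock_restraints()` emits the neutral six-column restraint table
(chain, residue, chain, residue, distance, weight) used to bias
coarse-grained docking toward in-register stacking — one side-chain
pair restraint per residue per adjacent chain pair (defaults 5 Å,
weight 1), plus optional per-chain Cys–Cys C$\alpha$ restraints
(6.5 Å). A neutral format is used deliberately: docking tools' native
restraint dialects are version-dependent, and the header documents the
mapping.

## Numerical and design choices

* **Conformer averaging** superposes every conformer onto the *first*
  (not an iterative mean structure) before per-atom averaging:
  deterministic, and adequate for the small NMR-style ensembles this
  targets. Whether upstream ensemble averages were computed after
  superposition is generally unstated in the literature;
  superpose-then-average is this package's convention.
* **Chain correspondence** when comparing a model against a reference
  tries both the given chain order and its reversal, keeping the lower
  RMSD — a fibril has no intrinsic chain labelling.
* **Chain-ID policy** for PDB output cycles A–Z, a–z, 0–9 (62 chains),
  enough for the 30-chain fibril in one file; more chains are an
  explicit error. Alternate locations keep the highest-occupancy
  conformer (ties: first record); insertion codes are rejected because
  short peptides never need them.
* **Ties** in centroid or best-of-K selection break to the lowest
  index; ranking ties keep input order.

## Problem sizes and limitations

The test suite and examples run on 5-chain protofilaments, 30-chain
fibrils of 13 residues (390 residues, the full-size system of
interest) and parameter grids of 18 synthetic fibrils — everything a
laptop executes in seconds. Known limitations: no mmCIF input, no
hetero-atoms or hydrogens on input, no flexible or partial
superposition (TM-score, sequence alignment), only the E/B subset of
the DSSP state alphabet, and no modelling of the upstream docking or
MD stages themselves.
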