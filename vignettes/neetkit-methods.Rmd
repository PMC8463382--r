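---
title: "Methods and design choices in neetkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in neetkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neetkit)
```

`neetkit` analyzes the redox chemistry of protein-bound [2Fe–2S]
clusters of the NEET family along five largely independent axes. This
vignette records the models behind each stage, the tunable parameters
and why their defaults are what they are, what the synthetic generators
do and do not emulate, and the decisions taken where the design was
genuinely open.

## Difference densities and atomic charge changes

Electron densities for the oxidized and reduced cluster live on regular
voxel lattices (Gaussian cube files; internally always Bohr and e).
The change on reduction is the voxel-wise difference
$\Delta\rho = \rho_\mathrm{red} - \rho_\mathrm{ox}$, and per-atom charge
changes are integrals of $\Delta\rho$ over neighborhoods of the atoms.

Two partitions are offered. The default assigns every voxel to its
nearest atom (Voronoi cells). It is deterministic, exhaustive and
exclusive, so per-atom charges sum to the grid total *exactly* — the
conservation law the test suite checks at 1e-10 e. The alternative,
`spheres(radius)`, integrates within a fixed radius of selected atoms
and reports the remainder as unassigned; it has **no default radius**
because no principled one exists — the integration neighborhood used
around selected atoms is an open choice, so the scheme in force is
always recorded in the output metadata. Voxel ownership ties go to the
lowest atom index, for reproducibility.

Integration is a midpoint Riemann sum with no sub-voxel correction. For
smooth Gaussian-like densities the midpoint rule converges faster than
any power of the spacing, so a 40³ grid spanning ±6σ already recovers
planted integrals to ~1e-4 e; the refinement test (8³ → 16³ → 32³ on a
two-Gaussian field) shows the error falling monotonically while
discretization still dominates. At the 20³–80³ sizes used elsewhere the
error is already at the Gaussian-tail/rounding floor (~1e-9), which is
why the monotonicity check deliberately uses the coarser sequence.

Grids with non-coincident lattices are **rejected, never resampled**:
interpolation would silently move charge between Voronoi cells and bias
ΔQ. Both cube sign dialects are honored on read (negative atom count =
MO cube with an extra header record; negative voxel counts = Angstrom
axes); files are always written in Bohr.

## Cluster sites and truncated QM models

A [2Fe–2S] site is detected as two Fe atoms sharing two bridging
sulfides, with protein S/N/O donors within **2.6 Å** of either iron.
The cutoff is not a literature constant; it was chosen once to cover
the longest reported iron–ligand bond in this family (0.246 nm) with
margin while excluding second-shell atoms. The His-bound iron is
labelled Fe_Y, its 2-Cys partner Fe_X; a centre with three Cys
thiolates and one His nitrogen gets class `3Cys:1His`.

The three truncation levels follow standard metalloprotein QM practice:

* **Level 1** — cluster + ligand side chains from C_β, each C_β
  saturated to a methyl by an added H (1.09 Å along the cut bond).
* **Level 2** — the full ligating residues plus the main-chain atoms of
  residues spanning between consecutive ligands *within a chain*; the
  spanning side chains are replaced by an H on C_α, termini capped
  ACE/NME. Ligands on different chains cannot be spanned; such pairs
  are not silently bridged, and a missing residue inside a span is a
  hard error naming the gap (a chain break would otherwise produce a
  chemically absurd model).
* **Level 3** — cluster + every residue with *any* atom within **4 Å**
  of any cluster-core atom (the 2 Fe + 2 bridging S), whole residues
  included. Residue granularity is a choice: including whole residues
  keeps models chemically sensible at the cost of a few extra atoms.

His protonation is carried as metadata only — hydrogens are placed by
standard geometry externally, and both protonation states differ only
in that flag. Formal charges are stored, not validated: −2 (oxidized)
and −3 (reduced) for a 3Cys:1His centre with thiolate ligands.
Coordinates are Å inside PDB frames and nm in every reported table.

Superposition uses the Kabsch SVD solution with the proper-rotation
determinant correction. The test suite cross-checks it against a
quaternion (Horn) implementation and against `bio3d::fit.xyz` at 1e-8,
keeping the implementation and its oracles on separate code paths.

## Seminario force constants and RESP charges

For bonded parameters the 3×3 interatomic Hessian block $H_{ij}$ is
eigendecomposed after negation and projected on the unit bond vector:
$k_{ij} = \sum_m |\lambda_m|\,|v_m\cdot\hat u_{ij}|$. Absolute
eigenvalues are the standard practice for slightly non-positive blocks;
the policy is recorded in each result. Both directional estimates
$k_{ij}$ and $k_{ji}$ are computed and averaged, and both are reported
so their (normally negligible) difference is visible — whether a
published table used one block or the average is not generally
knowable.

The projected curvature is $d^2E/dr^2$; reported constants follow the
AMBER convention $E = K_r (r - R_\mathrm{min})^2$ (no ½), so the raw
curvature is halved and converted at 1 Hartree/Bohr² =
9.37582×10⁵ kJ/mol nm² (checked against an independent dimensional
computation in the tests). On an exactly harmonic pairwise-bond model
the extraction is exact; angle cross-terms contaminate it *through the
eigenvector mixing*, quadratically in the angle/bond curvature ratio.
The three-atom validation toy uses a ratio of ~0.1 (bonds
25000/18000 kJ/mol nm², angle 25 kJ/mol/rad²), where the recovery error
stays below 2%; substantially stiffer angles relative to the bonds
degrade any bond-projected extraction.

RESP charges minimize the squared ESP misfit plus the hyperbolic
restraint $a\sum_A(\sqrt{q_A^2+b^2}-b)$ with $b = 0.1$ e and default
$a = 5\times10^{-4}$ a.u. — community defaults. Hydrogens are fitted
but not restrained. The total-charge and symmetry-class constraints are
Lagrange rows in the reweighted linear system, so they hold to solver
precision (1e-12) at every iteration; convergence is a deterministic
|Δq| threshold. A two-stage refit is available but off by default — at
a single stage the behavior is unambiguous, and which stage scheme a
given published parameterization used is rarely stated. Merz–Kollman
probe shells at 1.4/1.6/1.8/2.0 × vdW radius use a deterministic
Fibonacci spiral (no RNG), pruned of points falling inside any atom's
same-scale shell.

## Coevolution and the allostery screen

Column-pair association uses the weighted Pearson chi-squared over the
20-amino-acid alphabet. Sequence weights are inverse cluster sizes at
80% identity. Gaps are **pairwise-deleted, never a 21st symbol**: a
gap-gap "match" carries no evolutionary signal, and treating gaps as a
state lets alignment artifacts masquerade as covariation. For a
perfectly covarying pair of two-state columns with unit weights the
statistic equals the number of paired sequences — the hand-checkable
anchor the tests pin at χ² = 20 for n = 20.

The full L×L matrix is computed from a single cross-product of the
weighted one-hot-encoded alignment: gap rows are zero rows, so pairwise
deletion and per-pair marginals fall out exactly, and the result is
verified cell-by-cell against the direct per-pair tabulation. Raw
scores are min-max rescaled to [0, 1] over off-diagonal entries (the
published scores this emulates are served normalized, but the exact
rescaling is unpublished — a rank transform is provided as an
alternative, and the normalization metadata records the raw range).

The strong-pair screen retains pairs with normalized score **> 0.7**
AND within the **top 30%** of all scores AND sequence separation ≥ 5
AND minimal heavy-atom distance ≥ 5 Å. The two score filters are
applied conjunctively because both thresholds are part of the
procedure; since it is ambiguous whether the absolute cut applies
before or after the top-fraction cut, the conjunction (which is
order-independent) is the default and a `mode` flag gives either filter
alone. "Close proximity" has no standard definition; 5 Å heavy-atom
distance and 5-residue separation are the documented defaults, both
exposed and recorded in the report header. Unmappable alignment columns
are listed and skipped, never guessed.

## GROMOS conformational clustering

The greedy neighbor-count algorithm: repeatedly take the frame with the
most neighbors within the RMSD cutoff, form a cluster, remove it,
repeat. Ties go to the lowest frame index (the original scheme is
silent; determinism is required for reproducible representative
selection). Neighbors use **≤ cutoff**: boundary frames are measure-zero
in float data, and the non-strict form keeps the all-identical-frames
case in one cluster. The default cutoff is 0.11 nm on the backbone
(N, C_α, C), the value used to pick MD representatives for this system;
the superposition selection is the same as the metric selection. There
is no re-fitting to centroids — this is the pure seed-based scheme, not
k-medoids. Correctness is checked by exact agreement with a
brute-force restatement over 200 random matrices (M ≤ 12) and by
recovery of three planted basins.

## Lability kinetics

The lability experiment this stage operationalizes is qualitative —
absorbance at 458 nm decaying (or not) over time at 310/313/315/318 K.
The package's quantitative rule is its own construction and is labelled
as such in every fit object: traces are normalized by the mean of their
first three points (robust to a single noisy t = 0 reading), fitted
with the flat model and with
$A(t) = c + (a - c)e^{-kt}$, $c \in [0,1]$, $k \ge 0$,
and a trace is **labile** only if the exponential wins by AICc
(small-sample form, appropriate for ~60-point traces) *and* the fitted
total loss $(a-c)(1-e^{-kt_\mathrm{end}})$ over the observed window is
at least 0.2. The amplitude $a$ is a free parameter (~1) rather than
pinned at 1: the three-point window only *estimates* the initial
absorbance, and anchoring the model to that estimate propagates its
error into a systematic underestimate of $k$ for fast decays — with
$a$ free, the median relative bias of $\hat k$ stays within a few
percent at $k$ from 0.01 to 0.2 min⁻¹ (σ = 0.01, n = 60). The 0.2-loss
floor keeps flat noisy traces (σ ≤ 0.02) from ever being called labile
in the 1000-null control. Classification is invariant to rescaling of
absorbance and of the time unit ($k$ transforms reciprocally).
Arrhenius/Eyring activation analysis is deliberately out of scope — a
monotone-rate flag (Spearman correlation of (T, k) equal to 1 within a
sample label) is reported instead.

## What the synthetic generators emulate — and what they don't

Every generator is bit-reproducible from its seed, runs on a private
RNG stream (the caller's stream is untouched), and emits its ground
truth alongside the data rather than recomputing it, keeping oracles
independent of library code paths.

* `gen_gaussian_density` / `gen_redox_pair`: sums of normalized
  isotropic Gaussians with known integrals; the redox pair plants
  exactly 1.0 e of added density (default 0.5 on Fe_Y, 0.2 per bridging
  S, 0.1 on the His N — the localization pattern of the reduction).
  These are *not* physical electron densities: no core/valence
  structure, no negative regions in ρ, no basis-set ripple. They test
  integration and partitioning, not chemistry.
* `gen_harmonic_hessian`: finite-difference Hessians (step 1e-4 Bohr)
  of an analytic bond/angle energy — exactly the harmonic world in
  which Seminario extraction is well-posed; anharmonicity and
  long-range coupling of real Hessians are absent.
* `gen_msa`: i.i.d. background columns with planted coupled pairs
  (coupling interpolates independence → a deterministic symbol
  bijection). There is no phylogeny beyond identity clusters, no
  conservation gradient, no alignment error — so recovery results bound
  what the statistic can do under ideal sampling, not on a real family.
* `gen_conformers`: basin centres plus isotropic noise and a random
  rigid motion per frame (which the metric must undo). A plain 3-vector
  basin shift is applied to the second half of the atoms (a hinge
  deformation), because a uniform translation of all atoms is rigid and
  invisible to RMSD.
* `gen_decay_traces`: the fitted model plus Gaussian noise — no
  baseline drift, no instrument artifacts.
* `gen_mock_neet_structure`: a synthetic, idealized scaffold (explicitly
  not a real PDB entry) with exact planted geometry: Fe–S(Cys) 2.25 Å,
  Fe–N(His) 2.18 Å, bridging Fe–S ≈ 2.23 Å, spanning residues, a distal
  loop for the allostery screen, and two probe residues at 3.9/4.1 Å to
  exercise the 4-Å boundary from both sides.

Passing on these inputs therefore demonstrates algorithmic correctness
and calibration, not accuracy on laboratory data.

## Problem sizes and runtime envelope

The shipped tests and the acceptance script use: 40³ voxel grids
(24³–32³ where many replicates are needed); 50 random densities for the
conservation check; 200 random matrices for the clustering oracle;
n = 200 sequences × L = 100 columns × 100 replicates for coevolution
recovery; 100 replicates per rate (three rates) plus 1000 null traces
for kinetics. These sizes give stable statistics at desk scale — the
full suite runs in well under a minute on one CPU.

## Known limitations

* No Bader/AIM or fuzzy-atom partitioning; the Voronoi default is
  crisp and conservative but not basis-aware.
* Level-2 models cannot span ligands on different chains.
* The coevolution stage scores a given alignment; it does not build
  one, and it fits no global (DCA-style) model, so indirect couplings
  are not deconvolved.
* Structure distances for the allostery screen use a single
  representative model per call; for ensembles, screen each member and
  take the minimum distance (the conservative choice for a proximity
  exclusion).
* The kinetics stage fits a single first-order component; biphasic
  release would be mis-summarized by one rate.
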