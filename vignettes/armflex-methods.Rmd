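---
title: "Methods: quantifying bend and twist in alpha-solenoid repeat proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying bend and twist in alpha-solenoid repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armflex)
```

## The problem

Alpha-solenoid proteins — importin-alpha and its armadillo-repeat (ARM)
relatives — are elongated stacks of small helical repeats. In
importin-alpha, ten tandem ARM repeats of three helices each wrap into a
superhelix whose concave face binds the two basic clusters of a bipartite
nuclear-localization sequence (NLS): a major site around repeats 2–4
(positions P2–P5) and a minor site around repeats 6–8 (P1'–P2'), with a
10–12 residue linker spanning the two. The functional question is how the
solenoid flexes: its low-frequency motions decompose into a **bend**
(opening/closing of the concave face, changing the overall curvature) and
a **twist** (rotation of successive repeats about the superhelical axis),
and these motions modulate how the NLS-binding grooves present their
pockets.

`armflex` re-implements, as a tested and reusable pipeline, the analysis
chain used to characterize such systems:

1. reference-structure clustering of merged trajectories with a
   per-replicate convergence check,
2. elastic-network normal modes (NMs) with a degree-of-collectivity per
   mode and conformer generation along each mode,
3. principal component analysis (PCA) of the Cα displacement covariance
   and NM–PC overlap,
4. residue–residue dynamic cross-correlation maps (DCCM),
5. bend/twist geometry — a three-anchor radius of curvature and
   inter-repeat H3 helix-axis angles,
6. per-contact occupancy of salt bridges, hydrogen bonds and hydrophobic
   contacts at the receptor–peptide interface.

Because all-atom MD of the real complex is far outside a desk-scale test
budget, the package ships a **synthetic solenoid generator** whose
motions and contacts have analytically known ground truth. Every stage is
validated against that ground truth or an independent oracle.

## The synthetic world

`build_solenoid()` lays one Cα pseudo-atom per residue on an idealized
superhelix: `n_repeats = 10` repeats of `helices_per_repeat = 3` helices
of `residues_per_helix = 12` residues (360 atoms, mirroring the ~10×3
architecture of the ARM core). Helix geometry uses the canonical α-helix
parameters (1.5 Å rise per residue, 2.3 Å backbone radius, 100° per
residue); repeats are related by an exact screw transform (default 25°
twist about the z axis plus an 8 Å rise per repeat, giving a clearly
curved, clearly twisted solenoid that does not self-intersect — a guard
rejects parameter sets whose repeats come within 1 Å). Helices within a
repeat alternate direction, so "H3" is a well-defined, consistently
oriented helix in every repeat.

`simulate_trajectory()` applies, per frame with phase
`sin(2*pi*t/period)`:

* a **twist**: repeat `r` rotates by `(r − mid) × twist_amplitude × phase`
  degrees about the axis *parallel to the superhelical axis through that
  repeat's pivot atom* (the Cα nearest the repeat centroid);
* a **bend**: the N- and C-terminal halves rotate by
  `∓bend_amplitude × phase` about the normal of the anchor plane through
  the middle repeat's pivot;
* isotropic Gaussian noise of `noise_sd` Å per coordinate (seeded).

Two deliberate choices make the ground truth exact rather than
approximate. Rotating each repeat about its own pivot keeps the three
curvature anchors fixed under pure twist, so twist changes every
neighbouring H3 angle by exactly `twist_amplitude × phase` while leaving
the radius of curvature bit-for-bit constant — the bend/twist
decoupling the geometric analysis relies on holds *by construction*, and
the recovery tests can use closed forms. Likewise the hinge passes
through the middle anchor, so the bent anchor triangle (and hence the
radius of curvature extrema) has a closed form. The sinusoidal motion
law is not a claim about real dynamics; it simply gives analytically
known amplitude and period for recovery tests, since the true MD motion
law is unknowable.

Defaults (`motion_spec()`): bend half-angle 10°, per-repeat twist 5°,
period 100 frames, noise 0.3 Å, 100 frames sampled nominally every
10 ps. The amplitudes are of the order suggested by low-mode
displacements of solenoid proteins; the noise is small thermal jitter
that leaves two conformers separated by several Å RMSD clearly
distinguishable. These are stated-world constants, not tuning knobs.

What the generator does **not** emulate: side chains and rotamers,
solvent, force-field energetics, sequence-dependent geometry, anharmonic
or aperiodic dynamics. A green recovery test therefore establishes that
the *analysis* is correct, not that the synthetic system is a faithful
model of importin-alpha.

`build_complex()` places an extended 22-residue bipartite peptide
(sequence `GSAVKRPAATKKAGQAKKKKLD`, numbered 151–172 on chain B, minor
cluster KR, 10-residue linker, major cluster KKKK — validated to have
two basic clusters and a ≥ 10 residue linker) antiparallel along the
concave face, and adds just the pseudo-atoms each scheduled contact
needs: charged-group N/O pairs for salt bridges, donor N–H plus acceptor
O triplets for hydrogen bonds (placed collinear, so the
donor–hydrogen–acceptor deviation is 0° when formed), and side-chain
carbons for hydrophobic contacts. Each contact's `formed_frames` are
drawn (seeded) so occupancy equals its target *exactly*
(`occupancy × n_frames` must be an integer), formed geometry satisfies
its criterion with margin, and broken geometry violates the distance
criterion by at least 1 Å. The default schedule spans occupancies
1.0 / 0.8 / 0.5 / 0.5 / 0.3 / 0.0, deliberately straddling the 50%
reporting filter including the exact boundary.

## Clustering

`lz_cluster()` implements reference-structure clustering on the merged
trajectories: pick a remaining frame uniformly at random (seeded), remove
every frame within RMSD `d` of it (including itself), repeat until no
frames remain; then assign every original frame to its nearest reference
and tabulate per-run frequencies. The default `d = 2.5` Å follows the
published protocol choice, which was constrained to give a feasible
number of reference structures for subsequent normal-mode analysis.
RMSD is computed over Cα after Kabsch superposition — the procedure was
defined on a global Cα RMSD, and fitting is applied because unfitted
RMSD conflates rigid drift with conformational change. Nearest-reference
ties break to the lowest reference index for determinism.
`convergence_table()` reports the per-source frequency matrix and the
maximum inter-source frequency spread; independent replicates of the
same process should represent every reference equivalently (small
spread).

## Elastic-network normal modes

The all-atom vibrational analysis of the original protocol (CHARMM
minimization cascades, VIBRAN modes, VMOD restrained-MD displacement) is
out of scope by design; `armflex` substitutes a Cα anisotropic network
model. `build_hessian()` connects Cα pairs within `cutoff = 10` Å
(a conventional nonbonded cutoff, not claimed equivalent to the all-atom
force field) with uniform springs `gamma = 1`; off-diagonal 3×3 blocks
are `−γ r̂r̂ᵀ` and diagonal blocks enforce translational invariance. With
mass weighting (default) the eigenproblem is `M^{-1/2} H M^{-1/2}`.

What is preserved from the original protocol: the displacement grid
(±3.0 Å of mass-weighted RMS displacement in 0.1 Å steps — 61 conformers
per mode), the MRMS parameterization, the screening role of a restraint
energy, and the mode numbering convention (modes 1–6 rigid, mode 7 the
first internal mode). Eigenvalues are in arbitrary units; a connected
network must show exactly six numerical zero modes (tolerance
`1e-8 × max eigenvalue`), and a disconnected one warns with its
component count.

The **degree of collectivity** of a mode is
`κ = N⁻¹ exp(−Σᵢ α uᵢ² ln α uᵢ²)` with `uᵢ²` the squared displacement
magnitude of atom *i* and `α` normalizing `Σ α uᵢ² = 1`: κ = 1 when all
atoms move with equal amplitude, 1/N when one atom moves. For
mass-weighted eigenvectors the displacement is un-mass-weighted first so
κ refers to real-space motion.

The **restraint energy** of a displaced conformer is its harmonic
network energy normalized by total mass, so a pure-mode displacement
satisfies `E = ½ λ MRMS²` exactly — the closed-form limit the tests
check. The original protocol's restraint energy (a mean-field restraint
term with unstated definition and units) is *not* numerically comparable;
only its screening role is reproduced. Conformers above the 90th energy
percentile are flagged unfavorable (the original work states no
threshold; the percentile is a documented default).

On the default solenoid, mode 7 is a global bend — displacing along it
sweeps the radius of curvature monotonically from ~74 Å to ~37 Å — and
mode 9 changes the inter-repeat angles at nearly constant curvature,
mirroring the bend/twist assignment of the lowest modes in the real
system.

## PCA, overlap and cross-correlation

`compute_pca()` superposes frames on their ensemble mean (fit to frame 1,
then one re-fit to the running mean — the standard quasi-harmonic
practice; the exact reference is unstated in the source protocol),
forms the 3N×3N displacement covariance and returns descending
eigenpairs. `mode_overlap()` is the absolute normalized dot product
between a mode and a principal component; a trajectory generated along
ENM mode 7 with 5% noise is recovered as PC1 with overlap > 0.9.

`dccm()` computes `C_ij = ⟨Δrᵢ·Δrⱼ⟩ / √(⟨Δrᵢ²⟩⟨Δrⱼ²⟩)` per residue pair
from Cα displacements after the same fitting (the standard normalized
vector-dot form; scalar variants exist but are not implemented). Atoms
with displacement variance below 1e-12 Å² get zero off-diagonal entries
and a flag. `merge_ensemble()` concatenates trajectories or
mode-displacement series into the pseudo-trajectories over which
cross-correlations and occupancies are evaluated.

The closed-form DCCM and RMSF examples (+1/−1 two-atom constructions,
a single atom fluctuating ±1 Å) assume pre-aligned frames; fitting a
2-atom or partially frozen system would itself redistribute the motion.
These functions therefore take a `fit` argument (default `TRUE`), and
the idealized identities are asserted with `fit = FALSE`, while the
fitted path is covered by rigid-invariance property tests.

## Bend/twist geometry

The bend is quantified by the **radius of curvature** of three anchor
atoms — two distal tips and a middle vertex (for importin-alpha,
residues R117/A313/K486; for the synthetic solenoid, the pivot Cα of the
first, middle and last repeat):

> R = d² / (2 √(d² − m²)),

with `d` the distal-to-middle distance and `m` half the distal–distal
distance. The source prints this formula with garbled typography; the
circumradius reading adopted here is the unique standard formula in the
stated variables and is verified against the general circumradius
`|a||b||c|/(4·area)` on random triples. For asymmetric inputs `d` is the
mean of the two legs (the formula presumes near-isoceles geometry and
reduces to the exact value when symmetric). Collinear anchors
(`d − m < 1e-9` Å) raise an infinite-radius error rather than returning
a number.

The twist is quantified by angles between axis vectors fitted to the H3
helix of neighbouring repeats. The axis fit defaults to a
bisector-cross construction: local second differences
`r[i−1] + r[i+1] − 2r[i]` point exactly at the axis of an ideal helix,
and consecutive cross products are exactly axial, so an ideal helix is
recovered to machine precision. A plain principal-axis fit (available
as `method = "pca"`) is biased by roughly 2° on a finite helix because
the phase–height cross terms of the covariance do not vanish — that bias
is why it is not the default. Angles are reported unsigned in
[0°, 180°]; a signed torsion about the inter-centroid axis is emitted as
an auxiliary column. In the synthetic geometry the unsigned angle equals
the repeat twist (25° by construction), while the centroid-axis torsion
is a different, uniform value because the local inter-centroid axis is
tilted from the superhelical axis — the angle column is the quantity
with ground truth. The per-frame mean angle is the arithmetic mean over
the nine pairs.

`geometry_series()` tabulates R, the nine pair angles, their mean and
the torsions per frame, and is the discriminant for motion
classification: pure bend moves R (and only the two hinge-straddling
pair angles); pure twist moves every pair angle by exactly twice the
amplitude peak-to-peak while R stays constant. Fixture families with
larger bend amplitude recover larger R ranges, which is how apo-versus-
complex comparisons ("the unliganded receptor bends more") are
expressed.

## Interface contacts

Criteria, all inclusive at the boundary as printed in the source
protocol: donor–acceptor distance ≤ 3.5 Å for salt bridges and hydrogen
bonds; donor-hydrogen-acceptor deviation from linearity ≤ 60° for
hydrogen bonds (i.e. D-H-A angle ≥ 120°); closest side-chain
carbon–carbon distance ≤ 4 Å for hydrophobic contacts. Comparisons carry
a 1e-9 tolerance so geometrically exact boundary cases are not lost to
floating-point representation. Salt bridges reduce charged groups by the
minimum N–O distance; hydrogen-bond donors require an explicit hydrogen
(donors without one are skipped with a warning; a distance-only fallback
is opt-in); the hydrophobic residue set defaults to
Ala/Val/Leu/Ile/Pro/Phe/Met/Trp side-chain carbons (the source never
enumerates its set — this is a documented, overridable default).

Candidates are enumerated internally across the interface (every
donor×acceptor, basic×acidic and hydrophobic residue pair crossing the
two selections; intra-side pairs excluded), replacing the external
contact-listing program of the original workflow. `occupancy_report()`
evaluates every candidate in every frame and reports occupancies, split
into the full table and the ≥ 50% headline report. On synthetic
schedules the reported occupancies equal the targets with zero
tolerance — the module's primary acceptance surface.

## Pipeline and reproducibility

`run_pipeline()` executes generate → cluster → modes/displace →
PCA/DCCM → geometry → contacts with per-stage CSVs, a JSON manifest and
a run log; stage RNG streams derive from the single global seed and no
stage reads OS entropy, so reruns are bit-identical. Configuration files
are JSON (`read_pipeline_config()`); a YAML front end was deliberately
not added since no YAML parser is part of the package's dependency
footprint. A thin CLI wrapper is installed at
`system.file("cli", "armflex.R", package = "armflex")`.

## Numerical choices and degenerate inputs

* Zero-mode tolerance: eigenvalue < 1e-8 × the largest eigenvalue.
* Collinearity/degeneracy: superposition requires ≥ 3 non-collinear
  atoms (second singular value > 1e-8 × the first); curvature requires
  `d − m ≥ 1e-9` Å; helix fits require ≥ 4 Cα and nonzero curvature.
* Unknown elements are an error, never a silent default mass.
* PDB fixed-width: coordinates with magnitude ≥ 10000 Å cannot be
  written; first alternate location kept; insertion codes rejected
  (synthetic and cleaned inputs only).
* Nearest-reference ties break to the lowest reference index;
  uniform sampling over remaining frames is the stated interpretation of
  "sampled randomly".
* RMSF/PCA/DCCM fitting reference: two-pass fit (frame 1, then the
  running mean), chosen because the source leaves the reference
  unstated and this is stable standard practice.

## Known limitations

The elastic-network eigenvalues are in arbitrary units — no frequencies,
thermal amplitudes, or comparability to all-atom restraint energies. The
synthetic peptide's pseudo side chains are geometric tokens, not
chemistry; contact geometry is constructed, so occupancy tests validate
bookkeeping and criteria, not docking realism. The published headline
numbers of the motivating study (specific cluster time stamps, ~80%
cluster occupancy, the concrete contact inventory) derive from
3×100 ns all-atom MD of the crystallographic complex and are not
reproducible at desk scale; the acceptance surface is therefore
property-based plus the two printed protocol constants (the 61-conformer
grid and the collectivity extremes).
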