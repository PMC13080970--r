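---
title: "Judging receptor-bound radioligands from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging receptor-bound radioligands from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrmd)
```

## The scientific question

Targeted alpha-therapy agents couple a radiometal chelator (DOTA, DOTP,
HOPO, DFO\*) to a receptor-binding peptide such as octreotate, which
engages somatostatin receptor 2 (SSTR2), a class-A GPCR. Whether a given
chelator-peptide conjugate remains a good agonist cannot be read off the
chemistry alone: it shows up in the conformational ensemble of the bound
complex. Given such an ensemble — typically frames from molecular-dynamics
simulation — four quantities discriminate between candidate ligands:

1. **The active fraction.** Class-A GPCR activation involves a
   rearrangement of transmembrane helices 5-7, captured here by two
   geometric markers: a Cα-Cα distance across TM5/TM7 that contracts on
   activation, and a three-Cα angle that opens as TM6 swings outward. A
   frame is called *active* when the distance falls **below** its
   threshold **and** the angle rises **above** its threshold (defaults
   19.0 Å and 45°, strict comparisons). The active fraction is the
   proportion of analysed frames passing both.
2. **The ligand-receptor interaction energy** and its per-residue
   Coulomb/Lennard-Jones decomposition, which identifies the residues
   holding the ligand.
3. **Loop flexibility (RMSF)** of extracellular loop 2, whose closure over
   the ligand shows up as a depressed Cα fluctuation sum.
4. **Contact census and penetration depth:** which receptor residues sit
   within 3.0 Å of the ligand (typed by side-chain chemistry), and
   center-of-mass distances between anchor residues that measure how deep
   the ligand sits in the pocket.

This package implements those four analyses over multi-model PDB
trajectories with a JSON topology sidecar, plus a synthetic two-state
ensemble generator that makes every stage verifiable against planted
ground truth without running any molecular dynamics.

## The nonbonded model

The interaction energy between the ligand group $L$ and receptor group
$R$ in one frame is the plain-truncated pairwise sum

$$E = \sum_{i \in L}\sum_{j \in R, \; r_{ij} \le r_c}
  \underbrace{\frac{k\, q_i q_j}{r_{ij}}}_{\text{Coulomb}} +
  \underbrace{4\varepsilon_{ij}\!\left[\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12}
  - \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]}_{\text{Lennard-Jones}}$$

with $k = 1389.35458$ kJ mol⁻¹ Å e⁻² (the CODATA-derived
138.935458 kJ mol⁻¹ nm e⁻²), Lorentz-Berthelot combination
($\sigma_{ij}$ arithmetic mean, $\varepsilon_{ij}$ geometric mean, the
Amber-family convention matching GAFF2/ff19SB-provenance parameters), a
default cutoff $r_c = 10$ Å applied per atom pair at minimum-image
distance, and no shift or switch function.

Three deliberate modelling choices:

* **Short-range pairwise only, no Ewald mesh.** Production engines add a
  reciprocal-space electrostatic term that is *not decomposable by atom
  pair*; a per-residue decomposition is only well defined for pairwise
  terms. Absolute totals therefore differ from engine output, while
  decompositions and *comparisons between ligands* remain meaningful.
  This is stated in the documentation of `nonbonded_config()` as well.
* **No 1-4 exclusions or scaling.** Ligand and receptor are distinct
  molecules, so no cross-group bonded exclusions exist; intra-group
  energies are out of scope.
* **Conservation as an invariant, not an aspiration.** The per-residue
  decomposition reuses the identical pair list as the group total, so
  residue contributions sum to the total to floating-point summation
  order (verified at 1e-12 relative tolerance in the tests).

The per-frame series is summarised as mean ± standard deviation. Because
the field's "±" convention for replicate simulations is ambiguous, the
pipeline reports *both* the mean within-replicate per-frame sd and the sd
across replicate means, labelling each; neither is claimed as anyone
else's convention.

## Geometry machinery

* **Minimum image**: orthorhombic boxes only; each displacement component
  is wrapped to within half a box edge. Triclinic cells are rejected at
  the PDB reader (a CRYST1 record with non-90° angles leaves the box
  unset, with a warning) — membrane-protein cells built by the common
  packing workflows are orthorhombic, and restricting scope avoids a
  subtly wrong triclinic implementation.
* **Centers of mass** are mass-weighted (not geometric), with atoms of a
  residue first unwrapped to the image nearest the residue's first atom
  so a boundary-straddling residue gets a physical center.
* **Superposition** is the Kabsch algorithm via SVD with the determinant
  sign correction, so the returned rotation is always proper. Degenerate
  (collinear/coincident) references are detected from the second singular
  value of the centered reference and rejected.
* **RMSF** uses a two-pass alignment: align all retained frames to the
  first retained frame on the alignment selection, form the mean
  structure, re-align every frame to that mean, recompute the mean, and
  take $\mathrm{RMSF}_i = \sqrt{\langle\,|x_i(t)-\langle x_i\rangle|^2\,\rangle_t}$.
  When a box is present each frame is first made whole by min-image
  unwrapping relative to its first atom (assumes the assembly spans less
  than half the box — true for a receptor in a standard cell), which
  makes the statistic invariant to re-wrapped input.

The alignment selection defaults to all receptor Cα atoms. That is a
documented package choice, not a community standard: published RMSF
values depend on it, and comparisons should hold it fixed.

## Activation criteria: decisions on genuinely open points

The two thresholds are strict inequalities (a frame exactly at 19.0 Å or
45° is inactive): the literature prints the criteria as strict
comparisons, and the boundary is measure-zero for real ensembles.

The combination rule for the two markers is **AND** by default. The two
markers quantify *distinct necessary hallmarks* of the active state
(TM5/TM7 contraction and TM6 outward swing), so requiring both is the
conservative reading; `activation_criteria(..., combine = "or")` exposes
the alternative for sensitivity analysis. Replicate fractions are pooled
frame-weighted, with the unweighted mean and range reported alongside,
because the pooling convention is equally unspecified in the literature.

Marker residue numbers (e.g. 218/306 and 262/269/81 for SSTR2, PDB 7T11
numbering) are *configuration*, shipped as a preset
(`system.file("extdata", "sstr2_criteria.json", package = "gpcrmd")`) —
never hard-coded, since author numbering is structure-specific.

## Contact census choices

A receptor residue is in contact in a frame iff its minimum atom-atom
minimum-image distance to any ligand atom is ≤ cutoff (3.0 Å default,
boundary inclusive). Two readings of "N residues in contact" coexist in
the literature, so both are computed: census membership by contact
occupancy ≥ 0.5 over the analysed frames (the default reported set) and
the mean per-frame contact count. All atoms participate by default
(hydrogens included); `heavy_atoms_only = TRUE` gives the other
convention.

The side-chain class table places tyrosine with the hydrophobics (its
ring dominates pocket packing in this context), histidine with the
charged set, and glycine with the polar-uncharged set; all three are
conventions rather than facts, and the table is fully overridable via a
JSON file.

## What the synthetic generator emulates — and what it does not

`build_scaffold()` constructs a compact Cα-only receptor (default 40
residues on a helical arc, one atom per residue) with two reference
conformations differing *only* in the five marker atoms: active at
17.0 Å / 55°, inactive at 21.0 Å / 35°. These bracket the 19.0 Å / 45°
thresholds with margins of 2 Å and 10°. A pseudo-ligand with stated
charges and LJ parameters sits in a pocket — by default one +1 e atom
exactly 10 Å from a −1 e pocket Cα with every other atom neutral, so the
planted interaction energy is a single closed-form pair term
(−138.935458 kJ mol⁻¹ Coulomb plus one LJ term).

`generate_ensemble()` draws each frame's state i.i.d.
Bernoulli($f_\mathrm{active}$) and adds isotropic Gaussian noise per
coordinate (default σ = 0.10 Å, scalar or per-atom). Construction fails
unless both marker margins exceed 5× the noise-induced marker standard
deviation (≈ σ√2 for the distance; ≈ σ√2/arm-length for the angle), so
planted states are recovered essentially without mislabels — the Gaussian
tail beyond 5σ is below 10⁻⁶. All randomness flows from one integer
seed; the same seed reproduces the trajectory byte-identically.

Deliberate non-realism, and hence the limits of what green tests show:
frames are temporally uncorrelated (no kinetics or mixing time — no
acceptance metric here depends on autocorrelation), there is no solvent,
membrane, or counter-ion environment, the two-state geometry is exact
rather than a free-energy basin, and noise is isotropic and homoscedastic
within an atom. Passing tests demonstrate that each analysis recovers
known ground truth under its own model assumptions; they cannot certify
force-field or sampling quality of any real trajectory.

## Numerical and design notes

* Atom indices are 1-based everywhere (R's array convention internally
  and the PDB serial convention for users); residue identity is
  (chain, author residue number).
* Units: coordinates and distances in Å; LJ σ in nm (force-field
  convention), converted once inside the pair evaluator; ε and energies
  in kJ mol⁻¹; masses in amu; charges in e; times in ps.
* The discard window drops frames with time < `discard_before` (the
  convention for excluding initial equilibration, e.g. the first 50 ns of
  a production run); the stride subsamples deterministically from the
  first retained frame.
* `acos` arguments are clamped to [−1, 1] before angle evaluation; a
  zero-length marker arm raises a degenerate-geometry error rather than
  returning NaN; r = 0 in the pair evaluator raises a singularity error.
* Result writers emit deterministic column orders and 6-significant-digit
  numbers with a provenance block (content hash, seed, discard window),
  so identical analyses yield byte-identical files.
* Pure vectorised R (outer-product distance matrices, `rowsum`
  aggregation) is used throughout; at the ensemble sizes this package
  targets (10²-10⁵ frames of 10¹-10³ analysed atoms) dense linear algebra
  is fast enough that compiled code would add maintenance cost without
  analytical benefit.

## Verification sizes

The shipped test suite and the acceptance script regenerate everything
they check: 50 random systems of 10-300 atoms against a naive double-loop
energy oracle (1e-9 relative), decomposition conservation on every
system, closed-form pair checks, planted-fraction recovery at
n = 10⁴ frames against the 99% binomial CI, the RMSF closed form
σ√3 within 2% at n = 5×10⁴ frames with a rigid alignment subset,
Kabsch recovery against 10⁴ random rotations, a 50-frame contact-census
oracle, rigid-motion and re-wrapping invariance of every reported
statistic, and byte-identical re-execution of the three-replicate
pipeline. These sizes were chosen so each statistical tolerance sits
several standard errors away from its pass boundary.

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* No Ewald/PME term: totals are short-range pairwise by design (above).
* The PDB reader is strict fixed-column (PDB 3.3); malformed but
  human-readable files are rejected with a line number rather than
  repaired.
* No hydrogen-bond or cation-π detectors; contacts are purely metric.
* The synthetic generator is a verification instrument, not a sampler of
  physical ensembles.
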