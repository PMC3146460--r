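---
title: "Methods: single-trajectory MM-GBSA energetics and dihedral entropy for phosphopeptide recognition"
author: "phosdelta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosdelta)
```

# Scope and model

`phosdelta` post-processes molecular-dynamics trajectories of
domain–phosphopeptide complexes.  It does not run dynamics: topologies and
coordinate ensembles are inputs (AMBER prmtop subset, the package's
plain-text parameter table, DCD, multi-model PDB), and the synthetic
generator provides desk-scale stand-ins with known ground truth.

## Single-trajectory interaction energy

The binding interaction energy is the ensemble average of
complex-minus-parts, with all three terms evaluated on the *same*
coordinates.  Under that contract every intramolecular (bond, angle,
dihedral) contribution cancels identically, so the molecular-mechanics part
reduces to intermolecular pair sums and the solvation terms to differences
of per-group solvation energies:

$$\Delta E_{bind} = \langle \Delta U_{vdw} + \Delta U_{Coul}
  + \Delta W_{polar} + \Delta W_{np} \rangle .$$

The package asserts this cancellation structurally rather than numerically:
`interactionEnergyFrame()` never evaluates bonded terms at all, and the
tests verify the pair sums against independent double-loop oracles.
Entropic changes upon binding are *not* part of this estimate; the dihedral
entropy module quantifies local flexibility changes separately.

Derived columns satisfy
$E_{ele} = U_{Coul} + W_{polar}$,
$E_{tot} = E_{ele} + U_{vdw} + W_{np}$,
$E_{tot-np} = E_{tot} - W_{np}$;
these identities are validity conditions of the `EnergyComponents` class
(to $10^{-6}$) and are re-checked at the 0.01 kcal/mol rounding granularity
on every table the reporter emits.

## Energy kernels and their tunables

| parameter | default | unit | rationale |
|---|---|---|---|
| non-bonded cutoff | 40 | Å | hard truncation for Coulomb/LJ; no switching function |
| Coulomb constant | 332.0636 | kcal·Å/(mol·e²) | standard MM convention |
| GB dielectrics | 1 / 80 | — | protein interior / water |
| GB radius offset | 0.09 | Å | the `igb = 1` intrinsic-radius convention |
| SASA probe | 1.4 | Å | water probe |
| SASA sphere points | 960 | — | Shrake–Rupley sampling; ~1 % area error |
| non-polar γ, β | 0.00542, 0.92 | kcal/(mol·Å²), kcal/mol | PB-style preset; `npPreset = "gb"` gives 0.005, 0 |

The GB model is the Hawkins–Cramer–Truhlar pairwise-descreening form:
effective radii from closed-form descreening integrals over all group
members (no cutoff — the groups this package evaluates are small), then the
canonical pair function
$f_{GB} = \sqrt{r^2 + R_i R_j e^{-r^2/4R_iR_j}}$ with self terms.  The
closed-form integral is cross-checked in the tests against a numerical
quadrature of the same descreening volume integral, including the
overlapping and engulfed regimes.  Both Amber non-polar conventions are
provided because published analyses rarely print which was used; the choice
is recorded in all output metadata.  A Poisson–Boltzmann solver is *not*
implemented: `polarModel = "PB"` is an adapter slot
(`energyConfig(pbSolver = ...)`) so an external solver can be swapped in
with the same complex-minus-parts contract.

A physical note reflected in the tests: the GB energy of two separated
charged groups approaches the sum of Born self terms only as $1/r$ — at
100 Å a pair of half-charges still shares ~0.8 kcal/mol of screened
interaction.  The separability test therefore uses a very large gap.

## Global vs local (phosphate-shell) calculations

The local calculation restricts both sides to the neighbourhood that
actually discriminates pThr from pSer: receptor residues with any atom
within a cutoff of any phosphate atom (P, O1P, O2P, O3P, OG/OG1) of the
phosphoresidue, against the phosphoresidue ± one flanking neighbour.  The
conventional shell range is 5–7 Å; the default is the 6 Å midpoint.
Residue-level (any-atom) selection is used because published residue lists
are residue-, not atom-, granular.  The shell is selected once, on a
reference frame (by default the pooled-ensemble frame minimising mean RMSD
to all others, `centralFrame()`), and reused for the mutant so both sides
are compared over the same residue set.  GB radii and SASA are evaluated on
the reduced subsystem; `fullComplexRadii = TRUE` descreens radii within the
whole complex instead, for sensitivity checks.  The local polar model is GB.

Uncertainty is always the standard error across independent seeds, never
across frames: frames within a short trajectory are autocorrelated, seeds
are the independent unit.

## In-silico pThr ↔ pSer mutation

Mutation is template editing, mirroring the manual add/delete-methyl
protocol of end-point studies: pThr → pSer removes CG2 and its three
hydrogens and renames the residue (TPO → SEP, OG1 → OG by default; the
naming map is configurable because PDB and Amber disagree on
phosphoresidue names).  Charges for the product residue always come from a
caller-supplied parameter block — they are never re-derived — and omitting
the block is an error.  pSer → pThr rebuilds the methyl at ideal geometry:
C–C 1.525 Å, tetrahedral angles, the branch chosen anti to the O–P bond,
hydrogens staggered.  No minimisation follows (MD engines are out of
scope); a rebuilt methyl within 1 Å of a non-bonded atom triggers a
warning, not an error, and `validateMutation()` reports atom/bond deltas
and flags any bond in the mutated residue deviating more than 0.1 Å from
canonical lengths.  Because the mutant is not relaxed, mutant *ensembles*
come from the synthetic sampler (or from the caller's own dynamics), not
from re-using mutated frames as if equilibrated — except in the
methyl-deletion benchmark, where sharing frames is the point.

## Dihedral entropy

Each dihedral's entropy is $S = -R\sum_b p_b \ln p_b$ over an equal-width
periodic histogram of $[-180°, 180°)$, bins left-closed/right-open, with
$0\ln 0 := 0$ and $R = 1.9872\times10^{-3}$ kcal/(mol·K); results are
reported as $T\,S$ at 300 K by default.  The bin width is 10° (36 bins):
the upstream analyses this mirrors do not print their binning, so the value
is a package choice, recorded in every output, and coarse enough that
$10^5$ samples recover quadrature ground truth within 0.02 kcal/mol (a
property the acceptance checks enforce).  Seeds are pooled before
histogramming; per-seed entropies are attached as dispersion.  The
mutant-minus-wild decomposition matches dihedrals by residue and torsion
name, sums $T\Delta S$ within the classes φ, ψ, ω and sidechain (all χ),
and reports dihedrals existing on one side only — the pThr methyl torsion —
separately, excluded from the total, since a difference requires a matched
pair.  Dihedral coupling is deliberately ignored (independent-dihedral
approximation).

Rotamer analysis smooths the 1° histogram with a circular von Mises kernel
(bandwidth 15°, κ = (180/πh)²), takes maximal arcs between density valleys
as states, merges states below a 1 % population floor into their stronger
neighbour, and reports per-state populations (summing to 1), circular means
and circular standard deviations — the number of occupied wells and their
widths being the conformational and vibrational readings of dihedral
entropy.  No separate conformational/vibrational energy split is emitted;
the split is qualitative.

Angle conventions throughout: IUPAC torsion sign (checked against an
independent implementation), range $[-180°, 180°)$ with +180 wrapping to
−180.

## The synthetic generator: what it emulates, what it does not

`makeToyComplex()` builds the geometry that matters for phosphoresidue
recognition and nothing else: a 3-residue peptide (Ala–pThr/pSer–Ala) at
ideal internal coordinates, a pocket of single-atom pseudo-residues with
two Arg-like +1 charges at 2.9 Å of two phosphate oxygens (the
hydrogen-bonding readout every phospho site shares), a ring of nonpolar
atoms 3.6–4.2 Å from the methyl site in the enclosed-cavity variant
(moved beyond 8.5 Å for open-loop), and a clash-rejected filler shell
6.5–9.5 Å from the phosphorus that gives shell selections distance
structure.  The reference peptide torsions were chosen once to maximise the
smallest non-bonded distance (2.5 Å) so torsion resampling rarely clashes.
The wild-type phospho χ² sits at 150°.

`sampleEnsemble()` emulates the study design — five independent seeds,
frames every 1 ps, 1000 frames (1 ns) per seed by default — by holding the
pocket rigid and resampling every modelled peptide dihedral per frame from
a von Mises mixture, rejecting frames with any non-bonded pair (1-2 and 1-3
excluded; only pairs involving a moving atom are checked, the rigid pocket
being validated at build time) closer than 2.0 Å.  Default concentrations:
κ = 400 backbone (~3° circular sd), κ = 50 sidechain (~8°).  Per-seed
streams derive deterministically from (master seed, seed index); everything
is bit-reproducible.

What the generator does **not** emulate: explicit solvent, forces or
kinetics (frames are i.i.d. draws, not dynamics), backbone conformational
transitions, receptor flexibility, or real force-field charges (the
parameter blocks are a self-contained synthetic set with a deliberately
neutral methyl).  Passing tests therefore demonstrate that the *estimators*
are correct and that the *designed* contrasts are recovered — not that any
particular real system would show those numbers.

`methylDeletionBenchmark()` is the ground-truth contrast: the mutant is the
wild type minus the neutral methyl pseudo-group on identical frames, so
ΔΔU_Coul is exactly zero by construction, ΔΔU_vdw > 0 when a cavity was
built to enclose the methyl, and |ΔΔU_vdw| is strictly smaller for the
open-loop variant.  A separately resampled mutant ensemble widens the
phospho sidechain model (width × 3, mean shifted 47° by default) for the
entropy contrast: total matched-dihedral TΔS positive and
sidechain-dominated.

## Numerical and design choices

- **Indices are 1-based everywhere** (R convention, matching PDB residue
  numbering in reports); atom groups are named index sets on the topology.
- **Degenerate inputs**: empty selections, overlapping receptor/ligand
  groups, missing phosphate atoms, empty shells, unmatched dihedral sets
  and truncated trajectory files are all errors with specific messages;
  truncation errors name the last complete frame.
- **Determinism**: the toy pipeline writes no timestamps; reruns with the
  same configuration are bit-identical, which the tests assert on the JSON
  bundle.
- **Problem sizes**: the shipped tests and the acceptance script run the
  benchmark at 5 seeds × 100–200 frames with 240 SASA sphere points —
  sizes at which the sign/rank contrasts are stable across seeds while the
  whole suite stays desk-scale.  The generator defaults (1000 frames,
  960 points) reflect the emulated study design and full-precision surface
  areas.
- **GB radii defaults**: when a prmtop lacks RADII/SCREEN, an mbondi-style
  element table fills them (H 1.2, C 1.7, N 1.55, O 1.5, P 1.85 Å) with a
  logged message; published analyses rarely state their radii set, so this
  is config, not silent convention.
- **Waters and counter-ions** (WAT/HOH/Na+/Cl−) are stripped on load —
  the post-processing is implicit-solvent.

## Known limitations

No Poisson–Boltzmann solver, no periodic boundary conditions or Ewald
electrostatics, no bonded-energy evaluation (cancelled by construction),
no general mutagenesis beyond pThr↔pSer, no minimiser behind the mutation,
no mutual-information corrections to the entropy, and no claim that the
synthetic ensembles are physically faithful dynamics.  Interpretation of
real systems should rest on real trajectories fed through the same
estimators.
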