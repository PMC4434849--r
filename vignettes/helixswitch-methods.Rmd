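---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixswitch)
library(dplyr)
```

`helixswitch` implements the quantitative analyses used in structural studies
of short membrane-proximal peptides and transmembrane (TM) helix pairs — the
motivating system being the 26-residue cytosolic tail of the tumour marker
Trop2 (residues 298–323, phosphorylatable at Ser303) and its 23-residue TM
helix (residues 275–297). This vignette is the package's own account of the
models behind each module, the tunable parameters and their defaults, what
the synthetic generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## Peptide sequence arithmetic

Sequences are value objects (`peptide_seq()`) carrying author numbering, a
set of phosphorylated positions (flags on S/T/Y, not separate letters, so
sequence-level operations are phosphorylation-agnostic unless stated) and
terminal blocking-group flags.

* `charge_census()` counts basic = {R, K} and acidic = {D, E}. Histidine is
  counted as *other*: at pH 7.4 it is mostly neutral, and the motivating
  sequence contains no histidine, so either choice reproduces the printed
  census (9 basic, 4 acidic over 26 residues).
* `span_fraction()` rounds **half-up** to integer percent, because the
  nine-residue span over the 26-mer (9/26 = 34.6%) is conventionally quoted
  as 35%.
* `net_charge()` uses a phosphate charge of −2 by default (the dominant
  protonation state at pH 7.4; −1 is accepted).

```{r census}
charge_census(trop2_ic())
span_fraction(trop2_ic(), 310, 318)
longest_homopolymer(trop2_tm(), "V")
```

## Circular dichroism

Raw spectra are millidegree signals on a strictly monotone wavelength grid.
The processing chain is blank subtraction → scan averaging → conversion to
mean residue ellipticity (MRE),

$$[\theta](\lambda) = \frac{\theta_\mathrm{raw}(\lambda)}
  {10 \cdot c(\mathrm{M}) \cdot N \cdot l(\mathrm{cm})}
  \quad [\deg\,\mathrm{cm^2\,dmol^{-1}}],$$

with the concentration metadata stored in mM and converted internally. This
is the standard per-residue molar normalisation and the only one consistent
with concentration in mM, a residue count and a path length in cm together
with reference values of magnitude $10^4$.

Fractional helicity is the classic two-state estimator at 222 nm,

$$f_H = \frac{[\theta]_{obs} - [\theta]_{coil}}
             {[\theta]_{helix} - [\theta]_{coil}},$$

with $[\theta]_{coil} = 640$ and $[\theta]_{helix} = -42{,}500$
deg cm² dmol⁻¹. Out-of-range estimates are clamped to [0, 1] and flagged
rather than raised as errors, because real baselines can overshoot the
reference values; floating-point noise at the endpoints (|excess| < 1e−9)
is not flagged. No multi-component deconvolution is attempted — the
two-state 222 nm estimator is the model.

Minima are reported on the MRE spectrum with a sliding strict-minimum
window, default 5 nm, at the nearest grid point. The 198 nm minimum is the
random-coil signature; 208 plus 222 nm signal an α-helix.

```{r cd}
g <- generate_cd_spectrum(0.29, noise_mdeg = 0)
mre <- to_mean_residue_ellipticity(subtract_blank(g$sample, g$blank))
fractional_helicity(mre)
report_minima(mre)
```

## NMR-ensemble statistics

Ensembles are flat atom tables (one row per atom per model) with an enforced
shared roster. Multi-model PDB files are read via **bio3d** (insertion codes
rejected, first alternate location kept) and written by a small fixed-width
writer with MODEL/ENDMDL blocks.

* **Superposition** is the closed-form Kabsch/SVD solution, with the proper
  rotation enforced. `rmsd_to_mean()` follows the usual bundle-precision
  procedure: superpose all models on model 1 over the selection, form the
  coordinate-wise mean, re-superpose each model on the mean, report the mean
  ± sd of per-model RMSDs. One round of mean refinement is used; on test
  ensembles a second iteration changes the result by far less than 1e−6 Å.
* **Secondary structure** is assigned from backbone dihedrals with windows
  α: φ = −57 ± 40°, ψ = −47 ± 40° (minimum run 4) and 3₁₀: φ = −49 ± 30°,
  ψ = −26 ± 30° (minimum run 3), α taking precedence. This deterministic
  assigner is not a reimplementation of STRIDE: it has no hydrogen-bond
  energy term, but it reproduces span-level statements exactly on built
  ground truth, which is what the tests require.
* **Ramachandran regions** use a fixed four-class 10°-grid map built in code
  from basin rectangles, with the generous class defined as the additional
  regions dilated by 20° and separate, more permissive maps for glycine and
  a φ-restricted map for proline (pre-proline is not special-cased). The
  classes are nested by construction and percentages over any selection sum
  to 100. The map is the package's own; it follows the usual four-class
  scheme but is not byte-identical to any published program's grid, so
  percentages on real ensembles are comparable only qualitatively.
* **Salt bridges**: a bridge exists in a model when any acidic side-chain
  oxygen (Glu OE1/OE2, Asp OD1/OD2, phosphoserine O1P/O2P/O3P) lies within
  the cutoff (default 4.0 Å) of any basic side-chain nitrogen (Arg
  NH1/NH2/NE, Lys NZ). The report is the per-pair ensemble frequency, sorted
  descending; "most frequent" should be read with ties.
* **Hydrophobic clusters** are connected components (size ≥ 3) of a residue
  graph with edges at side-chain heavy-atom distance ≤ 5 Å. Sequence
  neighbours (|i−j| < 2) are excluded — adjacent side chains are trivially
  close and are not evidence of packing. The admitted residue set defaults
  to A, V, L, I, M, F, W, Y, P **plus S** and is configurable, because
  whether a serine belongs in a small hydrophobic cluster is usage, not
  physics.
* **ω classification**: |ω| ≥ 150° is *trans*, |ω| ≤ 30° *cis*, otherwise
  *twisted*. Only geometric ω is computed (no chemical-shift inference).
* **NOE restraint classes**: intra |i−j| = 0, sequential 1, medium 2–4,
  long ≥ 5. The |i−j| = 5 case is assigned to long-range, the standard NMR
  convention.
* **Violations**: a distance restraint is violated when the model distance
  exceeds the bound plus tolerance (default 0.2 Å; the boundary itself is
  compliant); torsion bounds (default tolerance 5°) are compared circularly
  so windows may straddle ±180°. Restraints whose atoms cannot be resolved
  are skipped, warned about and counted.
* **Chemical shift perturbations**:
  $\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.14\,\Delta\delta_N)^2}$, the
  common amide-weighted combination; unmatched residues are reported as
  missing rather than dropped.

## Two-helix trajectory geometry

Trajectories are bead tables (`frame`, `helix`, `resno`, `role`, xyz) with
an orthorhombic box and a flagged membrane normal (default z).

* **Axis fitting** computes 4-residue sliding-window centroids before the
  principal-component line fit; the windowing suppresses the helical wobble
  of individual beads (set `window = 1` for a plain PCA). The direction is
  oriented N→C. With 1 Å isotropic bead noise on a 23-residue helix the
  fitted direction is typically within ~1.6° of truth (mean over seeds),
  which is what makes median-angle recovery at the 3° level possible.
* **Interhelical distance** is the centroid distance after projecting out
  the membrane normal. The projection makes the 50 Å initial construction
  exact and removes vertical drift; the paper-style time course is therefore
  a purely lateral quantity.
* **Crossing angle** is the torsion of the two axis directions about their
  line of closest approach, folded to (−90°, 90°], with **negative =
  right-handed packing** — the usual convention for TM pairs. Exactly
  parallel axes return 0. Reflection of the coordinates flips the sign and
  preserves the magnitude, which the tests use as the chirality anchor.
* **Encounter / dimers**: the encounter is the first frame with minimum
  inter-helix bead distance ≤ cutoff (default 6 Å, the CG bead scale);
  dimer intervals are maximal contact runs of at least 10 frames, tolerating
  single-frame gaps. Neither value is stated in the motivating study; both
  are explicit parameters.
* **Angle distributions** are summarised over dimer frames only: median,
  5°-bin histogram, Gaussian smoothing over 3 bins, and a mode count of
  smoothed local maxima above 10% of the global maximum.
* **Orientation symmetry**: a frame is symmetric when the two directions of
  the motif contact profile (each valine to the opposing motif centre) agree
  within 2 Å at every position.

```{r tm}
sim <- simulate_rigid_dimerization(n_frames = 150, encounter_frame = 40,
                                   target_angle = -27, seed = 1)
tl <- detect_encounter_and_dimers(sim$trajectory)
glance(tl)
glance(angle_distribution_summary(tl))
```

## Synthetic generators: what they emulate, and what they do not

The generators stand in for the spectrometer, the NMR structure pipeline and
the coarse-grained MD engine. They define the study conditions used
throughout the tests and the acceptance script:

* `build_ideal_peptide()` builds N/CA/C/O backbones with ideal bond geometry
  from a φ/ψ plan (coil = (−120°, 120°) outside planned spans; measured
  dihedrals echo the plan to < 0.5°), one side-chain interaction centre per
  residue along CA→CB at a residue-specific radius, and charged-group
  pseudo-atoms for R/K/D/E/pS. Full rotamers are deliberately out of scope:
  the contact analyses tested here need interaction centres, not atoms.
* `jitter_ensemble()` applies isotropic Gaussian noise (model 1 stays
  unperturbed). For σ = 0.5 Å and k atoms the expected RMSD-to-mean is
  ≈ σ√3·√((k−1)/k), the closed form the tests check to within 10%.
* `generate_cd_spectrum()` mixes Gaussian-shaped coil/helix bases calibrated
  so that the coil basis is exactly 640 at 222 nm with its minimum at
  198 nm and the helix basis is exactly −42,500 at 222 nm with minima at
  208 and 222 nm. Only those calibration points are contractual; real CD
  band shapes are not Gaussian, so nothing away from the calibration points
  should be compared to experiment.
* `generate_restraints()` converts true model distances within a cutoff into
  upper bounds (distance + slack), optionally meeting exact per-class
  quotas, e.g. the 89/36/14/0 census of the non-phosphorylated tail. Slack
  ≥ 0 guarantees the source model satisfies its own restraints.
* `simulate_rigid_dimerization()` is kinematic, not dynamic: no forces, no
  lipids, no solvent. It reproduces the *analyzable phenomenology* —
  lateral diffusion, a programmed encounter frame, a persistent dimer with
  an exact crossing angle (the docked pair is tilted about the
  closest-approach line by half the target angle each, the second helix
  being the C2 image of the first), and scheduled axial rotations that
  create asymmetric episodes. A pre-encounter minimum-separation guard
  (18 Å) keeps the programmed encounter frame exact. Passing tests on this
  surrogate demonstrates the correctness of the *analyses*; it says nothing
  about the thermodynamics of real helix dimerization.

Every generator is deterministic under a fixed seed, and
`write_ground_truth()` emits a JSON sidecar of the programmed truth.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run at deliberately desk-scale
sizes: 20-model ensembles (~180 atoms/model), 80-point CD grids, and
500-frame trajectories (two 23-residue helices, ~90 beads/frame) — large
enough for the stochastic checks (median recovery within 1° noiseless / 3°
at σ = 1 Å; jitter RMSD within 10% of the closed form) while keeping a full
run in minutes.

Degenerate inputs are first-class: fewer than 3 non-collinear atoms refuse
to superpose; fewer than 7 backbone beads refuse an axis fit; exactly
parallel axes return a crossing angle of 0; a trajectory with no contact
yields an encounter of `NA` and an empty-summary flag rather than an error;
empty restraint classes count as 0 and the partition always sums to the
total.

## Known limitations

* The dihedral-window secondary-structure assigner and the in-code
  Ramachandran map reproduce span-level and class-level behaviour on built
  ground truth; neither is a drop-in replacement for STRIDE or PROCHECK on
  experimental ensembles.
* Side chains are single interaction centres; salt-bridge and cluster
  geometry on real structures (with full side-chain atoms) will differ
  quantitatively from the synthetic constructions.
* The rigid-body surrogate cannot, by design, say anything about encounter
  kinetics or dimer stability; only the geometry extractors are validated.
* Minimum-image handling is limited to the stated orthorhombic box; the
  bundled generators never wrap coordinates.
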