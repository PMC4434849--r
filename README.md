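# helixswitch

Quantitative structural analyses for short membrane-proximal peptides and
transmembrane (TM) helix pairs, motivated by the cytosolic tail of the tumour
marker protein Trop2 — a 26-residue tail (residues 298–323) whose
conformation switches on Ser303 phosphorylation — and its 23-residue TM helix
(residues 275–297), which dimerizes through a five-valine
(Val282–Val286) interface.

The package is for structural biologists who need the *numbers* behind such a
study, reproducibly and at desk scale:

* **Sequence arithmetic** — charge census (basic {R, K} vs acidic {D, E}),
  helical span fractions of the whole peptide, homopolymer motif discovery,
  formal net charge with phosphate states.
* **Circular dichroism** — blank subtraction, scan averaging, conversion to
  mean residue ellipticity `[θ] = θ_mdeg / (10 · c(M) · N · l(cm))`, the
  two-state fractional helicity at 222 nm
  `f_H = ([θ]_obs − [θ]_coil) / ([θ]_helix − [θ]_coil)` with
  `[θ]_coil = 640`, `[θ]_helix = −42,500 deg cm² dmol⁻¹`, and spectral
  minima reporting (198 nm coil vs 208/222 nm helix signatures).
* **NMR-ensemble statistics** — Kabsch superposition, RMSD to the mean
  coordinates, dihedral-window secondary structure (α / 3₁₀ / coil),
  Ramachandran four-class regions, salt-bridge detection with ensemble
  frequencies, hydrophobic clusters, ω (cis/trans/twisted) classification,
  CYANA-style `.upl`/`.aco` restraint I/O, NOE classification by |i−j| and
  violation checks, and combined ¹H/¹⁵N chemical shift perturbations
  `Δδ = √(Δδ_H² + (0.14·Δδ_N)²)`.
* **TM-dimer trajectory geometry** — helix-axis fits, membrane-plane
  interhelical distance, the signed crossing angle Ω about the line of
  closest approach (negative = right-handed packing), encounter and dimer
  detection, five-valine interface contact profiles, symmetric/asymmetric
  orientation calls and angle-distribution summaries (median, mode count).
* **Synthetic generators** — ideal peptides from φ/ψ plans, jittered
  ensembles, engineered salt bridges, calibrated two-state CD spectra,
  quota-exact restraint lists, and a kinematic rigid-body dimerization
  surrogate with programmed encounter frame, crossing angle and
  axial-rotation episodes — every generator seeded and shipping its ground
  truth.

Everything takes and returns tibbles, pipes cleanly, and has
`autoplot()` / `tidy()` / `glance()` methods where a result warrants them.

## Worked example

```r
library(helixswitch)

# The cytosolic tail: nine basic and four acidic residues over 26
charge_census(trop2_ic())
#> # A tibble: 1 × 4
#>   basic acidic other length
#>   <int>  <int> <int>  <int>
#> 1     9      4    13     26

span_fraction(trop2_ic(), 310, 318)   # the predicted helix = 35% of the tail
#> [1] 35
longest_homopolymer(trop2_tm(), "V")  # the VVVVV motif, Val282-Val286
#> # A tibble: 1 × 3
#>   first_label last_label run_length
#>         <int>      <int>      <int>
#> 1         282        286          5

# CD: a synthetic spectrum at 29% helicity, processed like a measurement
g   <- generate_cd_spectrum(0.29, noise_mdeg = 0)
mre <- to_mean_residue_ellipticity(subtract_blank(g$sample, g$blank))
fractional_helicity(mre)
#> # A tibble: 1 × 4
#>   f_helix f_helix_raw clamped theta_obs
#>     <dbl>       <dbl> <lgl>       <dbl>
#> 1    0.29        0.29 FALSE     -11871.

# A dimerization trajectory: encounter at frame 60, right-handed -27° dimer
sim <- simulate_rigid_dimerization(n_frames = 300, encounter_frame = 60,
                                   target_angle = -27, noise_sigma = 1,
                                   seed = 42)
tl <- detect_encounter_and_dimers(sim$trajectory)
glance(tl)
#> # A tibble: 1 × 5
#>   n_frames encounter_frame n_intervals n_dimer_frames median_angle
#>      <int>           <int>       <int>          <int>        <dbl>
#> 1      300              60           1            241        -27.1
glance(angle_distribution_summary(tl))
#> # A tibble: 1 × 4
#>   median n_modes     n empty
#>    <dbl>   <int> <int> <lgl>
#> 1  -27.1       1   241 FALSE
```

The fractional helicity recovers the generator's 29% exactly (the 222 nm
point of the synthetic bases is calibrated to the two-state model); the
timeline recovers the programmed encounter frame and the −27° median
crossing angle — unimodal, with the negative sign denoting right-handed
packing — from a trajectory carrying 1 Å bead noise.

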