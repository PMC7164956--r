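# trxmap

Analysis chain for time-resolved (pump–probe) protein crystallography, built
for the situation where a light pulse converts a small fraction *p* of the
molecules in a crystal to a photoproduct and only Bragg amplitudes are
measured. It is aimed at structural biologists and methods developers who
want the full difference-map / extrapolation machinery as inspectable,
testable R code, exercised end-to-end on synthetic crystals with known
ground truth rather than on downloads.

## What it computes

* **Weighted isomorphous difference maps.** Per reflection,
  ΔFo = w·(|Fo_light| − |Fo_dark|) with phases from the dark model and the
  q-weight w = [1 + σ²(ΔF)/⟨σ²(ΔF)⟩ + |ΔF|²/⟨|ΔF|²⟩]⁻¹. The Fourier
  synthesis Δρ(x) = (1/V)·Σ ΔFo·exp(iφ_dark)·exp(−2πi h·x) shows paired ∓
  features where atoms move, at half the absolute scale (difference-Fourier
  approximation). Amplitude sets are first brought to a common scale with
  k·exp(−B_rel s²) fits (18 Å low-resolution cutoff).
* **Extrapolated structure factors and population.**
  |Fe| = |Fc_dark| + α·ΔFo; α is scanned against the appearance of
  physically unrealistic negative density in the chromophore pocket, and
  converted to a population as population(%) = 2·(100/α) — α = 25 ↔ 8%.
* **Map statistics.** σ-level normalisation, signed peak detection with
  nearest-atom attribution, difference-difference maps (observed extremes
  affinely pinned to calculated), local Pearson correlation in 3.5/10 Å
  spheres.
* **Geometry.** IUPAC torsions (e.g. the chromophore D-ring twist
  C14-C15-C16-ND), Kabsch superposition RMSD, mean radial displacement of a
  residue stretch relative to a reference atom.
* **Photon budget.** E = hc/λ, photon fluence, absorption cross-section
  σ = ln(10)·ε·1000/N_A, photons per chromophore with a carrier attenuation
  factor.
* **Synthetic ground truth.** A 20-atom P1 toy crystal whose photoproduct
  is a known dihedral twist plus a water displacement, observed as coherent
  two-state amplitude mixtures with optional Gaussian noise — every pipeline
  stage is testable against the generator.

Structure factors are computed by direct summation with embedded
Cromer–Mann form factors (H, C, N, O, P, S, Fe); maps by FFT with the direct
double-loop sum as the test oracle. File formats: fixed-column PDB subset,
tab-separated reflection tables, CCP4/MRC (mode 2) maps.

## Worked example

The numbered scripts under `analysis/` run the whole study on the synthetic
crystal: `01_simulate.R` (fixture), `02_diffmap.R` (difference map + peak
table), `03_extrapolate.R` (α scan and population recovery), `04_geometry.R`
(torsion/RMSD/displacements), `05_photon_budget.R`. For example:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/03_extrapolate.R
```

prints (abridged):

```
recovery report
  true population: 8.0%
  selected alpha: 15 (oracle 25)
  population: 13.33% from selected alpha, 8.00% from oracle alpha
  Fe-map PCC vs pure photoproduct, r3.5A: 0.972
  Fe-map PCC vs pure photoproduct, r10.0A: 0.994
```

The negative-density scan picks α = 15 (its calibration-limited best guess),
the amplitude-space oracle — computable because the fixture's pure
photoproduct amplitudes are known — lands at α = 25, and the field's
conversion 2·(100/α) then returns exactly the true 8% population. The
extrapolated map correlates with the pure photoproduct at 0.97+ inside the
perturbed region. `02_diffmap.R` reports the matching map signature: the
strongest negative feature (−28.8σ) on the vacated water site, with paired
± features flanking the twisted arm. And the photon budget
(`05_photon_budget.R`):

```
             quantity    value         units
        photon energy 3.10e-19             J
       photon fluence 5.48e+15  photons/mm^2
        cross-section 1.06e-14 mm^2/molecule
 photons per molecule 5.80e+01             -

Inside the scattering carrier (attenuation x100): 0.58 photons per chromophore
```

Interactively, the same chain is three calls:

```r
library(trxmap)
truth <- synthetic_truth(seed = 1)                       # known ground truth
dm <- run_diffmap(truth$dark_model, truth$fo_light,
                  truth$fo_dark, run_config())           # scale->weight->map->peaks
rec <- run_recovery(run_config())                        # alpha scan + oracle
```

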