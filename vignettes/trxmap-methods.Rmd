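---
title: "Difference maps, extrapolated structure factors and population recovery: methods"
author: "trxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference maps, extrapolated structure factors and population recovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In a pump-probe (time-resolved) crystallography experiment a small fraction
*p* of the molecules in each crystal is driven into a photoproduct state, and
the only measured quantity is the Bragg amplitude set |Fo_light| next to a
reference |Fo_dark|. Everything this package does flows from two classical
devices for making that partial-occupancy signal visible:

* the **isomorphous difference map**: synthesise
  w(|Fo_light| − |Fo_dark|) with phases borrowed from the refined dark model.
  To first order this map equals ½·p·(ρ_light − ρ_dark): paired negative and
  positive features mark where atoms left and arrived, at half the absolute
  density scale (the difference-Fourier approximation);
* **extrapolated structure factors**: |Fe| = |Fc_dark| + α·ΔFo amplify the
  photoproduct signal so an Fe map approximates a fully converted crystal.
  Because the difference map sits at half scale, the working α relates to the
  population as population(%) = 2·(100/α); α = 25 corresponds to 8%.

The package implements the full chain — structure factors, scaling,
q-weighting, Fourier synthesis, peak analysis, α scanning, map-comparison
statistics, geometry metrics and the photolysis photon budget — and validates
every stage on synthetic toy crystals with known ground truth.

# Structure factors and maps

Structure factors are computed by direct summation,
F(h) = Σ_j occ_j · f_j(s) · exp(−B_j s²) · exp(2πi h·x_j), with
s = sinθ/λ = 1/(2d) and four-Gaussian Cromer–Mann form factors embedded for
H, C, N, O, P, S and Fe. The Debye–Waller convention is exp(−B s²), i.e.
exp(−B/(4d²)). Direct summation is exact at toy scale and doubles as the
oracle for the FFT synthesis. P 21 21 21 models are expanded to P 1 before
summation; everything downstream is space-group agnostic.

Maps are synthesised as ρ(x) = (1/V) Σ_h F_h exp(−2πi h·x) over the
Friedel-completed set by placing coefficients (and their conjugate mates) on
the FFT grid. F(000) is always omitted, so maps have zero mean. The default
grid spacing is d_min/3 along each cell edge (conventional three-fold
oversampling; configurable through `grid_oversample`). σ-scaling divides by
the rms about the mean over the **whole unit-cell grid** — toy cells are P 1,
so there is no asymmetric-unit subtlety, but peak heights quoted in σ should
be read with that convention in mind.

Sphere masks (for local correlations and the α-scan) use the minimum-image
convention in fractional space, valid for any triclinic cell and necessary
because toy cells are small enough for features to sit near cell edges.

# Scaling and q-weighting

Observed sets are brought to a common absolute scale in two steps —
|Fo_dark| onto |Fc_dark|, then |Fo_light| onto the scaled |Fo_dark| — with an
isotropic model k·exp(−B_rel s²) fitted by least squares over the common
reflections, excluding everything at lower resolution than the 18 Å cutoff
(the cutoff also removes those reflections from map synthesis). The fit
profiles B_rel with a closed-form optimal k at each candidate B.

The per-reflection weight is the standard q-weight
w = [1 + σ²(ΔF)/⟨σ²(ΔF)⟩ + |ΔF|²/⟨|ΔF|²⟩]⁻¹, means over the working set.
Its purpose is robustness: reflections whose difference is large relative to
the ensemble — measurement outliers, but also the reflections where the
difference-Fourier linearisation fails worst — are down-weighted. On the
synthetic fixture this is visible directly: the weighted map reproduces the
peak ordering of the ground-truth density difference (deepest hole at the
vacated water), which the unweighted map narrowly scrambles.

Two boundary conventions matter and are deliberate:

* when every σ is zero **and** every ΔF is zero (a true null experiment) the
  weights are set to 1 — there is nothing to suppress, and the q-weight
  normalisation would be 0/0;
* with σ ≡ 0 but non-zero differences the formula degenerates to pure
  magnitude suppression. That is statistically baseless (no measurement
  error, hence no outliers), and it biases extrapolation: the large-|ΔF|
  reflections carry the signal, and crushing them makes the α that best
  reconstructs the photoproduct amplitudes (≈25 on the weighted fixture,
  where the mean weight ≈ 0.5–0.7) diverge from the α the negativity scan
  finds. The α-calibration checks therefore run scan and oracle on the same
  **unweighted** noiseless differences, while the map/peak stage keeps the
  weighted protocol. With realistic noise the σ-term dominates the weights,
  the two routes agree, and weighting is essential (an unweighted noisy scan
  can fail to find any admissible α).

# Peak analysis

Peaks are 26-neighbour local extrema of the σ-scaled map, both signs, with
|height| at or above the 3σ detection threshold. Greedy suppression removes
any peak within 2 Å of a stronger peak **of the same sign**; opposite signs
never suppress each other, because a paired −/+ feature a bond-length apart
is exactly what a moving atom produces and what per-feature tables report.
Peak positions are grid points (no interpolation; the tests allow one grid
step). Each peak is attributed to the nearest model atom within 2.5 Å,
minimum-image. All of these are configurable.

# The α scan and population estimation

For each candidate α (default grid 5..100 in steps of 5) the Fe set
|Fc_dark| + α·ΔFo (signed; negatives clamped to zero and counted) is
synthesised with dark phases and σ-scaled, and the fraction of voxels within
3.5 Å of the mask atoms falling below −1σ is recorded. The baseline is the
same fraction for the ΔF = 0 map over the **same index set** (the low-
resolution cutoff removes a few strong terms, so baseline and scan maps must
be syntheses over identical coefficients). The selected α is the largest
candidate whose negative fraction stays within 0.01 of the baseline. The
breakdown on the synthetic fixture is gradual rather than a sharp elbow, so
the selection is calibration-dependent at the level of one or two grid
steps; the report therefore always prints the selection next to the
amplitude-space oracle (the α minimising rms(|Fe(α)| − |F_light_pure|),
computable only when ground truth is known).

The population conversion population(%) = 2·(100/α) carries the factor 2 of
the half-scale difference-Fourier approximation. On the weighted fixture the
oracle lands at α = 25 and the conversion returns exactly the true 8%
population — the attenuation of the weighted differences and the half-scale
factor together are what the working conversion absorbs. Under plain
unweighted amplitude arithmetic the natural relation would be α ≈ 1/p
(12.5 for 8%); the package reports the field's conversion and uses the
generator oracle, never the conversion, for recovery tests.

# Map comparison

The difference-difference map rescales the observed map affinely so its
global extremes match the calculated map's extremes, then subtracts.
Local agreement is quantified by the Pearson correlation over spheres of
3.5 or 10 Å radius. For validating extrapolation, the Fe map is compared
with the pure photoproduct amplitudes synthesised **with the same dark
phases**: that isolates the quantity extrapolation controls. With the
photoproduct's own phases the 3.5 Å correlation on this fixture saturates
near 0.85, because the local rearrangement is complete and the dark-phase
synthesis splits moved density between old and new sites (the "ghost" of the
difference-Fourier approximation). That is a limitation of single-pass
extrapolated maps in general — real studies recover the remainder by
refining a model against Fe — and is documented rather than hidden.

# The synthetic generator

`make_toy_dark()` builds a 20-atom P 1 crystal in a 22 Å cube: a planar arm
C14–C15–C16–ND(+C17) with a dark torsion of 20°, an anchor triad of
nitrogens, a water oxygen 2.8 Å from the arm, and a scaffold ring. The
photoproduct applies a rotation about the C15–C16 bond (the realised torsion
change equals the requested twist exactly) plus a rigid water displacement.
Observations mix the two states **coherently**, Fo_light = |(1−p)·Fc_dark +
p·Fc_light|, because a crystal's unit cells average in amplitude, not in
intensity — this keeps the difference-Fourier treatment an approximation,
exactly as for real data. Multiplicative Gaussian noise (σ column =
noise_rel × amplitude) exercises the weighting. All randomness sits behind
one integer seed; coordinates carry a ≤0.1 Å seeded jitter so different
seeds give distinct but topologically identical crystals.

Two design points deserve emphasis:

* **Dilution.** In a real crystal the photoproduct perturbs a tiny fraction
  of the scattering matter. The analysis chain relies on that: any
  intensity-equalising scale step adds a small multiple of the dark density
  to the difference map, and that artifact stays negligible only while the
  moved atoms are a small fraction of Σf². A 20-atom model cannot reach
  protein-like dilution with light atoms, so the scaffold ring carries Fe
  and S atoms that stand in for the scattering weight of the unmoved bulk,
  bringing the moved fraction to ≈6%. With a light-atom scaffold (moved
  fraction ≈27%) the scale-induced fill-in is comparable to the signal and
  the map signature drowns — a useful negative control, not a usable
  fixture.
* **Study conditions.** The defaults (p = 0.08, 70° twist, 1.5 Å water
  shift, 5% noise where noise is used, d_min = 1.5 Å) are the conditions the
  tests and the analysis scripts run; they emulate a strong single-photon
  photoproduct at realistic population. What the toy does **not** emulate:
  bulk solvent, merging statistics and partiality, anisotropy, space-group
  symmetry in the maps, and radiation damage. Passing tests demonstrate the
  correctness of the analysis chain under the stated statistical model, not
  instrument-level fidelity.

# Geometry and photon budget

Torsions use the IUPAC sign convention (checked against an independent
reference implementation), superposition is the Kabsch SVD solution with a
proper-rotation correction, and radial displacements are reported relative
to a reference atom resolved in the dark model — the water moves at early
delay times, so the dark position is the stable anchor (configurable).

The photon budget is scalar arithmetic with CODATA constants embedded at six
significant digits: E = hc/λ; fluence/E photons per area; cross-section
σ = ln(10)·ε·1000/N_A (cm² per molecule, reported in mm²); photons per
molecule = fluence × σ / attenuation. The attenuation factor is always an
input — the ~100× loss in a scattering grease carrier is an estimate, not a
law.

# Problem sizes and determinism

The test suite and analysis scripts run the full fixture at d_min = 1.5 Å
(≈6600 reflections, 44³ grid) for the recovery checks and a d_min = 2 Å
variant (≈2800 reflections) for orchestration tests; the whole suite
completes in well under a minute on one core. Pipeline runs are
bit-reproducible: every artifact of a rerun on the same inputs is
byte-identical, and each run writes a manifest (configuration, its hash,
package version) sufficient to reproduce it.

# Known limitations

* Parity with experimentally derived per-feature σ heights is out of reach
  by construction (it needs the measured data); the package reproduces the
  *shape* of such tables on synthetic analogues.
* The exact q-weight variant used by any given study (shell-wise means,
  σ-cutoffs) varies; this implementation uses global means.
* The negativity criterion has no sharp breakdown on smooth synthetic data;
  selections should always be read next to the reported oracle and the
  negative-fraction curve.
* Single-conformer models only (altloc A), isotropic B, no anomalous
  scattering, no bulk-solvent correction.
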