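---
title: "Detecting a thermal folding intermediate from conformational ensembles: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting a thermal folding intermediate from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`thermint` implements the analysis layer used to decide whether
conformations sampled for a three-state thermal folder belong to its
partially unfolded intermediate: a state with a solid core and
liquid-like loops. This vignette explains the models, the tunable
parameters and their defaults, what the synthetic-data generators do and
do not emulate, and the numerical choices made where the design was
genuinely open. No empirical claim is made here beyond what the test
suite computes.

## Geometric descriptors

Superposition is the Kabsch algorithm (SVD of the cross-covariance,
determinant-corrected so the rotation is always proper). Wherever an
ensemble is aligned — B-factors, covariance analysis, clustering — the
alignment uses the ensemble's `align_mask`, intended to hold the
structurally conserved core: aligning on disordered regions would leak
loop motion into every atom's apparent fluctuation. For B-factors and
mean structures the frames are aligned to the iteratively refined
running mean (converged when the mean moves by less than 1e-6 Å);
for cross-ensemble comparisons both ensembles are aligned to one
common reference structure, because eigenvectors from differently
oriented frames are not comparable.

B-factors are reported in Å² via `B = (8π²/3)⟨|Δr|²⟩`. TM-score is
dimensionless with the standard normalisation
`d0 = 1.24(L−15)^{1/3} − 1.8`; both conventions are the field's,
even where source material labels such axes in Å. TM-score is a
maximisation over superpositions; we use fragment seeds with iterative
refinement plus a final quasi-Newton polish of the soft TM objective,
which matters for short chains where `d0` is small and the RMSD-optimal
and TM-optimal superpositions differ.

Solvent accessibility is Shrake–Rupley quadrature on a deterministic
golden-spiral point set (default 240 points/atom, ~2% accuracy on an
isolated sphere; the per-frame annotation loop uses 120 for speed).
Radii are Bondi; unknown elements are an error rather than a guess.
The Trp accessibility `SAS_Trp` sums side-chain atoms of all Trp
residues jointly — matching the use of a single summed window in the
annotation criteria — with a per-residue mode available. In one-bead
models the bead counts as the side chain.

Contacts default to heavy-atom minimum distance ≤ 5.5 Å with sequence
separation ≥ 2. Both knobs are exposed because φ-values inherit them
directly. The synthetic annotation world instead fixes 5.3 Å: the toy
helix geometry places i,i+2 beads at 5.447 Å and i,i+3 at 5.117 Å, so
5.5 Å would sit 0.05 Å from a whole shell of native pairs and thermal
jitter would make those contacts flicker, inflating per-frame φ-error
variance for reasons that have nothing to do with the loops under
study. 5.3 Å keeps every native contact ≥ 0.18 Å from the threshold.

## Essential dynamics

The covariance of the aligned 3N coordinate vector uses the population
(1/n) normalisation so that `trace(C) = (3/8π²)ΣB_i` holds exactly.
Diagonalisation gives the essential modes. Three metrics compare
subspaces:

- `γ = (1/n) Σ_{i,j≤n} (ν_i^A · ν_j^B)²` — the Hess similarity, 1 for
  identical n-dimensional subspaces, with expectation `n/3N` for
  independent random subspaces (a Monte-Carlo null is provided;
  we deliberately do not hard-code any significance threshold).
- `κ = 2γ_AB / (γ_A^self + γ_B^self)` — the self-similarities come from
  splitting each ensemble in two (halves by default, odd/even
  optional). The printed form of this normalisation was an open
  question; the arithmetic mean is the default because it reduces to 1
  for identical ensembles, and a geometric-mean variant is exposed.
- `Ov = √(Σ_{i≤n} (r·ν_i)²)` — overlap of the unit transition vector
  with the first n modes. The transition vector is the first principal
  component of a pooled meta-ensemble with equal snapshot counts from
  the two states (the larger ensemble is downsampled, seeded).

`n = 50` eigenvectors is the conventional common essential space for a
protein-sized system; an ensemble supporting fewer modes is an error,
never a silent truncation. The toy worlds used in tests have 3N = 180,
so tests use n of 8–12. Covariance is unweighted Cartesian (mass
weighting is a flag). One consequence the generators must respect:
rigid-body components of any planted deformation are removed by the
alignment, so `sample_gaussian_ensemble()` projects its planted modes
onto the internal-motion subspace before recording them as ground
truth.

## φ-values

`φ_i = N_i / N_i^nat`: the fraction of residue i's *native* contacts
present in a snapshot. New non-native contacts never count. Residues
with no native contacts have undefined φ (NA), not zero. The profile
error against experiment is the signed sum `Σ(φ_calc − φ_exp)` over
residues with experimental φ < 1, defined calculated φ, and outside an
explicit exclusion list (supplied as configuration — e.g. a helix whose
experimental determinations are unreliable — never hard-coded).
Positive totals mean too native-like. The annotation criterion uses the
absolute value of this signed sum ("absolute accumulated error"); the
sum of per-residue absolute differences is also reported, as the two
differ whenever deviations cancel. Contact presence in a snapshot uses
the native cutoff unchanged by default; a hysteresis factor (e.g.
×1.2) is exposed. Per-frame φ-errors are computed (the intermediate
filter needs them); ensemble means are linear averages of per-frame φ,
an identity the tests verify.

## SAXS

`debye_curve()` computes vacuum point-scatterer intensities,
`I(s) = ΣᵢΣⱼ fᵢfⱼ sinc(s·rᵢⱼ)`, with unit per-bead factors by default
and a configurable factor table. **Deliberately out of scope** are the
hydration-shell and excluded-volume terms of full predictors such as
CRYSOL: the pipeline's logic — χ-based ranking and thresholding of
conformations against a reference curve — depends on curve shape, not
absolute intensity realism, and the multiplicative scale is refit per
curve anyway. Absolute χ values from this module should therefore not
be compared against values computed with hydration-aware predictors.

Guinier analysis fits `ln I` against `s²`, iterating the admissible
range `s < 1.3/Rg` (the conventional limit factor, configurable) to
self-consistency, with a two-cycle guard that takes the smaller range.
A caveat the tests document: for a uniform sphere the Guinier estimate
carries an intrinsic +1.8% bias when data extend to the full
`s·Rg = 1.3` limit; within the true Guinier regime (`s·Rg ≲ 0.8`) the
estimate is within 1%.

χ fitting interpolates the calculated curve linearly onto the
experimental grid (restricted to the overlap; extrapolation is
forbidden), solves the optimal scale in closed form and reports
`χ = √(Σ((I_e − cI_c)/σ)²/N)`. When the experimental curve carries no
errors — the situation for curves produced by matrix decomposition — a
homogeneous 7% fractional error is assumed (configurable), which makes
χ values against such curves systematically larger.

`pca_rank()` estimates the number of species in a temperature series.
The cumulative-explained-variance rule is available but is a poor
default here: SAXS curves of related conformations are so collinear
that the first uncentred singular value alone can explain > 99.5% of
the variance regardless of the true rank. The default therefore counts
singular values above a noise-floor ratio (`sv_k ≥ 0.005·sv_1`), which
separates rank 1 from rank 3 cleanly at the noise levels the generators
produce.

`mcr_als()` alternates exact non-negative least squares (Lawson–Hanson
active sets) for the concentration and spectra matrices, with optional
closure (rows of C renormalised to sum 1), SVD/purest-row
initialisation or a user-provided S, and convergence on the relative
lack-of-fit change (plus an absolute floor of 1e-12 for exactly
factorisable data). Two honest limitations, verified numerically and
reflected in the tests: (i) the closure renormalisation is not an
orthogonal projection, so the lack of fit is guaranteed non-increasing
only without closure; (ii) non-negativity plus closure do not remove
rotational ambiguity unless each component is essentially pure
somewhere — with populations from the three-state model below, the
intermediate peaks near 0.9, leaving an irreducible ambiguity band of a
few percent in C. Recovery tests therefore plant factorisations with
pure rows (essentially unique) or start ALS from the recorded ground
truth via `init = "provided"`.

## Three-state thermodynamics and spectra

Populations follow the sequential model `N ↔ I ↔ U`:
`K₁ = exp(−ΔG₁/RT)`, `K₂ = exp(−ΔG₂/RT)`,
`X_N = 1/(1 + K₁ + K₁K₂)`, `X_I = K₁X_N`, `X_U = K₁K₂X_N`, computed in
log space so extreme free energies cannot overflow. ΔG inputs are
kJ/mol (R = 8.314 J mol⁻¹ K⁻¹), tabulated on a temperature grid or via
Gibbs–Helmholtz `ΔG(T) = ΔH(1 − T/Tm) − ΔCp(Tm − T + T ln(T/Tm))`,
since global-fit ΔG values are typically reported as parameters rather
than tables.

Deconvolution solves, per wavelength, the least-squares system
`Y(λ,·) = X·[Y_N, Y_I, Y_U](λ)`. The temperature dependence of the
pure state spectra was an open modelling question: the default is
constant pure spectra, with a per-state linear-in-T baseline
(6 parameters per wavelength) as the standard thermal-unfolding
alternative, and optional non-negativity. A rank-deficient population
design (fewer than 3 temperatures, or collinear populations such as
ΔG ≡ 0 everywhere) is an error naming the condition number.

## Clustering

Leader clustering on coordinate RMSD in a common aligned frame:
frames are scanned in order and joined to the first cluster whose
incrementally updated centroid lies within the radius, else they open a
new cluster; an optional k-medoid-style refinement pass reassigns to
nearest centroids until stable. Representatives are the members closest
to their centroid (ties: lowest frame index). The radius is interpreted
as a centroid radius (the complete-linkage-diameter alternative is
noted but not implemented). RMSD uses Cα atoms by default. Cluster
*counts and memberships* on planted data are the reproducible surface;
published cluster population percentages depend on trajectories that
are not available and are not a target.

## The synthetic world

Toy proteins are Cα-bead chains built from helical columns (radius
2.3 Å, rise 1.5 Å, consecutive beads exactly 3.8 Å apart), one column
per residue range. Loops are placed as packed columns too, so that in
the native state they carry contacts with their neighbouring cores —
the feature the intermediate destroys. Column junctions are solved
exactly; any inter-bead clash below 2 Å is an error.

`make_disordered_ensemble()` emulates the intermediate: core beads
jitter (σ = 0.15 Å by default, norm-clipped at 0.5 Å), and each loop
bead is independently kept (with its retention probability) or
displaced by an isotropic vector of the given amplitude, re-drawn on
clashes. The generator measures the *realised* per-residue contact
retention with its own independent distance bookkeeping and records it
as ground truth — the quantity recovery tests compare against, since
input probabilities translate only approximately into realised
retention (both partners must stay put).

`toy_intermediate_world()` assembles the full annotation test bed. Its
fixed choices, calibrated once while constructing the world and then
frozen: planted fractions 50/30/20 native/intermediate/unfolded; loop
displacement amplitude 12 Å (random-coil-scale excursions for a
20-residue loop, large enough that loop contacts are genuinely lost
frame after frame rather than flickering); contact cutoff 5.3 Å and
core jitter 0.05 Å (see above); four Trp beads chosen on the core face
at positions whose core-only exposure is nearest 55 Å², so the summed
exposure sits mid-window once the loop clears. The synthetic
"experimental" references are built from independent draws of the same
intermediate generator: the SAXS reference is the ensemble-mean Debye
curve with 7% homogeneous errors, the φ reference the ensemble-mean
profile. The default three-state model uses Tm₁ = 318 K, ΔH₁ = 300
kJ/mol and Tm₂ = 334 K, ΔH₂ = 330 kJ/mol (ΔCp = 0): midpoints 16 K
apart with van 't Hoff enthalpies in the range typical of small-protein
thermal transitions, giving an intermediate that peaks near 0.9 —
chosen once to represent a well-populated, experimentally detectable
intermediate.

What a green test does and does not establish: the generators produce
ideal point-bead geometry, isotropic uncorrelated disorder, Gaussian
noise and exactly sequential three-state populations. They contain no
force-field energetics, no solvent, no secondary structure, no
aggregation, no correlated loop dynamics and no instrument systematics.
Green tests establish that the *analysis machinery* — metrics, fits,
decompositions, filters — is correct on data whose truth is known; they
say nothing about whether any particular simulation ensemble resembles
a real protein's intermediate.

## Known limitations

- Vacuum Debye scattering (no hydration shell): χ values are
  comparable within this package only.
- MCR-ALS rotational ambiguity without pure variables (above).
- The Guinier sphere bias at the full 1.3/Rg range (above).
- Leader clustering is order-dependent by construction; determinism is
  guaranteed for a fixed frame order and seed, not invariance to frame
  permutation.
- PDB I/O is deliberately minimal: first chain, altloc A, HETATM
  ignored unless whitelisted; it is not a general-purpose PDB parser.
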