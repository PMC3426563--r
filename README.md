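# thermint

Ensemble analysis of thermal protein folding intermediates.

Many medium-sized proteins unfold thermally through a partially
structured intermediate: a state with an intact hydrophobic core but
disordered loops, detectable experimentally as non-coincident unfolding
curves across probes. Characterising that state at atomic detail
requires confronting conformational ensembles (typically from molecular
dynamics) with the low-resolution experimental observables that define
the intermediate. `thermint` implements that confrontation pipeline as
a tested, reusable R package:

- **Structure/ensemble handling** — multi-model PDB and XYZ I/O, Kabsch
  superposition, TM-score, radius of gyration, B-factor profiles,
  residue contact maps, Shrake–Rupley solvent-accessible surface areas
  (including the summed Trp side-chain exposure that tracks near-UV
  absorbance).
- **Essential dynamics** — Cartesian covariance analysis of aligned
  ensembles and three subspace metrics: the Hess similarity
  γ = (1/n) Σᵢⱼ (νᵢᴬ·νⱼᴮ)², the noise-corrected relative similarity
  κ = 2γ_AB/(γ_A^self + γ_B^self), and the overlap
  Ov = √(Σᵢ (r·νᵢ)²) between an inter-state transition vector r and an
  essential subspace.
- **φ-value analysis** — per-residue φᵢ = Nᵢ/Nᵢⁿᵃᵗ from native-contact
  retention, and the signed accumulated error Σ(φᶜᵃˡᶜ − φᵉˣᵖ) against an
  experimental profile (positive: too native-like).
- **SAXS** — Debye-formula scattering from coordinates
  I(s) = ΣᵢΣⱼ fᵢfⱼ sin(s·rᵢⱼ)/(s·rᵢⱼ), iterative Guinier analysis
  (I(s) = I₀·exp(−(sRg)²/3), s < 1.3/Rg), error-weighted χ fitting with
  the 7% homogeneous-error convention, PCA rank estimation and MCR-ALS
  decomposition D = C·Sᵀ + R of temperature-series datasets.
- **Three-state thermodynamics** — sequential N ↔ I ↔ U populations
  from ΔG₁, ΔG₂ (tabulated or Gibbs–Helmholtz) and least-squares
  deconvolution of temperature-series spectra into pure state spectra.
- **Clustering** — RMSD-radius leader clustering with centroid-nearest
  representatives.
- **Intermediate annotation** — per-snapshot evaluation of the three
  experimental criteria (Trp SASA within 100–300 Å², SAXS χ below
  threshold, |accumulated φ-error| below threshold), with published
  loose (χ < 1.5, φ-err < 2) and strict (χ < 1.0, φ-err < 1.0) presets.
- **Synthetic data** — deterministic generators for every input, with
  planted ground truth: bead-model toy proteins, correlated-Gaussian
  ensembles, loop-disordered intermediates, SAXS mixtures, spectra
  series, and a complete three-population annotation world.

## Worked example

```r
library(thermint)

# a synthetic world: toy native structure, mixed ensemble of 250 frames
# (50% native-like, 30% intermediate-like, 20% unfolded-like), plus
# synthetic "experimental" intermediate SAXS curve and phi profile
w <- toy_intermediate_world(seed = 1, n_frames = 250)

rep_loose  <- annotate(w$ensemble, w$native_map, w$exp_phi, w$exp_saxs,
                       criteria_set("loose"))
rep_strict <- annotate(w$ensemble, w$native_map, w$exp_phi, w$exp_saxs,
                       criteria_set("strict"))
rep_loose
#> <AnnotationReport: 250 frames, 27.6% intermediate (loose criteria)>
rep_strict$fraction_intermediate
#> [1] 0.176
```

The loose criteria annotate 27.6% of frames as intermediate —
recovering the planted 30% within binomial sampling error — and the
strict criteria cut that to 17.6%, mirroring the loose-versus-strict
contraction seen with real ensembles. Essential-dynamics comparison of
the state sub-ensembles:

```r
nat <- which(w$labels == "native"); int <- which(w$labels == "intermediate")
sub <- function(i) new_ensemble(w$ensemble$topology, w$ensemble$frames[i],
                                align_mask = w$ensemble$align_mask)
sim <- relative_similarity(sub(nat), sub(int), n = 10, reference = w$native)
c(gamma = sim$gamma, kappa = sim$kappa)
#>      gamma      kappa
#> 0.06360835 0.63870932
```

Here the native-like and intermediate-like dynamics genuinely differ
(the loops switch from packed to disordered), so both the absolute and
noise-corrected similarities are far below 1.

A complete run — descriptors, B-factors, clustering, ED comparison, φ
profile, per-frame SAXS χ, annotation — with JSON/TSV reports:

```r
run_pipeline(list(seed = 1, output_dir = "reports",
                  simulate = list(n_frames = 100)))
```

A command-line front end with `simulate`, `pipeline`, `descriptors`,
`cluster`, `ed-compare`, `phi`, `saxs-fit`, `mcr`, `deconv-spectra` and
`annotate` subcommands is installed under `inst/cli/thermint`.

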