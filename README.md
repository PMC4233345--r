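# saskit

Small-angle scattering data analysis toolkit for R.

Small-angle X-ray scattering (SAXS) measures a one-dimensional intensity
profile I(s) of macromolecules in solution, s = 4π sinθ/λ. From that
single curve, structural biologists routinely extract the radius of
gyration and forward scattering (Guinier analysis), the hydrated particle
volume and molecular mass (Porod analysis), compositions of equilibrium
mixtures, and low-resolution structural models. saskit implements the
algorithmic core of such a processing pipeline as plain R functions:

* **Primary processing** — curve I/O (`read_curve`, `write_curve`),
  arithmetic, statistical comparison (`curve_compare`), averaging and
  merging; automatic Guinier analysis (`autorg`): the
  closest-to-the-origin window where ln I is linear in s² with
  s·Rg ≤ 1.3, giving Rg = √(−3·slope) and I(0) = exp(intercept).
* **Concentration series** — scaling and consistency checks across a
  dilution series, pointwise linear extrapolation of
  I(s, c) = I(s, 0) + c·B(s) to infinite dilution with Rg-consistency
  diagnostics, and merging (`find_fit_range`, `extrapolate_zero`,
  `merge_extrapolated`, `automerge`).
* **Porod volume and mass** (`autoporod`) — subtracts the constant A
  enforcing the s⁻⁴ decay, integrates Q = ∫ s²(I − A) ds with a Guinier
  head and an analytic K/s_max tail, and reports V_P = 2π² I(0)/Q and
  MM [kDa] = 0.625 · V_P [nm³].
* **Theoretical curves and fitting** — Debye-sum intensities from bead
  or Cα models with selectable per-bead form factors
  (`debye_intensity`), sparse regridding, and fitting with a
  non-negative scale plus bounded background constant (`fit_to_data`).
* **Mixtures** — form-factor assembly from curves, models and
  multi-model (NMR ensemble) files (`build_formfactors`), non-negative
  least-squares volume fractions (`fit_fractions`), two-state
  assembly/subcomplex decomposition (`two_state_decompose`).
* **Flexible systems** — genetic-algorithm selection of a variable-size
  sub-ensemble whose average curve fits the data (`select_ensemble`),
  with the Rg-distribution flexibility verdict (`flexibility_report`).
* **Random loops** — self-avoiding Cα traces at 3.8 Å steps with a >4 Å
  clash rule and a quasi-Ramachandran mask (`grow_loop`), libraries
  binned by length and end-to-end distance at 2 Å with 20 distinct
  traces per bin (`build_library`), and anchored linker queries
  (`query_linker`).
* **Multi-model analysis** — normalized spatial discrepancy (`nsd`),
  free and symmetry-restricted superposition (`superpose`),
  average-linkage clustering with the Kelley criterion
  (`cluster_models`), and MRC/CCP4 density-to-bead conversion
  (`read_density`, `density_to_beads`).
* **Synthetic data** (`analytic_curve`, `random_bead_model`,
  `noisy_series`, ...) — analytic sphere/ellipsoid/Guinier curves,
  random bead models and noisy concentration series, so every algorithm
  is testable against exact ground truth without downloads.

A thin command-line wrapper over these functions ships in
`inst/cli/saskit` (subcommands `autorg`, `autoporod`, `datcmp`, `datop`,
`dataver`, `automerge`, `debye`, `fit`, `oligomer`, `em2dam`, `nsd`,
`supcomb`, `damclust`, `ranlogs`, `eom-select`, `pipeline`, ...), and
`run_pipeline()` chains stages from a JSON configuration.

## Worked example

Estimate Rg, particle volume and molecular mass of a 30 Å sphere
(true volume 113097 Å³) from a noisy synthetic profile, then decompose a
monomer/dimer mixture:

```r
library(saskit)

sph   <- analytic_curve("sphere", s_grid = seq(0.002, 0.40, length.out = 1200),
                        radius = 30, i0 = 1000)
noisy <- apply_noise(sph, noise_model(relative = 0.01), seed = 7)
res   <- autoporod(noisy)
res$guinier
#> Rg = 23.690 +/- 0.056  I(0) = 1004 +/- 1.2  points 1-160  sRg(max) = 1.30  quality 0.87
res
#> Porod analysis: A = -0.001907, K = 0.006006, Q = 0.1767
#>   V_P = 112202 A^3, MM = 70.1 kDa  (range 0.0020 - 0.3377 A^-1)
```

The Guinier fit reports the sphere's radius of gyration (truth:
30·√(3/5) ≈ 23.24 Å; the 1.3 s·Rg window overshoots slightly because the
sphere only approximately obeys the Guinier law), and the Porod volume
lands within 1% of the true 113097 Å³. The MM line applies the protein
calibration 0.625 kDa per nm³.

```r
mono  <- random_bead_model(100, envelope_radius = 25, seed = 2)
dimer <- dimerize(mono)
s     <- seq(0.005, 0.3, length.out = 150)
ff    <- build_formfactors(list(mono, dimer), s_grid = s,
                           labels = c("monomer", "dimer"))
mix   <- apply_noise(saxs_curve(s, 0.35 * ff$components[, 1] +
                                   0.65 * ff$components[, 2]),
                     noise_model(0.02), seed = 3)
fit_fractions(ff, mix)
#> mixture_fit: chi2_red = 0.8163  scale = 1.005
#>   monomer              v = 0.3589
#>   dimer                v = 0.6411
```

The true monomer fraction was 0.35; with 2% noise the non-negative
least-squares decomposition recovers 0.359 at a reduced χ² near 1.

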