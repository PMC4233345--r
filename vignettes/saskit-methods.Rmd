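---
title: "Models and methods behind saskit"
author: "saskit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind saskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saskit)
```

saskit analyses one-dimensional small-angle X-ray scattering (SAXS)
profiles of biological macromolecules in solution: an isotropic intensity
$I(s)$ on a momentum-transfer grid $s = 4\pi\sin\theta/\lambda$, with
per-point counting errors $\sigma(s)$. This vignette records the models
the package implements, the numerical choices made where the literature
leaves the implementation open, and what the synthetic validation does and
does not demonstrate.

## Guinier analysis

At small angles a monodisperse particle obeys
$I(s) \approx I(0)\exp(-s^2 R_g^2/3)$. `autorg()` searches every
contiguous window of at least `min_window = 5` points in the low-angle
region, fits $\ln I$ against $s^2$ by weighted least squares, and keeps
windows with a negative slope, a significant fit, and
$s R_g \le$ `srg_limit` (default 1.3, the usual globular-protein rule of
thumb) at the window end. Among admissible windows the quality score
$0.4\,f_{\mathrm{len}} + 0.3\,(1 - f_{\mathrm{start}}) + 0.3\,R^2$
prefers long windows that start close to the origin — the
"closest-to-the-origin valid interval" behaviour. The weights are
exposed because no published criterion fixes them; only the selection
behaviour is contractual, and the tests assert that behaviour (exactness
on ideal data, 2% accuracy at 1% noise, scale equivariance, rejection of
aggregated profiles) rather than the score itself.

No lower $sR_g$ bound is imposed; windows that start deep into the curve
are penalised through the start-fraction term instead of being cut off.

## Curve algebra, comparison, merging

Subtraction and addition propagate $\sigma$ in quadrature; averaging is
inverse-variance weighted whenever all inputs carry errors. Comparison
(`curve_compare()`) first finds the optimal scale between two curves,
then forms the reduced $\chi^2$ with the scaled error of both curves in
the denominator and converts it to a $\chi^2$ p-value; two curves are
"similar" at $p \ge 0.01$ by default — the threshold is a convention, not
a derived quantity. Interpolation, where explicitly requested, is linear
in $s$ and never extrapolates. `curve_merge()` takes the low-angle curve
below the overlap window, the rescaled high-angle curve above it, and an
inverse-variance blend inside it.

## Extrapolation of a concentration series to infinite dilution

The measured intensity of an interacting solution is modelled as linear
in the solute concentration,
$I(s, c) = I(s, 0) + c\,B(s)$,
where $B(s)$ collects the interparticle-interference contribution.
`find_fit_range()` scans candidate high-angle windows, scales every
curve onto the most concentrated one and accepts the widest window in
which all pairwise comparisons are similar; a curve that never matches is
reported as an outlier (a changed sample, not just a changed scale).
`extrapolate_zero()` then regresses the scaled intensities on $c$ at
each grid point. The intercept standard error comes from the weight
matrix alone (the declared $\sigma$ are taken at face value), so two
concentrations already give an exact fit with finite errors.

Diagnostics, with defaults chosen here because no published values
exist: the Guinier $R_g$ of the extrapolated curve must agree with the
straight-line extrapolation of the per-curve $R_g$ to $c = 0$ within 5%;
the regression is done on $R_g^2$ by default (the Guinier-additive
quantity) with a flag for plain $R_g$; pointwise intercept errors may
not exceed 5 times the best input error; and a point counts as
"information gained" when it differs from every input curve by more than
3 intercept sigmas. The merge point between the extrapolated curve and
the averaged data is the grid point inside the fitting range with the
smallest normalised discontinuity.

## Porod invariant, particle volume and molecular mass

For a homogeneous particle $I(s) \to A + K s^{-4}$ at higher angles; the
constant $A$ absorbs internal-structure and background contributions and
must be subtracted before the Porod invariant
$Q = \int_0^\infty s^2 \left[I(s) - A\right] \mathrm{d}s$
is formed. The excluded (hydrated) particle volume is
$V_P = 2\pi^2 I(0)/Q$ and the molecular mass estimate is
$\mathrm{MM\,[kDa]} = 0.625 \cdot V_P\,[\mathrm{nm}^3]$, the protein
calibration ratio (a `ratio` argument allows recalibration).

Numerical choices:

* $Q$ is assembled from three pieces: the Guinier model on
  $[0, s_{\min}]$, trapezoidal integration of the data on
  $[s_{\min}, s_{\max}]$, and the analytic tail $K/s_{\max}$ beyond. The
  tail keeps $Q$ from being systematically underestimated on truncated
  ranges.
* The default cutoff is $s_{\max} = 8/R_g$, configurable, with an
  optional detector for the second minimum of the Porod plot
  $s^4 I(s)$ as an alternative cutoff.
* The background fit is performed in the Porod-plot basis,
  $s^4 I = A s^4 + K$, over the highest-angle half of the working range,
  and deliberately unweighted. Two facts drive this: (i) at
  $s_{\max} = 8/R_g$ a much shorter window spans less than one
  form-factor oscillation period of a compact body, which makes $A$
  phase-sensitive; (ii) the residuals in this fit are dominated by the
  coherent oscillation, not by counting noise, and $\sigma$-weighting
  would fixate the fit on the oscillation minima where the
  $A + K s^{-4}$ model is locally worst. On data that follow the model
  exactly, both bases give identical, exact answers. $A$ is clamped so
  that $I - A$ stays positive over the fitted tail.
* An optional Savitzky–Golay smoothing pass before integration is off by
  default.

On analytic bodies the chain recovers the sphere volume to about 1%, a
1:1:3 ellipsoid to about 3%, is exactly scale-invariant, and shifts by
under 0.5% when a flat constant is added to the data. With 1% noise the
median molecular mass over 20 replicates stays within a few percent of
truth. Real data add aggregation, interparticle effects and subtraction
artefacts that these synthetic checks do not probe; the empirical
finding that MM from $V_P$ is good to roughly 20% on real proteins
rests on large protein calibration sets and is neither re-derivable from
synthetic data nor asserted by the tests.

## Debye intensities and fitting with a bounded constant

Scattering from a coordinate model is computed with the Debye sum
$$I(s) = \sum_i \sum_j f_i(s) f_j(s)\,
  \frac{\sin(s r_{ij})}{s r_{ij}},$$
with per-bead form factors: constant (`point`), a Gaussian sphere
$w\,\mathrm{e}^{-(sR)^2/\alpha}$ with $R = 1.9$ Å and $\alpha = 4$ as the
dummy-residue default, or the hard-sphere amplitude. $I(0)$ equals
$(\sum_i w_i)^2$ identically, a property the tests assert for every
kind. Above 2000 beads the pair distances are binned at 0.1 Å with the
pair-weighted mean distance per bin, cancelling the first-order binning
error; the 500-bead oracle comparison shows agreement with the exact
double sum to better than $10^{-3}$ relative.

`fit_to_data()` fits $c\,I_{\mathrm{calc}} + b$ to an experimental curve
by weighted least squares with $c \ge 0$ and $b$ inside bounds
(default ±10% of the maximum intensity); a two-parameter box problem is
solved exactly by enumerating the active sets. The parameter search runs
on a sparser grid — contiguous blocks uniform in $s$, inverse-variance
averaged, at most 256 points — and the reported $\chi^2$ is recomputed on
the original grid. Uniform-in-$s$ blocks were chosen over
uniform-in-index to keep the block means unbiased on smooth profiles.

## Mixture decomposition

For an equilibrium mixture without interparticle interference,
$I(s) = S \sum_k v_k I_k(s)$ with volume fractions $v_k \ge 0$. Weights
are found by Lawson–Hanson non-negative least squares on the
$\sigma$-weighted design; fractions are the normalised weights and the
overall scale $S$ is reported separately, since the inputs' absolute
scales are arbitrary. Fractions are therefore weights on the supplied
intensities; converting them to mass fractions is the caller's business
when components differ in size. Components with known fractions are held
fixed by folding their contribution into the free columns. Exact
duplicates make the design rank-deficient; a tiny Tikhonov ridge
($10^{-7}$ of the largest column norm) then selects the minimum-norm
solution, which splits weight evenly across duplicates while conserving
their sum.

`two_state_decompose()` computes the Debye curves of a full assembly and
a chain subset and decomposes data into the two — the
monomer-versus-multimer and complex-versus-subcomplex scenario. The
recovered fraction is flagged when it leaves the reliable window
(0.15–0.90 for general subcomplexes, 0.2–0.8 for monomer/multimer): the
minor species then contributes too little signal for a stable estimate,
which the simulation sweep in the tests reproduces qualitatively.

## Ensemble selection for flexible systems

A flexible protein is represented by a pool of conformers with
theoretical curves $I_m(s)$; the data are fitted by the unweighted
average over a selected multiset of members (repeats encode weight).
`select_ensemble()` evolves such multisets with a genetic algorithm:
tournament selection, uniform crossover of the merged parent multisets,
point mutation, and insert/delete size mutation within bounds
[5, 50] — the adjustable-chromosome mechanism, applied per offspring.
Defaults (population 50, 200 generations, mutation rate 0.1, elitism 2,
plateau stop after 50 stale generations) are package choices; no
published parameter set exists. Two additions make the search reliable
on the rugged subset-selection landscape:

* the elite chromosome receives one pass of greedy single-member
  refinement per generation (delete / replace / duplicate moves);
* each initial population seeds a fifth of its chromosomes from the
  support of the non-negative least-squares decomposition of the data
  against the whole pool. NNLS solutions are sparse, and purely random
  multisets essentially never visit the parsimonious region where exact
  few-member solutions live; diffuse 15–20-member combinations that fit
  within the noise otherwise trap the search.
* `n_restarts` independent runs (default 5) are executed and the best
  final chromosome wins; a fixed seed makes the whole procedure
  bit-reproducible.

The flexibility diagnostic compares the $R_g$ distribution of the
selected ensemble against the pool: variance ratio at least 0.8 is
called flexible, at most 0.3 rigid, anything between indeterminate, and
the mean shift reports compaction or extension. The cutoffs are
conventions chosen here; the tests exercise the unambiguous ends
(selected $\equiv$ pool, a single repeated member) and one constructed
bimodal case in between.

## Random-loop libraries and anchored linkers

Cα-only loop placeholders are grown by consecutive addition of points at
3.8 Å from the predecessor, with a uniform random direction accepted only
if every non-neighbouring pair stays above 4 Å and the pseudo-angle pair
passes a quasi-Ramachandran mask. The published criterion names the mask
but not its coordinates, so the default — pseudo-bond angle in
[75°, 150°], with the rectangle θ ∈ [110°, 150°] × γ ∈ [−40°, 40°]
excluded as a crowded near-cis strip — is a configurable package choice.
Each growth step gets 100 direction draws, then single-step backtracking,
then whole-trace restarts (50), with a total work bound per restart.

`build_library()` grows a pool per length (default budget 500 traces per
length), bins traces by end-to-end distance into 2 Å bins centred at odd
multiples of 1 Å (tiling [0, contour length]), and selects exactly
`per_bin = 20` mutually distinct traces per bin (pairwise r.m.s.d. after
superposition above 0.5 Å). Bins that never collect 20 distinct traces
within the budget — the near-contour-length extremes, mostly — are
reported under-filled and not served, so every served bin holds exactly
20. `query_linker()` maps an anchor pair to its distance bin, picks a
stored trace at random and rigid-places it (first point onto anchor A,
end-to-end vector onto the anchor axis, minimal rotation); a missing bin
returns a failure signal rather than an error, which is what a rigid-body
assembler needs to veto a domain move.

## Multi-model comparison and clustering

The normalised spatial discrepancy between point models is
$$\mathrm{NSD}^2(A, B) = \frac{1}{2}\left[
  \frac{1}{N_A d_B^2}\sum_{i \in A}\min_j r_{ij}^2 +
  \frac{1}{N_B d_A^2}\sum_{j \in B}\min_i r_{ij}^2\right],$$
with $d_X$ the median nearest-neighbour distance within model $X$ — the
median rather than the mean because the normalisation reference should
not follow density outliers. `superpose()` minimises the NSD over poses:
for P1 a deterministic 432-orientation Euler grid seeds Nelder-Mead
refinement (optionally for the mirror image too); for P$n$ only the
rotation about and translation along the shared z axis are optimised,
preserving the symmetry; for P$n$2 superposition reduces to axis
alignment. Planted rigid transforms are recovered to NSD below
$10^{-3}$.

`cluster_models()` builds the pairwise NSD (or r.m.s.d.) matrix, merges
by average linkage, and picks the cut with the Kelley penalty: the mean
within-cluster spread per candidate $k$, normalised linearly onto
$[1, N-1]$, plus $k$; ties break toward smaller $k$. One numerical
guard is added: a spread profile that is flat to within $10^{-6}$ of the
largest pairwise distance carries no cluster signal, and stretching it
onto $[1, N-1]$ would amplify float noise into an arbitrary choice, so
it collapses to a constant and the $+k$ term decides. No model is ever
discarded; models whose mean distance exceeds the mean + 2 SD are merely
flagged.

`density_to_beads()` places one bead per voxel at or above a threshold
(radius = half the voxel diagonal); with a surface cutoff, beads with any
outside voxel within that distance are marked refinable and the interior
stays fixed, reproducing the combinatorial 98/27 surface/core split on a
5³ test block.

## The synthetic-data generators, and what the tests show

`analytic_curve()` provides the exact sphere form factor, a triaxial
ellipsoid averaged by 64-point Gauss–Legendre quadrature per direction
dimension (doubling the order changes results by under 0.1%), and the
exact Guinier law. `random_bead_model()` packs beads with minimum
separation by dart throwing with a stall detector; `dimerize()` builds
P$n$ multimers. `noisy_series()` implements the linear concentration
effect $I_0(s)(1 - k\,c\,\mathrm{e}^{-(s/s_0)^2})$ on per-unit-
concentration-normalised curves, and `apply_noise()` adds Gaussian noise
with $\sigma = 0.01\,|I| + 10^{-6} I(0)$ by default — synchrotron-quality
statistics. All generators are seed-deterministic.

These generators emulate ideal monodisperse (or exactly two-component)
solutions with Gaussian, uncorrelated, correctly estimated errors and a
strictly linear concentration effect. They do not emulate aggregation,
radiation damage, correlated detector noise, hydration-shell contrast,
smearing or nonlinear structure factors — so passing tests certify the
estimators and algorithms, not instrument-specific robustness.

Problem sizes used by the test-suite validation runs, chosen to keep a
full run within a few minutes on one core: loop-library slices use
lengths {10, 15, 20, 25, 30} at 500-trace budgets; mixture recovery uses
100-bead monomers, 150-point grids, 20 replicates; the distributional
$\chi^2$ checks use 50–100 replicates; ensemble recovery uses 50-member
pools of 40-bead conformers on 80-point grids.

## Known limitations

* The Porod constant estimator assumes the curve reaches
  $\sim 8/R_g$; strongly truncated data fall back on whatever tail
  exists and degrade gracefully but without the truncation correction
  factors some packages apply.
* NSD superposition is a deterministic local search from a global grid;
  pathological near-symmetric models can in principle settle in a
  secondary minimum.
* The GA fits the unweighted multiset average; explicit per-member
  weights (beyond multiplicity) are not modelled.
* Loop growth at lengths close to 100 with tight masks can exhaust its
  retry budget; the library builder reports rather than hides such
  bins.
* MRC/CCP4 reading supports mode-2 (float) maps with orthogonal cells,
  which covers standard single-particle EM exports; exotic modes are
  rejected with a format error.
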