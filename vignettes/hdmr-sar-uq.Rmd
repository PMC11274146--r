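---
title: "Surrogate-assisted UQ of MRI-induced SAR: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted UQ of MRI-induced SAR: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmruq)
```

## The statistical model

Twelve uncertain inputs — relative permittivity $\varepsilon_r$ and
conductivity $\sigma$ (S/m) of white matter, grey matter, CSF, bone, scalp
and eye humor — are modelled as mutually independent uniform random
variables spanning $\pm 20\%$ of their nominal values, the maximum-entropy
choice when only a range is credible. The frozen ordering
$x = [\varepsilon_{r1}\dots\varepsilon_{r6}, \sigma_1\dots\sigma_6]$ is a
package-wide contract: designs, caches, coefficient tables and sensitivity
tables are index-compatible because of it.

A deterministic solver maps $x$ to a voxel observable $y = F(x)$ — either
per-voxel SAR directly (*direct approach*) or the three complex E-field
components per voxel (*indirect approach*, output length $3 N_{vox}$), with
SAR assembled afterwards as
$\mathrm{SAR}_i = (|E_{x,i}|^2+|E_{y,i}|^2+|E_{z,i}|^2)\,\sigma_i/\rho_i$
using the *realized* conductivity of each voxel's tissue from the sampled
input vector. The kernel is implemented exactly in this form; a peak-vs-RMS
convention would insert a factor $\tfrac12$, which is available behind the
`rms` flag of `voxel_sar()` but is off by default.

## CUT-HDMR with gPC component functions

`build_hdmr()` approximates $F$ by a cut-type high-dimensional model
representation truncated at second order,
$$F(x) \approx F_0 + \sum_i F_i(x_i) + \sum_{i<j} F_{ij}(x_i, x_j),$$
anchored at the reference point $\bar x$ (the nominal vector, which for
symmetric uniform ranges is also the mean). $F_0 = F(\bar x)$; each $F_i$ is
fitted to model-values-minus-$F_0$ on the Gauss–Legendre line through
$\bar x$; each $F_{ij}$ to plane values with $F_0 + F_i + F_j$ subtracted at
the nodes. Component functions are total-degree-$p$ expansions in Legendre
polynomials *orthonormal under the uniform probability density* of their
sub-box, with probability-normalized quadrature weights. That normalization
is what makes the projection
$\alpha_n = \sum_j F(\tilde x_j)\Phi_n(\tilde x_j) w_j$ exact as written and
gives closed-form moments: the mean of a component is its constant
coefficient and its variance the sum of squared moduli of the rest
(`gpc_moments()`), so no sampling is spent on the importance weights.

Adaptivity: after all first-order fits, each dimension receives
$\eta_i = \lVert E[F_i]\rVert_2 / \lVert F_0\rVert_2$ and the important set
is $S = \{i : \eta_i > \xi\}$ (strict; a weight exactly equal to $\xi$ is
excluded). Pairs are generated only within $S$, while the first-order
components of unimportant dimensions remain in the expansion — they are
already paid for. Two deliberate resolutions of genuinely open points:

* **Vector outputs.** The importance weight is defined for scalar
  observables; for voxel vectors this package uses the ratio of L2 norms
  over all outputs. Alternatives (mean of per-voxel ratios, max ratio) are
  unstable wherever voxel values approach zero and were rejected.
* **Odd dependence.** The signed-mean weight cannot see zero-mean
  (odd) dependence: $F = c + x_1$ on a symmetric interval has
  $\eta_1 = 0$. This is a property of the definition, reproduced
  faithfully; `weight = "variance"` switches to
  $\sqrt{\sum \mathrm{Var}[F_i]}/\lVert F_0\rVert_2$, which sees odd terms.
  The mean-ratio reading stays the default.

Complex observables are fitted with complex coefficients directly — no
modulus before fitting — which is bit-identical to fitting real and
imaginary parts separately (the projection is linear; a test asserts this
to $10^{-14}$).

### Collocation accounting

Odd GL rules are mandatory: the middle node of an odd rule is the interval
midpoint, so every line and plane shares the center point $\bar x$, and
plane nodes with one coordinate at the center lie on the already-evaluated
lines. All model calls go through a cache keyed on the exact floating-point
input vector, which is safe because all nodes derive from a single rule
construction: the 1-D reference nodes are symmetrized
($t \leftarrow (t - \mathrm{rev}(t))/2$, middle forced to exactly 0) and
mapped as $\bar x_k + t\,(b_k-a_k)/2$, so shared nodes are bit-identical
wherever they arise. The deduplicated evaluation count then obeys
$$N_{cp} = 1 + N(N_{GL}-1) + |\mathrm{pairs}|\,(N_{GL}-1)^2,$$
which the test suite verifies against the realized cache for every build
configuration, and which gives the familiar budgets 25/49/73 (first order at
$N_{GL} = 3/5/7$) and 289/1105 (full second order at $N_{GL} = 3/5$) for
$N = 12$.

### Anchoring precision

Component functions of order $\ge 1$ vanish at $\bar x$ by construction.
Numerically this is exact (to rounding) for first-order components whenever
$p = N_{GL} - 1$ — three nodes projected onto three polynomials is an
interpolant — and for any model of total degree $\le p$. For a
*non-polynomial* model, the pair projection (9 plane nodes onto the 6-term
total-degree-2 basis) is not an interpolant, so $F_{ij}(\bar x_i,\bar x_j)$
vanishes only to quadrature accuracy. The anchoring property test therefore
asserts $10^{-10}$ relative on polynomial models, where it is a genuine
identity; on smooth models the residual is the same size as the truncation
error the validation metrics already measure.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `p` | 2 | — | total gPC degree per component; 2 matches the bivariate basis example and keeps the pair basis at 6 terms |
| `n_gl` | 3 | points | odd GL nodes per dimension; 3, 5, 7 supported in `run_config()` |
| `tol` ($\xi$) | $10^{-2}$ | — | importance tolerance; negative values retain every dimension (the full-pair configuration) |
| `max_order` | 2 | — | HDMR truncation; 1 or 2 |
| `n_mc` | 10,000 | samples | surrogate-assisted MC size; brute-force comparisons conventionally use 5,000 |
| `n_test` | 100 | points | validation test-set size |
| `checkpoint_every` | 50 | samples | convergence-trace cadence |
| `target_mass_g` | 1 / 10 | g | regulatory mass-averaging presets |
| `fraction` | 0.05 | — | top-SAR plotting mask |

Randomness: one master seed expands into per-purpose child streams through
a documented string hash (`child_seed()`), so MC draws, Latin hypercube
designs, Sobol cuts and test points never share a stream, and every result
is bit-reproducible from `(seed, purpose)`.

## The phantom: what it emulates and what it does not

`build_head_phantom()` provides the deterministic solver the framework
needs: a voxelized six-tissue layered sphere (white-matter core, then grey
matter, CSF, bone, scalp; radii 24/28/31/35/38 mm at 1.6 mm voxels on a
49³ grid by default, with two eye-humor spheres embedded in the front and
clipped to the outer radius). Its field solution is quasi-static: the
potential of a five-layer dielectric sphere in a uniform applied field
solved in closed form per layer, with complex permittivities
$\tilde\varepsilon = \varepsilon_0\varepsilon_r - i\sigma/2\pi f$ at
298.06 MHz so permittivity and conductivity enter with realistic relative
magnitudes. Eye voxels take the local background field scaled by the
embedded-sphere factor
$3\tilde\varepsilon_{bg}/(\tilde\varepsilon_{eye}+2\tilde\varepsilon_{bg})$,
which is what routes the eye parameters into the output. The interface
system is solved in nondimensional form (permittivities relative to
$\varepsilon_0$, radii relative to the outer radius, the $r^{-2}$
coefficients rescaled by $R_{out}^3$) — in raw units its condition number
is hopeless.

The phantom gives the surrogate machinery exactly what a full-wave solver
would — a smooth, deterministic, nonlinearly coupled map from all 12 inputs
to $\sim 10^4$–$10^5$ complex voxel fields (tests assert smoothness under
step-halving, nonzero mixed second differences, and that every input
influences the output) — while keeping every downstream number checkable
against closed forms (homogeneous limit, single-sphere factor, interface
continuity). What it does **not** emulate: wave propagation and standing
waves, coil port geometry, realistic anatomy, or the error *magnitudes* of
a volume-integral-equation solver on a segmented head. Passing tests
therefore demonstrate the correctness of the surrogate construction,
statistics, sensitivity and SAR post-processing — not the specific accuracy
percentages any particular EM solver would yield.

One measured property matters for interpretation: the phantom is smoother
than a realistic head model, and all twelve importance weights land in
$\sim 10^{-4}$–$7\times 10^{-3}$, *below* the default $\xi = 10^{-2}$. An
adaptive build at the default tolerance therefore retains no pairs on this
phantom. The accuracy-ordering studies (order 2 vs order 1, indirect vs
direct) consequently use the full second-order configuration — every
dimension retained, all 66 pairs, $N_{cp} = 289$ — which is also the
configuration all reported SAR statistics conventionally use; the adaptive
path itself is exercised on models with controlled weights either side of
the tolerance.

## Statistics, sensitivity, and error metrics

`mc_statistics()` accumulates element-wise running means and second
moments; the variance is second moment minus squared mean (of the modulus,
for complex observables), clamped at zero against rounding. Checkpoints
every 50 samples feed the convergence plots. `sobol_cut()` implements the
cut-based first-order index: the numerator varies one coordinate with all
others pinned at nominal; the denominator is a *separate* full-space MC run
on its own child stream (the one-run alternative would correlate numerator
and denominator errors). A classical variance-based alternative from the
HDMR component variances is available via
`hdmr_first_order_variances()` and is compared against the cut indices in
tests on additive models, where the two coincide.

Validation uses the per-voxel relative error averaged over test points
(the per-voxel average over $N_{test}$ is the only reading consistent with
a test-set of points; the printed form of such formulas sometimes confuses
the two summation indices), then the max and mean over voxels. Voxels whose
typical magnitude falls below $10^{-3}\times$ the volume median are
excluded from the *max* (their relative errors are amplified noise — the
same pathology seen near unexcited regions in realistic geometries) and
reported separately; the average error is reported both with and without
the guard.

Mass averaging grows whole cubic (Chebyshev) shells of tissue-containing
voxels around each center until the accumulated mass reaches 1 g or 10 g,
then assigns the mass-weighted mean; air voxels contribute nothing but do
not block growth, regions that can never reach the target are flagged
rather than dropped, and whole-shell growth means no fractional-shell
interpolation — a documented simplification relative to the IEEE/IEC
averaging-volume constructions. Mass weighting (not an arithmetic voxel
mean) is used because densities differ across tissues within a region; for
a uniform field both coincide, which is the invariance the tests pin down.
The implementation uses 3-D prefix sums, so each shell query is O(1) and
whole-volume 1g/10g maps stay interactive at desk scale.

## Problem sizes

The test and acceptance studies run on a 25³ grid at 3.2 mm voxels (7,075
tissue voxels; identical shell radii to the default phantom) and a 15³
smoke-test phantom, sizes chosen so the full suite — including four
289-evaluation builds, a 5,000-sample brute-force MC and a 10,000-sample
surrogate MC — completes in well under a minute while preserving every
qualitative property of the default 49³ geometry. The default geometry
remains available for interactive use; nothing in the implementation is
specialized to the reduced sizes.

## Known limitations

* Third- and higher-order component functions are out of scope, as is
  anisotropic per-dimension `n_gl`.
* Only uniform, independent marginals: no Gaussian/beta inputs, no
  correlations, no sparse (Smolyak) grids or adaptive degree selection.
* The quasi-static phantom cannot represent port-dependent excitation
  patterns or B1 maps; the machine-learning baselines sometimes used for
  comparison (RVFL, ELM, NN, GP) are not implemented — the validation
  harness accepts any user-supplied evaluator, so they can be bolted on
  externally. The least-squares gPC baseline is included.
* Surrogate containers are JSON + CSV directories rather than HDF5; the
  format is an equivalent hierarchical container chosen for zero extra
  dependencies, and round-trips to full double precision.
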