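---
title: "An avascular tumor model: stochastic lattice dynamics, mean-field limit, and morphological stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An avascular tumor model: stochastic lattice dynamics, mean-field limit, and morphological stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(avtumor)
```

## The model

`avtumor` simulates a two-dimensional avascular tumor growing inside a disc
of radius 1 whose boundary acts as the oxygen source. Cells consume oxygen,
divide when it is plentiful (`c >= kappa_prol`), fall quiescent at
intermediate levels, die when starved (`c < kappa_death`), and — having
died — degrade and free their voxel. Mechanics are Darcy flow: dividing
cells push their neighbors down pressure gradients, and a Young-Laplace
condition at the rim (`p = p_ext + sigma C`, with `C` the boundary
curvature, positive for a convex tumor) models the net effect of cell-cell
adhesion as a surface tension.

The package implements the model at three levels that share one
nondimensionalization (`R = mu_prol = c_out = D = 1`):

1. **Stochastic lattice model** (`simulate_dlcm()`): voxels carry
   occupancies `u` in `{-1, 0, 1, 2}` (necrotic, empty, single, double).
   Doubly occupied voxels are above carrying capacity and source pressure;
   the pressure field is re-solved after every event and converted to
   Poissonian movement rates, simulated exactly by Gillespie's direct
   method.
2. **Mean-field free-boundary model** (`run_pde()`): a cell density
   advected by `-grad p` with oxygen-thresholded growth, on the same
   lattice.
3. **Analytical reductions**: the radially symmetric dynamics
   (`integrate_radial()`, `find_stationary()`, `eigenvalue_radial()`) and
   the linear-stability dispersion relation for cosine perturbations of the
   rim (`dispersion()`), with its Saffman-Taylor, inner-region-perturbation
   and surface-tension components.

## Radially symmetric reduction

With constant density and radial symmetry, oxygen has the closed form of
`oxygen_profile()`, and the interior interfaces `(r_n, r_q)` are slaved to
the rim `r_p` by two algebraic relations parameterized by
`K = 4 (1 - kappa) / lambda` (`solve_regions()`). Mass balance closes the
system into a single ODE, `d(r_p^2)/dt = -mu_death r_n^2 - r_q^2 + r_p^2`,
whose solutions are sigmoidal and approach a stationary zonation:

```{r radial}
pp <- preset("table2_pde")
st <- find_stationary(pp)
st
eigenvalue_radial(st, pp$mu_death)      # < 0: stable equilibrium volume
prop31_guaranteed_stable(st)            # r_p below exp(-1)
```

The single eigenvalue of the reduced dynamics has a closed form whose
degenerate limits (`r_n -> 0`, `r_q -> r_n`) are evaluated analytically to
avoid 0/0. A tumor whose stationary rim radius is below `exp(-1) = 0.368`
is stable for *every* admissible zonation and death rate — a size-only
sufficient condition that the test suite verifies by grid search.

## Morphological stability

Perturbing the rim by `eps * cos(k theta)` yields the growth rate
`Lambda(k)` returned by `dispersion()`. The decomposition separates the
Saffman-Taylor contribution (destabilizing during growth when the external
medium is the more viscous phase, `D_ext < 1`), the oxygen-mediated damping
from the displaced interior interfaces (`inner_term()`, computed through
its closed combined form in the `theta = (r/r_p)^2` variables rather than
per-interface coefficients, since only the combination enters the rate),
and surface tension, `-sigma k (k^2 - 1) / r_p^3`.

```{r dispersion}
dispersion(1:6, st, pp$mu_death, D_ext = Inf, sigma = 1e-4)
sigma_stable(2, st, pp$mu_death)        # approx 3.1e-3
creeping_rate(st, pp$mu_death)          # k = 1: never negative
```

Mode `k = 1` translates the tumor towards the oxygen source ("creeping");
it is unaffected by surface tension and its closed-form rate is
nonnegative for every admissible state.

A note on orientation: the stabilizing dispersion relation requires the
tumor-side rim pressure to *rise* with curvature (bulges carry the higher
boundary pressure, the classical Hele-Shaw convention). The package uses
`p = p_ext + sigma C` with `C > 0` for a convex tumor throughout — in the
2D solvers and in the radial closed form — because that is the orientation
under which the surface-tension term of the dispersion relation damps
modes `k >= 2`; the opposite sign, tested explicitly during development,
makes bulges attract flux and fragments the tumor.

## Numerical choices

**Lattice and fields.** A Cartesian 4-connected lattice with the 5-point
Laplacian; Dirichlet data are eliminated into the right-hand side
(`assemble_laplacian()`). The oxygen system never changes shape, so its
factorization is cached per grid. Rim curvature is estimated from
circumscribed circles through vertices `i - w, i, i + w` of the
marching-squares contour with a resolution-adaptive window, then mapped to
rim voxels by kernel-weighted averaging (bandwidth 1.5 cells) and clamped
to `1/(3h)`: pointwise nearest-vertex lookup would hand adjacent rim
voxels jumpy Dirichlet values and inject spurious tangential velocities of
order `sigma dC / h`.

**Movement rates.** The edge flux `I = p_i - p_j` integrates the pressure
gradient over a shared edge and is therefore an area flux; since one cell
occupies `h^2`, events fire at `D * max(I, 0) / h^2`. This conversion makes
the realized boundary speed equal the Darcy velocity independent of
resolution, which is what allows lattice and mean-field runs to be
compared at all. With `D1 = 1`, division (rate 1 per relaxed voxel)
against rim relaxation (rate `D1` per excess cell) equilibrates at roughly
half of the proliferative rim doubly occupied, which slows the lattice
model's effective clock by a factor of about 2.7 relative to the
mean-field model — precisely the ratio between the lattice and effective
mean-field parameter sets shipped in `preset()` (`mu_death` 0.5 vs 1.35;
`lambda` 1 vs 1.15, the latter also absorbing the extra oxygen drawn by
doubly occupied voxels). Cross-model comparisons therefore rescale lattice
time by the printed ratio `1.35 / 0.5 = 2.7`.

**Field refresh cadence.** Pressure is re-solved after every event that
changes its sources or domain. Oxygen and rim curvature are refreshed on a
batched cadence (`dt_fields = 0.05`, well below the unit proliferation
time): oxygen is quasi-stationary and drifts on the slow growth timescale,
and per-event refreshing is available by shrinking `dt_fields`.

**Mean-field solver.** The density is advected with superbee-limited
upwind fluxes (monotone/TVD; plain first-order upwind's anisotropic
diffusion visibly squares off the rim), with a combined-CFL step bound of
half a cell. The conditional oxygen sink is an obstacle problem —
`c >= kappa_death`, with full consumption where the constraint is slack —
solved by projected red-black SOR, warm-started across steps; the contact
set *is* the necrotic region (on the core the converged field sits at the
threshold, so classifying by a strict inequality on the values is
boundary-sensitive and can erase necrosis entirely). Growth, pressure
sources and oxygen sinks all act at unit class rates on the tumor domain
(`rho >= 0.5` of a 5-point-smoothed density): at saturated density the
advection divergence then cancels the growth term exactly, so `rho = 1` is
a fixed point of the update, the interior stays saturated, and the
interface self-sharpens. Rim cells that overfill because the limited
reconstruction exports sub-saturated fluxes redistribute their excess to
unsaturated neighbors instead of losing it to clipping.

**Tolerances and degeneracies.** Root finding in the zonation relations is
bracketed (both relations are monotone) to residuals below `1e-10`;
`sigma_stable()` exploits the affine dependence of `Lambda(k)` on `sigma`
and needs no iteration; branch degeneracies (`r_n = 0`, `r_q = r_n`,
`theta_q = theta_n`, `D_ext = Inf`) are evaluated as analytic limits.

## What the generators emulate — and what they do not

`make_initial_disc()` builds the standard initial condition: a disc of
living cells (`r0 = 0.25` by default) optionally perturbed by a single
cosine mode (`eps = 0.05` for the mode-growth experiments, matching the
reference setting). `preset()` ships the published parameter sets; surface
tension is experiment-specific (`sigma_stable()` and the sufficient bound
`r_p^3 / 6` guide the choice). The mean-field noise amplitude defaults to
`1e-3` — the reference description says only that the noise is small.

Problem sizes used by the test suite are chosen for a single desk CPU:
lattice runs at `h = 0.03`–`0.04` (a stationary tumor spans roughly 20–25
voxels across) and mean-field runs at `h = 0.02`. At these resolutions the
discreteness itself is a strong noise source: a lattice tumor's rim
carries mode amplitudes of order one voxel, so its roundness fluctuates
around 0.7–0.9 rather than the near-1 values a finer grid would give, and
the lattice model holds approximate radial symmetry only for a limited
window (to `t` of order 10 lattice time units) even at stabilizing surface
tension. Comparisons against the radially symmetric solution are therefore
made after the zonation transient and before symmetry degrades, and the
necrotic radius of the mean-field solver carries a half-cell quantization
that biases its late-time equilibrium area low at `h = 0.02`. For measured
boundary-mode growth rates the lattice noise acts as phase diffusion: a
coherent-ensemble control (averaging radial profiles across runs seeded
with a common perturbation phase) shows the coherent mode amplitude barely
grows at `h = 0.04`, so per-run amplitude fits on the lattice model
underestimate the dispersion-relation rates at this resolution while the
mean-field measurements reproduce them. Passing
tests at these scales demonstrate the implemented mechanics and their
agreement with the analysis in the resolved regimes; they do not certify
quantitative behavior at resolutions or horizons beyond those exercised.

## Known limitations

* Solvers implement the free-flowing external medium (`D_ext = Inf`), the
  regime of all shipped experiments; the analysis functions accept any
  `D_ext`.
* The mean-field representation is sharp-interface-by-threshold; formal
  level-set tracking, higher-order advection and 3D geometry are out of
  scope.
* Detached cell clusters are flagged (contours report their component
  count) and the largest component is measured; mode analysis refuses
  non-star-shaped contours rather than guessing.
* The translation between lattice and effective mean-field parameters is
  shipped as the published preset values; the package does not re-derive
  it.
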