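---
title: "Receptor dimerization equilibria and response-heterogeneity scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor dimerization equilibria and response-heterogeneity scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerscale)
```

## Scientific problem

Cells sense extracellular ligands through receptors whose abundance varies
from cell to cell, so a population exposed to a uniform ligand dose responds
heterogeneously. How strongly receptor variability propagates into response
variability depends on the receptor architecture: whether the signaling unit
is a single ligand-bound receptor or a ligand-induced dimer. This package
implements the equilibrium binding models for the main architectures, a
*local scaling* metric quantifying the propagation, population simulations
that turn the scaling into measurable coefficients of variation (CV), and a
general mass-action solver that both cross-checks the closed forms and
handles architectures without convenient closed forms.

## Models

All models are mass-action binding equilibria written with *association*
constants, under the default assumption that free ligand concentration `C`
is clamped (an effectively infinite extracellular reservoir). Receptor
amounts are in arbitrary receptor units (ARU), ligand concentrations in
arbitrary concentration units (ACU); association constants carry the inverse
units so all equilibrium relations are dimensionally consistent.

* **AL (monomeric):** `A + L <-> F` with `F = K_P * C * A` and conservation
  `A + F = A0`. Closed form `F = A0 * K_P*C / (1 + K_P*C)`.
* **ALA (homodimer, sequential):** `A + L <-> P`, `P + A <-> F` with
  `P = K_P*C*A`, `F = K_F*A*P`, conservation `A + P + 2F = A0`.
* **LAAL (two-ligand homodimer):** `A + L <-> P`, `P + P <-> F` with
  `F = K_F*P^2`, same conservation.
* **ALB_SEQ (heterodimer, sequential):** `A + L <-> P`, `P + B <-> F` with
  conservations `A + P + F = A0` and `B + F = B0`.
* **ALB_NONSEQ (heterodimer, either subunit binds first):** adds
  `B + L <-> P_B`, `P_B + A <-> F`; the two routes to `F` form a
  thermodynamic cycle, so the user-supplied constants must satisfy detailed
  balance `K_P * K_F = K_PB * K_FB` (checked to relative `1e-6`, reflecting
  the limited precision of user-entered constants). Solved numerically.
* **Competition:** an activator and a zero-activity inhibitor share the same
  receptor pool (`A + P_L + 2F_L + P_I + 2F_I = A0` for the homodimer).
  Solved numerically.

The downstream response is `E = e * F^n` with ligand-specific activity `e`
and readout exponent `n` (default 1, linear).

## Numerical choices

* **Closed forms.** The homodimer and heterodimer equilibria reduce to
  quadratics. We use the cancellation-stable root forms, e.g. free subunits
  `A = 2*A0 / (b + sqrt(b^2 + 8*phi*A0))` with `b = 1 + K_P*C` for the
  homodimers, and the smaller root `F = 2c / (b + sqrt(b^2 - 4ac))` for the
  heterodimer, so extreme parameter ratios (groups spanning `1e-6`–`1e6`)
  lose no precision to subtraction. Conservation residuals are attached to
  every solution and tested to relative `1e-9` across `1e4` random draws.
* **Network solver.** Every species is a monomial in the free "base"
  species (one per conservation law), making the conservation residuals
  posynomials. `solve_equilibrium()` runs a damped Newton iteration on the
  logarithms of the base amounts (relative tolerance `1e-12`, at most 200
  iterations, step halving, bisection fallback in one dimension) and
  refuses to return solutions whose relative residual exceeds `1e-9`.
  Degenerate totals (zero) are handled exactly rather than asymptotically.
  A vectorized one-dimensional Newton path solves per-cell competition
  populations efficiently.
* **Local scaling.** `S = d ln E / d ln A0` is computed by central
  differences on `ln F` with step `h = 1e-4` in log-space (truncation error
  `O(h^2) ~ 1e-8`, far below reported tolerances) and multiplied by `n`.
  Because the derivative is taken on `ln F`, the activity rate `e` cancels
  *exactly*: `S` is bit-identical across activities, not merely equal to
  tolerance. At `F = 0` the scaling is undefined and an error is raised
  rather than a sentinel returned.
* **Derived closed forms.** For the homodimer,
  `S = 2 / (1 + 2F/A0)`: a function of the bound fraction alone, which is
  the single-ligand collapse. For the heterodimer,
  `S_A = A0*(B0 - F) / (A0*B0 - F^2)` and symmetrically `S_B`; they obey the
  sum rule `S_A + S_B = S_joint`. Both are validated against the numeric
  derivative to `1e-4` across random draws and used as fast paths in the
  scan tables.

## Population simulations

Per-cell receptor totals are gamma distributed, parameterized by mean and
standard deviation via moment matching (`shape = (mean/sd)^2`,
`scale = sd^2/mean`). Draws use `qgamma` on a common uniform sample so
two-subunit populations can be made rank-correlated through a Gaussian
copula; `sd = 0` yields a constant population. All simulations are seeded
and bit-reproducible.

Comparing ligands fairly requires matching their *mean* population response:
`match_mean_activity()` sets `e = target / mean(F^n)` exactly (closed form,
no iteration), reusing the same receptor sample for every ligand so panel
differences reflect binding parameters only.

### Panel design

The package ships representative panels chosen from model structure, not
fitted to any simulation output:

* `al_affinity_panel()`: five monomeric ligands with affinities log-spaced
  over four decades at unit concentration — identical CV despite very
  different mean occupancy, because the monomeric response is linear in
  `A0`.
* `ala_bound_fraction_panel()`: homodimer ligands at the partial-binding
  midpoint (`K_P*C = 1`) with `K_F` chosen so the reference-cell bound
  fraction hits `{0.1, 0.3, 0.5, 0.7, 0.9}` (from `f`, free subunits are
  `A = A0*(1-f)/2`, hence `K_F = 2f/(A0*(1-f)^2)`). The extremes `f = 0, 1`
  are unattainable limits. At population noise `sd = 0.5` a literally pure
  quadratic ligand would push the CV ratio slightly above the small-noise
  twofold bound (higher moments of the gamma distribution enter), so the
  default panel spans the symmetric deciles; the twofold bound is
  *approached* with extreme panels at small receptor noise, where the
  delta-method regime `CV(E) ~ S * CV(A0)` holds.
* `alb_occupancy_panel()`: weak, intermediate and saturating heterodimer
  ligands.
* `heterodimer_population_set()`: four two-subunit populations probing
  subunit imbalance and variability. With a tight limiting subunit and an
  abundant, highly variable partner, weak ligands read out the variable
  subunit (`S_B` near its maximum) while saturating ligands read out the
  tight one (`S_B` near 0), so the ligand-dependent CV ratio grows far
  beyond the homodimer's twofold bound (a delta-method estimate for the
  shipped `abundant_variable` population is ~14).

Problem sizes (grid resolutions, cell counts, panel sizes) are package
defaults chosen to keep Monte-Carlo error well below the tolerances we
state; they can all be overridden.

## Competition and tunable heterogeneity

A zero-activity competitive inhibitor breaks the single-ligand collapse:
the competition scaling is `S = 2/(1 + 2(F_L + F_I)/A0)`, so at a fixed
activator-complex amount `F_L` the inhibitor adds occupancy that lowers
`S`. `hold_complex_constant()` re-tunes the activator concentration (by
root-finding on `log10 C_L`) so `F_L` stays fixed while the inhibitor dose
rises; along this path the population CV falls monotonically — response
heterogeneity becomes tunable without changing the mean signal.

## Extensions

* **Receptor turnover** (`solve_with_turnover()`): constant production,
  first-order degradation, with complexes optionally degraded faster than
  free subunits; binding stays equilibrated on the slow turnover timescale.
  Uniform degradation reduces exactly to the fixed-total model with
  `A0 = production/degradation`; the scaling is then taken with respect to
  the production rate.
* **Finite ligand pools** (`solve_finite_ligand()`): the clamped-`C`
  assumption is replaced by a ligand conservation law and solved with the
  network solver; depletion shifts even the monomeric scaling below 1.
* **Nonlinear readout** (`scaling_with_nonlinearity()`): `E = e*F^n` gives
  `S(n) = n * S(1)` by the chain rule, verified against direct
  finite differences.

## What the simulations do and do not emulate

The package models *equilibrium* binding with static per-cell receptor
levels: no binding/trafficking kinetics, no temporal gene-expression noise,
no spatial effects, no downstream signaling cascade beyond the power-law
readout. CVs are exact functionals of the sampled population, not
measurement-noise-corrupted observables. The gamma distribution is a
standard model for protein expression variability, not a fitted empirical
distribution.

## Reproducibility

Every runner logs the package version, config path, config MD5 and seed.
Configs (YAML or JSON) reject unknown keys. The test suite validates the
closed forms against the independent network solver and a brute-force
bisection oracle, and all stochastic results are fixed-seed reproducible
byte for byte.
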