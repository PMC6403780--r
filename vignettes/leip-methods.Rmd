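---
title: "Effective short-range parameters for charge regulation in flexible weak polyelectrolytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective short-range parameters for charge regulation in flexible weak polyelectrolytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A linear weak polyelectrolyte is described at two coupled levels:

* **Ionization (site binding, SB).** `N` identical sites, each protonated
  (`s_i = 1`) or not (`s_i = 0`), with reduced chemical potential
  `mu = pH - pK` per bound proton. All energies in this package are decimal
  logs: a term `E` in the reduced free energy contributes a statistical
  weight `10^-E`, so pK arithmetic is exact.
* **Conformation (rotational isomeric states, RIS).** Rotatable backbone
  bonds take three states - trans and the two gauche states, at torsions
  180 and +/-60 degrees - with gauche weight `sigma`
  (`p_sigma = -log10(sigma)`) and optional couplings `psi`/`omega` between
  consecutive gauche pairs of equal/opposite handedness.

The joint SBRIS chain used throughout is the *minimal model*: sites every
`spacing = 3` backbone nodes (bond length 0.2 nm, valence angle 120
degrees), with exactly one rotatable bond per inter-site segment - the
middle one; the flanking bonds are frozen trans. Adjacent protonated sites
interact through the connecting bond with energy `eps_t` (trans) or `eps_g`
(gauche); `u_g = 0` (`eps_g -> infinity`) forbids the gauche state between
two charges. A *roto-microstate* is a pair `(s, c)` of ionization and
conformation vectors; [`reduced_free_energy()`] evaluates its full energy,
returning `+Inf` for forbidden states so that enumeration and Monte Carlo
share a single energy function.

Distant charges (site pairs separated by at least two site positions)
interact through the screened Debye-Hueckel potential
`phi(d) = (1/ln 10) (lB / d) exp(-kappa d)` with `lB = 0.7` nm (water,
298 K - temperature enters only through this default) and
`kappa^-1 = 0.304 / sqrt(I)` nm. Adjacent sites interact *only* through
`eps_t`/`eps_g`; the pair sets are disjoint by construction, in the solver
and in the simulator alike, so nothing is double counted.

## Exact short-range machinery

With only short-range terms the chain is a one-dimensional transfer-matrix
system. The package implements the 2x2 site matrix (rigid SB chain), the
3x3 bond matrix (neutral RIS chain) and the 6x6 super-matrix of the SBRIS
chain, in which each 3x3 conformational block is decorated with the
activity `z = 10^(pK - pH)` and the diagonal short-range factor
`diag(u_t, u_g, u_g)` of the bond it introduces. Three numerical choices
matter:

* **End convention.** With one super-matrix per rotatable bond the first
  site's activity has no matrix of its own; it is absorbed into the start
  vector `r = (q, z q)`. This is the single committed convention, and it is
  pinned by a release-blocking test: the super-matrix partition function
  must equal brute-force enumeration over all `2^N 3^(N-1)`
  roto-microstates to 1e-10 on every small system.
* **Log-domain scans.** Running vectors are renormalized after every
  multiplication and a decimal-log scale is accumulated. At `N = 50` and
  extreme pH the raw products span hundreds of orders of magnitude;
  renormalization keeps every observable finite without changing ratios.
* **Projector insertion, not finite differences.** Site- and bond-resolved
  observables (`theta_i`, gauche probabilities, pair correlations
  `<s_i s_j>`, and the covariances that form the solver's Jacobian) replace
  one transfer matrix by its protonated- or gauche-selecting part. This is
  exact, so the solver's inner loop needs no step-size tuning; a central
  finite difference in the per-site chemical potential is kept in the test
  suite as an independent cross-check of the projector route.

## Distance moments

The long-range energy of a flexible chain requires inter-site distances
averaged over the conformational ensemble. The package evaluates
`<d_ij^2>` exactly by a generator contraction: each inter-site segment has
a state-dependent rigid transform (displacement and frame rotation,
extracted once from the explicit geometry builder), and a 5x5 generator per
state accumulates `|sum of segment displacements|^2` through the same 6x6
weighted scan (30x30 blocks). This is why the rotatable bond must be one of
the first `spacing - 1` bonds of its segment: the torsion of a segment's
last bond acts beyond the next site and would break the segment-local
transfer structure. Sampling appears nowhere in this path; a Monte Carlo
estimate of the same average is used only as an independent oracle in the
tests.

The long-range average itself uses the factorized first-moment
approximation `phi0 = sum phi(sqrt(<d_ij^2>_0)) <s_i s_j>_0`. Two open
choices were resolved as follows, and both alternatives remain available
for sensitivity checks:

* the distance average is taken over the **full** ensemble, not conditioned
  on the pair being protonated, because the factorized form reads as a
  product of independent averages (`conditional_distance = TRUE` switches
  to the conditioned variant; on enumerable systems the difference is well
  below the method's own truncation error);
* higher distance moments are out of scope; `phi(sqrt(<d^2>))` is the
  committed first approximation.

One consequence worth stating plainly: on rigid chains `phi0` is exact and
`gb_bound()` is a true upper bound on the exact `Omega` for any shifts.
On flexible chains the factorized `phi0` slightly *underestimates* the
exact long-range average (the screened potential is convex and
decreasing), so the reported flexible `Omega~` can undershoot the exact
`Omega` by up to the truncation error; the tests verify that the
inequality is restored when `<Delta H>_0` is enumerated exactly.

## The variational correction

The Gibbs-Bogoliubov principle bounds the exact semi-grand potential by
`Omega <= Omega0 + <Delta H>_0`, where `Omega0` belongs to a short-range
trial Hamiltonian with shifted parameters: `pK -> pK - x` and, for the
flexible chain, `p_sigma -> p_sigma + x_sigma` (rigid chains instead shift
the nearest-neighbour energy, `epsilon -> epsilon + x_eps`). With the sign
convention fixed so that a repulsive long-range field gives `x >= 0`
(protonation becomes harder, `pK_eff = pK - x`), the bound reads

```
Omega~ = Omega0(x, x_sigma) + ln 10 * (phi0 - x nu0 - x_sigma g0)
```

and stationarity yields the coupled system `J (x, x_sigma)' = grad phi0`
with `J` the (negative, ln 10-scaled) covariance matrix of `(nu0, g0)` -
all entries exact projector averages. `x` is the mean long-range cost of
binding one proton at constant gauche count; `x_sigma` the cost of rotating
one bond into gauche at constant charge. Both vanish at high pH and
whenever the long-range term is disabled, which the solver short-circuits
exactly.

Numerics of the solver:

* damped Newton on the 2x2 residual with a finite-difference Jacobian of
  the residual map; the `phi0` partials use central differences with step
  1e-4 (decimal-log units). Convergence is declared when the scaled
  residual (an error estimate in shift units) falls below 1e-8, with at
  most 50 iterations; non-convergence is flagged in the output, never
  silent.
* **Continuation.** Titration grids are solved from high pH downward, each
  point warm-started from the previous solution. This keeps the solver on
  one branch across the sharp conformational transition; with the gauche
  correction switched off (`correct_sigma = FALSE`) the titration curve at
  low ionic strength develops a genuine branch jump - the
  spurious-transition artifact of the under-parameterized correction - and
  the package reports the continuation branch and flags non-monotone
  `theta` through a warning and the `nonmonotone_theta` attribute rather
  than hiding it.
* **Degeneracies.** When the gauche degrees of freedom carry no variance
  (`sigma = 0`, or saturated ensembles) the `x_sigma` row of the system is
  singular; the solver then pins `x_sigma = 0` and solves the 1-D problem,
  which also makes the frozen flexible chain reduce to the rigid solver
  exactly (a tested property, using the rigid solver's distance-matrix
  override).

## The Monte Carlo standard

The semi-grand canonical (constant-pH) Metropolis simulator is the
validation standard: explicit 3-D coordinates, full Debye-Hueckel pair
sums, no approximations beyond the model itself. Trial moves are a bond
rotation (probability 0.999) that rigidly rotates everything downstream of
the bond, or a protonation toggle (0.001); within a type the target is
uniform, and a proposed bond state is uniform over the two others.
Acceptance is `min(1, 10^-dF)`. Energy differences are incremental - bond
moves re-sum only the cross pairs, site moves only the pairs involving that
site - and a debug mode recomputes the total periodically; the worst drift
observed in the tests is at machine-precision level. Forbidden moves
(`u_g = 0` with both flanking sites charged) have `dF = +Inf` and are
rejected without special-casing. Each replica starts from the all-trans,
fully deprotonated state (the high-pH reference; the protocol source is
silent on initialization); replica `k` uses seed `seed + k - 1` through R's
RNG, so runs are bit-reproducible. The sampling stride is configurable
because the protocol source does not state one; the default records every
tenth configuration.

The default `mc_config()` is the full production protocol (5e7 + 4.5e8
configurations, 8 replicas). The tests and the acceptance script run
scaled-down problems chosen to keep everything on one CPU in minutes while
leaving the statistical errors small compared with the tolerances tested:
20-site chains with ~2e6 configurations and 4 replicas for the
simulator-versus-theory checks, 100 randomized small systems for the
enumeration equalities, 12-14 sites for the rigid-chain bound and accuracy
checks, and the full 50-site chain (where no enumeration is needed) for
the titration landmarks.

## What the tests do and do not show

All validation inputs are generated by the package itself - the chain
builder, the enumeration oracles and the simulator; there is no external
data. Passing tests show that the implementation is internally exact where
it claims exactness (transfer matrices, distance moments, incremental
energies), that the variational bound and its stationarity hold against
enumeration, and that the effective-parameter model reproduces the
simulator's titration and conformer curves for the minimal model's
conditions. They do not show that the minimal model describes any
particular real polyelectrolyte: excluded volume is neglected, ions enter
only through the screening length, sites are identical, and only one bond
per segment rotates. Known limitations inherited from the method: the
factorized `phi0` is a first-moment approximation (its error, not
statistical noise, dominates the residual LEIP-vs-MC gap of up to ~0.01 in
`theta` at low ionic strength), and corrections beyond
`(x, x_sigma)`/`(x, x_eps)` - triplet or next-nearest-neighbour shifts -
are not implemented.

## Worked example

```{r, eval = FALSE}
library(leip)
chain <- chain_spec(50, spacing = 3, bond_length = 0.2, bond_angle = 120)
params <- energy_params(pK = 9, sigma = 10, eps_t = 1, u_g = 0)

# LEIP titration at four ionic strengths
tt <- titrate(chain, params, pH = seq(12, 2, by = -0.25),
              ionic_strength = c(1, 0.1, 0.01, 0.001))

# scaled-down Monte Carlo cross-check at one state point
est <- run_mc(chain_spec(20), params, solution_conditions(8, 1),
              mc_config(steps_equilibration = 2e5,
                        steps_production = 2e6, n_replicas = 4))
```
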