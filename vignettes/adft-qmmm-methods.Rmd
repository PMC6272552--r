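---
title: "Auxiliary-density QM/MM: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auxiliary-density QM/MM: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
energy models, the approximations and their domains of validity, the
tunable parameters and why their defaults are what they are, and the
places where the design was genuinely open and a choice had to be made.
Nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The electronic model

The QM region is described by restricted closed-shell auxiliary density
functional theory. Orbitals are contracted Cartesian Gaussians (s, p and
d shells; every Cartesian component is individually normalized, and
contractions are renormalized to unit self-overlap). The density is
fitted variationally into primitive Hermite Gaussian auxiliary functions
$\bar c$ with total Hermite index up to 2, normalized to unit
self-overlap with the closed-form one-dimensional factor
$[(\zeta/2)^t (2t)!/t!\,\sqrt{\pi/2\zeta}]^{-1/2}$. The fitting
coefficients solve $G\,x = J$ with the Coulomb metric
$G_{\bar c\bar d} = \langle \bar c \| \bar d\rangle$ and
$J_{\bar c} = \sum_{ab} P_{ab} \langle ab \| \bar c\rangle$, through an
eigen-pseudoinverse with relative cutoff $10^{-10}$. Because the fit is
variational, the fitted Coulomb energy $x\cdot J - \tfrac12 x\cdot Gx$
approaches the exact electronic repulsion from below — a bound the test
suite checks against a brute-force four-center oracle on randomized
densities.

Exchange-correlation is the local density approximation — Dirac exchange
with VWN (parameterization V) correlation — evaluated **on the fitted
density**, which is what makes the whole SCF auxiliary-density-driven:
three-center integrals are the most expensive electronic quantity, and
four-center integrals never appear outside test oracles. Points where
the fitted density is negative (fitted densities are not pointwise
positive) are clamped to zero and counted in the result object. The
Kohn–Sham matrix is assembled as the exact derivative of this energy
with respect to the density matrix,
$K = H + \sum_{\bar c}\langle ab\|\bar c\rangle\,(x + z)_{\bar c}$ with
$z = G^{-}v_{xc}$; this derivative identity, not any particular
recursion, is the binding contract and is verified by central finite
differences.

A density-fitted exact-exchange energy (full-domain limit) is available
as an energy-only diagnostic; with an auxiliary set spanning the orbital
products it reproduces brute-force four-center exchange. Locality
restriction of the exchange domains is exposed as a hook but has no
default: a meaningful cutoff needs system classes larger than this
package targets.

### Integral evaluation

All exact integrals use the Hermite (McMurchie–Davidson-style) scheme:
Gaussian-product expansion coefficients by recursion, Coulomb kernels by
Boys-function downward recursion (series branch below $x = 40$,
asymptotic branch with upward recursion above; the switch point keeps
both branches at ~1e-15). The contract for every integral class is
agreement with independent oracles written in the tests — Gauss–Hermite
quadrature for overlap/kinetic, erf-based closed forms for s-type
Coulomb integrals, the $\zeta\to\infty$ delta-function limit linking
three-center integrals to nuclear attraction, and base R symbolic
differentiation for the $1/R$ derivative tensors.

## 2. Electrostatic embedding and the near/far machinery

MM point charges enter the core Hamiltonian as one-electron operators.
For each QM atom, sites are split into near field (exact integrals) and
far field, where the integral is replaced by the order-8 multipolar
expansion over raised-angular-momentum overlaps and $1/R$ derivative
tensors $T_{AD}(m)$. Because $T$ depends only on the two centers, the
far-field charge sums $\sum_D Q_D T_{AD}(m)$ are accumulated once per
(QM atom, $m$) before the orbital loops; the per-pair near lists are
unions of two per-atom lists, with a small per-pair correction for sites
near one atom but not the other. An alternative per-site accumulation
path exists purely as a cross-check and agrees to 1e-12.

**Classification radii.** The amplitude condition
$\sum_k |c_k| R^l e^{-\zeta_k R^2} \le \tau$ (solved numerically;
`shell_extent()`) describes where an orbital's amplitude is negligible,
but amplitude decay alone does not bound the truncation error of an
order-8 Taylor expansion — the convergence radius of the $1/R$ series
around the expansion center is limiting, and both scale as
$1/\sqrt{\zeta_{\min}}$. Classification therefore uses the amplitude
radius multiplied by a convergence safety factor (`conv_factor`, default
3). The factor was fixed by a randomized sweep over s/p/d pairs with
exponents 0.1–50 against the $\tau$ accuracy target, with about a 2x
margin; the property tests then verify that sites just outside the
classification radius are expanded to within $2\times10^{-10}$. Distance
ties at the boundary count as near (conservative, deterministic).
Three-center ERIs are classified the same way against the sum of the
shell's classification radius and the auxiliary function's potential
extent, the radius where the non-multipole remainder
$N(\pi/\zeta)^{3/2}\,\mathrm{erfc}(\sqrt{\zeta}R)/R$ falls below $\tau$.

**SCF schemes.** `conventional` stores all exact three-center ERIs,
`direct` recomputes them exactly every cycle, and `mixed` stores
near-field ERIs and recomputes far-field ones from the double asymptotic
expansion every cycle (the embedding Hamiltonian likewise uses the
near/far split only in the mixed scheme). The flagship invariant is that
all three converge to the same energy to well below 1e-8 hartree, which
the acceptance checks measure for embedded water.

**Near-field growth.** For spatially extended systems the number of
near-field ERIs grows linearly with system size once the chain length
exceeds the near radius. With $\tau = 10^{-10}$-honoring radii, the near
radius is ~20–45 bohr (the diffuse H primitive alone has a 12-bohr
amplitude radius), so n-alkanes up to roughly C32 are pre-asymptotic:
doubling counts there still reflect the quadratic regime, and the
doubling ratio does not settle into the ~2 band until C64 to C128. The
acceptance script reports both the short-chain ratios and the C128/C64
ratio so this crossover is visible rather than hidden.

## 3. Force field, coupling and boundaries

The MM energy is the standard six-term form: harmonic bonds, angles and
Urey–Bradley 1-3 terms (all with the $k/2\,(x-x_0)^2$ convention stated
in the parameter files), cosine dihedrals $V(1+\cos(n\phi-\delta))$,
12-6 Lennard-Jones in $\varepsilon/R_{\min}$ form, and point-charge
Coulomb, evaluated over full double loops with no cutoff (systems here
are clusters of at most a few thousand atoms). Exclusions are 1-2 and
1-3, with 1-4 at full strength; parameter files use kcal/mol, Angstrom
and degrees and are converted to atomic units on read. All gradients are
analytic and validated against finite differences; net force and torque
vanish on isolated systems.

The additive QM/MM energy assigns: intra-QM physics to the SCF,
QM–MM electrostatics to the embedding (so nonbonded MM pairs touching a
QM atom are skipped classically), QM–MM dispersion/repulsion to the
ε/R_min Lennard-Jones coupling with Lorentz/geometric combination — with
the force-field exclusion list honored across the boundary, since a
bonded QM–MM pair at covalent distance would otherwise sit on the
repulsive wall — and bonded terms crossing the boundary to the force
field. The MM boundary atom's point charge is excluded from the
embedding field by default (over-polarization guard; configurable).
Subtractive (ONIOM-style) coupling evaluates the capped model region at
both levels with the identical extracted charge field, so replacing the
QM evaluator by the MM one collapses exactly to the plain MM energy — a
regression test.

Link atoms are hydrogens at fraction $\alpha$ along the boundary bond;
$\alpha$ defaults to the ratio of equilibrium bond lengths
(QBA–H over QBA–MBA, e.g. 1.090/1.530 for a C–C cut) and is
overridable per bond. Printed definitions of $\alpha$ as a ratio of
vectors are dimensionally inconsistent; the scalar ratio implied by the
placement formula is used. Link forces are projected by the chain rule,
$(1-\alpha)$ to the QM boundary atom and $\alpha$ to the MM boundary
atom. QM nuclear gradients are central finite differences of the SCF
energy (two SCF evaluations per degree of freedom — acceptable at
fixture scale; analytic ADFT gradients are out of scope); MM-site
gradients are analytic Hellmann–Feynman plus nuclear terms, which is
exact at SCF stationarity.

FIRES: the inner radius is the largest inner-tag distance from the
reference atom; only outer molecules **inside** the sphere are
penalized (the harmonic sum runs over intruders, not all outer
molecules — the restraint's purpose is to keep them out), and the
reaction force lands on the boundary inner molecule, making the total
restraint force zero identically. The restraint force constant in the
shipped checks is 100 kcal/mol/Å², inside the range effective for ion
solvation studies.

## 4. Sampling

MD is velocity Verlet; the canonical ensemble uses a Langevin thermostat
in the BAOAB splitting (friction default 0.1 fs⁻¹), replacing chain
thermostats and extended-Lagrangian Drude propagation: Drude particles
are instead relaxed to their self-consistent minimum at fixed nuclei
(BFGS on the analytic gradient, residual below 1e-8), which reproduces
the closed forms $d = q'E/k_d$ and $\alpha = q'^2/k_d$.

FEP uses the dual-topology convention $H(\lambda) = \lambda H_A +
(1-\lambda)H_B$ with $\lambda = 1$ being state A, 11 windows by default,
forward and backward passes, exponential averaging per window and
standard errors by 3-block averaging. The replica-exchange acceptance
uses the standard Metropolis exponent **including** $\beta$ — an
exponent without the inverse temperature is dimensionally inconsistent
for energies in physical units — and neighbor pairs follow the
alternating odd/even schedule; accepted swaps exchange the
configurations of the pair (equivalent, for all logged observables, to
swapping the parameter values). All stochastic components are
reproducible under fixed seeds.

The harmonic-alchemy benchmark ($k: 1\to4$ at $k_BT = 1$, 11 windows,
1e5 exactly Boltzmann-distributed samples per window) has the closed
form $\Delta F = \tfrac12\ln 4$; recovery within three block-averaged
standard errors, and forward/backward hysteresis consistent with zero,
are the sampling module's flagship checks.

## 5. Fixtures: what they emulate and what they do not

The generator builds water droplets (rigid 3-site geometry, 0.9572 Å
and 104.52°, SPC charges, packed by rejection sampling at liquid-like
density with a 1.5 Å minimum intermolecular distance), ideal-geometry
n-alkanes, ion-in-droplet systems (21 waters covers about two solvation
shells around a monovalent ion) and harmonic toys. They provide
plausible, deterministic cluster geometries — not equilibrated liquid
structure, no periodic boundary conditions, no experimental-quality
force-field parameters. Passing tests therefore demonstrate the
correctness of the energy/gradient machinery and the statistical
estimators on realistic-scale inputs; they do not validate force-field
accuracy against real solvation data.

## 6. Numerical choices and known limitations

* **Grid.** Exchange-correlation integration uses per-atom
  Gauss–Legendre radial rules under the Becke mapping (40 points) with a
  product angular rule (9 polar x 18 azimuthal) and Becke fuzzy-cell
  weights (3 switch iterations, no size adjustment). A single-center
  rule integrates normalized s-Gaussians to 1e-6 or better; Becke
  partitioning limits tight off-center features on multi-center grids to
  ~1e-4 relative, a known property of this grid class. Every internal
  contract (derivative checks, scheme equality, oracle comparisons) uses
  the same grid on both sides, so grid error cancels in all of them.
* **Conditioning of the fitting metric.** The default spd auxiliary sets
  (even-tempered, ratio 2.5, spanning $[\zeta_{\min}, 2\zeta_{\max}]$)
  give Coulomb-metric condition numbers around 1e7–1e8. That is
  harmless for energies — the Coulomb fit is variationally insensitive —
  but it amplifies the curvature of the XC term along density-response
  directions enough that finite-difference probes of derivative
  identities at steps of 1e-4 to 1e-5 pick up 1e-5-level noise even at
  perfect stationarity. Derivative contracts are therefore verified with
  the s-only sets (condition ~1e4–1e6), where the same analytic code
  agrees with finite differences to 1e-7 or better.
* **SCF convergence** is DIIS on the orthonormal-basis commutator with
  condition-based pruning of stale error vectors and damped mixing for
  the first cycles; convergence requires RMS density change below 1e-7
  (default) and energy stability. Non-convergence returns an explicit
  flagged result carrying the full cycle trace.
* **Degenerate inputs.** Coincident charged sites in the nuclear terms,
  coincident centers in $1/R$ tensors, selectors matching no atoms,
  unknown elements and malformed file rows all raise errors naming the
  offending entity. A site exactly on a QM nucleus is near-field by
  construction and its exact integral is finite.
* **Scope.** Restricted closed shell only; s/p/d orbitals and Hermite
  index ≤ 2; LDA only; no periodic boundary conditions, Ewald sums,
  SHAKE constraints, or analytic QM nuclear gradients. Problem sizes in
  the shipped checks: water monomers for SCF contracts, 2000-site charge
  clouds for embedding, C8–C128 alkanes for integral counting, a
  21-water ion droplet over 1000 MD steps for the boundary restraint,
  and 1e5-sample windows for the free-energy estimators.
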