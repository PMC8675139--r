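---
title: "Linear atomic cluster expansion force fields: models, fitting, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear atomic cluster expansion force fields: models, fitting, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acemol)
```

## The model

`acemol` implements body-ordered linear force fields for molecules in vacuum
via the atomic cluster expansion (ACE). The total energy of a configuration is
a sum of site energies,

$$E(X) = \sum_i E_i, \qquad
  E_i = E_0(z_i) + \sum_k c_{z_i k}\, B_k(\mathcal{N}_i)
      + \sum_n c^{\mathrm{pair}}_{n}\, g_n(\mathcal{N}_i),$$

where $\mathcal{N}_i$ is the neighborhood of atom $i$ inside an outer cutoff
$r_\mathrm{out}$, $E_0$ is an element-wise one-body energy, the $B_k$ are
permutation- and $O(3)$-invariant polynomial basis functions, and the $g_n$
are a small auxiliary two-body basis carrying short-range repulsion. The model
is linear in all free coefficients, so fitting is a (regularized) linear
least-squares problem and forces are exact analytic gradients.

The invariant basis is built in three stages:

1. **Density projection.** The neighborhood density of atom $i$, one channel
   per chemical element, is projected onto one-particle functions
   $\phi_{znlm}(r) = R_n(|r|)\,Y_{lm}(\hat r)$, giving the *atomic base*
   $A_{z_i v} = \sum_j \phi_v(r_{ij})$ — a single sum over neighbors.
2. **Products.** Products of $\nu$ atomic-base entries form
   permutation-invariant $\nu$-correlations, i.e. $(\nu+1)$-body functions.
   Because the sum over neighbors is taken *before* the product (the
   "density trick"), the evaluation cost is linear in the neighbor count and
   independent of the body order; the price is self-interaction terms
   (repeated neighbor indices), which are absorbed exactly by the lower-order
   basis functions and verified against an explicit ordered-tuple oracle in
   the tests.
3. **Symmetrization.** Products are averaged over $O(3)$ using generalized
   coupling coefficients over the factors' $m$-indices. The surviving
   invariant combinations form the B-basis. Linear dependencies among them
   are removed by a rank-revealing factorization of their evaluation matrix
   on sampled environments.

The basis is truncated by three parameters: the cutoff radius
$r_\mathrm{out}$, the maximum correlation order $\nu^\max$, and per-order
caps on the polynomial degree $D = \sum_t n_t + w_Y l_t$, with $w_Y$ trading
radial against angular resolution. The angular resolution is not a free
knob: $l_\max = \lfloor \max_\nu D^\max_\nu / w_Y \rfloor$ follows from the
degree caps. Defaults follow common practice for small organics:
$\nu^\max = 4$ for up to three distinct elements ($3$ for four or more),
$w_Y = 2$, and degree caps chosen per fit (package default
`c(12, 10, 8, 6)` balances basis size against accuracy at desk scale).

### Radial basis

The radial functions are $R_n(r) = p_n(x(r))\, f_\mathrm{cut}(r)$ with a
one-dimensional transform, a cutoff envelope, and orthogonal polynomials:

* the transform $x_\mathrm{raw}(r) = ((1+r_0)/(1+r))^q$ (defaults $r_0 = 1.5$
  Å, $q = 2$) amplifies the resolution near the central atom, followed by an
  affine standardization $x = (x_\mathrm{raw}-\mu)/\sigma$;
* the two-sided envelope $\propto (r-r_\mathrm{in})^2 (r_\mathrm{out}-r)^2$
  vanishes with zero slope at the inner and outer cutoff and is identically
  zero outside $(r_\mathrm{in}, r_\mathrm{out})$;
* the polynomials obey a three-term recursion built numerically (Stieltjes
  procedure against 2000-point Gauss–Legendre quadrature) under the measure
  in which the *radial functions* — not the bare polynomials — are
  orthonormal in $x$-coordinates.

The standardization constants $\mu$, $\sigma$ and the envelope amplitude are
fixed, at spec construction, so that this measure has total mass 1, mean 0
and variance 1. That choice makes $p_0(x) = 1$ and $p_1(x) = x$ *exactly* the
first two orthonormal polynomials — reconciling the conventional seed of the
recursion with orthonormality of $\{R_n\}$, which would otherwise conflict.

The inner cutoff $r_\mathrm{in}$ excludes the short-range region where
training data is scarce and high-degree polynomials would oscillate. A
sensible default is the minimum interatomic distance in the training set
minus 0.05 Å, clamped to at least 0.5 Å (the CLI applies this rule).
Short-range physics is instead carried by the auxiliary pair basis, which
uses the same transform and polynomials but a one-sided envelope
$(1 - r/r_\mathrm{out})^2$ that stays active as $r \to 0$. The pair basis
uses the same outer cutoff as the multibody basis by default (configurable);
its polynomial degree defaults to 6, and it is fitted jointly with the
multibody coefficients in one linear system.

### Spherical harmonics and coupling coefficients

Real spherical harmonics are evaluated by regular solid-harmonic recursions
in Cartesian coordinates (orthonormal on the sphere, Condon–Shortley phase
omitted), which are smooth everywhere away from the origin and give analytic
gradients. The invariant coupling coefficients are obtained numerically: for
each sequence of angular momenta, the fixed space of the tensor-product
rotation action is computed as the common null space of $D(Q)\otimes\cdots-I$
over a small fixed set of generic rotations, with inversion handled by
parity (odd total $l$ admits no invariant). The Wigner matrices $D(Q)$ in
the package's real convention are themselves solved exactly from sampled
directions. Couplings are then symmetrized over permutations of identical
factors, orthonormalized, and sparsified (entries below $10^{-12}$ dropped).
This avoids real-harmonic Clebsch–Gordan bookkeeping entirely; correctness
is certified by convention-independent random-rotation tests
(invariance to $10^{-10}$ over hundreds of rotations/reflections).

### Identifiability of the coefficients

For total-energy observations the coefficient vector of a multi-element
model is *structurally* non-identifiable: the features
$\sum_{i: z_i = z}\sum_{j: z_j = z'} R_n(r_{ij})$ are exactly symmetric
under swapping center and neighbor element, so antisymmetric coefficient
combinations lie in the kernel of the energy functional on every dataset.
Predictions are unaffected; regularized solvers simply pick one
representative. Exact coefficient *recovery* experiments (planted-model
tests) therefore use a single-element system, where the kernel is trivial,
and prune the basis on environments drawn from the same distribution as the
training data so the design matrix has full column rank.

## Fitting

The loss is a weighted least-squares functional over per-configuration
energies and per-component forces; with one energy row and $3N$ force rows
per configuration it becomes $\|\Psi c - t\|^2$. Defaults
$w^E = 1\,\mathrm{eV}^{-1}$ and $w^F = 1\,(\mathrm{eV/Å})^{-1}$ weight
energies and forces equally per observation; both support per-configuration
overrides.

Regularization uses a diagonal smoothness prior
$\Gamma_{vv} = \sum_t (n_t^p + l_t^p)$ — a rough estimate of the size of the
$p$-th derivative of each basis function, scaling down high-degree terms.
The default $p = 2$ penalizes curvature; at $p = 0$ the prior degenerates to
a constant per correlation order. Two solvers are provided:

* **LSQR + Tychonov**: the iterative Paige–Saunders solver on the augmented
  system $[\Psi; \lambda\Gamma]$, with fixed iteration caps and tolerances
  (deterministic);
* **RRQR**: pivoted rank-revealing QR of the preconditioned matrix
  $\Psi\Gamma^{-1}$, truncating diagonal values below $\lambda$ and mapping
  back through $\Gamma^{-1}$.

RRQR tends to give better solutions when the system is overdetermined, so
the default (`solver = "auto"`) uses RRQR when rows $\ge 1.2\times$ columns
and LSQR otherwise.

Three one-body strategies are supported, and their differences matter more
for extrapolation than for test error: supplied isolated-atom energies
(exact dissociation limits — the *physical* choice), the training-set
average energy per atom (zero-mean fits), and force-only fitting followed by
a single per-atom constant chosen in closed form to zero the mean signed
per-atom training energy residual.

## The evaluation battery

Test-set error alone hides much of what matters in a force field, so the
package ships protocol implementations that probe the fitted surface:

* **Normal modes** — mass-weighted Hessian by central finite differences of
  the analytic forces (step 0.005 Å, symmetrized), with rigid-body
  translations/rotations projected out (Eckart conditions) before
  diagonalization so the $3N-6$ internal modes are not contaminated by
  finite-difference anharmonicity along the null directions; frequencies in
  cm$^{-1}$ from CODATA constants. The finite-difference step is the main
  numerical dial: at 0.005 Å, orientation dependence of the frequencies is
  of order 0.1 cm$^{-1}$ on stiff modes and shrinks quadratically with the
  step.
* **Constrained dihedral scans** — per grid angle, a stiff harmonic
  restraint (default $10^3$ eV/rad$^2$) drives a BFGS minimization, the
  dihedral is restored exactly by rotation about the bond, and a
  projected-gradient polish (forces projected onto the constraint tangent
  space) finishes to a 0.1° constraint tolerance; points are chained along
  the grid. Angles follow the IUPAC signed convention in $(-180°, 180°]$.
* **Rigid bond scans** — one atom displaced along the bond, all else fixed;
  with isolated-atom one-body terms the dissociation plateau equals the
  fragment-energy sum exactly, by compact support.
* **Langevin MD** — BAOAB splitting, 0.3 fs default timestep, friction
  0.01 fs$^{-1}$ default, all randomness from one seed (bit-reproducible).
  Every step monitors for "holes": the run terminates, flagged, when the
  potential energy falls more than a configurable floor (default 10 eV)
  below the starting energy or any pair distance drops below the inner
  cutoff. The hole criterion is a documented package choice — dynamics that
  reach such regions are already unphysical, and the precise threshold only
  decides how promptly the run is flagged. An equilibrate-then-sample
  routine (defaults: 500 equilibration steps, then samples 200 steps apart)
  reproduces the standard temperature-transfer protocol.

## Synthetic data: what it does and does not show

The generator provides labels from two analytic, body-ordered references:
Morse pairs on the covalent bond graph plus harmonic angle bending
(dihedral-free by construction — deliberately, so constrained-scan tests
have an exact flat-profile oracle), and "planted" linear ACE models with
known coefficients. Sampling is either Gaussian displacement of the
template's Cartesian coordinates (near-equilibrium regime) or seeded
Langevin trajectories subsampled at a fixed stride, stratified over several
temperatures (barrier-crossing regime). Stiffness parameters are drawn from
documented ranges ($D_e \in (3.5, 5)$ eV, $a \in (1.8, 2.2)$ Å$^{-1}$,
$k_\theta \in (2.5, 3.5)$ eV/rad$^2$ — typical covalent-bond scales) so that
different bonds are distinguishable in a fit.

Passing tests on these data certify the machinery — invariances, exact
gradients, recoverability, solver behavior, protocol correctness — but not
chemical accuracy on real systems: the references lack dihedral torsion
(except where added explicitly), non-bonded dispersion/electrostatics, and
the label noise structure of electronic-structure data. Conclusions about
accuracy on real molecules require real reference data.

## Problem sizes and numerical choices

The shipped tests and the verification script run at desk scale, chosen as
the smallest sizes at which each property is sharply testable: invariance
suites over 20 environments × 100 rotations; oracle comparisons over 100
small environments; planted-model recovery from 300 labeled 6-atom
configurations; MD checks over $10^3$–$2\times10^4$ steps of a triatomic.
Key tolerances: coupling null-space threshold $10^{-8}$ (relative), basis
pruning threshold $10^{-10}$ (relative singular value, fixed documented
seed), coupling sparsification $10^{-12}$, LSQR stopping $10^{-14}$.
Degenerate inputs are defined away (coincident atoms are rejected at
construction) or handled exactly (empty environments evaluate to the
one-body energy; atoms beyond the cutoff contribute exact zeros).
Neighbor sums are accumulated in a canonical sorted order, which makes every
evaluation bit-reproducible under permutations of the input.

## Known limitations

Molecules in vacuum only (no periodic boundary conditions, no virials);
no long-range electrostatics or charge transfer; no basis sparsification
beyond rank pruning; the brute-force correlation oracle is exponential in
the correlation order and guards itself above 8 neighbors; dihedral
constraints handle one dihedral per scan and refuse bonds inside rings.
Pure-R evaluation is comfortable at the tested sizes (tens of atoms,
hundreds of basis functions) but is not tuned for long production MD.
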