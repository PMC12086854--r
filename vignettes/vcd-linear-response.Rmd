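---
title: "Vibrational circular dichroism from atomic-orbital linear response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibrational circular dichroism from atomic-orbital linear response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Vibrational circular dichroism (VCD) is the differential absorption of
left- and right-circularly polarized infrared light by the vibrational
transitions of a chiral molecule.  Within the double harmonic
approximation the signed VCD intensity of fundamental mode $i$ is its
rotational strength

$$R_i = \sum_\alpha
  \Big(\sum_{\lambda\beta} P^\lambda_{\alpha\beta} S_i^{\lambda\beta}\Big)
  \Big(\sum_{\lambda\beta} M^\lambda_{\alpha\beta} S_i^{\lambda\beta}\Big),$$

and the ordinary IR intensity is the dipole strength
$D_i = \tfrac{1}{2\omega_i}\,|\sum_{\lambda\beta}
P^\lambda_{\alpha\beta}S_i^{\lambda\beta}|^2$.
Here $P^\lambda$ is the atomic polar tensor (derivative of the electric
dipole moment with respect to the position, or in the velocity form the
velocity, of nucleus $\lambda$), $M^\lambda$ is the atomic axial tensor
(derivative of the magnetic dipole moment with respect to the nuclear
velocity), and $S_i^{\lambda\beta}$ is the mass-weighted transformation
from Cartesian displacements to the normal coordinate.  Everything is in
Hartree atomic units; magnetic operators follow the Gaussian-CGS
convention and carry explicit factors of $1/c$.  In this normalization
("half convention") the nuclear parts are
$P^{\lambda,\mathrm{nuc}}_{\alpha\beta} = Z_\lambda\delta_{\alpha\beta}$
and $M^{\lambda,\mathrm{nuc}}_{\alpha\beta} =
\tfrac{Z_\lambda}{4c}\,\varepsilon_{\alpha\gamma\beta}
(R_\gamma^\lambda - O^{\mathrm{mag}}_\gamma)$.

The axial tensor is not a Born–Oppenheimer observable: a static nuclear
displacement of a real closed-shell wavefunction generates no magnetic
moment.  Two perturbation theories recover it:

* **Nuclear velocity perturbation theory (NVPT).**  The leading
  beyond-Born–Oppenheimer coupling $-i\sum_\lambda \dot R^\lambda
  \cdot\nabla_\lambda$ is treated as an imaginary perturbation.  Basis
  functions acquire a velocity-gauge phase
  $e^{\,i\dot R^{\lambda_\mu}\cdot(r-O^{\mathrm{sp}})}$ tied to the atom
  they ride on ("velocity atomic orbitals"), which makes the velocity
  form of the electric dipole and the magnetic dipole consistent to
  first order.  The right-hand side couples to the nuclear-displacement
  responses, so all displacement channels must be solved first.
* **Magnetic field perturbation theory (MFPT).**  The axial tensor is the
  mixed derivative with respect to nuclear velocity and external magnetic
  field; only three response equations (one per field direction) are
  needed.  Basis functions carry London phases
  $e^{-\tfrac{i}{2c}(B\times(R_\mu-O^{\mathrm{mag}}))\cdot r}$
  (gauge-including atomic orbitals), which removes the magnetic gauge
  origin from every first-order integral.

IR intensities come from nuclear displacement perturbation theory (NDPT,
length-form dipole derivatives; real symmetric perturbations solved with
the full self-consistent coupling) or from NVPT (velocity form); the two
agree only in the complete-basis limit, and the package ships a basis
ladder (minimal, split-valence, polarized) along which their difference
decreases monotonically.

## Two solvers, one contract

The package implements both response paths over the same all-electron
restricted Hartree–Fock reference:

* the **AO solver** parametrizes the perturbed one-electron density as
  $D^{(1)} = [D^{(0)}, X]_S + D^{(1)}_{\mathrm{oo}}$ with an
  anti-Hermitian generator $X$, fixes the occupied–occupied block from
  the differentiated idempotency condition
  ($D^{(1)}_{\mathrm{oo}} = -D^{(0)}S^{(1)}D^{(0)}$), and solves the
  projected linearized stationarity condition of $FDS - SDF = 0$ in the
  Löwdin-orthogonalized basis by preconditioned conjugate gradients.  The
  projected operator is the singlet orbital Hessian — coupling of
  $(A{+}B)$ type for real perturbations and $(A{-}B)$ type for imaginary
  ones — hence symmetric positive definite, and plain CG applies.  The
  Coulomb response of an antisymmetric density factor vanishes
  identically, so imaginary channels carry an exchange-only coupling
  (exact at Hartree–Fock; `uncoupled_imaginary = TRUE` reproduces the
  uncoupled equations of pure density functionals).
* the **MO solver** solves the per-orbital Sternheimer equations in the
  virtual-projected space.  In the canonical basis the projected operator
  is diagonal, so each orbital equation is solved exactly and an outer
  damped iteration (mixing 0.5) handles the self-consistent coupling.
  The occupied–occupied response never solves an equation: it follows
  from the differentiated orthonormality as $u_{\mathrm{oo}} =
  -\tfrac12 S^{(1),\mathrm{MO}}$.

The two solvers share nothing beyond the integrals, and their channel-by-
channel agreement (max-abs deviation of $D^{(1)}$, tensors and every
$R_i$ below $10^{-8}$) is the package's central internal validation,
exercised by the test suite and the acceptance script on the chiral
H$_2$O$_2$ fixture.

## Working entirely in the AO basis

Property assembly needs the one-sided coefficient response
$U = C^{(1)}C^{(0)T}$, not just the symmetrized density.  The identity

$$U = (1 - D S)\,\big(d + D s D\big)\,S D \;-\; \tfrac12 D s D$$

recovers it from the AO-level response factor $d$ and perturbed overlap
factor $s$ alone (in the standard normalization gauge), which is what
lets the velocity channels and the magnetic-field tensors consume
displacement responses computed purely in the AO basis — no molecular
orbitals appear in the production path of the AO solver.

Imaginary matrices are stored as their real factors ("times $i$"
convention): Hermitian imaginary matrices appear as real antisymmetric
factors and the entire solver algebra stays real.

## Integrals

A compact McMurchie–Davidson engine (Rcpp) computes overlap, kinetic,
nuclear attraction, $\nabla$ and electron-repulsion integrals over
arbitrary primitive Cartesian Gaussians, including rectangular blocks
between different primitive tables.  Every derived integral is assembled
from exact operator identities rather than numerical differentiation:
$(r_g - A_g)\chi$ is the angular-momentum-raised function,
$\partial\chi/\partial A_g = 2\alpha\,\chi^{+g} - l_g\,\chi^{-g}$, and
moment-weighted operators move the multiplicative moment onto the bra.
Derivative and moment-weighted repulsion integrals come from mixed blocks
$(e\,\nu|\rho\sigma)$ with one raised or differentiated index, mapped to
all index positions by permutational symmetry.

The independent oracles deliberately avoid those identities: geometric
central differences of rebuilt integrals, tensor-product Gauss–Hermite
quadrature of the explicit integrand (including the complex gauge
phases), and an exponential-tilt trick — multiplying a Gaussian by
$e^{h(r_g-O_g)}$ is exactly another polynomial Gaussian with a shifted
center, so differentiating engine-evaluated tilted matrix elements
reproduces moment-weighted matrices through a completely different code
path.

## Gauge origins

Both origins default to the common origin $(0,0,0)$.  The GIAO
first-order overlap and Hamiltonian matrices are rigorously independent
of $O^{\mathrm{mag}}$ (asserted to $10^{-12}$/$10^{-10}$).  The axial
tensors themselves are not: the operator definition of the magnetic
moment forces the exact covariance law
$\delta M^\lambda = -\tfrac{1}{4c}\, d \times P^\lambda$ under an origin
shift $d$, with $P^\lambda$ the paired polar tensor (velocity form for
NVPT, length form for MFPT).  The package therefore references the
nuclear axial part to the same origin, which makes every rotational
strength exactly origin-invariant (the shift contracts to a vanishing
triple product); both the covariance law and the $R_i$ invariance are
asserted to $10^{-10}$.  The free neutral atom provides the absolute
anchor: its total polar and axial tensors vanish identically (electrons
co-move with the nucleus), which both theory routes reproduce to
$10^{-10}$ — this is what pins the $1/4c$ normalization and the relative
factor between the NVPT and MFPT electronic parts.  The velocity-gauge
spatial origin $O^{\mathrm{sp}}$ turns out to be immaterial here: in an
all-electron theory shifting it only multiplies each velocity atomic
orbital by a constant phase, so all observables are exactly
$O^{\mathrm{sp}}$-invariant (asserted to $10^{-10}$); the dependence
reported for pseudopotential implementations enters through nonlocal
projectors, which this mean field does not have.

## Harmonic analysis and spectra

The Hessian is seminumerical: symmetric second differences of the
converged SCF energy with increment $10^{-2}$ bohr (configurable), then
mass weighting, Eckart projection of the 3 translations and 3 (2 if
linear) rotations, and diagonalization.  Projected rigid modes come out
numerically zero ($<1$ cm$^{-1}$ on the stationary fixtures) and are
excluded from strength tables.  A quasi-Newton minimizer on the SCF
energy is included so fixtures sit at true stationary points; the shipped
fixture coordinates were refined to max forces below $3\times10^{-7}$ au
and frozen.

Spectra use unit-area Lorentzians,
$L(\omega) = \sum_i s_i\,\frac{w/2\pi}{(\omega-\omega_i-\Delta)^2 +
(w/2)^2}$, full width at half maximum $w = 12$ cm$^{-1}$ by default and
optional rigid shift $\Delta$ (0 by default; alignment shifts such as
+55 cm$^{-1}$ are opt-in).  A single mode of unit strength peaks at
$2/\pi w$, and the profile closure integrates to the summed strengths to
$10^{-6}$ relative.

## Fixtures and what the tests do (and do not) show

All test inputs are generated in code: H$_2$, H$_2$O, HOF, the chiral
H$_2$O$_2$ enantiomer pair (exact mirror images, dihedral 112°) and the
trans-planar achiral H$_2$O$_2$, with a built-in minimal basis plus
split-valence and polarized ladder rungs for H, O, F.  At the
all-electron Hartree–Fock/minimal-basis level the trans-planar
H$_2$O$_2$ stationary point is the achiral torsional saddle (one soft
imaginary mode near $-46$ cm$^{-1}$), and the torsional minimum is
extremely shallow and nearly planar; the strongly skewed chiral fixture
is therefore a fixed chirality-test structure rather than a minimum.
The parity, cross-solver and gauge checks do not require stationarity,
and the harmonic analyses quoted for it describe that reference
structure.
Problem sizes (7–40 AOs, 2–4 atoms) were chosen so the full suite —
including seminumerical Hessians for three molecules — completes in
minutes; they probe every term of the formalism but say nothing about
basis-set convergence of absolute VCD intensities for real systems,
which requires polarized triple-zeta bases and correlated mean fields.

## Numerical choices

* SCF: DIIS on the Löwdin-orthogonalized commutator residual, core
  Hamiltonian guess, convergence $10^{-10}$ (max-abs commutator), max 200
  iterations.
* Response: residual threshold $5\times10^{-12}$ on the projected working
  equation; Jacobi preconditioner from Löwdin-diagonal level differences
  (floor 0.25 au); CG stagnation (25 iterations without decrease) and
  iteration caps raise errors carrying the residual history.
* Near-degenerate occupied–virtual gaps ($<10^{-6}$ au) are refused with
  the orbital pair named.
* Linear dependence: smallest overlap eigenvalue below $10^{-9}$ aborts
  the integral build.
* Determinism: there is no random state anywhere in the production path;
  CG starts from zero and identical inputs give bit-identical outputs.

## Known limitations

Closed-shell restricted Hartree–Fock only (no DFT exchange–correlation
response, no open shells); dense integral storage caps practical basis
sizes near 60 AOs; no anharmonicity, solvent, temperature or isotope
automation; Cartesian (6d/10f) Gaussians only.
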