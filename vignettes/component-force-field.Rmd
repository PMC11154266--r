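---
title: "Component-resolved intermolecular force fields: models, fitting, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component-resolved intermolecular force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saptfit)
```

## The model

Symmetry-adapted perturbation theory (SAPT) resolves the interaction energy
of a molecular dimer into four physically interpretable components:
exchange (Pauli repulsion), electrostatics (permanent charge distributions),
induction (polarization response), and dispersion (correlated-fluctuation
attraction). `saptfit` implements a classical, atom-pairwise model for each
component, driven by monomer-derived atomic properties (valence widths,
multipoles, Hirshfeld ratios, free-atom dispersion data) and by a small
table of *global parameters*: one value per atom type and component,
`K^elst`, `K^exch`, `K^indu`, `K^disp`, for the nine types
`r paste(atom_type_labels(), collapse = ", ")`. Hydrogens are typed by their
bonding partner, carbon by coordination number, nitrogen and oxygen by
neighbor count. The global parameters are the only quantities fitted; the
atomic properties stay fixed.

All physics is computed in atomic units internally (files carry angstrom)
and energies are reported in kcal/mol.

### Exchange

The Pauli repulsion between atoms i in monomer A and j in monomer B is
proportional to the overlap of their valence densities,

$$E_\mathrm{exch} = \sum_{i\in A, j\in B} K^\mathrm{exch}_i K^\mathrm{exch}_j\, S_{ij},
\qquad S_{ij} = \left[\tfrac13 (B_{ij} r_{ij})^2 + B_{ij} r_{ij} + 1\right] e^{-B_{ij} r_{ij}},$$

with the overlap exponent $B_{ij} = (\sigma_i \sigma_j)^{-1/2}$ built from
the atomic valence widths. The inverse-square-root form is the only
dimensionally consistent reading (it gives $B$ units of inverse length); the
pair parameter is the product of the two atomic parameters throughout —
a geometric-mean rule differs only by the reparameterization
$K \to K^2$ and is absorbed by fitting.

### Electrostatics

Damped multipole electrostatics sums nucleus–nucleus, nucleus–multipole and
multipole–multipole terms over all intermolecular atom pairs. Each atom
carries its nuclear charge $Z_i$ separately from an electronic multipole set
(negative monopole, dipole, traceless quadrupole) in the global frame.
Nucleus–multipole terms are damped by $f_1(r) = 1 - e^{-K^\mathrm{elst}_i r}$,
multipole–multipole terms by the two-exponent generalization $f_2$; both
vanish at contact (full charge penetration) and approach 1 at long range.
At equal exponents $f_2$ has a removable singularity; below $10^{-6}$
relative difference the series limit
$1 - (1 - K r/2)e^{-Kr}$ is used. As printed, this limit form transiently
exceeds 1 for $Kr > 2$; it is implemented as defined rather than "repaired",
since the fitted exponents keep the affected region at sub-yoctohartree
weight.

Interaction tensors are generated by differentiating the damped kernel
$g(r)/r$ (ranks 0–4, i.e. through quadrupole–quadrupole), not by
multiplying bare tensors by $g$. This choice makes the tensors exactly the
Cartesian derivatives of a scalar kernel, which is what the test suite
verifies by numerical differentiation; the kernels live in a small closed
term algebra ($c\,r^q e^{-kr}$) so all derivatives are analytic.

### Dispersion

Effective atomic dispersion data are the free-atom values scaled by the
Hirshfeld volume ratio ($C_6 \to C_6 h^2$, $\alpha \to \alpha h$). Pair
coefficients use the polarizability-weighted combination rule; $C_8$ follows
from the radial-moment ratio $Q_i = Z_i \langle r^4\rangle_i / \langle
r^2\rangle_i$ as $C_8 = 3 C_6 \sqrt{Q_i Q_j}$, and
$C_{10} = \tfrac{49}{40} C_8^2 / C_6$ exactly. Each $r^{-n}$ term is damped
by the Tang–Toennies function
$f_n(x) = 1 - e^{-x}\sum_{k=0}^{n} x^k/k!$, evaluated through the
regularized incomplete gamma function (`stats::pgamma`), which is exact and
stable at large $x$. The damping argument is built from the overlap
exponent, $x = Br + (2B^2r + 3B)\,r/((Br)^2 + 3Br + 3)$. The energy is

$$E_\mathrm{disp} = -\sum_{ij}\left[\frac{C_6}{r^6}f_6 +
K^\mathrm{disp}_i K^\mathrm{disp}_j\left(\frac{C_8}{r^8}f_8 +
\frac{C_{10}}{r^{10}}f_{10}\right)\right],$$

with coefficients stored as positive magnitudes and an explicit leading
minus sign; the leading $r^{-6}$ term carries no fitted parameter.

### Induction

Each atom carries an isotropic polarizability $\alpha_i$ (Hirshfeld-scaled
free-atom value). The external field on each atom is the permanent-multipole
field of the partner monomer; induced dipoles couple through Thole-damped
dipole field tensors over *all* atom pairs and are iterated to
self-consistency with mixing factor $\omega = 0.7$:

$$\mu_i \leftarrow (1-\omega)\,\mu_i + \omega\,\alpha_i\Big(F^\mathrm{ext}_i
+ \sum_{k\neq i} T_{ik}\,\mu_k\Big).$$

The Thole smearing (coefficient $a = 0.39$,
$u = r/(\alpha_i\alpha_j)^{1/6}$) enters as the standard exponential-cube
factors $\lambda_3 = 1 - e^{-au^3}$ and
$\lambda_5 = 1 - (1 + au^3)e^{-au^3}$ on the rank-2 tensor — the printed
smeared density is not directly usable as a tensor factor — and
$\lambda_7$ on the rank-3 quadrupole-field term. Convergence is declared
when the largest per-atom dipole change drops below $10^{-10}$ a.u. (at
most 500 iterations by default) — the tight threshold matters: a looser
$10^{-6}$ cut leaves an iteration-path-dependent residue of order
$10^{-7}$ kcal/mol in the induction energy, visible as a spurious frame
dependence. Non-convergence signals a polarization catastrophe and is an
error, never silently accepted. The converged dipoles
are independent of $\omega$ and match a direct linear solve of the same
equations, which the suite asserts to $10^{-8}$ a.u.

The induction energy is the classical term
$-\sum_i \mu_i\cdot F^\mathrm{ext}_i$ — summed over both monomers' induced
dipoles, with no factor $\tfrac12$ (the fitted $K^\mathrm{indu}$ absorbs
scale) — plus a short-range overlap correction
$\sum_{ij} K^\mathrm{indu}_i K^\mathrm{indu}_j S_{ij}$.

## Fitting

The composite loss is

$$L = (1-\gamma)\,\mathrm{MSE}(E_\mathrm{total}) +
\gamma \sum_{c} \mathrm{MSE}(E_c), \qquad \gamma = 0.4,$$

with equal weight per dimer. Minimization uses BFGS (`stats::optim`).
Two parameterization choices matter:

* The electrostatic exponents are optimized on the **log scale** — they are
  positive rates spanning a multiplicative range.
* The bilinear families (exchange, induction overlap, dispersion) are
  optimized on the **linear scale**. A log transform makes the loss
  curvature for a coupling of size $K$ scale as $K^2$, so near-zero
  couplings (e.g. a dispersion weight of a few $10^{-3}$) become numerically
  flat and unrecoverable; on the linear scale their least-squares problem is
  well conditioned at any magnitude. Positivity is enforced by a floor at
  $10^{-10}$ when reporting.

The default strategy is **staged**. Each bilinear family is pre-fitted
independently from a *lifted* rank-1 least-squares start: the energies are
linear in the product matrix $P = kk^\top$, so the linear least-squares
solution for $P$ followed by a dominant-eigenvector factorization gives a
starting point that is essentially exact on identifiable noiseless data and
immune to the quartic landscape's mixed-sign local minima (a family-wide
sign flip is an exact degeneracy; the positive branch is canonical). The
multi-modal electrostatic fit is started from a short deterministic ladder
of exponents (1.5, 3.0, 4.5 bohr⁻¹ plus the user's initial value), keeping
the best minimum, and the final joint composite-loss minimization is
warm-started from these; exponents that run beyond 25 bohr⁻¹ — beyond
which damping is indistinguishable from none at any sampled distance — are
reseeded mid-range and refit, keeping the improvement. Every minimization
interleaves BFGS chunks with Levenberg–Marquardt refinements on the exact
residual Jacobian: near a zero-residual minimum the Gauss–Newton curvature
resolves stiff, weakly-coupled directions (near-zero dispersion weights,
buried-atom exponents) that quasi-Newton steps crawl along. The reported
result is always the joint minimization of $L$; a single-start
`strategy = "joint"` is available. Convergence is declared at gradient
max-norm $10^{-8}$, and the best iterate is always returned with its loss
trace.

Greedy augmentation (`augment_training_set()`) alternates fitting with
screening a candidate pool: while any pool dimer's absolute total-energy
error exceeds 1 kcal/mol (the chemical-accuracy threshold), the smallest
offending dimer (fewest atoms, ties by name) moves into the training set and
the fit is refit, warm-started from the previous parameters. The one-dimer-
per-iteration rule makes the procedure deterministic and testable.

## The synthetic benchmark

Nothing in the fitting pipeline requires quantum-chemical data, so the
package ships a generator that emulates the full study design with known
ground truth:

* **Monomers** — nine idealized textbook geometries (methane, ethane,
  ethene, ethyne, methanol, formaldehyde, acetone, formic acid, formamide)
  spanning the eight organic functional-group classes and jointly covering
  all nine atom types.
* **Properties** — element-wise base values with seeded multiplicative
  jitter (5% by default). Free-atom $C_6$ and $\alpha$ are standard
  free-atom reference values; radial moments are representative magnitudes.
  Valence widths (H 1.10, C 1.50, N 1.40, O 1.30 bohr) are chosen so that
  density overlaps at van der Waals contact are of order $10^{-2}$–$10^{-1}$,
  putting exchange energies at the few-kcal/mol scale of equilibrium dimers
  under order-unity global parameters. Partial charges are atom-type-based
  with jitter, renormalized so each monomer is exactly neutral; dipoles and
  traceless quadrupoles are small seeded values.
* **Geometries** — homodimer training configurations and heterodimer test
  configurations at random orientations, with center-of-mass separations
  drawn between 0.4 and 1.2 times the contact distance and a hard floor of
  2 bohr on interatomic distances. The compressed end of this range is
  deliberate: charge-penetration damping and the higher dispersion terms
  only act at short range, so a training set confined to equilibrium
  separations leaves their parameters unidentifiable. Sampling the
  repulsive wall through stretched geometries is the standard recipe for
  making every term of a force field observable.
* **References** — each component evaluated under a hidden ground-truth
  parameter table (the shipped `default_parameters("base")` set by
  default), plus optional independent Gaussian noise per component; the
  stored total is the sum of the stored components, so the component-sum
  invariant always holds and, at zero noise, the generator's references are
  exactly recoverable by the energy models.

Because references are model-consistent, passing the parameter-recovery and
held-out-error tests demonstrates that the estimator and pipeline are
correct — not that the model reproduces real SAPT physics. Real reference
data would add model error on top; the error statistics measured here are
lower bounds of that setting by construction.

### Problem sizes

The shipped tests fit 54 homodimer configurations (6 per monomer, with
separation factors stratified across the sampling range so the compressed
wall is always represented) and hold out 36 heterodimers; these sizes keep
every atom-type pair observed while a full fit runs in about a minute on a
single core. The acceptance script uses the same sizes.

One caveat survives the stratified design: for an occasional seed a single
damping exponent (typically of a buried heavy atom) is only weakly
determined — the training residual it controls sits at the 1e-5 kcal/mol
level — and its fitted value can drift far from the truth while every
prediction stays essentially exact. This is a property of the data draw,
not of the estimator; the recovery summaries report both the maximum and
the median relative error so the two situations are distinguishable.

## Numerical choices and degenerate inputs

* Covalent radii (H 0.31, C 0.76, N 0.71, O 0.66 Å, scale 1.2) drive bond
  perception; explicit connectivity from a manifest takes precedence, so
  typing cannot drift with geometry noise.
* Overlapping atoms (< 0.3 Å) and untypable coordinations are errors, not
  warnings; an atom with no bonds in a multi-atom monomer warns.
* Scan grids that drive atoms inside 0.5 bohr flag the point but still
  report the energy; the equilibrium is the grid minimum refined by the
  quadratic through its two neighbors, and an unbracketed minimum (at a
  grid edge) warns.
* Parameter files round-trip through a 17-significant-digit decimal
  representation; XYZ geometry round-trips are exact to $10^{-6}$ Å.
* Sub-seeds for monomers, dimers and noise are derived from the master seed
  and a name tag, so every generated object is individually reproducible
  and insertion order cannot silently change downstream draws.

## Limitations

* The atom-type enumeration covers H/C/N/O organic chemistry only; ions,
  aromatic perception, and elements beyond the four are out of scope.
* Multipoles truncate at quadrupoles; polarizabilities are isotropic; no
  charge transfer or many-body dispersion.
* No nuclear gradients: the models serve energy prediction and fitting, not
  dynamics.
* The synthetic benchmark shares its functional form with the fitted model;
  it cannot detect model inadequacy against real quantum-chemical
  references.
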