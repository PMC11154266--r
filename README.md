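# saptfit

Component-resolved intermolecular force fields in R: physics-motivated
models for the four SAPT (symmetry-adapted perturbation theory) interaction
energy components of small organic dimers, plus everything needed to fit
and validate them.

Molecular-dynamics force fields for biomolecules live or die by their
noncovalent interaction energies. SAPT decomposes a dimer interaction into
exchange (Pauli repulsion), electrostatics, induction and dispersion, and
that decomposition can be modeled term by term with compact, transferable
expressions. `saptfit` implements such a scheme for H/C/N/O organic
chemistry:

* **Exchange** — repulsion proportional to the overlap of atomic valence
  densities, `E = Σ K_i K_j S_ij` with
  `S_ij = [⅓(Br)² + Br + 1] e^{-Br}`, `B = (σ_i σ_j)^{-1/2}`.
* **Electrostatics** — damped multipole electrostatics through
  quadrupole–quadrupole order, with charge-penetration damping
  `f₁ = 1 − e^{-Kr}` (nucleus–multipole) and its two-exponent
  generalization `f₂` (multipole–multipole); interaction tensors are exact
  Cartesian derivatives of the damped Coulomb kernels.
* **Induction** — Thole-damped induced dipoles (smearing `a = 0.39`)
  iterated to self-consistency with mixing `ω = 0.7`, plus a short-range
  overlap term.
* **Dispersion** — Tang–Toennies-damped `−C₆/r⁶ − K_iK_j(C₈/r⁸ + C₁₀/r¹⁰)`
  with Hirshfeld-ratio-scaled free-atom coefficients,
  `C₈ = 3C₆√(Q_iQ_j)`, `C₁₀ = (49/40)C₈²/C₆`.

Each component carries one global parameter per atom type (nine types:
HC, HN, HO, C4, C3, C2, N3, O1, O2 — 36 parameters total), fitted to
reference component energies by minimizing the composite loss

```
L = (1 − γ) MSE(E_total) + γ Σ_c MSE(E_c),   γ = 0.4
```

with staged BFGS + Levenberg–Marquardt refinement. The package also
provides greedy training-set augmentation under a 1 kcal/mol error
threshold, MAE/RMSE error reports, correlation exports,
center-of-mass potential-energy scans, and a fully seeded synthetic
benchmark generator (idealized monomers covering eight functional-group
classes, plausible atomic properties, model-consistent reference energies
under a hidden ground-truth parameter table).

## Worked example

Generate the synthetic benchmark, fit the 36 global parameters to the
homodimer training set, and score the held-out heterodimers:

```r
library(saptfit)

cfg   <- synth_config(seed = 1)          # hidden truth = default_parameters("base")
suite <- make_benchmark_suite(cfg)       # 54 homodimers train, 36 heterodimers test

fit <- fit_global_parameters(suite$train)
glance(fit)
#> # A tibble: 1 × 6
#>       loss n_iter converged grad_norm gamma n_dimers
#>      <dbl>  <dbl> <lgl>         <dbl> <dbl>    <int>
#> 1 2.34e-11   3460 TRUE       6.98e-11   0.4       54

error_report(predict_sapt(suite$test, fit$parameters),
             reference_components(suite$test))
#> # A tibble: 5 × 4
#>   component        mae       rmse     n
#>   <chr>          <dbl>      <dbl> <int>
#> 1 elst      0.00157    0.00648       36
#> 2 exch      0.00000182 0.00000511    36
#> 3 indu      0.00000138 0.00000424    36
#> 4 disp      0.00000995 0.0000342     36
#> 5 total     0.00158    0.00649       36
```

The references are generated by the same models under the hidden
ground-truth table, so a correct estimator must drive both the training
loss and the held-out errors toward numerical zero — three to eleven orders
of magnitude below the 1 kcal/mol chemical-accuracy target here, limited
only by one weakly-determined damping exponent of this particular draw
(the median parameter-recovery error at this seed is ~2e-5 %). With
`noise_sigma = 0.25` the generator adds per-component Gaussian noise and
the held-out total-energy RMSE settles near the implied 0.5 kcal/mol noise
floor instead.

Single dimers work the same way:

```r
d <- suite$test$dimer[[1]]
sapt_energy(d, fit$parameters)
#> # A tibble: 1 × 5
#>    elst  exch   indu  disp total
#>   <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1  1.84  14.0 -0.862 -5.64  9.36
sc <- com_scan(d, fit$parameters, grid = seq(0.55, 4.5, by = 0.05),
               ref_params = cfg$ground_truth)
attr(sc, "equilibrium")          # 21.46 bohr: quadratic-refined grid minimum
autoplot(sc)
```

## Package layout

| area | functions |
|---|---|
| chemical data model & I/O | `sapt_monomer()`, `sapt_dimer()`, `perceive_bonds()`, `assign_atom_types()`, `read_xyz()`, `read_properties()`, `read_parameters()`, `read_manifest()` + writers |
| energy models | `sapt_energy()`, `exchange_energy()`, `electrostatic_energy()`, `induction_energy()`, `dispersion_energy()`, `overlap()`, `elst_damping()`, `interaction_tensors()`, `tang_toennies()`, `combine_c6()`, `induced_dipoles()` |
| training | `sapt_loss()`, `fit_global_parameters()`, `augment_training_set()` |
| evaluation | `error_report()`, `correlation_table()`, `plot_correlation()`, `com_scan()` |
| synthetic benchmark | `synth_config()`, `builtin_monomer_library()`, `generate_properties()`, `generate_dimer_configs()`, `generate_reference_energies()`, `make_benchmark_suite()` |

The methods vignette (`vignettes/component-force-field.Rmd`) documents the
model equations, unit conventions, every tunable parameter, the synthetic
benchmark design (including why the training geometries sample the
repulsive wall), and the package's numerical choices and limitations.
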