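# deltapes

Delta-machine-learning potential energy surfaces with permutationally
invariant polynomials, in R.

## The problem

High-accuracy molecular potential energy surfaces (PES) are fitted to
coupled-cluster (CCSD(T)) energies, but those calculations are too
expensive to run at the thousands of configurations a global fit needs.
A practical compromise is **delta-machine-learning**: fit a cheap
low-level surface `V_LL` (a DFT-quality fit, or even a classical force
field) on abundant data, then fit a *small correction* on sparse
high-level data and add the two,

```
V_LL→CC = V_LL + ΔV_CC−LL .
```

Because the high-level minus low-level difference varies far less over
configuration space than the surface itself, the correction needs only a
small basis and few training points, and adds almost nothing to the
evaluation cost.

Both surfaces are linear models in **permutationally invariant
polynomials (PIPs)** of Morse variables,

```
V(x) = Σ_i c_i p_i(y),    y_αβ = exp(−r_αβ / λ),    λ = 2 Bohr,
```

where `r_αβ` are the interatomic distances and each basis function `p_i`
is a symmetrized monomial: the sum of one orbit of monomials under the
group permuting like atoms (for ethanol, symmetry `321111` — the three
methyl H and the two methylene H — a group of order 12).  Exchanging
equivalent nuclei then provably cannot change the energy.  For ethanol
this construction gives **208** basis functions at maximum polynomial
order 2 and **14,752** at order 4, so a correction fitted at order 2 adds
about 1% to the cost of evaluating an order-4 surface.

The package is aimed at people building or studying such fits: it
implements the basis construction (with an independent Burnside-count
cross-check), linear least-squares fitting of energies and analytic
gradients, a classical bond/angle/dihedral force field with harmonic or
Morse stretches (the published ethanol stretch parameters ship as a
fixture), and the validation machinery the field uses — geometry
optimization, harmonic normal-mode frequencies, rigid torsional scans,
and gradient-fidelity metrics.  A synthetic surrogate generator
(perturbed force field = low level, unperturbed = high level) makes the
entire pipeline runnable and testable without any electronic-structure
data.

## Worked example

The full synthetic delta-ML experiment — sample 2319 ethanol geometries
from the high-level surface up to 30,000 cm⁻¹ above its minimum, fit a
208-function order-2 correction to high-minus-low residuals at 2069 of
them, hold out 250 — is one call:

```r
library(deltapes)
ex <- delta_ml_experiment(surrogate_spec(seed = 1))
cat(sprintf("LL vs HL held-out RMSE: %.1f cm-1\n", ex$rmse_ll_test))
cat(sprintf("corrected held-out RMSE: %.1f cm-1 (%.1fx better)\n",
            ex$rmse_composed_test, ex$rmse_improvement))
cat(sprintf("frequency MAE: %.1f -> %.1f cm-1\n",
            ex$freq_mae_ll, ex$freq_mae_composed))
```

```
LL vs HL held-out RMSE: 661.6 cm-1
corrected held-out RMSE: 84.6 cm-1 (7.8x better)
frequency MAE: 50.4 -> 12.2 cm-1
```

The uncorrected low-level surface misses held-out high-level energies by
~660 cm⁻¹ RMSE; adding the small fitted correction cuts that by a factor
of about 8, and the harmonic frequencies at the minimum move from ~50
cm⁻¹ mean absolute error to ~12 cm⁻¹ — the qualitative signature of a
working delta-ML correction.

Lower-level building blocks are exported individually:

```r
basis <- build_pip_basis(ethanol_symmetry(), 2)   # 208 PIPs
basis$n_p == count_orbits_burnside(ethanol_symmetry(), 2)  # TRUE
ff <- ethanol_forcefield("morse")                 # packaged fixture
sp <- optimize_geometry(ff, ethanol_geometry())
nm <- normal_modes(hessian(ff, sp$geometry),
                   atomic_masses(sp$geometry$elements))
physical_frequencies(nm)                          # 21 modes, cm-1
```

See `vignettes/delta-ml-pes.Rmd` for the model, conventions, parameter
choices and limitations.

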