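---
title: "Delta-ML potential energy surfaces with permutationally invariant polynomials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-ML potential energy surfaces with permutationally invariant polynomials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the model and
its assumptions, the conventions and tunable parameters with their
defaults and the reasons for them, what the synthetic data generator
does and does not emulate, and the numerical choices a maintainer would
want written down.

## The model

A potential energy surface is represented as a linear expansion

$$ V(\mathbf{x}) \;=\; \sum_{i=1}^{n_p} c_i\, p_i(\mathbf{y}), \qquad
   y_{\alpha\beta} = e^{-r_{\alpha\beta}/\lambda}, $$

where $r_{\alpha\beta}$ are the $M = N(N-1)/2$ interatomic distances of
an $N$-atom configuration and $\lambda$ is a range parameter.  The Morse
variables $y$ are bounded in $(0,1)$ and decay with separation, which
keeps polynomial fits well behaved where raw distances would diverge.
The default $\lambda$ is exactly 2 Bohr (1.05835... &Aring;), the customary
value for this family of fits; it is stored internally in &Aring;ngstr&ouml;m and
is a `morse_transform()` argument, not a constant.

### Basis convention

Each basis function $p_i$ is a **symmetrized monomial**: the plain sum
of one orbit of monomials (in the $M$ pair variables) under the group
that permutes like atoms, with no normalization factor, and with the
constant monomial counted as orbit 1.  For ethanol's `321111` symmetry
(3 methyl H, 2 methylene H, each remaining atom its own class; group
order $3!\cdot 2! = 12$) this convention yields 208 orbits at maximum
total degree 2 and 14,752 at degree 4 — both counts are verified in the
test suite against an independent Burnside/cycle-index count that never
enumerates an orbit.  Two deterministic tie-breaks make the basis
reproducible: monomials are enumerated by degree and then combination
order, and each orbit is identified by the element-wise minimal image of
its exponent vector over the group (canonical-form hashing).  Because
the orbit partition is exhaustive, invariance of every $p_i$ under the
group action is exact by construction, not approximate.

The atom-to-class mapping defaults to contiguous blocks in the order the
class sizes are written; any other XYZ ordering can be accommodated by
passing explicit `classes` to `symmetry_spec()`, since the upstream
convention for atom ordering is not standardized.  Exact per-term
agreement with any particular external basis-generation code is *not*
claimed — only the orbit counts and the invariance property, which are
convention-independent.

A memory guard (default $5\times 10^7$ monomials) aborts basis
construction before an infeasible order/atom-count combination exhausts
memory, reporting the projected count.

### Units and masses

Internally: coordinates in &Aring;ngstr&ouml;m, energies in the unit the data
carried (cm⁻¹ for PIP fits, kcal/mol for the force field), conversions
only at I/O and reporting boundaries (1 hartree = 219474.6313632 cm⁻¹,
1 kcal/mol = 349.755 cm⁻¹, 1 Bohr = 0.52917721067 &Aring;).  Atomic masses
default to standard atomic weights (C 12.011, O 15.999, H 1.008) with a
most-abundant-isotope table selectable per call, because the mass
convention behind published frequency tables is usually unstated; the
convention used is recorded in every `normal_modes()` result.

### Fitting

Coefficients are obtained by weighted linear least squares.  The design
matrix has one row per training energy and, when gradients are used,
$3N$ rows of analytic basis derivatives per record, each gradient row
weighted by `gradient_weight` (default 1 — the relative weighting behind
published fits of this kind is not standardized, so it is exposed as an
option and echoed in the result).  Columns are equilibrated to unit
infinity-norm before a rank-revealing QR solve (undone afterwards);
rank deficiency falls back to the minimum-norm SVD solution with a
warning, and an optional ridge penalty is available (default 0).  The
package fits **absolute** energies: the constant orbit plays the
intercept role, and shifting energies to the surface minimum is treated
as a reporting transformation, never part of the model.  RMSEs are
root-mean-square *energy* residuals even when gradient rows were used in
the fit.

### Delta composition

`fit_delta()` fits a (typically small) basis to residuals
$E_{HL}(g) - V_{LL}(g)$ using energy rows only — corrections of this
kind are trained on sparse high-level energies without high-level
gradients — and `compose_delta()` keeps the two surfaces separate,
summing energies and gradients exactly at evaluation time rather than
refitting a merged surface.  Keeping them separate costs nothing (the
correction is ~1–2% of the low-level term count at the ethanol defaults)
and preserves the ability to report the correction on its own.

## The force field

The classical surface is a sum of bond, angle and dihedral terms with no
nonbonded contributions:

* bonds: $\tfrac12 k (r - r_e)^2$ (harmonic) or
  $D_e\,(1 - e^{-\alpha (r - r_e)})^2$ (Morse);
* angles: $\tfrac12 k (\theta - \theta_e)^2$;
* dihedrals: $k\,(1 + \cos(n\phi - \delta))$.

The harmonic prefactor is one global switch (`"half"`, the default, or
`"full"`), and the Morse width is always curvature-matched to the
harmonic constant under the active convention:
$\alpha = \sqrt{k/2D_e}$ (half) or $\alpha = \sqrt{k/D_e}$ (full), so
both forms share minimum location and second derivative at $r_e$
exactly.  Both conventions are implemented because the printed form of
the source equations does not settle the prefactor; the half-$k$ default
reproduces, e.g., $\alpha \approx 2.185$ &Aring;⁻¹ for the O–H row of the
packaged parameters.  The packaged ethanol fixture carries the published
stretch rows (C–C, C–O, O–H, C–H: $r_e$, $k_{bond}$, $D_e$); its angle
and dihedral constants are **synthetic stand-ins** with typical alcohol
magnitudes (clearly marked in the parameter file), because the source
force field's bending and torsion values are not published alongside the
stretches.  Consequently force-field frequency tables and the ethanol
methyl barrier are *not* reproduction targets of this package — the
machinery is validated on closed forms (dissociation limits, curvature
matching, $2k$ cosine barriers) instead.  Dihedral multiplicity defaults
to $n = 3$, $\delta = 0$ (3-fold rotors) in the fixture.

Analytic gradients use the standard angle and torsion derivative
formulas (the torsion following the Blondel–Karplus construction) and
are tested against central finite differences on every surface type.

## Analysis machinery

* **Optimization**: L-BFGS with analytic gradients, then Newton
  refinement on the finite-difference Hessian with the
  translation/rotation nullspace projected out, to a default gradient
  norm of 10⁻⁶ (energy unit / &Aring;).  Saddle refinement from a displaced
  start works because the Newton step inverts the signed spectrum; it is
  best-effort and the result is always labeled by its Hessian signature.
* **Hessians**: central differences of analytic gradients (default step
  0.005 &Aring;).  Finite differencing contaminates the six null modes by a
  few cm⁻¹ at the default step (the contamination scales as the square
  of the step, verified in the tests); analyses that need a clean
  nullspace use 0.001–0.002 &Aring;.  Symbolic second derivatives were
  deliberately not implemented — the step-halving convergence check is
  part of the test surface.
* **Frequencies**: eigenvalues of $M^{-1/2} H M^{-1/2}$ converted to
  cm⁻¹, imaginary modes reported as negative, MAE between surfaces
  computed over index-matched ascending-sorted physical modes (the six
  smallest-magnitude modes dropped).
* **Torsion scans** default to rigid-fragment rotation about the central
  bond (the minimal reading of a "not fully relaxed" scan).  A
  restrained-relaxation mode (stiff harmonic restraint on the scanned
  dihedral, everything else optimized) is provided and labeled, since
  scan protocols differ between studies; relaxed profiles can only lie
  at or below the rigid ones pointwise in absolute energy.
* **Gradient fidelity**: per-geometry $\cos\theta$ between two gradient
  vectors and the mean absolute difference of their $3N$ components.

## The synthetic surrogate and what it shows

No external quantum-chemistry data ship with (or are needed by) the
package.  The surrogate pair is: **high level** = the packaged Morse
ethanol force field; **low level** = the same force field with every
force constant perturbed by ±10% and every bond length by ±0.02 &Aring;,
drawn once per parameter *type* (so permutational symmetry survives) from
a seeded generator.  This builds in the premise that makes delta-ML
work — the HL−LL difference is smooth and much smaller in spread than
the surface variation itself — and `make_surrogate_pair()` measures and
reports that ratio (well below 0.5 at the defaults, as the test suite
asserts, with a warning if it ever reaches 1).

Geometries are sampled by normal-mode displacement from the surface
minimum plus uniform rigid rotations of the methyl and hydroxyl rotors,
with rejection above an energy ceiling (default 30,000 cm⁻¹ above the
minimum, matching the energy range such fits are trained over).  Each
sample scales its mode amplitudes by an effective temperature drawn as
`temperature * runif(1, 0.15, 1)^2` with `temperature = 3000` cm⁻¹:
trajectory-style data are bottom-heavy (most configurations near the
well bottom, occasional high excursions), and this one-line emulation
reproduces that shape — at the defaults the sampled energies span more
than half the ceiling, and enough samples fall inside the 5,000 and
10,000 cm⁻¹ windows that energy-cutoff refits of the 208-function
correction basis remain overdetermined (both properties are asserted in
the tests), as they are in the study design this emulates.  The default
experiment sizes mirror that design: 2319
sampled geometries split 2069/250 for the correction fit (and
8500/2500 for full low-level fits where those are exercised); these
sizes run in seconds to a couple of minutes on one CPU.

What passing tests on the surrogate do **not** show: the generator is a
force field perturbed into another force field, so it has no
electronic-structure error structure (no basis-set or correlation
artifacts, no multireference regions), its anharmonicity is limited to
Morse stretches and cosine torsions, and sampling is harmonic-plus-rotor
rather than true molecular dynamics.  Results on it demonstrate that the
*pipeline* — basis, fit, composition, analysis — behaves correctly and
that the delta construction recovers a smooth correction; they say
nothing quantitative about any particular quantum-chemistry method pair.

## Numerical choices and degenerate inputs

* Distances below 10⁻⁶ &Aring; raise a degenerate-geometry error (clash
  tolerance is configurable).
* `evaluate_basis()` handles exact zeros in `y` (only the constant
  orbit survives at `y = 0`); the Jacobian switches from the fast
  log-space path to an exact per-variable path when any component is
  non-positive.
* Collinear angle triples raise an error naming the triple rather than
  returning NaN.
* All randomness flows through explicit integer seeds (`withr`-scoped,
  never the global RNG state), and fit results echo their options;
  identical spec + seeds reproduce surfaces, samples and fits to the
  last bit.

## Known limitations

Only the symmetrized-monomial PIP construction is implemented (no
invariant-theory primary/secondary bases, no purification, no
fragmented bases for large molecules).  The force field has no
intermolecular or nonbonded terms and no 1–4 interactions.  High-level
gradients are not used in correction fits (the machinery accepts
gradient rows, so this is a protocol choice, not a code limitation).
Anharmonic spectroscopy, diffusion Monte Carlo and transfer-learning
variants are out of scope.
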