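# Synthetic surrogate surfaces and geometry sampling: a high-level /
# low-level surface pair built from the packaged ethanol force field, so
# the whole delta-ML pipeline runs and is testable with no external
# electronic-structure data.

#' Specification of a surrogate high-level / low-level surface pair
#'
#' The high-level (HL) surface is the unperturbed packaged ethanol force
#' field (optionally plus a small seeded PIP perturbation); the low-level
#' (LL) surface is the same force field with its parameters perturbed by
#' seeded random amounts -- by default +-10 percent on every force
#' constant (bond, angle and dihedral k) and +-0.02 Angstrom on bond
#' equilibrium lengths, drawn once per parameter *type* so permutational
#' symmetry is preserved.  With these defaults HL - LL is smooth and much
#' smaller in spread than the LL energies themselves, which is the
#' premise the delta correction relies on.
#'
#' @param seed integer seed; fixes the surfaces and all sampling.
#' @param k_frac fractional half-width of the force-constant
#'   perturbation.
#' @param re_shift half-width of the bond-length perturbation, Angstrom.
#' @param bond_style `"morse"` (default) or `"harmonic"` bond stretches
#'   for both surfaces.
#' @param pip_perturbation optional list(order, scale_cm1): adds a seeded
#'   PIP surface of that order with coefficients ~ N(0, scale) (cm^-1)
#'   to the HL definition.
#' @param temperature sampling amplitude ceiling in cm^-1 (see
#'   [sample_geometries()]): each sample draws an amplitude between a
#'   small fraction of this value and the full value, so the energy
#'   distribution is bottom-heavy but reaches the ceiling.
#' @param e_max energy ceiling above the HL minimum for sampling, cm^-1
#'   (default 30,000).
#' @return an object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(seed = 1L, k_frac = 0.10, re_shift = 0.02,
                           bond_style = c("morse", "harmonic"),
                           pip_perturbation = NULL,
                           temperature = 3000, e_max = 30000) {
  bond_style <- match.arg(bond_style)
  if (k_frac < 0 || re_shift < 0) stop("perturbation widths must be >= 0")
  structure(list(seed = as.integer(seed), k_frac = k_frac,
                 re_shift = re_shift, bond_style = bond_style,
                 pip_perturbation = pip_perturbation,
                 temperature = temperature, e_max = e_max),
            class = "surrogate_spec")
}

# perturb per unique parameter type so equivalent atoms stay equivalent
perturb_forcefield <- function(ff, k_frac, re_shift) {
  draw <- function(width) stats::runif(1, -width, width)
  for (ty in unique(ff$bonds$type)) {
    rows <- ff$bonds$type == ty
    ff$bonds$k[rows] <- ff$bonds$k[rows] * (1 + draw(k_frac))
    ff$bonds$re[rows] <- ff$bonds$re[rows] + draw(re_shift)
    mo <- rows & ff$bonds$style == "morse"
    if (any(mo))
      ff$bonds$alpha[mo] <- morse_alpha(ff$bonds$k[mo], ff$bonds$de[mo],
                                        ff$k_convention)
  }
  for (ty in unique(ff$angles$type)) {
    rows <- ff$angles$type == ty
    ff$angles$ka[rows] <- ff$angles$ka[rows] * (1 + draw(k_frac))
  }
  for (ty in unique(ff$dihedrals$type)) {
    rows <- ff$dihedrals$type == ty
    ff$dihedrals$kd[rows] <- ff$dihedrals$kd[rows] * (1 + draw(k_frac))
  }
  ff
}

#' Build a surrogate high-level / low-level surface pair
#'
#' See [surrogate_spec()] for what the two surfaces are.  When
#' `check_premise` is TRUE the function samples `n_check` geometries from
#' the HL surface and reports the ratio sd(HL - LL) / sd(LL) in the
#' returned object; a ratio of 1 or more (the correction varying as
#' strongly as the surface itself) triggers a premise-violation warning.
#'
#' @param spec a [surrogate_spec()].
#' @param check_premise verify and record the smooth-difference premise.
#' @param n_check geometries used for the premise check.
#' @return list with elements `hl`, `ll` (both `pes_surface`), `spec`,
#'   and `premise_ratio` (NA if unchecked).
#' @export
make_surrogate_pair <- function(spec = surrogate_spec(),
                                check_premise = TRUE, n_check = 200) {
  hl <- ethanol_forcefield(bond_style = spec$bond_style)
  ll <- withr::with_seed(spec$seed,
    perturb_forcefield(hl, spec$k_frac, spec$re_shift))
  if (!is.null(spec$pip_perturbation)) {
    pp <- spec$pip_perturbation
    basis <- build_pip_basis(ethanol_symmetry(), pp$order)
    coefs <- withr::with_seed(spec$seed + 1L,
                              stats::rnorm(basis$n_p, sd = pp$scale_cm1))
    hl <- compose_delta(hl, potential_model(basis, coefs,
                                            energy_unit = "cm-1",
                                            note = "seeded HL perturbation"))
  }
  ratio <- NA_real_
  if (check_premise) {
    geoms <- sample_geometries(hl, n = n_check, e_max = spec$e_max,
                               seed = spec$seed + 2L,
                               temperature = spec$temperature)
    e_hl <- vapply(geoms, function(g)
      convert_energy(pes_energy(hl, g), hl$energy_unit, "cm-1"), numeric(1))
    e_ll <- vapply(geoms, function(g)
      convert_energy(pes_energy(ll, g), ll$energy_unit, "cm-1"), numeric(1))
    ratio <- stats::sd(e_hl - e_ll) / stats::sd(e_ll)
    if (!is.finite(ratio) || ratio >= 1)
      warning(sprintf("premise violation: sd(HL-LL)/sd(LL) = %.3g; the correction varies as strongly as the surface",
                      ratio))
  }
  list(hl = hl, ll = ll, spec = spec, premise_ratio = ratio)
}

# ethanol rotor definitions used by the default sampler
ethanol_rotors <- function() {
  list(list(axis = c(6L, 7L), atoms = 1:3),   # methyl about C-C
       list(axis = c(7L, 8L), atoms = 9L))    # hydroxyl H about C-O
}

#' Sample geometries from a surface
#'
#' Emulates thermal trajectory sampling without molecular dynamics: the
#' surface is minimized from `start`, normal modes are computed at the
#' minimum, and each sample displaces the minimum along all physical
#' modes with Gaussian mass-weighted amplitudes, plus uniform random
#' rigid rotations of the listed torsional rotors.  Each sample's mode
#' amplitude is scaled by an effective temperature drawn as
#' `temperature * runif(1, 0.15, 1)^2`, which makes the energy histogram
#' bottom-heavy (as trajectory data are: most configurations near the
#' well bottom, occasional excursions toward the ceiling).  Samples whose
#' energy exceeds `e_max` above the minimum are rejected until exactly
#' `n` are accepted.
#'
#' @param surface any `pes_surface`.
#' @param n number of samples to return.
#' @param e_max ceiling above the minimum, cm^-1.
#' @param seed integer seed (whole draw is reproducible).
#' @param temperature upper mode-amplitude parameter, cm^-1: a sample at
#'   the full amplitude carries roughly `temperature/2` of harmonic
#'   energy per physical mode.
#' @param start starting geometry for the minimization (default the
#'   ideal ethanol geometry).
#' @param rotors list of `list(axis = c(i, j), atoms = ...)` rigid-rotor
#'   randomizations (default: ethanol methyl and hydroxyl rotors; pass
#'   `list()` for none).
#' @return list of [geometry()] objects, length exactly `n`.
#' @export
sample_geometries <- function(surface, n, e_max = 30000, seed = 1L,
                              temperature = 3000,
                              start = ethanol_geometry(),
                              rotors = ethanol_rotors()) {
  sp <- optimize_geometry(surface, start, tol = 1e-6)
  H <- hessian(surface, sp$geometry)
  masses <- atomic_masses(sp$geometry$elements)
  nm <- normal_modes(H, masses)
  # eigenvalues of the mass-weighted Hessian in cm-1 / (A^2 amu)
  lam <- (nm$frequencies * 2 * pi * pes_constants$speed_of_light * 100)^2 *
    sign(nm$frequencies) * (1e-20 * pes_constants$amu_to_kg) /
    pes_constants$cm1_to_joule
  phys <- order(abs(nm$frequencies))[-(1:6)]
  if (any(lam[phys] <= 0))
    stop("surface minimum has non-positive physical curvature; cannot sample")
  e_min <- convert_energy(sp$energy, surface$energy_unit, "cm-1")
  invsq <- rep(1 / sqrt(masses), each = 3)
  x0 <- coords_to_par(sp$geometry)
  withr::with_seed(seed, {
    out <- vector("list", n)
    accepted <- 0L; tried <- 0L
    while (accepted < n) {
      tried <- tried + 1L
      t_eff <- temperature * stats::runif(1, 0.15, 1)^2
      q <- stats::rnorm(length(phys)) * sqrt(t_eff / lam[phys])
      disp <- invsq * as.vector(nm$modes[, phys, drop = FALSE] %*% q)
      x <- matrix(x0 + disp, ncol = 3, byrow = TRUE)
      for (rt in rotors)
        x <- rotate_about_axis(x, rt$atoms, x[rt$axis[1], ], x[rt$axis[2], ],
                               stats::runif(1, 0, 2 * pi))
      g <- geometry(sp$geometry$elements, x)
      e <- convert_energy(pes_energy(surface, g), surface$energy_unit, "cm-1")
      if (is.finite(e) && e - e_min <= e_max) {
        accepted <- accepted + 1L
        out[[accepted]] <- g
      }
      if (tried >= 200 && accepted / tried < 0.01)
        stop("acceptance rate below 1%: lower `temperature` or raise `e_max`")
    }
    out
  })
}

#' Evaluate a surface over geometries into a dataset
#'
#' @param surface any `pes_surface`.
#' @param geoms list of [geometry()] objects.
#' @param with_gradients also evaluate analytic 3N gradients.
#' @param energy_unit unit for the dataset (surface output is converted).
#' @param provenance free-text provenance note.
#' @return a [pes_dataset()].
#' @export
build_dataset <- function(surface, geoms, with_gradients = FALSE,
                          energy_unit = "cm-1",
                          provenance = "synthetic surrogate") {
  energies <- vapply(seq_along(geoms), function(i) {
    e <- tryCatch(pes_energy(surface, geoms[[i]]),
                  error = function(err)
                    stop(sprintf("energy evaluation failed at geometry %d: %s",
                                 i, conditionMessage(err))))
    convert_energy(e, surface$energy_unit, energy_unit)
  }, numeric(1))
  grads <- NULL
  if (with_gradients) {
    grads <- t(vapply(seq_along(geoms), function(i)
      convert_energy(pes_gradient(surface, geoms[[i]]),
                     surface$energy_unit, energy_unit),
      numeric(3 * n_atoms(geoms[[1]]))))
  }
  pes_dataset(geoms, energies, gradients = grads, energy_unit = energy_unit,
              provenance = provenance)
}
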