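# Surface-agnostic validation machinery: geometry optimization,
# finite-difference Hessians, harmonic normal modes, rigid torsional
# scans, and gradient-fidelity metrics.

coords_to_par <- function(g) as.vector(t(g$coords))
par_to_geometry <- function(par, template) {
  geometry(template$elements, matrix(par, ncol = 3, byrow = TRUE),
           template$comment)
}

#' Optimize a geometry on a surface
#'
#' Quasi-Newton (L-BFGS-B) minimization of the surface energy with
#' analytic gradients, followed by Newton refinement using the
#' finite-difference Hessian until the gradient norm drops below `tol`.
#' Because the Newton polish inverts the signed Hessian spectrum
#' (rotation/translation null directions excluded), starting close enough
#' to a saddle converges to that saddle: saddle refinement from a
#' displaced start is supported on a best-effort basis and the result is
#' labeled by its Hessian signature.
#'
#' @param surface any `pes_surface`.
#' @param start starting [geometry()].
#' @param tol convergence threshold on the Cartesian gradient 2-norm, in
#'   the surface's energy unit per Angstrom (default 1e-6).
#' @param maxit L-BFGS iteration cap.
#' @param max_newton Newton refinement iteration cap.
#' @param hessian_step finite-difference step for the refinement
#'   Hessians, Angstrom.
#' @return an object of class `stationary_point`: fields `geometry`,
#'   `energy`, `grad_norm`, `n_negative` (negative Hessian eigenvalues
#'   beyond the 6 near-zero modes) and `label` (`"minimum"`, `"saddle"`
#'   or `"stationary"`).
#' @export
optimize_geometry <- function(surface, start, tol = 1e-6, maxit = 2000,
                              max_newton = 60, hessian_step = 0.005) {
  fn <- function(p) pes_energy(surface, par_to_geometry(p, start))
  gr <- function(p) pes_gradient(surface, par_to_geometry(p, start))
  opt <- stats::optim(coords_to_par(start), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  p <- opt$par
  gnorm <- sqrt(sum(gr(p)^2))
  it <- 0L
  while (gnorm > tol / 100 && it < max_newton) {
    g <- par_to_geometry(p, start)
    H <- hessian(surface, g, step = hessian_step)
    ev <- eigen(H, symmetric = TRUE)
    lam <- ev$values
    keep <- abs(lam) > 1e-7 * max(abs(lam))
    gv <- crossprod(ev$vectors, gr(p))
    step <- -ev$vectors[, keep, drop = FALSE] %*% (gv[keep] / lam[keep])
    snorm <- sqrt(sum(step^2))
    if (snorm > 0.25) step <- step * 0.25 / snorm
    p2 <- p + as.vector(step)
    g2 <- sqrt(sum(gr(p2)^2))
    if (!is.finite(g2) || g2 > gnorm && snorm > 1e-10) {
      # damped retry
      p2 <- p + as.vector(step) / 4
      g2 <- sqrt(sum(gr(p2)^2))
    }
    if (!is.finite(g2)) break
    p <- p2; gnorm <- g2; it <- it + 1L
    if (gnorm <= .Machine$double.eps * 1e3) break
  }
  if (gnorm > tol)
    stop(sprintf("geometry optimization did not converge: gradient norm %.3g > tol %.3g",
                 gnorm, tol))
  g <- par_to_geometry(p, start)
  H <- hessian(surface, g, step = hessian_step)
  lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  nzero <- 6L
  lam_phys <- lam[order(abs(lam))][-seq_len(min(nzero, length(lam)))]
  n_neg <- sum(lam_phys < 0)
  structure(list(geometry = g, energy = pes_energy(surface, g),
                 grad_norm = gnorm, n_negative = n_neg,
                 label = if (n_neg == 0) "minimum"
                         else if (n_neg == 1) "saddle" else "stationary"),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  cat(sprintf("<stationary_point: %s, E = %.8g, |grad| = %.3g, %d negative mode(s)>\n",
              x$label, x$energy, x$grad_norm, x$n_negative))
  invisible(x)
}

#' Relative energetics of stationary points
#'
#' Formats energies of a set of stationary points relative to a
#' reference, side by side in kcal/mol and cm^-1.
#'
#' @param points named list of `stationary_point` objects.
#' @param reference name of the reference point (default the first).
#' @param energy_unit unit the stationary-point energies are in.
#' @return data.frame with columns `point`, `kcal_mol`, `cm1`.
#' @export
relative_energetics <- function(points, reference = names(points)[1],
                                energy_unit = "cm-1") {
  e0 <- points[[reference]]$energy
  de <- vapply(points, function(p) p$energy - e0, numeric(1))
  data.frame(point = names(points),
             kcal_mol = convert_energy(de, energy_unit, "kcal/mol"),
             cm1 = convert_energy(de, energy_unit, "cm-1"),
             row.names = NULL)
}

#' Finite-difference Hessian of a surface
#'
#' Central differences of the analytic Cartesian gradient, symmetrized as
#' (H + t(H))/2.
#'
#' @param surface any `pes_surface`.
#' @param g a [geometry()].
#' @param step displacement step, Angstrom (default 0.005; steps below
#'   1e-6 trigger a numerical-noise warning).
#' @return 3N x 3N symmetric matrix with an `energy_unit` attribute,
#'   energy unit per Angstrom^2.
#' @export
hessian <- function(surface, g, step = 0.005) {
  if (step <= 0) stop("step must be positive")
  if (step < 1e-6)
    warning("Hessian step below 1e-6 Angstrom is likely dominated by numerical noise")
  n3 <- 3 * n_atoms(g)
  H <- matrix(0, n3, n3)
  p0 <- coords_to_par(g)
  for (j in seq_len(n3)) {
    pp <- p0; pp[j] <- pp[j] + step
    pm <- p0; pm[j] <- pm[j] - step
    H[, j] <- (pes_gradient(surface, par_to_geometry(pp, g)) -
               pes_gradient(surface, par_to_geometry(pm, g))) / (2 * step)
  }
  H <- (H + t(H)) / 2
  attr(H, "energy_unit") <- surface$energy_unit
  H
}

#' Harmonic normal modes from a Hessian
#'
#' Diagonalizes the mass-weighted Hessian M^(-1/2) H M^(-1/2) and
#' converts eigenvalues to wavenumbers,
#' nu_i = sign(lambda_i) * sqrt(|lambda_i|) / (2 pi c); imaginary
#' frequencies are reported as negative numbers.
#'
#' @param h Hessian matrix (energy unit per Angstrom^2; the unit is read
#'   from the matrix's `energy_unit` attribute unless given explicitly).
#' @param masses per-atom masses in amu (see [atomic_masses()]).
#' @param energy_unit energy unit of `h`.
#' @param mass_convention recorded in the result for bookkeeping.
#' @param zero_threshold modes with |nu| below this (cm^-1, default 5)
#'   are counted as the translation/rotation nullspace.
#' @return an object of class `normal_modes`: `frequencies` (cm^-1,
#'   ascending), `modes` (mass-weighted eigenvectors, columns matching
#'   the frequencies), `n_zero`, and the conventions used.
#' @export
normal_modes <- function(h, masses,
                         energy_unit = attr(h, "energy_unit"),
                         mass_convention = "standard",
                         zero_threshold = 5) {
  if (is.null(energy_unit))
    stop("supply energy_unit (or a Hessian carrying the attribute)")
  n3 <- nrow(h)
  if (!isTRUE(all.equal(h, t(h), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("Hessian is not symmetric")
  if (length(masses) * 3 != n3) stop("need one mass per atom")
  if (any(masses <= 0)) stop("masses must be positive")
  invsq <- rep(1 / sqrt(masses), each = 3)
  hw <- h * tcrossprod(invsq)
  ev <- eigen((hw + t(hw)) / 2, symmetric = TRUE)
  # eigenvalue unit: energy_unit / (A^2 amu) -> s^-2
  efac <- switch(energy_unit,
                 "cm-1" = pes_constants$cm1_to_joule,
                 "kcal/mol" = pes_constants$kcalmol_to_joule,
                 "hartree" = pes_constants$hartree_to_cm1 *
                   pes_constants$cm1_to_joule,
                 stop("unknown energy unit: ", energy_unit))
  lam_si <- ev$values * efac / (1e-20 * pes_constants$amu_to_kg)
  nu <- sign(lam_si) * sqrt(abs(lam_si)) /
    (2 * pi * pes_constants$speed_of_light) / 100
  ord <- order(nu)
  structure(list(frequencies = nu[ord],
                 modes = ev$vectors[, ord, drop = FALSE],
                 n_zero = sum(abs(nu) < zero_threshold),
                 energy_unit = energy_unit,
                 mass_convention = mass_convention,
                 zero_threshold = zero_threshold),
            class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat(sprintf("<normal_modes: %d modes (%d near-zero), %s masses>\n",
              length(x$frequencies), x$n_zero, x$mass_convention))
  cat(" frequencies (cm-1):",
      paste(sprintf("%.1f", x$frequencies), collapse = " "), "\n")
  invisible(x)
}

#' Physical (non-null) frequencies of a normal-mode result
#'
#' Drops the `n` modes of smallest absolute frequency (default 6, the
#' translation/rotation nullspace of a nonlinear molecule) and returns
#' the rest sorted ascending.
#'
#' @param nm a [normal_modes()] result, or a plain frequency vector.
#' @param n_drop number of null modes to drop.
#' @return numeric vector of frequencies, cm^-1, ascending.
#' @export
physical_frequencies <- function(nm, n_drop = 6) {
  freqs <- if (inherits(nm, "normal_modes")) nm$frequencies else nm
  keep <- order(abs(freqs))[-seq_len(min(n_drop, length(freqs)))]
  sort(freqs[keep])
}

#' Mean absolute error between two frequency lists
#'
#' Index-matched pairing of two ascending-sorted lists over the same
#' number of physical modes.
#'
#' @param ref,test numeric vectors of equal length, sorted ascending.
#' @return scalar MAE in the input unit (cm^-1 by convention).
#' @export
frequency_mae <- function(ref, test) {
  if (length(ref) != length(test))
    stop(sprintf("frequency lists differ in length: %d vs %d",
                 length(ref), length(test)))
  mean(abs(ref - test))
}

# rotate a set of atoms about the axis through points a1 -> a2 by angle
rotate_about_axis <- function(coords, atoms, a1, a2, angle) {
  axis <- a2 - a1
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  coords[atoms, ] <- sweep(sweep(coords[atoms, , drop = FALSE], 2, a1) %*%
                             t(R), 2, a1, "+")
  coords
}

#' Torsional scan about a dihedral
#'
#' Rigid scan (default): the rotor atoms are rotated about the central
#' bond of the dihedral by each grid angle away from the reference
#' geometry, all other coordinates frozen -- the "not fully relaxed"
#' protocol.  The `"relaxed"` mode instead re-optimizes all coordinates
#' at each grid point under a stiff harmonic restraint holding the
#' scanned dihedral (labeled in the output; this is a constrained
#' relaxation, not a rigid scan).
#'
#' @param surface any `pes_surface`.
#' @param g reference [geometry()].
#' @param dihedral integer vector of 4 atom indices; the rotation axis is
#'   its central bond.
#' @param rotor_atoms indices of the rotating fragment; must not contain
#'   either axis atom.
#' @param grid scan angles in degrees (offsets from the reference
#'   geometry).
#' @param mode `"rigid"` or `"relaxed"`.
#' @param restraint_k harmonic dihedral restraint for the relaxed mode,
#'   energy unit per rad^2.
#' @return an object of class `torsion_scan`: `angle_deg`, `energy`
#'   (absolute, surface unit), `energy_rel` (above the scan minimum),
#'   `barrier` (max - min), `mode`.
#' @export
torsion_scan <- function(surface, g, dihedral, rotor_atoms,
                         grid = seq(0, 360, by = 10),
                         mode = c("rigid", "relaxed"),
                         restraint_k = 1e4) {
  mode <- match.arg(mode)
  dihedral <- as.integer(dihedral)
  if (length(dihedral) != 4) stop("dihedral must name 4 atoms")
  axis <- dihedral[2:3]
  if (any(axis %in% rotor_atoms))
    stop("rotor_atoms must not contain an axis atom")
  a1 <- g$coords[axis[1], ]; a2 <- g$coords[axis[2], ]
  energies <- vapply(grid, function(ang) {
    x <- rotate_about_axis(g$coords, rotor_atoms, a1, a2, ang * pi / 180)
    gg <- geometry(g$elements, x, g$comment)
    if (mode == "rigid") return(pes_energy(surface, gg))
    phi0 <- dihedral_angle(x[dihedral[1], ], x[dihedral[2], ],
                           x[dihedral[3], ], x[dihedral[4], ])
    restrained <- function_surface(
      energy_fn = function(gr2) {
        phi <- dihedral_angle(gr2$coords[dihedral[1], ], gr2$coords[dihedral[2], ],
                              gr2$coords[dihedral[3], ], gr2$coords[dihedral[4], ])
        dphi <- atan2(sin(phi - phi0), cos(phi - phi0))
        pes_energy(surface, gr2) + restraint_k * dphi^2
      },
      natoms = n_atoms(g), energy_unit = surface$energy_unit)
    opt <- stats::optim(coords_to_par(gg),
                        function(p) pes_energy(restrained,
                                               par_to_geometry(p, gg)),
                        method = "L-BFGS-B",
                        control = list(maxit = 500))
    pes_energy(surface, par_to_geometry(opt$par, gg))
  }, numeric(1))
  rel <- energies - min(energies)
  structure(list(angle_deg = grid, energy = energies, energy_rel = rel,
                 barrier = max(rel), mode = mode,
                 energy_unit = surface$energy_unit,
                 dihedral = dihedral),
            class = "torsion_scan")
}

#' @export
print.torsion_scan <- function(x, ...) {
  cat(sprintf("<torsion_scan (%s): %d points, barrier %.4g %s>\n",
              x$mode, length(x$angle_deg), x$barrier, x$energy_unit))
  invisible(x)
}

#' Gradient-fidelity metrics for one geometry
#'
#' Compares a test gradient vector with a reference one: the cosine of
#' the angle between them and the mean absolute difference of their
#' components.
#'
#' @param g_ref,g_test numeric vectors of equal length (3N Cartesian
#'   gradient components).
#' @return list with `cos_theta` (NA with a warning if either vector has
#'   zero norm) and `mae`.
#' @export
gradient_fidelity <- function(g_ref, g_test) {
  if (length(g_ref) != length(g_test))
    stop("gradient vectors differ in length")
  nr <- sqrt(sum(g_ref^2)); nt <- sqrt(sum(g_test^2))
  ct <- if (nr == 0 || nt == 0) {
    warning("cos(theta) undefined for a zero-norm gradient vector")
    NA_real_
  } else {
    max(-1, min(1, sum(g_ref * g_test) / (nr * nt)))
  }
  list(cos_theta = ct, mae = mean(abs(g_ref - g_test)))
}

#' Gradient-fidelity report over a set of geometries
#'
#' Evaluates reference and test surfaces' gradients at each geometry
#' (test converted into the reference's energy unit) and tabulates
#' per-geometry cos(theta) and component MAE plus their means.
#'
#' @param ref_surface,test_surface `pes_surface` objects.
#' @param geometries list of [geometry()] objects.
#' @return data.frame with columns `cos_theta` and `mae`, with attributes
#'   `mean_cos_theta` and `mean_mae`.
#' @export
gradient_fidelity_report <- function(ref_surface, test_surface, geometries) {
  rows <- lapply(geometries, function(g) {
    gr <- pes_gradient(ref_surface, g)
    gt <- convert_energy(pes_gradient(test_surface, g),
                         test_surface$energy_unit, ref_surface$energy_unit)
    gradient_fidelity(gr, gt)
  })
  out <- data.frame(cos_theta = vapply(rows, `[[`, numeric(1), "cos_theta"),
                    mae = vapply(rows, `[[`, numeric(1), "mae"))
  attr(out, "mean_cos_theta") <- mean(out$cos_theta)
  attr(out, "mean_mae") <- mean(out$mae)
  out
}
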