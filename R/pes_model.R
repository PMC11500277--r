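# Morse-variable transform, linear PIP potential models, and the
# delta-ML composition of a low-level surface with a fitted correction.

#' Morse-variable transform
#'
#' Maps internuclear distances to bounded, decaying coordinates
#' y = exp(-r / lambda).  The range parameter defaults to 2 Bohr
#' (1.05835... Angstrom), the customary value for PIP fits.
#'
#' @param lambda range parameter; a length, by default in Angstrom.
#' @param unit unit of `lambda` (`"angstrom"` or `"bohr"`).
#' @return an object of class `morse_transform` (lambda stored in
#'   Angstrom).
#' @export
morse_transform <- function(lambda = 2, unit = c("bohr", "angstrom")) {
  unit <- match.arg(unit)
  lam <- convert_length(lambda, from = unit, to = "angstrom")
  if (!is.finite(lam) || lam <= 0) stop("lambda must be positive")
  structure(list(lambda = lam), class = "morse_transform")
}

#' Morse variables from distances
#'
#' @param r numeric vector of internuclear distances, Angstrom; must be
#'   positive.
#' @param transform a [morse_transform()].
#' @return y = exp(-r / lambda), elementwise; values in (0, 1).
#' @export
morse_variables <- function(r, transform = morse_transform()) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("distances must be positive and finite")
  exp(-r / transform$lambda)
}

#' Linear PIP potential model
#'
#' The potential is V(x) = sum_i c_i p_i(y(x)) where p_i are the
#' symmetrized-monomial PIPs of `basis` and y are Morse variables of the
#' interatomic distances.  Energies are modeled as absolute values of the
#' training data; shifting to the surface minimum is a reporting choice,
#' not part of the model (the constant orbit plays the intercept role).
#'
#' @param basis a [build_pip_basis()] object.
#' @param coefficients numeric vector of length `basis$n_p`.
#' @param transform a [morse_transform()].
#' @param energy_unit unit the coefficients (and hence energies) carry.
#' @param note free-text provenance note.
#' @return an object of class `potential_model` (also a `pes_surface`).
#' @export
potential_model <- function(basis, coefficients,
                            transform = morse_transform(),
                            energy_unit = "cm-1", note = "") {
  if (!inherits(basis, "pip_basis")) stop("basis must be a pip_basis")
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != basis$n_p)
    stop(sprintf("coefficient length %d != n_p %d",
                 length(coefficients), basis$n_p))
  structure(list(basis = basis, coefficients = coefficients,
                 transform = transform, energy_unit = energy_unit,
                 natoms = basis$spec$natoms, note = note),
            class = c("potential_model", "pes_surface"))
}

#' @export
print.potential_model <- function(x, ...) {
  cat(sprintf("<potential_model: %d PIPs (order %d, symmetry %s), lambda %.6f A, unit %s>\n",
              x$basis$n_p, x$basis$max_order,
              paste(x$basis$spec$sizes, collapse = ""),
              x$transform$lambda, x$energy_unit))
  invisible(x)
}

#' Potential energy of a surface at a geometry
#'
#' Generic over every surface type in the package: [potential_model()],
#' [delta_model()], [forcefield()] and [function_surface()].
#'
#' @param surface a `pes_surface`.
#' @param g a [geometry()].
#' @param ... passed to methods.
#' @return scalar energy in `surface$energy_unit`.
#' @export
pes_energy <- function(surface, g, ...) UseMethod("pes_energy")

#' Cartesian gradient of a surface at a geometry
#'
#' @inheritParams pes_energy
#' @return numeric 3N vector (atom-major: x1,y1,z1,x2,...), energy unit
#'   per Angstrom.
#' @export
pes_gradient <- function(surface, g, ...) UseMethod("pes_gradient")

check_natoms <- function(surface, g) {
  if (n_atoms(g) != surface$natoms)
    stop(sprintf("geometry has %d atoms but surface expects %d",
                 n_atoms(g), surface$natoms))
}

#' @export
pes_energy.potential_model <- function(surface, g, ...) {
  check_natoms(surface, g)
  y <- morse_variables(pair_distances(g), surface$transform)
  sum(surface$coefficients * evaluate_basis(surface$basis, y))
}

# d r_k / d x  as an M x 3N matrix plus the distances themselves
pair_distance_jacobian <- function(g, clash_tol = 1e-6) {
  p <- pair_list(n_atoms(g))
  dx <- g$coords[p$a, , drop = FALSE] - g$coords[p$b, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  if (any(r < clash_tol)) stop("degenerate geometry: coincident atoms")
  u <- dx / r
  Tm <- matrix(0, p$M, 3 * n_atoms(g))
  for (i in 1:3) {
    Tm[cbind(seq_len(p$M), 3 * (p$a - 1) + i)] <- u[, i]
    Tm[cbind(seq_len(p$M), 3 * (p$b - 1) + i)] <- -u[, i]
  }
  list(r = r, T = Tm)
}

# full Cartesian Jacobian of the basis functions: n_p x 3N
basis_cartesian_jacobian <- function(basis, transform, g) {
  pj <- pair_distance_jacobian(g)
  y <- morse_variables(pj$r, transform)
  B <- basis_jacobian(basis, y)              # n_p x M
  dydr <- -y / transform$lambda
  B %*% (dydr * pj$T)                        # n_p x 3N
}

#' @export
pes_gradient.potential_model <- function(surface, g, ...) {
  check_natoms(surface, g)
  J <- basis_cartesian_jacobian(surface$basis, surface$transform, g)
  as.vector(crossprod(J, surface$coefficients))
}

#' Compose a low-level surface with a correction surface (delta-ML)
#'
#' The corrected surface is the exact sum of a low-level surface (a
#' [potential_model()] or [forcefield()]) and a (typically much smaller)
#' fitted correction: energies and gradients are added, with the
#' low-level values converted into the correction's energy unit.  The
#' two surfaces are kept separate rather than merged into a single refit.
#'
#' @param v_ll low-level surface (any `pes_surface`).
#' @param delta correction surface (a `potential_model`).
#' @return an object of class `delta_model` (also a `pes_surface`).
#' @export
compose_delta <- function(v_ll, delta) {
  if (!inherits(v_ll, "pes_surface") || !inherits(delta, "pes_surface"))
    stop("both components must be pes_surface objects")
  if (v_ll$natoms != delta$natoms)
    stop(sprintf("atom count mismatch: low-level %d vs correction %d",
                 v_ll$natoms, delta$natoms))
  structure(list(v_ll = v_ll, delta = delta,
                 natoms = delta$natoms,
                 energy_unit = delta$energy_unit),
            class = c("delta_model", "pes_surface"))
}

#' @export
print.delta_model <- function(x, ...) {
  cat(sprintf("<delta_model: %s + correction (%s), unit %s>\n",
              class(x$v_ll)[1], class(x$delta)[1], x$energy_unit))
  invisible(x)
}

#' @export
pes_energy.delta_model <- function(surface, g, ...) {
  convert_energy(pes_energy(surface$v_ll, g),
                 surface$v_ll$energy_unit, surface$energy_unit) +
    pes_energy(surface$delta, g)
}

#' @export
pes_gradient.delta_model <- function(surface, g, ...) {
  convert_energy(pes_gradient(surface$v_ll, g),
                 surface$v_ll$energy_unit, surface$energy_unit) +
    pes_gradient(surface$delta, g)
}

#' Wrap plain R functions as a surface
#'
#' Convenience for tests and custom analytic surfaces: supply an energy
#' function of a geometry and (optionally) a gradient function; if the
#' gradient is omitted it is computed by central finite differences.
#'
#' @param energy_fn function(geometry) -> scalar.
#' @param gradient_fn function(geometry) -> 3N vector, or NULL.
#' @param natoms atom count the surface expects.
#' @param energy_unit energy unit label.
#' @param fd_step finite-difference step (Angstrom) when `gradient_fn` is
#'   NULL.
#' @return an object of class `function_surface` (also a `pes_surface`).
#' @export
function_surface <- function(energy_fn, gradient_fn = NULL, natoms,
                             energy_unit = "cm-1", fd_step = 1e-5) {
  structure(list(energy_fn = energy_fn, gradient_fn = gradient_fn,
                 natoms = as.integer(natoms), energy_unit = energy_unit,
                 fd_step = fd_step),
            class = c("function_surface", "pes_surface"))
}

#' @export
pes_energy.function_surface <- function(surface, g, ...) {
  check_natoms(surface, g)
  surface$energy_fn(g)
}

#' @export
pes_gradient.function_surface <- function(surface, g, ...) {
  check_natoms(surface, g)
  if (!is.null(surface$gradient_fn)) return(surface$gradient_fn(g))
  numeric_gradient(surface, g, step = surface$fd_step)
}

# central-difference Cartesian gradient of any surface (oracle / fallback)
numeric_gradient <- function(surface, g, step = 1e-5) {
  n <- n_atoms(g)
  grad <- numeric(3 * n)
  for (a in seq_len(n)) for (i in 1:3) {
    gp <- g; gp$coords[a, i] <- gp$coords[a, i] + step
    gm <- g; gm$coords[a, i] <- gm$coords[a, i] - step
    grad[3 * (a - 1) + i] <-
      (pes_energy(surface, gp) - pes_energy(surface, gm)) / (2 * step)
  }
  grad
}

#' Save a potential model to a plain-text (JSON) file
#'
#' Stores the symmetry spec, order, Morse range parameter, units and the
#' coefficient vector at full precision; [read_potential_model()]
#' rebuilds the basis and returns an identical model.
#'
#' @param model a `potential_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_potential_model <- function(model, path) {
  obj <- list(
    format = "deltapes-potential-model", version = 1L,
    sizes = model$basis$spec$sizes, natoms = model$basis$spec$natoms,
    classes = model$basis$spec$classes, max_order = model$basis$max_order,
    lambda_angstrom = model$transform$lambda,
    energy_unit = model$energy_unit, note = model$note,
    coefficients = model$coefficients
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a potential model written by [write_potential_model()]
#'
#' @param path file path.
#' @return a `potential_model`.
#' @export
read_potential_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "deltapes-potential-model"))
    stop("not a deltapes potential model file: ", path)
  spec <- symmetry_spec(obj$sizes, natoms = obj$natoms,
                        classes = lapply(obj$classes, as.integer))
  basis <- build_pip_basis(spec, obj$max_order)
  tr <- structure(list(lambda = obj$lambda_angstrom),
                  class = "morse_transform")
  potential_model(basis, obj$coefficients, transform = tr,
                  energy_unit = obj$energy_unit, note = obj$note %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
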