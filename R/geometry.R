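# Molecular geometry container, XYZ I/O, distances, atom permutations.

#' Create a molecular geometry
#'
#' A `geometry` is the basic container for one nuclear configuration:
#' element symbols plus an N x 3 matrix of Cartesian coordinates in
#' Angstrom.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix, Angstrom.
#' @param comment free-text comment (carried through XYZ round-trips).
#' @return an object of class `geometry`.
#' @export
geometry <- function(elements, coords, comment = "") {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3)
    stop("coords must be an N x 3 matrix")
  if (length(elements) != nrow(coords))
    stop("length(elements) must equal nrow(coords)")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  elements <- canonical_element(elements)
  atomic_masses(elements) # validates symbols against the mass table
  structure(
    list(elements = elements, coords = unname(coords),
         comment = as.character(comment)[1]),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms [%s]>\n", n_atoms(x),
              paste(x$elements, collapse = " ")))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g a `geometry`.
#' @return integer atom count.
#' @export
n_atoms <- function(g) length(g$elements)

#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ: an atom-count line, a comment line, then N lines of
#' `element x y z`; frames may be concatenated.  Element symbols are
#' case-insensitive on read.  If the comment line contains
#' `energy=<value>` the value is parsed into an `energy` attribute on the
#' frame (opportunistic, never required).
#'
#' @param path file path.
#' @return list of `geometry` objects, one per frame.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  # drop trailing blank lines only
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)]))
    lines <- lines[-length(lines)]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("XYZ parse error at line %d: expected atom count, got '%s'",
                   i, lines[i]))
    if (i + 1L + n > length(lines))
      stop(sprintf("XYZ parse error at line %d: frame truncated (%d atoms declared)",
                   i, n))
    comment <- lines[i + 1L]
    el <- character(n); xyz <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      ln <- i + 1L + k
      tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(tok) < 4)
        stop(sprintf("XYZ parse error at line %d: expected 'element x y z'", ln))
      el[k] <- tok[1]
      v <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(v)))
        stop(sprintf("XYZ parse error at line %d: non-numeric coordinate", ln))
      xyz[k, ] <- v
    }
    g <- geometry(el, xyz, comment = comment)
    em <- regmatches(comment,
                     regexpr("energy=\\s*[-+0-9.eE]+", comment))
    if (length(em) == 1)
      attr(g, "energy") <- as.numeric(sub("energy=\\s*", "", em))
    frames[[length(frames) + 1L]] <- g
    i <- i + 2L + n
  }
  if (length(frames) == 0) stop("empty XYZ file: ", path)
  frames
}

#' Write geometries to an XYZ file
#'
#' @param geoms a `geometry` or list of geometries.
#' @param path output file path.
#' @param digits coordinate digits (default 12, round-trips to < 1e-10 A).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geoms, path, digits = 12) {
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    writeLines(as.character(n_atoms(g)), con)
    writeLines(g$comment, con)
    writeLines(sprintf("%-3s % .*f % .*f % .*f", g$elements,
                       digits, g$coords[, 1], digits, g$coords[, 2],
                       digits, g$coords[, 3]), con)
  }
  invisible(path)
}

#' Interatomic distance matrix
#'
#' @param g a `geometry` with at least 2 atoms.
#' @param clash_tol minimum allowed interatomic distance in Angstrom
#'   (default 1e-6); closer pairs raise a degenerate-geometry error.
#' @return symmetric N x N matrix of Euclidean distances, Angstrom.
#' @export
distance_matrix <- function(g, clash_tol = 1e-6) {
  if (n_atoms(g) < 2) stop("distance_matrix needs at least 2 atoms")
  d <- as.matrix(stats::dist(g$coords))
  dimnames(d) <- NULL
  off <- d[upper.tri(d)]
  if (any(off < clash_tol))
    stop(sprintf("degenerate geometry: atom pair closer than %g Angstrom",
                 clash_tol))
  d
}

# Fixed enumeration of the M = N(N-1)/2 unordered atom pairs:
# (1,2),(1,3),...,(1,N),(2,3),...  Everything indexed over pair variables
# (Morse variables, PIP monomials) uses this order.
pair_list <- function(n) {
  if (n < 2) stop("need at least 2 atoms")
  idx <- utils::combn(n, 2)
  list(a = idx[1, ], b = idx[2, ], M = ncol(idx))
}

# distances as the length-M pair vector (same order as pair_list)
pair_distances <- function(g, clash_tol = 1e-6) {
  d <- distance_matrix(g, clash_tol = clash_tol)
  p <- pair_list(n_atoms(g))
  d[cbind(p$a, p$b)]
}

#' Apply an atom permutation to a geometry
#'
#' Reorders atoms by `perm` (row `i` of the result is atom `perm[i]` of
#' the input).  Atoms may only be mapped onto atoms of the same element.
#'
#' @param g a `geometry`.
#' @param perm integer permutation of `1:n_atoms(g)`.
#' @return permuted `geometry`.
#' @export
apply_permutation <- function(g, perm) {
  n <- n_atoms(g)
  perm <- as.integer(perm)
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    stop("perm must be a permutation of 1..N")
  if (!all(g$elements[perm] == g$elements))
    stop("symmetry violation: permutation maps atoms of different elements onto each other")
  geometry(g$elements[perm], g$coords[perm, , drop = FALSE],
           comment = g$comment)
}

# Rigid-motion helpers (used by tests and the sampler)
rotate_geometry <- function(g, R, center = c(0, 0, 0)) {
  xc <- sweep(g$coords, 2, center)
  geometry(g$elements, sweep(xc %*% t(R), 2, center, "+"), g$comment)
}

translate_geometry <- function(g, v) {
  geometry(g$elements, sweep(g$coords, 2, v, "+"), g$comment)
}

# Random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  R <- R %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
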