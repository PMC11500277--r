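# Permutationally invariant polynomial (PIP) bases: monomial-orbit
# symmetrization over the permutation group of like atoms, acting on the
# M = N(N-1)/2 unordered-pair variables.

#' Permutational symmetry specification
#'
#' Describes which atoms of an N-atom molecule are mutually permutable.
#' The spec is a vector of class sizes summing to N, conventionally
#' written as a digit string: ethanol is `"321111"` (3 methyl H, 2
#' methylene H, then C, C, O, hydroxyl H, each in its own class).
#'
#' @param sizes class sizes: an integer vector, or a digit string such as
#'   `"321111"` (each character one class).
#' @param natoms total atom count N; defaults to `sum(sizes)`.
#' @param classes optional list of atom-index vectors, one per class,
#'   mapping each geometry atom to its symmetry class; the default assigns
#'   contiguous blocks in the order the sizes are written, so any XYZ atom
#'   ordering can be accommodated by passing `classes` explicitly.
#' @param elements optional element symbols used to check that each class
#'   is chemically homogeneous.
#' @return an object of class `symmetry_spec`.
#' @export
symmetry_spec <- function(sizes, natoms = NULL, classes = NULL,
                          elements = NULL) {
  if (is.character(sizes) && length(sizes) == 1)
    sizes <- as.integer(strsplit(sizes, "")[[1]])
  sizes <- as.integer(sizes)
  if (any(is.na(sizes)) || any(sizes < 1))
    stop("class sizes must be positive integers")
  if (is.null(natoms)) natoms <- sum(sizes)
  if (sum(sizes) != natoms)
    stop(sprintf("class sizes sum to %d but natoms = %d", sum(sizes), natoms))
  if (natoms < 2) stop("need at least 2 atoms")
  if (is.null(classes)) {
    ends <- cumsum(sizes)
    classes <- mapply(function(a, b) seq.int(a, b),
                      c(1L, utils::head(ends, -1) + 1L), ends,
                      SIMPLIFY = FALSE)
  }
  if (length(classes) != length(sizes) ||
      !identical(sort(unlist(classes)), seq_len(natoms)) ||
      any(lengths(classes) != sizes))
    stop("classes must partition 1..N with the stated sizes")
  if (!is.null(elements)) {
    elements <- canonical_element(elements)
    for (cl in classes)
      if (length(unique(elements[cl])) > 1)
        stop("symmetry violation: class {",
             paste(cl, collapse = ","),
             "} mixes elements ", paste(unique(elements[cl]), collapse = ","))
  }
  structure(list(sizes = sizes, natoms = as.integer(natoms),
                 classes = classes,
                 M = as.integer(natoms * (natoms - 1) / 2)),
            class = "symmetry_spec")
}

#' @export
print.symmetry_spec <- function(x, ...) {
  cat(sprintf("<symmetry_spec: %s on %d atoms, group order %d, %d pair variables>\n",
              paste(x$sizes, collapse = ""), x$natoms,
              prod(factorial(x$sizes)), x$M))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", factorial(n))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Build the permutation group of a symmetry spec
#'
#' The group is the direct product of the symmetric groups on each
#' equivalence class (ethanol's `"321111"` gives order 3!x2! = 12),
#' together with the induced action on the M unordered atom pairs.
#'
#' @param spec a [symmetry_spec()] (or anything coercible: a digit string
#'   or size vector).
#' @return an object of class `permutation_group` with fields
#'   `atom_perms` (order x N matrix; row g maps atom i to `atom_perms[g, i]`)
#'   and `pair_perms` (order x M matrix; row g maps pair k to
#'   `pair_perms[g, k]` in the canonical pair enumeration).
#' @export
build_permutation_group <- function(spec) {
  if (!inherits(spec, "symmetry_spec")) spec <- symmetry_spec(spec)
  n <- spec$natoms
  class_perms <- lapply(spec$classes, function(cl) {
    lapply(all_permutations(length(cl)), function(p) cl[p])
  })
  grid <- do.call(expand.grid,
                  c(lapply(class_perms, seq_along), KEEP.OUT.ATTRS = FALSE))
  ord <- nrow(grid)
  atom_perms <- matrix(seq_len(n), ord, n, byrow = TRUE)
  for (g in seq_len(ord))
    for (ci in seq_along(spec$classes))
      atom_perms[g, spec$classes[[ci]]] <- class_perms[[ci]][[grid[g, ci]]]

  p <- pair_list(n)
  pair_key <- matrix(0L, n, n)
  pair_key[cbind(p$a, p$b)] <- seq_len(p$M)
  pair_key[cbind(p$b, p$a)] <- seq_len(p$M)
  pair_perms <- matrix(0L, ord, p$M)
  for (g in seq_len(ord)) {
    ia <- atom_perms[g, p$a]; ib <- atom_perms[g, p$b]
    pair_perms[g, ] <- pair_key[cbind(ia, ib)]
  }
  stopifnot(prod(factorial(spec$sizes)) == ord)
  structure(list(spec = spec, order = ord,
                 atom_perms = atom_perms, pair_perms = pair_perms),
            class = "permutation_group")
}

#' @export
print.permutation_group <- function(x, ...) {
  cat(sprintf("<permutation_group: order %d on %d atoms / %d pairs>\n",
              x$order, x$spec$natoms, x$spec$M))
  invisible(x)
}

# Enumerate all exponent vectors of total degree <= order in M variables,
# ordered by degree then by combination order (deterministic).  Returns an
# integer n_mono x M matrix; row 1 is the constant monomial.
enumerate_monomials <- function(M, order, memory_guard = 5e7) {
  n_mono <- choose(M + order, order)
  if (n_mono > memory_guard)
    stop(sprintf("basis too large: %.3g monomials exceeds the memory guard (%.3g)",
                 n_mono, memory_guard))
  blocks <- list(matrix(0L, 1, M))
  for (d in seq_len(order)) {
    # combinations with repetition: distinct choices from 1..M+d-1 minus 0:(d-1)
    cmb <- utils::combn(M + d - 1L, d) - (seq_len(d) - 1L)
    # tabulate variable picks per column in one pass
    key <- (rep(seq_len(ncol(cmb)), each = d) - 1L) * M + as.vector(cmb)
    cnt <- tabulate(key, nbins = ncol(cmb) * M)
    blocks[[d + 1L]] <- matrix(as.integer(cnt), ncol(cmb), M, byrow = TRUE)
  }
  do.call(rbind, blocks)
}

mono_key <- function(E) {
  do.call(paste, c(lapply(seq_len(ncol(E)), function(j) E[, j]), sep = ","))
}

#' Build a permutationally invariant polynomial basis
#'
#' Enumerates all monomials of total degree up to `max_order` in the M
#' pair variables and partitions them into orbits of the induced
#' permutation group by canonical-form hashing.  Each basis function is
#' the symmetrized monomial: the plain sum of the distinct monomials in
#' one orbit (no normalization factor).  The constant monomial forms
#' orbit 1, so the count `n_p` includes the constant term; under this
#' convention ethanol's `"321111"` spec yields 208 basis functions at
#' order 2 and 14,752 at order 4.
#'
#' @param spec a [symmetry_spec()] (or digit string / size vector).
#' @param max_order maximum total polynomial degree (>= 0).
#' @param memory_guard refuse to enumerate more than this many monomials
#'   (default 5e7); the projected count is reported in the error.
#' @return an object of class `pip_basis` with fields `n_p` (number of
#'   orbits), `n_mono`, `exponents` (sparse monomial-exponent matrix),
#'   `orbit` (orbit index per monomial) and the group.
#' @seealso [count_orbits_burnside()] for an independent count,
#'   [evaluate_basis()], [basis_jacobian()].
#' @export
build_pip_basis <- function(spec, max_order, memory_guard = 5e7) {
  if (!inherits(spec, "symmetry_spec")) spec <- symmetry_spec(spec)
  max_order <- as.integer(max_order)
  if (max_order < 0) stop("max_order must be >= 0")
  grp <- build_permutation_group(spec)
  M <- spec$M
  E <- enumerate_monomials(M, max_order, memory_guard)
  n_mono <- nrow(E)

  # canonical form: elementwise string-minimal image over the group.
  # image of exponent vector e under pair-perm pp satisfies e'[pp[k]] = e[k],
  # i.e. e' = e[inv(pp)] columnwise.
  canon <- NULL
  for (g in seq_len(grp$order)) {
    pp <- grp$pair_perms[g, ]
    inv <- integer(M); inv[pp] <- seq_len(M)
    key <- mono_key(E[, inv, drop = FALSE])
    canon <- if (is.null(canon)) key else pmin(canon, key)
  }
  orbit <- match(canon, canon[!duplicated(canon)])
  n_p <- max(orbit)

  Es <- Matrix::Matrix(E, sparse = TRUE)
  A <- Matrix::sparseMatrix(i = orbit, j = seq_len(n_mono), x = 1,
                            dims = c(n_p, n_mono))
  # per-variable nonzero rows, for evaluation at arbitrary y (incl. zeros)
  col_rows <- lapply(seq_len(M), function(j) which(E[, j] > 0L))
  col_exps <- lapply(seq_len(M), function(j) E[col_rows[[j]], j])

  structure(list(spec = spec, group = grp, max_order = max_order,
                 M = M, n_mono = n_mono, n_p = n_p,
                 exponents = Es, degrees = as.integer(rowSums(E)),
                 orbit = orbit, A = A,
                 col_rows = col_rows, col_exps = col_exps),
            class = "pip_basis")
}

#' @export
print.pip_basis <- function(x, ...) {
  cat(sprintf("<pip_basis: symmetry %s, order %d, %d monomials in %d orbits>\n",
              paste(x$spec$sizes, collapse = ""), x$max_order,
              x$n_mono, x$n_p))
  invisible(x)
}

#' Count PIP basis functions by Burnside's lemma
#'
#' Independent of [build_pip_basis()]: for each group element the number
#' of monomials of degree <= `max_order` fixed by it is counted from the
#' cycle structure of its induced pair permutation (an exponent vector is
#' fixed iff it is constant on cycles), and the orbit count is the group
#' average.  No orbit is ever enumerated.
#'
#' @inheritParams build_pip_basis
#' @return integer orbit count (constant term included).
#' @export
count_orbits_burnside <- function(spec, max_order) {
  if (!inherits(spec, "symmetry_spec")) spec <- symmetry_spec(spec)
  max_order <- as.integer(max_order)
  if (max_order < 0) stop("max_order must be >= 0")
  grp <- build_permutation_group(spec)
  M <- spec$M
  total <- 0
  for (g in seq_len(grp$order)) {
    pp <- grp$pair_perms[g, ]
    seen <- logical(M); cyc <- integer(0)
    for (k in seq_len(M)) {
      if (!seen[k]) {
        len <- 0L; j <- k
        while (!seen[j]) { seen[j] <- TRUE; j <- pp[j]; len <- len + 1L }
        cyc <- c(cyc, len)
      }
    }
    # number of cycle-constant exponent assignments with weighted degree
    # sum <= max_order: DP over the cycle-length generating function
    dp <- numeric(max_order + 1L); dp[1] <- 1
    for (len in cyc) {
      nd <- numeric(max_order + 1L)
      for (s in 0:max_order) {
        if (dp[s + 1] > 0) {
          deg <- s
          while (deg <= max_order) {
            nd[deg + 1] <- nd[deg + 1] + dp[s + 1]
            deg <- deg + len
          }
        }
      }
      dp <- nd
    }
    total <- total + sum(dp)
  }
  cnt <- total / grp$order
  if (abs(cnt - round(cnt)) > 1e-9)
    stop("Burnside count is not an integer; internal error")
  as.integer(round(cnt))
}

# raw monomial values at a pair-variable vector y (handles y = 0 exactly)
mono_values <- function(basis, y) {
  if (all(y > 0)) {
    return(exp(as.vector(basis$exponents %*% log(y))))
  }
  v <- rep(1, basis$n_mono)
  for (j in seq_len(basis$M)) {
    rows <- basis$col_rows[[j]]
    if (length(rows) > 0)
      v[rows] <- v[rows] * y[j]^basis$col_exps[[j]]
  }
  v
}

#' Evaluate a PIP basis at a pair-variable vector
#'
#' Component i is the sum of the monomials of orbit i evaluated at `y`
#' (symmetrized-monomial convention); component 1 is the constant, 1.
#' The result is exactly invariant under the induced pair permutations of
#' `y`.
#'
#' @param basis a [build_pip_basis()] object.
#' @param y numeric vector of length M (typically Morse variables).
#' @return numeric vector of length `basis$n_p`.
#' @export
evaluate_basis <- function(basis, y) {
  if (length(y) != basis$M)
    stop(sprintf("y has length %d, expected %d", length(y), basis$M))
  if (!all(is.finite(y))) stop("y must be finite")
  as.vector(basis$A %*% mono_values(basis, y))
}

#' Analytic Jacobian of a PIP basis
#'
#' Entry (i, k) is the partial derivative of basis function i with
#' respect to pair variable `y[k]`, computed from the exponent vectors.
#'
#' @inheritParams evaluate_basis
#' @return numeric `n_p` x M matrix.
#' @export
basis_jacobian <- function(basis, y) {
  if (length(y) != basis$M)
    stop(sprintf("y has length %d, expected %d", length(y), basis$M))
  if (!all(is.finite(y))) stop("y must be finite")
  if (all(y > 0)) {
    v <- mono_values(basis, y)
    Jm <- Matrix::Diagonal(x = v) %*% basis$exponents %*%
      Matrix::Diagonal(x = 1 / y)
    return(as.matrix(basis$A %*% Jm))
  }
  # general path (some y exactly zero): column-by-column
  J <- matrix(0, basis$n_p, basis$M)
  for (j in seq_len(basis$M)) {
    rows <- basis$col_rows[[j]]
    if (length(rows) == 0) next
    y2 <- y; y2[j] <- 1
    vj <- mono_values(basis, y2)       # product excluding variable j
    d <- numeric(basis$n_mono)
    e <- basis$col_exps[[j]]
    d[rows] <- e * y[j]^(e - 1L) * vj[rows]
    J[, j] <- as.vector(basis$A %*% d)
  }
  J
}

#' Write a PIP basis to a plain-text (JSON) file
#'
#' Stores the symmetry spec, order, monomial exponent vectors (sparse
#' triplets), orbit assignment and a format version; [read_pip_basis()]
#' reconstructs an identical basis.
#'
#' @param basis a `pip_basis`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pip_basis <- function(basis, path) {
  Et <- Matrix::summary(Matrix::Matrix(basis$exponents, sparse = TRUE))
  obj <- list(
    format = "deltapes-pip-basis", version = 1L,
    sizes = basis$spec$sizes, natoms = basis$spec$natoms,
    classes = basis$spec$classes, max_order = basis$max_order,
    n_mono = basis$n_mono, n_p = basis$n_p,
    triplets = list(i = Et$i, j = Et$j, x = as.integer(Et$x)),
    orbit = basis$orbit
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PIP basis written by [write_pip_basis()]
#'
#' Rebuilds the basis from the stored spec and order and checks that the
#' stored orbit partition matches the reconstruction.
#'
#' @param path file path.
#' @return a `pip_basis`.
#' @export
read_pip_basis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "deltapes-pip-basis"))
    stop("not a deltapes PIP basis file: ", path)
  spec <- symmetry_spec(obj$sizes, natoms = obj$natoms,
                        classes = lapply(obj$classes, as.integer))
  basis <- build_pip_basis(spec, obj$max_order)
  if (basis$n_p != obj$n_p || basis$n_mono != obj$n_mono)
    stop("stored basis is inconsistent with its spec/order")
  basis
}
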