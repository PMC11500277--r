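# Classical intramolecular force field: harmonic or Morse bond stretches,
# harmonic angle bends, cosine dihedral torsions.  Native energy unit is
# kcal/mol; angles are degrees on disk, radians internally.

#' Morse width parameter from harmonic force constant and well depth
#'
#' Matches the curvature of the Morse bond De*(1 - exp(-alpha*(r-re)))^2
#' to the harmonic stretch at the equilibrium distance.  Under the
#' default `"half"` convention the harmonic term is (1/2)*k*(r-re)^2 and
#' alpha = sqrt(k / (2*De)); under `"full"` it is k*(r-re)^2 and
#' alpha = sqrt(k / De).  Either consistent pairing reproduces the
#' harmonic second derivative at re exactly.
#'
#' @param k_bond harmonic force constant, kcal/mol/A^2.
#' @param D_e dissociation energy, kcal/mol.
#' @param convention `"half"` (default) or `"full"` harmonic prefactor.
#' @return alpha in 1/Angstrom.
#' @export
morse_alpha <- function(k_bond, D_e, convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (any(k_bond <= 0) || any(D_e <= 0))
    stop("k_bond and D_e must be positive")
  if (convention == "half") sqrt(k_bond / (2 * D_e)) else sqrt(k_bond / D_e)
}

prefactor <- function(convention) if (convention == "half") 0.5 else 1.0

#' Construct a force field
#'
#' Total energy is the sum of bond, angle and dihedral terms:
#' bonds are `pref*k*(r - re)^2` (harmonic) or
#' `De*(1 - exp(-alpha*(r - re)))^2` (Morse, alpha from [morse_alpha()]);
#' angles are `pref*k*(theta - theta_e)^2`; dihedrals are
#' `k*(1 + cos(n*phi - delta))`.  `pref` is 1/2 or 1 according to the
#' single global `k_convention` switch.  No nonbonded terms are included.
#'
#' @param elements element symbols of the molecule's atoms.
#' @param bonds data.frame with columns i, j, type, style ("harmonic" or
#'   "morse"), k, re, and de (NA for harmonic rows).
#' @param angles data.frame with columns i, j, k (j central), type, ka,
#'   theta_e (radians).
#' @param dihedrals data.frame with columns i, j, k, l, type, kd, n,
#'   delta (radians).
#' @param k_convention `"half"` or `"full"` harmonic prefactor.
#' @return an object of class `forcefield` (also a `pes_surface`), energy
#'   unit kcal/mol.
#' @export
forcefield <- function(elements, bonds, angles, dihedrals,
                       k_convention = c("half", "full")) {
  k_convention <- match.arg(k_convention)
  n <- length(elements)
  idx <- c(bonds$i, bonds$j, angles$i, angles$j, angles$k,
           dihedrals$i, dihedrals$j, dihedrals$k, dihedrals$l)
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n))
    stop("topology references an atom index outside 1..N")
  if (nrow(bonds) > 0) {
    if (any(bonds$k <= 0) || any(bonds$re <= 0))
      stop("bond k and re must be positive")
    mo <- bonds$style == "morse"
    if (any(mo & (is.na(bonds$de) | bonds$de <= 0)))
      stop("Morse bonds need a positive D_e")
    bonds$alpha <- NA_real_
    bonds$alpha[mo] <- morse_alpha(bonds$k[mo], bonds$de[mo], k_convention)
  }
  if (nrow(angles) > 0 &&
      (any(angles$ka <= 0) || any(angles$theta_e <= 0) ||
       any(angles$theta_e >= pi)))
    stop("angle terms need ka > 0 and 0 < theta_e < pi")
  if (nrow(dihedrals) > 0 && any(dihedrals$n < 1))
    stop("dihedral multiplicity must be >= 1")
  structure(list(elements = canonical_element(elements),
                 natoms = n, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, k_convention = k_convention,
                 energy_unit = "kcal/mol"),
            class = c("forcefield", "pes_surface"))
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("<forcefield: %d atoms, %d bonds (%s), %d angles, %d dihedrals, %s-k convention>\n",
              x$natoms, nrow(x$bonds),
              paste(unique(x$bonds$style), collapse = "/"),
              nrow(x$angles), nrow(x$dihedrals), x$k_convention))
  invisible(x)
}

# --- internal geometry kernels -------------------------------------------

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at three atom positions
#' @param p1,p2,p3 coordinate vectors; `p2` is the central atom.
#' @return angle in radians.
#' @export
angle_between <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosv)))
}

#' Dihedral (torsion) angle of four atom positions
#'
#' Signed angle in (-pi, pi] about the p2-p3 axis, by the atan2
#' convention (0 is cis).
#'
#' @param p1,p2,p3,p4 coordinate vectors.
#' @return angle in radians.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m <- b2 / sqrt(sum(b2^2))
  atan2(sum(vcross(n1, n2) * m), sum(n1 * n2))
}

# dphi/dx for the four dihedral atoms; returns 4 x 3 matrix.
dihedral_gradient_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  g1 <- -nb2 / sum(n1^2) * n1
  g4 <-  nb2 / sum(n2^2) * n2
  s12 <- sum(b1 * b2) / sum(b2^2)
  s32 <- sum(b3 * b2) / sum(b2^2)
  g2 <- -(1 + s12) * g1 + s32 * g4
  g3 <- s12 * g1 - (1 + s32) * g4
  rbind(g1, g2, g3, g4)
}

# dtheta/dx for the three angle atoms (j central); returns 3 x 3 matrix.
angle_gradient_rows <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  uh <- u / nu; vh <- v / nv
  cosv <- sum(uh * vh)
  sinv <- sqrt(max(0, 1 - cosv^2))
  if (sinv < 1e-8)
    stop("collinear atom triple: angle gradient undefined")
  gi <- (cosv * uh - vh) / (nu * sinv)
  gk <- (cosv * vh - uh) / (nv * sinv)
  rbind(gi, -(gi + gk), gk)
}

# --- energy and gradient --------------------------------------------------

#' Force-field energy of a geometry
#'
#' @param ff a [forcefield()].
#' @param g a [geometry()] with matching atom count.
#' @return scalar energy, kcal/mol (zero when every term sits at its
#'   minimum).
#' @export
ff_energy <- function(ff, g) {
  check_natoms(ff, g)
  x <- g$coords
  pref <- prefactor(ff$k_convention)
  e <- 0
  b <- ff$bonds
  for (t in seq_len(nrow(b))) {
    r <- sqrt(sum((x[b$i[t], ] - x[b$j[t], ])^2))
    e <- e + if (b$style[t] == "morse") {
      b$de[t] * (1 - exp(-b$alpha[t] * (r - b$re[t])))^2
    } else {
      pref * b$k[t] * (r - b$re[t])^2
    }
  }
  a <- ff$angles
  for (t in seq_len(nrow(a))) {
    th <- angle_between(x[a$i[t], ], x[a$j[t], ], x[a$k[t], ])
    if (abs(sin(th)) < 1e-8)
      stop(sprintf("collinear angle triple (%d,%d,%d)", a$i[t], a$j[t], a$k[t]))
    e <- e + pref * a$ka[t] * (th - a$theta_e[t])^2
  }
  d <- ff$dihedrals
  for (t in seq_len(nrow(d))) {
    phi <- dihedral_angle(x[d$i[t], ], x[d$j[t], ], x[d$k[t], ], x[d$l[t], ])
    e <- e + d$kd[t] * (1 + cos(d$n[t] * phi - d$delta[t]))
  }
  e
}

#' Analytic Cartesian gradient of a force field
#'
#' @inheritParams ff_energy
#' @return numeric 3N vector, kcal/mol/A.
#' @export
ff_gradient <- function(ff, g) {
  check_natoms(ff, g)
  x <- g$coords
  pref <- prefactor(ff$k_convention)
  grad <- matrix(0, ff$natoms, 3)
  b <- ff$bonds
  for (t in seq_len(nrow(b))) {
    dx <- x[b$i[t], ] - x[b$j[t], ]
    r <- sqrt(sum(dx^2))
    dedr <- if (b$style[t] == "morse") {
      ee <- exp(-b$alpha[t] * (r - b$re[t]))
      2 * b$de[t] * (1 - ee) * b$alpha[t] * ee
    } else {
      2 * pref * b$k[t] * (r - b$re[t])
    }
    w <- dedr * dx / r
    grad[b$i[t], ] <- grad[b$i[t], ] + w
    grad[b$j[t], ] <- grad[b$j[t], ] - w
  }
  a <- ff$angles
  for (t in seq_len(nrow(a))) {
    th <- angle_between(x[a$i[t], ], x[a$j[t], ], x[a$k[t], ])
    dth <- angle_gradient_rows(x[a$i[t], ], x[a$j[t], ], x[a$k[t], ])
    dedt <- 2 * pref * a$ka[t] * (th - a$theta_e[t])
    ids <- c(a$i[t], a$j[t], a$k[t])
    grad[ids, ] <- grad[ids, ] + dedt * dth
  }
  d <- ff$dihedrals
  for (t in seq_len(nrow(d))) {
    ids <- c(d$i[t], d$j[t], d$k[t], d$l[t])
    phi <- dihedral_angle(x[ids[1], ], x[ids[2], ], x[ids[3], ], x[ids[4], ])
    dphi <- dihedral_gradient_rows(x[ids[1], ], x[ids[2], ], x[ids[3], ],
                                   x[ids[4], ])
    dedp <- -d$kd[t] * d$n[t] * sin(d$n[t] * phi - d$delta[t])
    grad[ids, ] <- grad[ids, ] + dedp * dphi
  }
  as.vector(t(grad))
}

#' @export
pes_energy.forcefield <- function(surface, g, ...) ff_energy(surface, g)

#' @export
pes_gradient.forcefield <- function(surface, g, ...) ff_gradient(surface, g)

# --- parameter / topology I/O --------------------------------------------

type_key <- function(...) {
  v <- c(...)
  rv <- rev(v)
  if (paste(v, collapse = "-") <= paste(rv, collapse = "-"))
    paste(v, collapse = "-") else paste(rv, collapse = "-")
}

#' Load a force field from parameter and topology files
#'
#' Parameter file: whitespace-separated keyed rows
#' `bond typeA typeB k re [De]`,
#' `angle typeA typeB typeC k theta_e_deg`,
#' `dihedral typeA typeB typeC typeD k n delta_deg`; `#` comments.
#' Topology file: `atom index element type` rows plus `bond i j`,
#' `angle i j k`, `dihedral i j k l` index tuples.  Units on disk:
#' kcal/mol, Angstrom, degrees.  Every topology tuple must resolve to a
#' parameter row by its (direction-insensitive) atom-type key.
#'
#' @param param_file,topology_file file paths.
#' @param bond_style `"harmonic"` or `"morse"`; `"morse"` requires De in
#'   the bond rows.
#' @param k_convention harmonic prefactor convention, see [morse_alpha()].
#' @return a [forcefield()].
#' @export
load_forcefield <- function(param_file, topology_file,
                            bond_style = c("harmonic", "morse"),
                            k_convention = c("half", "full")) {
  bond_style <- match.arg(bond_style)
  k_convention <- match.arg(k_convention)
  toks <- function(path) {
    ln <- readLines(path)
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    strsplit(ln[nzchar(ln)], "\\s+")
  }
  bond_par <- list(); angle_par <- list(); dihedral_par <- list()
  for (tk in toks(param_file)) {
    kind <- tk[1]
    if (kind == "bond") {
      bond_par[[type_key(tk[2], tk[3])]] <-
        list(k = as.numeric(tk[4]), re = as.numeric(tk[5]),
             de = if (length(tk) >= 6) as.numeric(tk[6]) else NA_real_)
    } else if (kind == "angle") {
      angle_par[[type_key(tk[2], tk[3], tk[4])]] <-
        list(ka = as.numeric(tk[5]), theta_e = as.numeric(tk[6]) * pi / 180)
    } else if (kind == "dihedral") {
      dihedral_par[[type_key(tk[2], tk[3], tk[4], tk[5])]] <-
        list(kd = as.numeric(tk[6]), n = as.integer(tk[7]),
             delta = as.numeric(tk[8]) * pi / 180)
    } else stop("unknown parameter record: ", kind)
  }
  el <- character(0); ty <- character(0)
  bi <- list(); ai <- list(); di <- list()
  for (tk in toks(topology_file)) {
    kind <- tk[1]
    if (kind == "atom") {
      k <- as.integer(tk[2]); el[k] <- tk[3]; ty[k] <- tk[4]
    } else if (kind == "bond") {
      bi[[length(bi) + 1]] <- as.integer(tk[2:3])
    } else if (kind == "angle") {
      ai[[length(ai) + 1]] <- as.integer(tk[2:4])
    } else if (kind == "dihedral") {
      di[[length(di) + 1]] <- as.integer(tk[2:5])
    } else stop("unknown topology record: ", kind)
  }
  if (any(is.na(el))) stop("topology atom list has gaps")
  lookup <- function(tbl, key, what) {
    p <- tbl[[key]]
    if (is.null(p))
      stop(sprintf("no %s parameters for type key '%s'", what, key))
    p
  }
  bonds <- do.call(rbind, lapply(bi, function(v) {
    p <- lookup(bond_par, type_key(ty[v[1]], ty[v[2]]), "bond")
    if (bond_style == "morse" && is.na(p$de))
      stop("Morse bond style requested but no D_e for key ",
           type_key(ty[v[1]], ty[v[2]]))
    data.frame(i = v[1], j = v[2], type = type_key(ty[v[1]], ty[v[2]]),
               style = bond_style, k = p$k, re = p$re, de = p$de)
  }))
  angles <- do.call(rbind, lapply(ai, function(v) {
    p <- lookup(angle_par, type_key(ty[v[1]], ty[v[2]], ty[v[3]]), "angle")
    data.frame(i = v[1], j = v[2], k = v[3],
               type = type_key(ty[v[1]], ty[v[2]], ty[v[3]]),
               ka = p$ka, theta_e = p$theta_e)
  }))
  dihedrals <- do.call(rbind, lapply(di, function(v) {
    key <- type_key(ty[v[1]], ty[v[2]], ty[v[3]], ty[v[4]])
    p <- lookup(dihedral_par, key, "dihedral")
    data.frame(i = v[1], j = v[2], k = v[3], l = v[4], type = key,
               kd = p$kd, n = p$n, delta = p$delta)
  }))
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          type = character(0),
                                          style = character(0), k = numeric(0),
                                          re = numeric(0), de = numeric(0))
  if (is.null(angles)) angles <- data.frame(i = integer(0), j = integer(0),
                                            k = integer(0), type = character(0),
                                            ka = numeric(0),
                                            theta_e = numeric(0))
  if (is.null(dihedrals)) dihedrals <- data.frame(i = integer(0), j = integer(0),
                                                  k = integer(0), l = integer(0),
                                                  type = character(0),
                                                  kd = numeric(0), n = integer(0),
                                                  delta = numeric(0))
  forcefield(el, bonds, angles, dihedrals, k_convention = k_convention)
}

#' The packaged ethanol force field
#'
#' Loads the ethanol fixture shipped with the package: the four Morse /
#' harmonic bond stretch rows (C-C, C-O, O-H, C-H with published re,
#' k_bond and De values) plus angle and dihedral parameters that are
#' synthetic stand-ins (clearly marked in the parameter file), since the
#' source force field's bending and torsion constants are not published
#' alongside the stretches.  Atom order: 3 methyl H, 2 methylene H,
#' methyl C, methylene C, O, hydroxyl H -- matching the contiguous
#' `"321111"` symmetry spec of [ethanol_symmetry()].
#'
#' @inheritParams load_forcefield
#' @return a [forcefield()] for the 9-atom ethanol molecule.
#' @export
ethanol_forcefield <- function(bond_style = c("morse", "harmonic"),
                               k_convention = c("half", "full")) {
  bond_style <- match.arg(bond_style)
  k_convention <- match.arg(k_convention)
  load_forcefield(
    system.file("extdata", "ethanol.params", package = "deltapes",
                mustWork = TRUE),
    system.file("extdata", "ethanol.top", package = "deltapes",
                mustWork = TRUE),
    bond_style = bond_style, k_convention = k_convention)
}

#' Permutational symmetry spec for the packaged ethanol fixture
#'
#' `"321111"` with contiguous classes: atoms 1-3 the methyl hydrogens,
#' 4-5 the methylene hydrogens, then C, C, O, hydroxyl H.
#'
#' @return a [symmetry_spec()].
#' @export
ethanol_symmetry <- function() {
  symmetry_spec("321111", natoms = 9,
                elements = c("H", "H", "H", "H", "H", "C", "C", "O", "H"))
}

# NERF placement: position X bonded to A (length r), angle X-A-B = theta,
# dihedral X-A-B-C = phi.
zmat_place <- function(A, B, C, r, theta, phi) {
  u1 <- (B - A) / sqrt(sum((B - A)^2))
  v <- C - B
  w <- v - sum(v * u1) * u1
  u2 <- w / sqrt(sum(w^2))
  u3 <- vcross(u1, u2)
  A + r * (cos(theta) * u1 + sin(theta) * (cos(phi) * u2 + sin(phi) * u3))
}

#' Ideal trans-ethanol geometry
#'
#' Builds a staggered trans conformation from internal coordinates that
#' sit exactly at the packaged force field's equilibrium bond lengths and
#' angles (dihedrals at the cosine-term minima), so it is a near-minimum
#' of [ethanol_forcefield()].  Atom order matches [ethanol_symmetry()].
#'
#' @return a [geometry()].
#' @export
ethanol_geometry <- function() {
  r_cc <- 1.5204; r_co <- 1.4396; r_oh <- 0.9609; r_ch <- 1.0937
  a_cco <- 108.4 * pi / 180; a_coh <- 108.5 * pi / 180
  a_hcc <- 110.7 * pi / 180
  deg <- function(d) d * pi / 180
  x <- matrix(0, 9, 3)
  x[6, ] <- c(0, 0, 0)                       # methyl C
  x[7, ] <- c(r_cc, 0, 0)                    # methylene C
  # O bonded to C7, angle C6-C7-O8, placed in the xy-plane
  x[8, ] <- x[7, ] + r_co * c(-cos(a_cco), sin(a_cco), 0)
  x[9, ] <- zmat_place(x[8, ], x[7, ], x[6, ], r_oh, a_coh, deg(180))
  # methyl H: staggered w.r.t. O (dihedral H-C6-C7-O8 = 180, +-60)
  for (kk in 1:3)
    x[kk, ] <- zmat_place(x[6, ], x[7, ], x[8, ], r_ch, a_hcc,
                          deg(c(180, 60, -60)[kk]))
  # methylene H: dihedral H-C7-C6-H1 = -60 / +60 (H1 is anti to O)
  x[4, ] <- zmat_place(x[7, ], x[6, ], x[1, ], r_ch, a_hcc, deg(-60))
  x[5, ] <- zmat_place(x[7, ], x[6, ], x[1, ], r_ch, a_hcc, deg(60))
  geometry(c("H", "H", "H", "H", "H", "C", "C", "O", "H"), x,
           comment = "ideal staggered trans-ethanol")
}
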