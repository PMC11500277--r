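quadratic_surface <- function(center, k = 7.5) {
  function_surface(
    energy_fn = function(g) k * sum((g$coords - center)^2),
    gradient_fn = function(g) as.vector(t(2 * k * (g$coords - center))),
    natoms = nrow(center), energy_unit = "cm-1")
}

test_that("optimization recovers the minimum of a quadratic surface", {
  set.seed(421)
  center <- matrix(stats::rnorm(9, sd = 1.5), 3, 3)
  center <- center + 3 * diag(3)      # keep atoms apart
  surf <- quadratic_surface(center)
  start <- geometry(c("O", "H", "H"), center + matrix(stats::rnorm(9, sd = 0.3), 3, 3))
  sp <- optimize_geometry(surf, start, tol = 1e-8)
  expect_lt(max(abs(sp$geometry$coords - center)), 1e-8)
  expect_lt(sp$grad_norm, 1e-8)
})

test_that("force-field optimization descends and converges tightly", {
  set.seed(422)
  ff <- ethanol_forcefield()
  start <- perturbed_ethanol(sd = 0.08)
  e_start <- ff_energy(ff, start)
  sp <- optimize_geometry(ff, start, tol = 1e-6)
  expect_lt(sp$grad_norm, 1e-6)
  expect_lte(sp$energy, e_start)
  expect_equal(sp$label, "minimum")

  pts <- list(trans = sp, shifted = sp)
  tab <- relative_energetics(pts, energy_unit = "kcal/mol")
  expect_equal(tab$kcal_mol, c(0, 0))
  expect_equal(tab$cm1, c(0, 0))
})

test_that("diatomic Hessian contains the analytic stretch curvature", {
  ff <- diatomic_ff("harmonic", k = 551.9110, re = 1.5204, de = 82.69,
                    elements = c("C", "C"))
  g <- geometry(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 1.5204)))
  H <- hessian(ff, g, step = 0.001)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  # stretch eigenvalue of the Cartesian Hessian is 2 * d2V/dr2 = 2k (half-k)
  expect_equal(max(ev), 2 * 551.9110, tolerance = 1e-5)
})

test_that("the Hessian at a minimum is positive semidefinite and step-converged", {
  ff <- ethanol_forcefield()
  sp <- optimize_geometry(ff, ethanol_geometry(), tol = 1e-8)
  H <- hessian(ff, sp$geometry, step = 0.002)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-4 * max(ev))
  masses <- atomic_masses(sp$geometry$elements)
  f1 <- physical_frequencies(normal_modes(hessian(ff, sp$geometry, step = 0.002),
                                          masses))
  f2 <- physical_frequencies(normal_modes(hessian(ff, sp$geometry, step = 0.001),
                                          masses))
  expect_lt(max(abs(f1 - f2)), 0.1)
  expect_warning(hessian(ff, sp$geometry, step = 1e-8), "noise")
})

test_that("normal-mode frequencies obey closed forms and scaling laws", {
  # zero Hessian -> all zero frequencies
  z <- matrix(0, 6, 6); attr(z, "energy_unit") <- "cm-1"
  expect_equal(normal_modes(z, c(1, 1))$frequencies, rep(0, 6))

  # doubling all masses divides every frequency by sqrt(2)
  ff <- ethanol_forcefield()
  sp <- optimize_geometry(ff, ethanol_geometry())
  H <- hessian(ff, sp$geometry)
  m <- atomic_masses(sp$geometry$elements)
  f1 <- normal_modes(H, m)$frequencies
  f2 <- normal_modes(H, 2 * m)$frequencies
  expect_equal(f2, f1 / sqrt(2), tolerance = 1e-8)

  # Morse O-H diatomic: nu = (alpha / 2 pi c) * sqrt(2 De / mu)
  ffd <- diatomic_ff("morse")
  gd <- geometry(c("O", "H"), rbind(c(0, 0, 0), c(0, 0, 0.9609)))
  nm <- normal_modes(hessian(ffd, gd, step = 0.001), atomic_masses(c("O", "H")))
  alpha <- morse_alpha(1056.6764, 110.66)
  mu <- prod(atomic_masses(c("O", "H"))) / sum(atomic_masses(c("O", "H"))) *
    deltapes::pes_constants$amu_to_kg
  de_j <- 110.66 * deltapes::pes_constants$kcalmol_to_joule
  nu_closed <- alpha * 1e10 * sqrt(2 * de_j / mu) /
    (2 * pi * deltapes::pes_constants$speed_of_light) / 100
  expect_lt(abs(max(nm$frequencies) - nu_closed), 1)
})

test_that("frequency MAE is the index-matched mean absolute difference", {
  expect_equal(frequency_mae(c(100, 200), c(100, 200)), 0)
  expect_equal(frequency_mae(c(100, 200), c(110, 210)), 10)
  expect_equal(frequency_mae(c(100, 200), c(110, 190)), 10)
  expect_error(frequency_mae(1:3, 1:4), "length")
})

test_that("torsion scans reproduce closed-form barriers and periodicity", {
  g <- optimize_geometry(ethanol_forcefield(), ethanol_geometry())$geometry
  pure <- function_surface(function(gg) {
    phi <- dihedral_angle(gg$coords[1, ], gg$coords[6, ],
                          gg$coords[7, ], gg$coords[8, ])
    500 * (1 + cos(3 * phi))
  }, natoms = 9, energy_unit = "cm-1")
  ts <- torsion_scan(pure, g, c(1, 6, 7, 8), rotor_atoms = 1:3,
                     grid = seq(0, 360, by = 2))
  expect_equal(ts$barrier, 1000, tolerance = 1e-9)  # 2 * k_dihedral
  # 120-degree periodicity for a 3-fold rotor
  e <- ts$energy_rel
  expect_lt(max(abs(e[1:60] - e[61:120])), 1e-6)
  # periodic closure over a full turn
  expect_lt(abs(e[1] - e[181]), 1e-8)

  # on the force field, a rigid methyl rotation changes only dihedral terms,
  # so the scan equals the dihedral-term contribution exactly
  ff <- ethanol_forcefield()
  nob <- ff; nob$bonds <- ff$bonds[0, ]; nob$angles <- ff$angles[0, ]
  full <- torsion_scan(ff, g, c(1, 6, 7, 8), 1:3, grid = seq(0, 120, by = 5))
  dih_only <- torsion_scan(nob, g, c(1, 6, 7, 8), 1:3,
                           grid = seq(0, 120, by = 5))
  expect_equal(full$energy_rel, dih_only$energy_rel, tolerance = 1e-9)

  expect_error(torsion_scan(ff, g, c(1, 6, 7, 8), rotor_atoms = c(1, 6)),
               "axis atom")
})

test_that("relaxed scans lie at or below the rigid profile", {
  ff <- ethanol_forcefield()
  g <- optimize_geometry(ff, ethanol_geometry())$geometry
  grid <- c(20, 60)
  rigid <- torsion_scan(ff, g, c(1, 6, 7, 8), 1:3, grid = grid)
  relaxed <- torsion_scan(ff, g, c(1, 6, 7, 8), 1:3, grid = grid,
                          mode = "relaxed")
  expect_equal(relaxed$mode, "relaxed")
  # relaxation can only lower the absolute energy at each grid point
  expect_true(all(relaxed$energy <= rigid$energy + 1e-6))
})

test_that("gradient fidelity metrics match hand-computed values", {
  v <- stats::rnorm(27)
  expect_equal(gradient_fidelity(v, v), list(cos_theta = 1, mae = 0))
  expect_equal(gradient_fidelity(v, -v)$cos_theta, -1)
  e1 <- c(1, rep(0, 26)); e2 <- c(0, 1, rep(0, 25))
  gf <- gradient_fidelity(e1, e2)
  expect_equal(gf$cos_theta, 0)
  expect_equal(gf$mae, 2 / 27)
  expect_warning(gf0 <- gradient_fidelity(rep(0, 27), e1), "zero-norm")
  expect_true(is.na(gf0$cos_theta))
  expect_equal(gf0$mae, 1 / 27)
})
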