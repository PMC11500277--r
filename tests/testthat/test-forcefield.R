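test_that("morse_alpha matches the curvature-matching closed forms", {
  expect_equal(morse_alpha(1056.6764, 110.66), sqrt(1056.6764 / 221.32))
  expect_equal(round(morse_alpha(1056.6764, 110.66), 3), 2.185)
  expect_equal(morse_alpha(2 * 110.66, 110.66), 1)
  expect_equal(morse_alpha(100, 50, "full"), sqrt(2))
  expect_error(morse_alpha(-1, 10), "positive")

  # second derivative at r_e: Morse gives 2*De*alpha^2, harmonic 2*pref*k;
  # both conventions must agree bond by bond
  tab <- data.frame(k = c(551.9110, 1056.6764, 577.2346, 742.5561),
                    de = c(82.69, 110.66, 85.56, 98.71))
  for (conv in c("half", "full")) {
    pref <- if (conv == "half") 0.5 else 1.0
    a <- morse_alpha(tab$k, tab$de, conv)
    expect_lt(max(abs(2 * tab$de * a^2 - 2 * pref * tab$k)), 1e-10)
  }
})

test_that("bond terms hit their minimum, dissociation limit and harmonic limit", {
  ffm <- diatomic_ff("morse", k = 551.9110, re = 1.5204, de = 82.69,
                     elements = c("C", "C"))
  at <- function(r) geometry(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, r)))
  expect_equal(ff_energy(ffm, at(1.5204)), 0)
  expect_equal(ff_energy(ffm, at(500)), 82.69, tolerance = 1e-10)

  ffh <- diatomic_ff("harmonic", k = 551.9110, re = 1.5204, de = 82.69,
                     elements = c("C", "C"))
  # agreement to second order: |E_h - E_m| <= C * dr^3 near r_e
  drs <- c(0.01, 0.005, 0.0025)
  gap <- vapply(drs, function(dr)
    abs(ff_energy(ffh, at(1.5204 + dr)) - ff_energy(ffm, at(1.5204 + dr))),
    numeric(1))
  expect_lt(max(gap / drs^3), 600)   # bounded cubic coefficient
  # identical curvature: the gap scales as dr^3 (ratio ~8 on halving)
  expect_equal(gap[1] / gap[2], 8, tolerance = 0.1)
})

test_that("the packaged ethanol fixture loads with the published stretches", {
  ff <- ethanol_forcefield()
  expect_equal(nrow(ff$bonds), 8)
  expect_equal(sum(ff$bonds$type == "CT-HC"), 5)
  ch <- ff$bonds[ff$bonds$type == "CT-HC", ][1, ]
  expect_equal(ch$re, 1.0937)
  expect_equal(ch$k, 742.5561)
  expect_equal(ch$de, 98.71)
  cc <- ff$bonds[ff$bonds$type == "CT-CT", ][1, ]
  expect_equal(cc$re, 1.5204)
  expect_equal(nrow(ff$angles), 13)
  expect_equal(nrow(ff$dihedrals), 12)
  expect_true(all(ff$dihedrals$n == 3))
})

test_that("missing parameters raise a lookup error naming the type key", {
  params <- withr::local_tempfile(fileext = ".params")
  topo <- withr::local_tempfile(fileext = ".top")
  writeLines("bond CT CT 500 1.5 80", params)
  writeLines(c("atom 1 C CT", "atom 2 C CT", "atom 3 O OX",
               "bond 1 2", "bond 2 3"), topo)
  expect_error(load_forcefield(params, topo), "CT-OX")
})

test_that("force-field gradients match finite differences on random geometries", {
  set.seed(419)
  for (style in c("morse", "harmonic")) {
    ff <- ethanol_forcefield(bond_style = style)
    for (i in 1:5) {
      g <- perturbed_ethanol(sd = 0.06)
      ga <- ff_gradient(ff, g)
      gn <- deltapes:::numeric_gradient(ff, g)
      expect_lt(max(abs(ga - gn)), 1e-6 * sqrt(sum(ga^2)))
    }
  }
})

test_that("force-field energy is invariant under rigid motion and H swaps", {
  set.seed(420)
  ff <- ethanol_forcefield()
  g <- perturbed_ethanol()
  e0 <- ff_energy(ff, g)
  for (i in 1:5) {
    moved <- translate_geometry(rotate_geometry(g, random_rotation()),
                                stats::rnorm(3))
    expect_lt(abs(ff_energy(ff, moved) - e0), 1e-10 * max(1, abs(e0)))
  }
  grp <- build_permutation_group(ethanol_symmetry())
  for (i in seq_len(grp$order)) {
    gp <- apply_permutation(g, grp$atom_perms[i, ])
    expect_lt(abs(ff_energy(ff, gp) - e0), 1e-10 * max(1, abs(e0)))
  }
  # net force and torque vanish
  ga <- matrix(ff_gradient(ff, g), 9, 3, byrow = TRUE)
  expect_lt(max(abs(colSums(ga))), 1e-9)
  torque <- colSums(t(vapply(1:9, function(a)
    deltapes:::vcross(g$coords[a, ], -ga[a, ]), numeric(3))))
  expect_lt(max(abs(torque)), 1e-9)
})

test_that("an isolated dihedral term is exactly 2*pi/n periodic", {
  ff <- forcefield(c("C", "C", "C", "C"), empty_bonds, empty_angles,
                   data.frame(i = 1L, j = 2L, k = 3L, l = 4L, type = "X",
                              kd = 2.5, n = 3L, delta = 0))
  base <- geometry(rep("C", 4),
                   rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0),
                         c(1.5, 0.8, 0.6)))
  e_at <- function(rot) {
    x <- deltapes:::rotate_about_axis(base$coords, 4, base$coords[2, ],
                                      base$coords[3, ], rot)
    ff_energy(ff, geometry(rep("C", 4), x))
  }
  for (phi in seq(0, 2 * pi, length.out = 7))
    expect_equal(e_at(phi), e_at(phi + 2 * pi / 3), tolerance = 1e-10)
})

test_that("collinear angle triples raise a numerical-geometry error", {
  ff <- forcefield(c("C", "C", "C"), empty_bonds,
                   data.frame(i = 1L, j = 2L, k = 3L, type = "X",
                              ka = 50, theta_e = 1.9),
                   empty_dihedrals)
  g <- geometry(rep("C", 3), rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))
  expect_error(ff_energy(ff, g), "collinear")
})
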